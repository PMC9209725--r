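# Plain-text model and config input/output.
#
# Models can be exported to (and re-imported from) the XPPAUT .ode dialect,
# which allows cross-validation of the shipped models against external
# continuation tools. Parameter/config files are flat `key = value` text.

#' Export a model as XPPAUT-dialect .ode text
#'
#' Writes one `d<state>/dt=<expr>` line per state, fixed (auxiliary)
#' quantities as `name=expr` lines, conserved totals as `aux` lines,
#' `init` and `par` lines. The arithmetic subset used by the shipped models
#' (`+ - * / ^ ( ) sqrt`) is shared between R and XPPAUT, so expressions are
#' emitted verbatim; any other function call is an error.
#'
#' @param model A [model_spec()].
#' @param file Optional path; when given the text is also written there.
#' @return The .ode text as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
export_ode <- function(model, file = NULL) {
  check_exportable(model)
  lines <- c(
    paste0("# ", model$name),
    if (length(model$aux)) paste0(names(model$aux), "=", unname(model$aux)),
    paste0("d", model$state_names, "/dt=", unname(model$rhs_text)),
    if (!is.null(model$init)) {
      paste0("init ", model$state_names, "=",
             format(unname(model$init), digits = 15, scientific = FALSE,
                    trim = TRUE))
    },
    paste0("par ", names(model$params), "=",
           vapply(unname(model$params), format, "", digits = 15)),
    vapply(model$conserved, function(cl) {
      w <- cl$weights[cl$weights != 0]
      terms <- paste0(ifelse(w == 1, "", paste0(w, "*")), names(w))
      paste0("aux ", cl$label, "=", paste(terms, collapse = "+"))
    }, ""),
    "done")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

check_exportable <- function(model) {
  ok_funs <- c("+", "-", "*", "/", "^", "(", "sqrt", "exp", "log")
  for (s in c(model$aux, model$rhs_text)) {
    calls <- setdiff(all.names(parse(text = s)[[1]]),
                     all.vars(parse(text = s)[[1]]))
    bad <- setdiff(calls, ok_funs)
    if (length(bad)) {
      stop_config("RHS construct not exportable to .ode: ",
                  paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Parse XPPAUT-dialect .ode text back into a model
#'
#' Mini-parser for the subset emitted by [export_ode()]: `d<state>/dt=`
#' equations, fixed quantities, `init`, `par` and `aux` lines. Round-tripping
#' a model through text and re-integrating reproduces the original
#' trajectory to integrator precision.
#'
#' @param x Path to an .ode file, or the text itself as a character vector.
#' @param name Model name (default: taken from the leading comment).
#' @return A [model_spec()] (conserved-total `aux` lines are re-attached as
#'   auxiliary outputs, not conservation laws).
#' @export
parse_ode <- function(x, name = NULL) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  states <- character(); rhs <- character()
  params <- numeric(); inits <- numeric()
  aux <- character()
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      if (is.null(name)) name <- trimws(sub("^#", "", ln))
      next
    }
    if (ln == "done") break
    if (grepl("^d[A-Za-z]", ln) && grepl("/dt=", ln, fixed = TRUE)) {
      st <- sub("^d([A-Za-z][A-Za-z0-9_]*)/dt=.*$", "\\1", ln)
      ex <- sub("^d[A-Za-z][A-Za-z0-9_]*/dt=", "", ln)
      states <- c(states, st)
      rhs[st] <- ex
    } else if (grepl("^init ", ln)) {
      kv <- strsplit(sub("^init ", "", ln), "=", fixed = TRUE)[[1]]
      inits[trimws(kv[1])] <- as.numeric(kv[2])
    } else if (grepl("^par ", ln)) {
      kv <- strsplit(sub("^par ", "", ln), "=", fixed = TRUE)[[1]]
      params[trimws(kv[1])] <- as.numeric(kv[2])
    } else if (grepl("^aux ", ln)) {
      kv <- strsplit(sub("^aux ", "", ln), "=", fixed = TRUE)[[1]]
      # conserved-total reporting line; keep as a trailing auxiliary
      next
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      aux[trimws(kv[1])] <- paste(kv[-1], collapse = "=")
    }
  }
  if (!length(states)) stop_config("no d<state>/dt lines found")
  model_spec(name %||% "parsed_ode", states, params, rhs, aux = aux,
             init = if (length(inits)) inits[states])
}

#' Read a flat key = value config file
#'
#' Lines of the form `name = value`; `#` starts a comment; optional
#' namespaces such as `m1.k_aerk` can be selected and stripped with
#' `namespace`.
#'
#' @param path File path.
#' @param namespace Optional namespace prefix (without the dot).
#' @return Named numeric vector.
#' @export
read_params <- function(path, namespace = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop_config("malformed config line(s): ",
                            paste(lines[bad], collapse = "; "))
  out <- vapply(kv, function(p) as.numeric(trimws(p[2])), numeric(1))
  names(out) <- vapply(kv, function(p) trimws(p[1]), "")
  if (any(is.na(out))) {
    stop_config("non-numeric value for: ",
                paste(names(out)[is.na(out)], collapse = ", "))
  }
  if (!is.null(namespace)) {
    pre <- paste0(namespace, ".")
    out <- out[startsWith(names(out), pre)]
    names(out) <- substring(names(out), nchar(pre) + 1L)
  }
  out
}

#' Write a flat key = value config file
#'
#' @param params Named numeric vector.
#' @param path File path.
#' @param namespace Optional namespace prefix to prepend.
#' @param header Optional comment line(s) written at the top.
#' @export
write_params <- function(params, path, namespace = NULL, header = NULL) {
  nm <- names(params)
  if (!is.null(namespace)) nm <- paste0(namespace, ".", nm)
  lines <- c(if (!is.null(header)) paste0("# ", header),
             paste0(nm, " = ", format(unname(params), digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' Read perturbation scenarios from an ini-style file
#'
#' Sections `[name]` hold `param = value` overrides plus the reserved keys
#' `description` and `expect`.
#'
#' @param path File path.
#' @return Named list of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur <- NULL; ov <- list(); desc <- ""; expect <- NULL
  flush <- function() {
    if (!is.null(cur)) {
      out[[cur]] <<- scenario(cur, ov, description = desc, expect = expect)
    }
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      cur <- gsub("^\\[|\\]$", "", ln)
      ov <- list(); desc <- ""; expect <- NULL
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (key == "description") desc <- val
      else if (key == "expect") expect <- val
      else ov[[key]] <- as.numeric(val)
    }
  }
  flush()
  out
}

#' Write a trajectory as TSV
#'
#' One `time` column plus one column per state; a `#` header records
#' provenance (model name, optional seed).
#'
#' @param traj A `trajectory`.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# model=", traj$model_name,
                    if (!is.null(seed)) paste0(" seed=", seed)), con)
  utils::write.table(
    data.frame(time = traj$time, traj$states, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bifurcation diagram as TSV
#'
#' Long format: control value, one row per equilibrium, with all state
#' coordinates and a stability flag; saddle nodes summarized in `#` header
#' lines.
#'
#' @param diagram A `bifurcation_diagram`.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_diagram <- function(diagram, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# control=", diagram$control,
                    if (!is.null(seed)) paste0(" seed=", seed)), con)
  if (nrow(diagram$saddle_nodes)) {
    writeLines(paste0("# ", diagram$saddle_nodes$label, " ",
                      format(diagram$saddle_nodes$value, digits = 10)), con)
  }
  rows <- do.call(rbind, lapply(seq_along(diagram$values), function(i) {
    eqs <- diagram$equilibria[[i]]
    if (!length(eqs)) return(NULL)
    do.call(rbind, lapply(eqs, function(e) {
      data.frame(control = diagram$values[i], t(e$state),
                 stable = e$stable, check.names = FALSE)
    }))
  }))
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
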