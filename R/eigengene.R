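# Gene-set eigengene analysis: summarize a gene set per sample by the first
# principal component of its standardized expression submatrix, then
# correlate that summary with a sample trait (disease status, age, ...).

#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) to share the same distribution: the mean of
#' the order statistics across columns. Ties are handled by averaging the
#' reference values over tied ranks. Optionally applies `log2(x + 1)`
#' afterwards.
#'
#' @param x Numeric matrix (genes x samples).
#' @param log2 If `TRUE`, log2(x + 1) is applied after normalization.
#' @return Matrix of the same shape with dimnames preserved.
#' @examples
#' quantile_normalize(matrix(c(1, 3, 4, 2), 2, 2))  # rows: 1.5/3.5, 3.5/1.5
#' @export
quantile_normalize <- function(x, log2 = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_config("expression matrix must be finite numeric")
  }
  if (log2 && any(x < 0)) {
    stop_config("negative values: log transform not applicable")
  }
  out <- limma::normalizeQuantiles(x)
  if (log2) out <- base::log2(out + 1)
  dimnames(out) <- dimnames(x)
  out
}

#' Compute the eigengene of a gene set
#'
#' The rows of the gene-set submatrix are z-scored gene-wise and the first
#' principal component across samples (first right singular vector) is taken
#' as the eigengene. Its sign is oriented so that the correlation with the
#' set's mean standardized profile is non-negative, which keeps results
#' reproducible across runs and platforms. Scores are standardized to zero
#' mean and unit variance.
#'
#' @param x Numeric expression matrix (genes x samples, rownames = gene ids).
#' @param gene_set Character vector of gene ids (or a list with elements
#'   `name` and `genes`).
#' @param min_genes Minimum number of set genes that must be present.
#' @return An `eigengene_result`: list with `scores` (per sample, unit
#'   variance), `var_explained`, `orientation`, `n_genes_used`, `n_samples`,
#'   `missing_genes`.
#' @export
compute_eigengene <- function(x, gene_set, min_genes = 2) {
  set_name <- NULL
  if (is.list(gene_set) && !is.null(gene_set$genes)) {
    set_name <- gene_set$name
    gene_set <- gene_set$genes
  }
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop_config("matrix must have gene rownames")
  present <- intersect(gene_set, rownames(x))
  missing <- setdiff(gene_set, rownames(x))
  if (length(present) < min_genes) {
    stop_config("gene set has fewer than ", min_genes,
                " genes in the matrix; missing: ",
                paste(utils::head(missing, 10), collapse = ", "))
  }
  sub <- x[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene row(s) dropped",
            call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < min_genes) stop_config("too few variable genes in set")
  }
  z <- t(scale(t(sub)))                      # gene-wise z-scores
  sv <- svd(z)
  scores <- sv$v[, 1]
  var_explained <- sv$d[1]^2 / sum(sv$d^2)
  orientation <- 1
  mean_profile <- colMeans(z)
  if (stats::cor(scores, mean_profile) < 0) {
    orientation <- -1
    scores <- -scores
  }
  scores <- as.numeric(scale(scores))        # zero mean, unit variance
  names(scores) <- colnames(x)
  structure(list(scores = scores, var_explained = var_explained,
                 orientation = orientation, n_genes_used = nrow(z),
                 n_samples = ncol(x), missing_genes = missing,
                 set_name = set_name),
            class = "eigengene_result")
}

#' @export
print.eigengene_result <- function(x, ...) {
  cat("<eigengene_result>",
      if (!is.null(x$set_name)) paste0(" set = ", x$set_name), "\n", sep = "")
  cat(sprintf("  %d genes x %d samples; variance explained %.3f\n",
              x$n_genes_used, x$n_samples, x$var_explained))
  invisible(x)
}

#' Pearson correlation with Student asymptotic p value
#'
#' Computes the Pearson correlation between eigengene scores and a sample
#' trait together with its asymptotic p value from the Student t
#' distribution: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom, two-sided. A binary 0/1 trait gives the point-biserial
#' correlation, which is the same quantity.
#'
#' @param scores Numeric vector (e.g. eigengene scores).
#' @param trait Numeric or 0/1 vector of the same length, non-constant.
#' @return List with `r`, `p`, `t`, `df`, `n`, and `exact` (`TRUE` when
#'   `|r| = 1` and `p` is reported as exactly 0).
#' @examples
#' correlate_trait(c(1, 2, 3, 4), c(0, 0, 1, 1))  # r = 2/sqrt(5), p ~ 0.106
#' @export
correlate_trait <- function(scores, trait) {
  if (inherits(scores, "eigengene_result")) scores <- scores$scores
  n <- length(scores)
  if (length(trait) != n) stop_config("trait length must match sample count")
  if (n < 3) stop_config("need at least 3 samples")
  if (stats::sd(trait) == 0 || stats::sd(scores) == 0) {
    stop_config("constant input: correlation undefined")
  }
  r <- stats::cor(scores, trait)
  df <- n - 2
  if (abs(r) >= 1 - 1e-15) {
    return(list(r = sign(r), p = 0, t = Inf * sign(r), df = df, n = n,
                exact = TRUE))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(r = r, p = p, t = t, df = df, n = n, exact = FALSE)
}

#' Gene-set association table
#'
#' Applies [compute_eigengene()] and [correlate_trait()] to each gene set
#' and returns one row per set, mirroring the usual
#' dataset-by-gene-set association layout.
#'
#' @param x Expression matrix (genes x samples).
#' @param trait Per-sample trait (binary disease indicator or numeric).
#' @param gene_sets Named list of character vectors of gene ids.
#' @param file Optional path: write the table as TSV.
#' @return Data frame with columns `gene_set`, `n_genes`, `var_explained`,
#'   `r`, `p`.
#' @export
gene_set_association <- function(x, trait, gene_sets, file = NULL) {
  if (!length(gene_sets)) {
    out <- data.frame(gene_set = character(), n_genes = integer(),
                      var_explained = numeric(), r = numeric(),
                      p = numeric())
  } else {
    if (is.null(names(gene_sets))) {
      names(gene_sets) <- paste0("set", seq_along(gene_sets))
    }
    rows <- lapply(names(gene_sets), function(nm) {
      eg <- compute_eigengene(x, gene_sets[[nm]])
      ct <- correlate_trait(eg$scores, trait)
      data.frame(gene_set = nm, n_genes = eg$n_genes_used,
                 var_explained = eg$var_explained, r = ct$r, p = ct$p)
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Read gene sets from GMT or one-set-per-line text
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the plain
#' format is one gene id per line (a single unnamed set).
#'
#' @param path File path.
#' @param format `"gmt"` or `"list"` (default guessed from the extension).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "list"
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "gmt") {
    out <- lapply(lines, function(ln) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) stop_config("malformed GMT line: ", ln)
      stats::setNames(list(unique(parts[-(1:2)])), parts[1])
    })
    do.call(c, out)
  } else {
    list(set1 = unique(trimws(lines)))
  }
}

#' Read a genes-x-samples expression matrix from TSV
#'
#' First column = gene ids, header row = sample ids.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}
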