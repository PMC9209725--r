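# Synthetic data with the statistical structure the eigengene analysis
# assumes: a genes x samples matrix containing planted co-expression
# modules whose per-sample factors have an exact, specified Pearson
# correlation with a binary disease label, under additive Gaussian noise.

#' Generate a synthetic expression matrix with planted modules
#'
#' The binary trait is balanced 50/50. For each planted set, a per-sample
#' factor is built by an exact projection construction: a standard normal
#' vector is orthogonalized against the (standardized) trait and the two are
#' recombined as `r * trait_std + sqrt(1 - r^2) * noise_orth`, which makes
#' the sample Pearson correlation between factor and trait exactly the
#' requested value. Set genes are `loading * factor + N(0, noise_sd)`;
#' background genes are pure standard normal noise.
#'
#' @param n_genes Total number of genes (background included).
#' @param n_samples Number of samples (even; at least 4).
#' @param sets List of planted-set descriptions, each a list with `size`
#'   (number of genes), `loading` (factor loading scale) and `r` (target
#'   factor-trait correlation, in `[-1, 1]`).
#' @param noise_sd Standard deviation of the additive gene-level noise.
#' @param seed Integer seed; identical seeds give bit-identical output (the
#'   caller's RNG state is left untouched).
#' @return List with `matrix` (genes x samples), `trait` (0/1), `gene_sets`
#'   (named list of gene ids), `factors` (per-set planted factor), and
#'   `spec` (the arguments, as provenance metadata).
#' @examples
#' sim <- simulate_expression(100, 20, sets = list(list(size = 10,
#'   loading = 1, r = 0.5)), noise_sd = 0.3, seed = 1)
#' dim(sim$matrix)
#' @export
simulate_expression <- function(n_genes, n_samples,
                                sets = list(), noise_sd = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, n_samples >= 4, n_samples %% 2 == 0,
            noise_sd >= 0)
  used <- sum(vapply(sets, function(s) s$size, numeric(1)))
  if (used > n_genes) stop_config("planted sets larger than n_genes")
  for (s in sets) {
    if (abs(s$r) > 1) stop_config("target correlation must be in [-1, 1]")
  }
  with_preserved_seed(seed, {
    trait <- rep(c(0, 1), each = n_samples / 2)
    t_std <- as.numeric(scale(trait))
    gene_names <- sprintf("gene_%05d", seq_len(n_genes))
    mat <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                  dimnames = list(gene_names,
                                  sprintf("sample_%03d", seq_len(n_samples))))
    gene_sets <- list()
    factors <- list()
    offset <- 0
    for (i in seq_along(sets)) {
      s <- sets[[i]]
      z <- stats::rnorm(n_samples)
      z_orth <- z - sum(z * t_std) / sum(t_std^2) * t_std
      if (stats::sd(z_orth) == 0) {
        stop_config("degenerate orthogonal component; change the seed")
      }
      z_orth <- as.numeric(scale(z_orth))
      f <- s$r * t_std + sqrt(1 - s$r^2) * z_orth
      idx <- offset + seq_len(s$size)
      offset <- offset + s$size
      noise <- matrix(stats::rnorm(s$size * n_samples, sd = noise_sd),
                      s$size, n_samples)
      mat[idx, ] <- s$loading * matrix(f, s$size, n_samples, byrow = TRUE) +
        noise
      nm <- s$name %||% paste0("planted_", i)
      gene_sets[[nm]] <- gene_names[idx]
      factors[[nm]] <- f
    }
    list(matrix = mat, trait = trait, gene_sets = gene_sets,
         factors = factors,
         spec = list(n_genes = n_genes, n_samples = n_samples, sets = sets,
                     noise_sd = noise_sd, seed = seed))
  })
}

#' Integrate a model and add observation noise
#'
#' Produces noisy trajectory fixtures for testing the robustness of state
#' classification: the deterministic solution plus i.i.d. Gaussian
#' observation noise on every state reading.
#'
#' @param model A [model_spec()].
#' @param obs_noise_sd Observation noise standard deviation (0 returns the
#'   deterministic trajectory unchanged).
#' @param seed Integer seed (caller's RNG state preserved).
#' @param ... Passed to [integrate_model()] (`init`, `times`, `input_step`).
#' @return A `trajectory` whose `states` carry the added noise; the clean
#'   states are kept in `$states_clean`.
#' @export
simulate_noisy_trajectory <- function(model, obs_noise_sd = 0, seed = 1,
                                      ...) {
  traj <- integrate_model(model, ...)
  traj$states_clean <- traj$states
  if (obs_noise_sd > 0) {
    noise <- with_preserved_seed(seed, {
      matrix(stats::rnorm(length(traj$states), sd = obs_noise_sd),
             nrow(traj$states), ncol(traj$states))
    })
    traj$states <- traj$states + noise
  }
  traj
}
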