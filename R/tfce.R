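#' Threshold-free cluster enhancement and permutation inference
#'
#' TFCE integrates, over all supra-threshold levels h, the size of the
#' connected component containing each element (extent, exponent E) times
#' the level height (exponent H): `TFCE(p) = sum_k e(h_k, p)^E h_k^H dh`
#' with `h_k = k dh`. It needs no arbitrary cluster-forming threshold and
#' does not assume stationary smoothness. Family-wise error control uses
#' the permutation distribution of the image-wide maximum enhanced value
#' (Freedman-Lane residual permutation under nuisance covariates).
#'
#' @name tfce_inference
NULL

#' TFCE parameters
#'
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2.0).
#' @param dh integration step; `NULL` (default) means `max(|stat|)/100`,
#'   resolved when a map is enhanced and recorded in output metadata.
#' @return A `ctcov_tfce_params` list.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, dh = NULL) {
  stopifnot(E >= 0, H >= 0, is.null(dh) || dh > 0)
  structure(list(E = E, H = H, dh = dh), class = "ctcov_tfce_params")
}

#' Enhance a statistic map by TFCE
#'
#' Positive and negative tails are enhanced separately (on the negated map)
#' and the negative tail is returned with negative sign. Implemented with
#' an incremental union-find sweep over descending thresholds; correctness
#' is defined by per-threshold connected-component recomputation.
#'
#' @param stat numeric statistic vector over domain elements.
#' @param domain the domain providing adjacency.
#' @param params a [tfce_params()] object.
#' @return list with `enhanced` (numeric vector) and `dh` (step used).
#' @export
tfce_enhance <- function(stat, domain, params = tfce_params()) {
  stopifnot(inherits(domain, "ctcov_domain"),
            length(stat) == domain$n_elements, all(is.finite(stat)))
  dh <- params$dh
  if (is.null(dh)) {
    mx <- max(abs(stat))
    if (mx == 0) return(list(enhanced = numeric(length(stat)), dh = NA_real_))
    dh <- mx / 100
  }
  enh <- .tfce_enhance_cpp(as.numeric(stat), domain$edges,
                           params$E, params$H, dh)
  list(enhanced = enh, dh = dh)
}

#' Max-statistic permutation FWE inference on a contrast
#'
#' Freedman-Lane scheme: the reduced (nuisance-only: intercept plus
#' covariates) model is fitted, its residual rows are permuted, the reduced
#' fit is re-added, and the full-model contrast t-map of each permuted
#' dataset is TFCE-enhanced; the image-wide maximum is recorded. With no
#' covariates the reduced model is the intercept alone, equivalent to plain
#' group-label permutation for contrast statistics.
#' `p_fwe(p) = (1 + #permutation maxima >= TFCE_obs(p)) / (n_perm + 1)`.
#'
#' @param data a `ctcov_cohort` or subjects x elements matrix.
#' @param design a [make_design()] object.
#' @param domain the spatial domain.
#' @param params [tfce_params()].
#' @param n_perm number of random permutations (>= 1).
#' @param alpha significance level for the reported mask, in (0, 1).
#' @param rng_seed integer seed (permutations are deterministic given it).
#' @param tail `"pos"` (default; the enhanced positive tail is tested),
#'   `"neg"`, or `"both"` (maximum absolute enhanced value).
#' @return A `ctcov_inference` list: `t_obs`, `enhanced`, `p_fwe`,
#'   `sig_mask`, `max_dist`, `n_perm`, `alpha`, `tail`, `dh`, `params`,
#'   `dof`, `rng_seed`.
#' @export
permutation_fwe <- function(data, design, domain, params = tfce_params(),
                            n_perm = 1000, alpha = 0.05, rng_seed = 1,
                            tail = c("pos", "neg", "both")) {
  tail <- match.arg(tail)
  if (alpha <= 0 || alpha >= 1) stop("alpha outside (0,1)")
  stopifnot(n_perm >= 1)
  Y <- if (inherits(data, "ctcov_cohort")) data$thickness else as.matrix(data)
  stopifnot(nrow(Y) == nrow(design$X))
  X <- design$X
  cvec <- design$contrast
  obs <- ols_tmap(X, cvec, Y)
  # fix dh from the observed map so observed and permuted enhancements are
  # on the same integration grid
  pr <- params
  if (is.null(pr$dh)) {
    mx <- max(abs(obs$t))
    pr <- tfce_params(params$E, params$H,
                      dh = if (mx > 0) mx / 100 else 1)
  }
  side_stat <- function(enh) switch(tail,
    pos = enh, neg = -enh, both = abs(enh))
  enh_obs <- tfce_enhance(obs$t, domain, pr)$enhanced
  s_obs <- side_stat(enh_obs)

  # reduced (nuisance) model: intercept + covariates
  Z <- cbind(intercept = rep(1, nrow(X)))
  if (length(design$covariate_names))
    Z <- cbind(Z, X[, design$covariate_names, drop = FALSE])
  gam <- solve(crossprod(Z), crossprod(Z, Y))
  fitZ <- Z %*% gam
  Rz <- Y - fitZ

  max_dist <- numeric(n_perm)
  with_seed(rng_seed, {
    n <- nrow(Y)
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      Yb <- fitZ + Rz[pm, , drop = FALSE]
      tb <- ols_tmap(X, cvec, Yb)$t
      eb <- tfce_enhance(tb, domain, pr)$enhanced
      max_dist[b] <- max(side_stat(eb))
    }
  })
  p_fwe <- (1 + vapply(s_obs, function(v) sum(max_dist >= v), 0)) /
    (n_perm + 1)
  structure(list(t_obs = obs$t, enhanced = enh_obs, p_fwe = p_fwe,
                 sig_mask = p_fwe <= alpha, max_dist = max_dist,
                 n_perm = n_perm, alpha = alpha, tail = tail,
                 dh = pr$dh, params = pr, dof = obs$dof,
                 rng_seed = rng_seed),
            class = "ctcov_inference")
}

#' @export
print.ctcov_inference <- function(x, ...) {
  cat(sprintf(
    "<ctcov_inference> tail=%s n_perm=%d alpha=%g: %d/%d significant\n",
    x$tail, x$n_perm, x$alpha, sum(x$sig_mask), length(x$sig_mask)))
  invisible(x)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure: reject the k smallest p-values where
#' `k = max{i : p_(i) <= i q / m}`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return logical rejection vector aligned with `pvals`.
#' @export
bh_fdr <- function(pvals, q) {
  if (q <= 0 || q >= 1) stop("q outside (0,1)")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH") <= q
}
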