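#' Structural covariance networks
#'
#' The system-level mapping procedure: each subject's mean thickness is
#' subtracted from their parcel values (removing global thickness), each
#' parcel column is residualized against age, and parcels are correlated
#' across the subjects of a group. Starting from seed parcels at the peaks
#' of the significant thinning clusters, the seed map collects every parcel
#' with a significant positive correlation with the seed — the structural
#' counterpart of a functional seed-correlation map.
#'
#' @name structural_covariance
NULL

#' Subtract each subject's mean parcel value from their row
#' @param pm a [parcel_means()] object.
#' @return the parcel matrix with every row mean 0.
#' @export
center_subjects <- function(pm) {
  stopifnot(inherits(pm, "ctcov_parcel_matrix"), ncol(pm$values) >= 2)
  pm$values <- pm$values - rowMeans(pm$values)
  pm
}

#' Residualize every parcel column against age
#' @param pm a [parcel_means()] object.
#' @param age numeric age vector, one per subject.
#' @return the parcel matrix with each column replaced by the residuals of
#'   `column ~ 1 + age`.
#' @export
age_residualize <- function(pm, age) {
  stopifnot(inherits(pm, "ctcov_parcel_matrix"),
            length(age) == nrow(pm$values))
  if (var(age) == 0) stop("constant age")
  pm$values <- lm.fit(cbind(1, age), pm$values)$residuals
  dimnames(pm$values) <- list(NULL, pm$parcels$name)
  pm
}

#' Parcel-by-parcel Pearson correlation matrix for one group
#'
#' @param pm a (centered, residualized) [parcel_means()] object restricted
#'   to the subjects of one group.
#' @param group group label stored with the result.
#' @return A `ctcov_covariance`: `group`, `corr` (K x K), `n_subjects`,
#'   `undefined` (parcel ids with zero variance, whose entries are `NA`).
#' @export
covariance_matrix <- function(pm, group = "") {
  stopifnot(inherits(pm, "ctcov_parcel_matrix"), nrow(pm$values) >= 3)
  v <- apply(pm$values, 2, var)
  undefined <- which(v == 0)
  corr <- suppressWarnings(cor(pm$values))
  diag(corr) <- 1
  structure(list(group = group, corr = corr,
                 n_subjects = nrow(pm$values),
                 undefined = as.integer(undefined)),
            class = "ctcov_covariance")
}

#' Seed parcels at the peaks of significant clusters
#'
#' Clusters are the connected components of the significance mask; they are
#' ranked by their maximum enhanced statistic, and for each cluster the
#' element with the largest enhanced value (ties: lowest element id) names
#' a seed parcel. Distinct parcels are collected, one per cluster, until
#' `n_seeds` are found or clusters are exhausted.
#'
#' @param result a `ctcov_inference` from [permutation_fwe()].
#' @param domain the domain (for cluster connectivity).
#' @param parcellation the parcellation mapping peak elements to parcels.
#' @param n_seeds number of seed parcels wanted (default 2).
#' @return integer vector of parcel ids.
#' @export
peak_seed <- function(result, domain, parcellation, n_seeds = 2) {
  sig <- which(result$sig_mask)
  if (length(sig) == 0) stop("no significant peak")
  sub <- domain$edges[domain$edges[, 1] %in% sig &
                        domain$edges[, 2] %in% sig, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(sub), sig), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(sig) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  enh <- result$enhanced[sig]
  # rank clusters by their peak enhanced value, descending
  cl_peak <- tapply(seq_along(sig), comp, function(ix) {
    ix[order(-enh[ix], sig[ix])][1]
  })
  cl_max <- tapply(enh, comp, max)
  ord <- order(-cl_max)
  seeds <- integer(0)
  for (k in ord) {
    el <- sig[cl_peak[[k]]]
    pid <- parcellation$element_to_parcel[el]
    if (!(pid %in% seeds)) seeds <- c(seeds, pid)
    if (length(seeds) >= n_seeds) break
  }
  seeds
}

#' Parcels positively correlated with a seed parcel
#'
#' Members are the parcels j != seed with `r_sj > 0` and one-sided
#' p-value below `alpha`, where `t = r sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom. No multiplicity correction is applied.
#'
#' @param cov a [covariance_matrix()] result.
#' @param seed seed parcel id.
#' @param alpha significance level (default 0.05).
#' @param one_sided test positive correlations one-sidedly (default TRUE).
#' @return A `ctcov_seed_map`: `seed_parcel`, `members` (parcel ids,
#'   excluding the seed), `alpha`, `one_sided`, `r` (seed correlation row).
#' @export
seed_map <- function(cov, seed, alpha = 0.05, one_sided = TRUE) {
  stopifnot(inherits(cov, "ctcov_covariance"),
            seed >= 1, seed <= nrow(cov$corr))
  n <- cov$n_subjects
  if (n < 4) stop("too few subjects for correlation test")
  r <- cov$corr[seed, ]
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- pt(tt, df = n - 2, lower.tail = FALSE)
  if (!one_sided) p <- 2 * pmin(p, 1 - p)
  members <- which(r > 0 & p < alpha)
  members <- setdiff(members, seed)
  structure(list(seed_parcel = as.integer(seed),
                 members = as.integer(members),
                 alpha = alpha, one_sided = one_sided, r = r),
            class = "ctcov_seed_map")
}
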