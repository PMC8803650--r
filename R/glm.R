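#' Group designs and element-wise contrast t-maps
#'
#' The group model is a full-factorial (cell-means) design: one column per
#' group level plus centered nuisance covariates (age always for thickness;
#' age and total intracranial volume for volume-mode analyses — thickness
#' does not scale linearly with head size, so TIV is not a thickness
#' covariate; sex and education are never modeled). Contrasts are t-tests
#' between group means with a single pooled error variance per element.
#'
#' @name glm_stats
NULL

#' Construct a design for group contrasts
#'
#' @param covariates data.frame with a `group` column and any covariate
#'   columns named in `covariate_names`.
#' @param contrast named numeric vector of group weights, e.g.
#'   `c(CON = 1, AUD = -1)`; unnamed groups get weight 0. Nuisance
#'   covariate rows of the contrast are always 0.
#' @param covariate_names character vector of nuisance covariate column
#'   names (default `"age"`); covariates are mean-centered.
#' @param groups group levels in column order; default the order of
#'   appearance.
#' @return A `ctcov_design` list: `X` (n x p design matrix), `contrast`
#'   (length-p vector), `groups`, `covariate_names`, `contrast_name`,
#'   `dof` (n - rank).
#' @export
make_design <- function(covariates, contrast, covariate_names = "age",
                        groups = NULL) {
  stopifnot("group" %in% names(covariates))
  if (is.null(groups)) groups <- unique(covariates$group)
  stopifnot(all(covariates$group %in% groups),
            all(names(contrast) %in% groups))
  G <- sapply(groups, function(g) as.numeric(covariates$group == g))
  colnames(G) <- groups
  Z <- NULL
  if (length(covariate_names)) {
    stopifnot(all(covariate_names %in% names(covariates)))
    Z <- sapply(covariate_names, function(v) {
      x <- covariates[[v]]
      x - mean(x)
    })
    colnames(Z) <- covariate_names
  }
  X <- cbind(G, Z)
  cvec <- numeric(ncol(X))
  names(cvec) <- colnames(X)
  cvec[names(contrast)] <- contrast
  r <- qr(X)$rank
  if (r < ncol(X)) stop("rank-deficient design")
  structure(list(X = X, contrast = cvec, groups = groups,
                 covariate_names = covariate_names,
                 contrast_name = paste(
                   paste(names(contrast)[contrast > 0], collapse = "+"),
                   paste(names(contrast)[contrast < 0], collapse = "+"),
                   sep = ">"),
                 dof = nrow(X) - r),
            class = "ctcov_design")
}

# element-wise OLS t-statistics for contrast c on response matrix Y (n x m)
ols_tmap <- function(X, cvec, Y) {
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  dof <- nrow(X) - qr(X)$rank
  sigma2 <- colSums(res^2) / dof
  cxc <- drop(t(cvec) %*% XtXi %*% cvec)
  tval <- drop(cvec %*% beta) / sqrt(pmax(sigma2 * cxc, .Machine$double.xmin))
  list(t = tval, dof = dof, beta = beta)
}

#' Fit an element-wise group contrast t-map
#'
#' Ordinary least squares per element with a common design;
#' `t = c'b / sqrt(s2 c'(X'X)^-1 c)`. On a two-group design without
#' covariates this is exactly the classic pooled two-sample t-statistic.
#'
#' @param data a `ctcov_cohort` (or a bare subjects x elements matrix).
#' @param design a [make_design()] object matching the data rows.
#' @return A `ctcov_statmap`: `t` (element vector), `dof`, `contrast_name`.
#' @export
fit_contrast <- function(data, design) {
  Y <- if (inherits(data, "ctcov_cohort")) data$thickness else as.matrix(data)
  stopifnot(inherits(design, "ctcov_design"), nrow(Y) == nrow(design$X))
  f <- ols_tmap(design$X, design$contrast, Y)
  structure(list(t = f$t, dof = f$dof,
                 contrast_name = design$contrast_name),
            class = "ctcov_statmap")
}

#' Element-wise regression of thickness on a behavioral score
#'
#' Fits `thickness ~ intercept + score + covariates` per element and
#' returns the t-map for the score slope (positive t: thickness increases
#' with the score).
#'
#' @param data a `ctcov_cohort`.
#' @param score name of a covariate column holding the score.
#' @param covariates nuisance covariate names (default `"age"`).
#' @return A `ctcov_statmap` for the score slope.
#' @export
fit_score_regression <- function(data, score, covariates = "age") {
  stopifnot(inherits(data, "ctcov_cohort"),
            score %in% names(data$covariates))
  s <- data$covariates[[score]]
  if (var(s) == 0) stop("zero-variance score")
  Z <- sapply(covariates, function(v) {
    x <- data$covariates[[v]]
    x - mean(x)
  })
  X <- cbind(intercept = 1, score = s - mean(s), Z)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  cvec <- c(0, 1, numeric(length(covariates)))
  f <- ols_tmap(X, cvec, data$thickness)
  structure(list(t = f$t, dof = f$dof,
                 contrast_name = paste0("slope:", score)),
            class = "ctcov_statmap")
}

#' Residualize a vector against a covariate
#'
#' Least-squares residuals of `y ~ 1 + x`; the result is orthogonal to both
#' `x` and the constant, and the operation is idempotent.
#'
#' @param y numeric response vector.
#' @param x numeric covariate vector (must have positive variance).
#' @return numeric residual vector.
#' @export
residualize <- function(y, x) {
  stopifnot(length(y) == length(x))
  if (var(x) == 0) stop("constant covariate")
  lm.fit(cbind(1, x), y)$residuals
}
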