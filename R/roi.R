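#' Parcel-level tests and network bookkeeping
#'
#' Thickness is averaged per parcel ("ROI"), groups are compared per parcel
#' with the same full-factorial model as the element-wise analysis, and the
#' resulting one-sided p-values are thresholded by Benjamini-Hochberg FDR.
#' Significant parcels are then summarized by intrinsic-network family and
#' hemisphere, the bookkeeping used to report which functional systems a
#' thinning pattern loads on.
#'
#' @name roi_network
NULL

#' Mean thickness per parcel
#'
#' @param data a `ctcov_cohort` or subjects x elements matrix; means are
#'   taken from the data as given (conventionally the unsmoothed fields).
#' @param parcellation the parcellation.
#' @return A `ctcov_parcel_matrix`: `values` (subjects x parcels matrix),
#'   `parcels` (metadata data.frame).
#' @export
parcel_means <- function(data, parcellation) {
  Y <- if (inherits(data, "ctcov_cohort")) data$thickness else as.matrix(data)
  stopifnot(inherits(parcellation, "ctcov_parcellation"),
            ncol(Y) == length(parcellation$element_to_parcel))
  K <- n_parcels(parcellation)
  sizes <- tabulate(parcellation$element_to_parcel, nbins = K)
  if (any(sizes == 0)) stop("empty parcel")
  # subjects x parcels sums via indicator matrix
  M <- Matrix::sparseMatrix(i = seq_along(parcellation$element_to_parcel),
                            j = parcellation$element_to_parcel,
                            x = 1, dims = c(ncol(Y), K))
  pm <- as.matrix(Y %*% M) / matrix(sizes, nrow(Y), K, byrow = TRUE)
  colnames(pm) <- parcellation$parcels$name
  structure(list(values = pm, parcels = parcellation$parcels),
            class = "ctcov_parcel_matrix")
}

#' Parcel-level group contrast with FDR control
#'
#' Per-parcel contrast t-statistics (same design machinery as
#' [fit_contrast()]) with one-sided p-values in the contrast direction,
#' masked by [bh_fdr()] at level `q`.
#'
#' @param pm a [parcel_means()] object.
#' @param design a [make_design()] object.
#' @param q FDR level (default 0.01).
#' @return list: `t`, `p` (one-sided), `dof`, `mask` (logical per parcel),
#'   `q`, `parcels`.
#' @export
roi_group_test <- function(pm, design, q = 0.01) {
  stopifnot(inherits(pm, "ctcov_parcel_matrix"))
  f <- ols_tmap(design$X, design$contrast, pm$values)
  p <- pt(f$t, df = f$dof, lower.tail = FALSE)
  list(t = f$t, p = p, dof = f$dof, mask = bh_fdr(p, q), q = q,
       parcels = pm$parcels)
}

#' Count parcels per network family and hemisphere
#'
#' Accepts either parcel ids (with a parcellation) or a data.frame of
#' printed labels with columns `name` and `hemisphere`. With
#' `dedupe_by_name = TRUE`, multiple listings of the same (name,
#' hemisphere) pair count once — label tables can list one parcel under
#' several headings.
#'
#' @param x integer parcel ids, or a data.frame with `name`, `hemisphere`.
#' @param parcellation required when `x` is a vector of parcel ids.
#' @param dedupe_by_name collapse repeated (name, hemisphere) pairs.
#' @return A `ctcov_network_summary`: `counts` data.frame (network_family,
#'   hemisphere, n), `by_family` named totals, `total`.
#' @export
network_summary <- function(x, parcellation = NULL, dedupe_by_name = TRUE) {
  if (is.data.frame(x)) {
    stopifnot(all(c("name", "hemisphere") %in% names(x)))
    fam <- vapply(seq_len(nrow(x)), function(i)
      parse_label(x$name[i], x$hemisphere[i])$network_family, "")
    df <- data.frame(name = x$name, hemisphere = x$hemisphere,
                     network_family = fam, stringsAsFactors = FALSE)
  } else {
    stopifnot(!is.null(parcellation),
              all(x %in% parcellation$parcels$parcel_id))
    p <- parcellation$parcels
    df <- p[match(x, p$parcel_id),
            c("name", "hemisphere", "network_family")]
  }
  if (dedupe_by_name)
    df <- df[!duplicated(df[, c("name", "hemisphere")]), , drop = FALSE]
  if (nrow(df) == 0) {
    counts <- data.frame(network_family = character(),
                         hemisphere = character(), n = integer())
  } else {
    counts <- aggregate(list(n = rep(1L, nrow(df))),
                        by = list(network_family = df$network_family,
                                  hemisphere = df$hemisphere), FUN = sum)
  }
  by_family <- tapply(counts$n, counts$network_family, sum)
  structure(list(counts = counts,
                 by_family = as.list(by_family),
                 total = nrow(df)),
            class = "ctcov_network_summary")
}

#' @export
print.ctcov_network_summary <- function(x, ...) {
  cat(sprintf("<ctcov_network_summary> %d parcels\n", x$total))
  if (length(x$by_family))
    for (f in names(x$by_family))
      cat(sprintf("  %-16s %d\n", f, x$by_family[[f]]))
  invisible(x)
}
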