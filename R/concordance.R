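#' Binary maps and overlap-percentage concordance
#'
#' Structural covariance seed maps (parcel sets rendered to elements) and
#' functional connectivity maps (thresholded at a correlation level) are
#' compared as element sets on a common domain. The concordance statistic
#' is the percentage of shared elements, with the smaller map defining the
#' 100% reference; the Dice coefficient is reported alongside.
#'
#' @name concordance
NULL

#' Construct a binary map over a domain
#' @param members integer element ids (1-based) in the map.
#' @param n_elements number of elements of the common domain.
#' @param source one of `"covariance"`, `"functional"`, `"significance"`.
#' @return A `ctcov_binary_map`.
#' @export
binary_map <- function(members, n_elements,
                       source = c("covariance", "functional",
                                  "significance")) {
  members <- sort(unique(as.integer(members)))
  stopifnot(all(members >= 1), all(members <= n_elements))
  structure(list(members = members, n_elements = as.integer(n_elements),
                 source = match.arg(source)),
            class = "ctcov_binary_map")
}

#' Threshold a scalar field into a binary map
#'
#' Strict inequality: an element belongs to the map iff its value exceeds
#' `r_min` (a value exactly at the threshold is excluded).
#'
#' @param field numeric element vector.
#' @param r_min threshold.
#' @param source map provenance label (default `"functional"`).
#' @return A `ctcov_binary_map`.
#' @export
threshold_map <- function(field, r_min, source = "functional") {
  stopifnot(all(is.finite(field)))
  binary_map(which(field > r_min), length(field), source)
}

#' Render a parcel set to a binary element map
#' @param parcel_ids integer parcel ids.
#' @param parcellation the parcellation.
#' @param source map provenance label (default `"covariance"`).
#' @export
parcels_to_map <- function(parcel_ids, parcellation,
                           source = "covariance") {
  binary_map(parcels_to_elements(parcel_ids, parcellation),
             length(parcellation$element_to_parcel), source)
}

#' Union of two binary maps on the same domain
#' @param a,b binary maps.
#' @return A `ctcov_binary_map` with the union membership.
#' @export
union_maps <- function(a, b) {
  stopifnot(inherits(a, "ctcov_binary_map"),
            inherits(b, "ctcov_binary_map"))
  if (a$n_elements != b$n_elements) stop("domain mismatch")
  binary_map(union(a$members, b$members), a$n_elements, a$source)
}

#' Overlap percentage and Dice coefficient of two binary maps
#'
#' `overlap_pct = 100 |A intersect B| / |reference|`, where the reference
#' is the smaller map by default (ties: map `a`).
#'
#' @param a,b binary maps on the same domain.
#' @param reference `"smaller"` (default), `"a"`, or `"b"`.
#' @return A `ctcov_concordance` list: `overlap_pct`, `dice`, `reference`,
#'   `size_a`, `size_b`, `size_intersection`.
#' @export
overlap <- function(a, b, reference = c("smaller", "a", "b")) {
  reference <- match.arg(reference)
  stopifnot(inherits(a, "ctcov_binary_map"),
            inherits(b, "ctcov_binary_map"))
  if (a$n_elements != b$n_elements) stop("domain mismatch")
  na <- length(a$members); nb <- length(b$members)
  ref <- switch(reference,
                smaller = if (na <= nb) "a" else "b",
                a = "a", b = "b")
  nref <- if (ref == "a") na else nb
  if (nref == 0) stop("undefined percentage: empty reference map")
  ni <- length(intersect(a$members, b$members))
  structure(list(overlap_pct = 100 * ni / nref,
                 dice = if (na + nb > 0) 2 * ni / (na + nb) else NaN,
                 reference = ref, size_a = na, size_b = nb,
                 size_intersection = ni),
            class = "ctcov_concordance")
}

#' @export
print.ctcov_concordance <- function(x, ...) {
  cat(sprintf(
    "<ctcov_concordance> overlap %.1f%% (ref=%s, |A|=%d, |B|=%d, |A&B|=%d), dice %.3f\n",
    x$overlap_pct, x$reference, x$size_a, x$size_b,
    x$size_intersection, x$dice))
  invisible(x)
}
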