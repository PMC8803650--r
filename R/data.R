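#' Published cortical-thinning parcel labels for AUD and OUD
#'
#' Schaefer-style parcel labels reported as showing significant cortical
#' thickness reduction in alcohol use disorder (AUD) and opioid use
#' disorder (OUD) relative to controls, split into labels common to both
#' groups and labels exclusive to each. Ships as a plain-text fixture and
#' serves as the worked example for [network_summary()] bookkeeping: over
#' the union of the common and AUD-exclusive labels, deduplicated by (name,
#' hemisphere), the family counts are DMN 9, ECN 8, SAL/VAN 6.
#'
#' @param category optional subset: any of `"common_aud_oud"`,
#'   `"exclusive_aud"`, `"exclusive_oud"`.
#' @return data.frame with columns `category`, `network_heading`,
#'   `hemisphere`, `name`.
#' @export
ct_reduction_labels <- function(category = NULL) {
  path <- system.file("extdata", "sud_ct_reduction_parcels.tsv",
                      package = "ctcov", mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(category)) {
    stopifnot(all(category %in% unique(d$category)))
    d <- d[d$category %in% category, , drop = FALSE]
  }
  d
}
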