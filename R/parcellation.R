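#' Parcellations and intrinsic-network labels
#'
#' A parcellation assigns every domain element to exactly one of K named
#' parcels (default K = 200, Schaefer-style). Each parcel carries a
#' hemisphere and one of 17 intrinsic connectivity network (ICN) labels in
#' the Yeo nomenclature; networks group into eight families (DMN, ECN,
#' SAL/VAN, DAN, SMN, Limbic, TemporoParietal, Visual). Parcel names follow
#' the `<NETWORK><subnetwork>_<Region>_<index>` dialect, e.g.
#' `"DMNb_PrefrontalCortex_dorsal_4"` or `"SAL/VANb_Insula_2"`.
#'
#' @name parcellation
NULL

# network prefix -> family; prefixes as printed, longest matched first.
.network_families <- c(
  "DMNa" = "DMN", "DMNb" = "DMN", "DMNc" = "DMN",
  "ECNa" = "ECN", "ECNb" = "ECN", "ECNc" = "ECN",
  "SAL/VANa" = "SAL/VAN", "SAL/VANb" = "SAL/VAN",
  "DANa" = "DAN", "DANb" = "DAN",
  "SMNa" = "SMN", "SMNb" = "SMN",
  "Limbica" = "Limbic", "Limbicb" = "Limbic",
  "Temporparietal" = "TemporoParietal",
  "Temporoparietal" = "TemporoParietal",
  "Visual" = "Visual")

#' Network labels usable in synthetic parcellations
#' @return character vector of network labels (canonical spellings).
#' @export
network_labels <- function() {
  setdiff(names(.network_families), "Temporoparietal")
}

#' Parse a Schaefer-style parcel label
#'
#' Splits `"<NETWORK><sub>_<Region>_<idx>"` into its network, subnetwork,
#' network family, region, and index. Both the `"Temporparietal"` spelling
#' used in printed parcel tables and the regular `"Temporoparietal"` are
#' accepted. The parse round-trips: `format_label(parse_label(x, h))` is
#' `x`.
#'
#' @param name parcel label string.
#' @param hemisphere `"L"` or `"R"`.
#' @return A list with fields `name`, `hemisphere`, `network` (prefix as
#'   given), `subnetwork` (`"a"`, `"b"`, `"c"` or `NA`), `network_family`,
#'   `region`, `index`.
#' @export
parse_label <- function(name, hemisphere) {
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  prefixes <- names(.network_families)
  prefixes <- prefixes[order(nchar(prefixes), decreasing = TRUE)]
  hit <- NA_character_
  for (p in prefixes) {
    if (startsWith(name, paste0(p, "_"))) { hit <- p; break }
  }
  if (is.na(hit)) stop("unknown network label: ", name)
  rest <- substring(name, nchar(hit) + 2)
  m <- regmatches(rest, regexec("^(.+)_([0-9]+)$", rest))[[1]]
  if (length(m) != 3) stop("unknown network label: ", name)
  sub <- NA_character_
  if (grepl("[abc]$", hit) && hit != "Temporparietal")
    sub <- substring(hit, nchar(hit))
  list(name = name, hemisphere = hemisphere, network = hit,
       subnetwork = sub,
       network_family = unname(.network_families[hit]),
       region = m[2], index = as.integer(m[3]))
}

#' @rdname parse_label
#' @param info a list as returned by [parse_label()].
#' @export
format_label <- function(info) {
  paste(info$network, info$region, info$index, sep = "_")
}

new_parcellation <- function(element_to_parcel, parcels) {
  element_to_parcel <- as.integer(element_to_parcel)
  stopifnot(all(element_to_parcel >= 1),
            all(element_to_parcel <= nrow(parcels)),
            identical(sort(unique(parcels$parcel_id)),
                      seq_len(nrow(parcels))))
  structure(list(element_to_parcel = element_to_parcel,
                 parcels = parcels),
            class = "ctcov_parcellation")
}

#' @export
print.ctcov_parcellation <- function(x, ...) {
  cat(sprintf("<ctcov_parcellation> %d parcels over %d elements\n",
              nrow(x$parcels), length(x$element_to_parcel)))
  invisible(x)
}

#' Number of parcels
#' @param parcellation a parcellation.
#' @export
n_parcels <- function(parcellation) nrow(parcellation$parcels)

#' Generate a synthetic parcellation of a domain
#'
#' Partitions the domain into `n_parcels` spatially contiguous parcels by
#' multi-source breadth-first growth from randomly placed seed elements,
#' split evenly between hemispheres (left = negative x coordinate). Each
#' parcel gets a hemisphere, a network label cycled through the 17-network
#' nomenclature, and a well-formed Schaefer-style name that round-trips
#' through [parse_label()].
#'
#' @param domain the domain to parcellate.
#' @param n_parcels number of parcels K (default 200).
#' @param rng_seed integer seed for seed-element placement.
#' @return A parcellation object.
#' @export
make_parcellation <- function(domain, n_parcels = 200, rng_seed = 1) {
  stopifnot(inherits(domain, "ctcov_domain"), n_parcels >= 2,
            n_parcels <= domain$n_elements)
  n <- domain$n_elements
  x <- if (!is.null(domain$coordinates)) domain$coordinates[, 1]
       else seq_len(n) - (n + 1) / 2
  hemi_of <- ifelse(x < stats::median(x), "L", "R")
  adj <- vector("list", n)
  for (i in seq_len(nrow(domain$edges))) {
    u <- domain$edges[i, 1]; v <- domain$edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  assign_hemi <- function(elements, k, seeds) {
    lab <- integer(length(elements))
    names(lab) <- elements
    frontier <- seeds
    lab[as.character(seeds)] <- seq_len(k)
    inset <- rep(FALSE, n); inset[elements] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        for (q in adj[[f]]) {
          if (inset[q] && lab[as.character(q)] == 0L) {
            lab[as.character(q)] <- lab[as.character(f)]
            nxt <- c(nxt, q)
          }
        }
      }
      frontier <- nxt
    }
    # strays in disconnected pockets: attach to the nearest seed in space
    left <- elements[lab == 0L]
    if (length(left)) {
      co <- domain$coordinates
      for (e in left) {
        d2 <- rowSums((co[seeds, , drop = FALSE] -
                         matrix(co[e, ], length(seeds), 3, byrow = TRUE))^2)
        lab[as.character(e)] <- which.min(d2)
      }
    }
    lab
  }
  with_seed(rng_seed, {
    res <- integer(n)
    kl <- floor(n_parcels / 2); kr <- n_parcels - kl
    el <- which(hemi_of == "L"); er <- which(hemi_of == "R")
    stopifnot(length(el) >= kl, length(er) >= kr)
    labL <- assign_hemi(el, kl, sort(sample(el, kl)))
    labR <- assign_hemi(er, kr, sort(sample(er, kr)))
    res[el] <- labL[as.character(el)]
    res[er] <- labR[as.character(er)] + kl
    nets <- network_labels()
    regions <- c("PrefrontalCortex", "ParietalLobe", "Temporal", "Insula",
                 "Cingulate", "Occipital", "Precuneus", "FrontalMedial")
    hemi <- c(rep("L", kl), rep("R", kr))
    net <- nets[(seq_len(n_parcels) - 1L) %% length(nets) + 1L]
    reg <- regions[((seq_len(n_parcels) - 1L) %/% length(nets)) %%
                     length(regions) + 1L]
    name <- character(n_parcels)
    seen <- new.env(hash = TRUE)
    for (i in seq_len(n_parcels)) {
      key <- paste(net[i], reg[i], hemi[i])
      idx <- if (is.null(seen[[key]])) 1L else seen[[key]] + 1L
      seen[[key]] <- idx
      name[i] <- paste(net[i], reg[i], idx, sep = "_")
    }
    fam <- unname(.network_families[net])
    subnet <- ifelse(net %in% c("Visual", "Temporparietal"), NA_character_,
                     substring(net, nchar(net)))
    parcels <- data.frame(parcel_id = seq_len(n_parcels), name = name,
                          hemisphere = hemi, network = net,
                          subnetwork = subnet, network_family = fam,
                          stringsAsFactors = FALSE)
    new_parcellation(res, parcels)
  })
}

#' Write / read a parcellation as two TSV files
#'
#' `parcels.tsv` holds parcel metadata (parcel_id, name, hemisphere,
#' network, network_family); `elements.tsv` maps 0-based element ids to
#' parcel ids.
#'
#' @param parcellation a parcellation object.
#' @param dir directory for the two files.
#' @export
write_parcellation <- function(parcellation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(parcellation$parcels, file.path(dir, "parcels.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(
    data.frame(element_id = seq_along(parcellation$element_to_parcel) - 1L,
               parcel_id = parcellation$element_to_parcel),
    file.path(dir, "elements.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(dir) {
  parcels <- read.delim(file.path(dir, "parcels.tsv"),
                        stringsAsFactors = FALSE)
  el <- read.delim(file.path(dir, "elements.tsv"))
  new_parcellation(el$parcel_id[order(el$element_id)], parcels)
}

#' Element ids belonging to a set of parcels
#' @param parcel_ids integer parcel ids.
#' @param parcellation a parcellation.
#' @return integer vector of element indices (1-based).
#' @export
parcels_to_elements <- function(parcel_ids, parcellation) {
  which(parcellation$element_to_parcel %in% parcel_ids)
}
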