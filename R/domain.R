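#' Spatial domains for vertex- and voxel-wise analysis
#'
#' A domain is the discretized spatial support on which per-subject scalar
#' fields (cortical thickness in mm, statistic maps) live: either a
#' triangulated spherical mesh standing in for a registered cortical surface
#' ("surface" mode) or the in-mask voxels of a 3D lattice with 6-neighbor
#' connectivity ("volume" mode). The element adjacency is the substrate for
#' both smoothing and threshold-free cluster enhancement.
#'
#' Elements are indexed 1..n_elements in memory; on-disk TSV exports use
#' 0-based contiguous element ids.
#'
#' @name domain
NULL

new_domain <- function(n_elements, edges, mode, coordinates = NULL,
                       shape = NULL, mask_index = NULL, level = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  # canonical order: u < v, sorted, no duplicates, no self-edges
  if (nrow(edges) > 0) {
    u <- pmin(edges[, 1], edges[, 2])
    v <- pmax(edges[, 1], edges[, 2])
    keep <- u != v
    edges <- unique(cbind(u[keep], v[keep]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(
    list(n_elements = as.integer(n_elements), edges = edges,
         mode = match.arg(mode, c("surface", "volume")),
         coordinates = coordinates, shape = shape,
         mask_index = mask_index, level = level),
    class = "ctcov_domain")
}

#' @export
print.ctcov_domain <- function(x, ...) {
  cat(sprintf("<ctcov_domain> mode=%s, %d elements, %d edges\n",
              x$mode, x$n_elements, nrow(x$edges)))
  invisible(x)
}

#' Build a volume-mode domain from a binary voxel mask
#'
#' One element per in-mask voxel; adjacency is 6-connectivity (face
#' neighbors) restricted to the mask, so diagonal contacts do not connect.
#' This is the substrate used for masked voxel-based morphometry of
#' subcortical and cerebellar gray matter.
#'
#' @param shape integer vector of length 3, lattice dimensions (x, y, z).
#' @param mask logical array of dimension `shape` (or a vector that can be
#'   reshaped to it); `TRUE` marks in-mask voxels.
#' @param voxel_size_mm edge length of a voxel in mm (isotropic).
#' @return A domain of mode `"volume"`. Element order follows the R
#'   column-major order of the mask array (x fastest). Coordinates are the
#'   0-based voxel indices scaled by `voxel_size_mm`.
#' @export
build_lattice_domain <- function(shape, mask, voxel_size_mm = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  mask <- array(as.logical(mask), dim = shape)
  if (!any(mask)) stop("empty domain")
  idx <- array(0L, dim = shape)
  idx[mask] <- seq_len(sum(mask))
  pairs_axis <- function(a, b) {
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  e <- list()
  if (nx > 1) e[[length(e) + 1L]] <-
    pairs_axis(idx[1:(nx - 1), , , drop = FALSE], idx[2:nx, , , drop = FALSE])
  if (ny > 1) e[[length(e) + 1L]] <-
    pairs_axis(idx[, 1:(ny - 1), , drop = FALSE], idx[, 2:ny, , drop = FALSE])
  if (nz > 1) e[[length(e) + 1L]] <-
    pairs_axis(idx[, , 1:(nz - 1), drop = FALSE], idx[, , 2:nz, drop = FALSE])
  edges <- if (length(e)) do.call(rbind, e) else matrix(integer(), ncol = 2)
  w <- which(mask, arr.ind = TRUE)
  coords <- (w - 1) * voxel_size_mm
  colnames(coords) <- c("x", "y", "z")
  new_domain(sum(mask), edges, "volume", coordinates = coords,
             shape = shape, mask_index = which(mask))
}

#' Build a surface-mode domain as a subdivided icosahedral sphere
#'
#' A synthetic stand-in for a registered average cortical surface: the
#' icosahedron subdivided `level` times and projected onto a sphere, giving
#' `10 * 4^level + 2` vertices. Vertex adjacency is the triangle edge set.
#'
#' @param subdivision_level nonnegative integer, at most 6.
#' @param radius_mm sphere radius in mm; the default 80 mm gives
#'   approximately hemispheric-brain edge lengths.
#' @return A domain of mode `"surface"` with vertex coordinates in mm.
#' @export
build_mesh_domain <- function(subdivision_level, radius_mm = 80) {
  level <- as.integer(subdivision_level)
  stopifnot(level >= 0, level <= 6)
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  verts <- verts / sqrt(rowSums(verts^2))
  for (l in seq_len(level)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(verts)
    newverts <- list(verts)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[a, ] + verts[b, ])
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      newverts[[length(newverts) + 1L]] <<- matrix(m, nrow = 1)
      midcache[[key]] <- nv
      nv
    }
    newfaces <- matrix(0L, nrow = 4 * nrow(faces), ncol = 3)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1]; b <- faces[f, 2]; c <- faces[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newfaces[4 * f - 3, ] <- c(a, ab, ca)
      newfaces[4 * f - 2, ] <- c(ab, b, bc)
      newfaces[4 * f - 1, ] <- c(ca, bc, c)
      newfaces[4 * f, ] <- c(ab, bc, ca)
    }
    verts <- do.call(rbind, newverts)
    faces <- newfaces
  }
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  coords <- verts * radius_mm
  colnames(coords) <- c("x", "y", "z")
  new_domain(nrow(verts), edges, "surface", coordinates = coords,
             level = level)
}

#' Mean edge length of a domain in mm
#' @param domain a domain with coordinates.
#' @return mean Euclidean distance between adjacent elements.
#' @export
mean_edge_length <- function(domain) {
  stopifnot(inherits(domain, "ctcov_domain"), !is.null(domain$coordinates))
  d <- domain$coordinates[domain$edges[, 1], , drop = FALSE] -
    domain$coordinates[domain$edges[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# Sparse symmetric diffusion operator W = I - L / (2 * d_max); doubly
# stochastic, so it preserves the field mean exactly and, having spectrum in
# [0, 1], never increases variance.
diffusion_operator <- function(domain) {
  n <- domain$n_elements
  e <- domain$edges
  if (nrow(e) == 0)
    return(Matrix::Diagonal(n))
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  a <- 1 / (2 * max(deg))
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = a, dims = c(n, n))
  Matrix::Diagonal(n, 1 - a * deg) + A
}

#' Smooth a scalar field on a domain
#'
#' Iterative symmetric neighbor averaging approximating a Gaussian kernel of
#' the requested full width at half maximum. Each iteration applies the
#' doubly-stochastic diffusion operator `I - L/(2 d_max)` (graph Laplacian
#' `L`), which on a path graph is the (1/4, 1/2, 1/4) stencil. The global
#' mean is preserved exactly and the variance never increases. The iteration
#' count, when not given, is derived from `fwhm_mm` and the mean edge length
#' through the per-step impulse variance `edge_len^2 / 2`.
#'
#' @param field numeric vector of length `n_elements`, or a matrix with one
#'   column per field (elements in rows).
#' @param domain the domain carrying the adjacency.
#' @param fwhm_mm requested smoothing kernel FWHM in mm (used only when
#'   `iterations` is missing; requires domain coordinates).
#' @param iterations explicit number of averaging iterations (overrides
#'   `fwhm_mm`).
#' @return The smoothed field(s), same shape as the input.
#' @export
smooth_field <- function(field, domain, fwhm_mm = NULL, iterations = NULL) {
  stopifnot(inherits(domain, "ctcov_domain"))
  vec <- is.null(dim(field))
  x <- if (vec) matrix(field, ncol = 1) else as.matrix(field)
  stopifnot(nrow(x) == domain$n_elements, all(is.finite(x)))
  if (is.null(iterations)) {
    stopifnot(!is.null(fwhm_mm), fwhm_mm > 0)
    ell <- mean_edge_length(domain)
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
    iterations <- max(1L, as.integer(ceiling(2 * sigma^2 / ell^2)))
  }
  stopifnot(iterations >= 1)
  W <- diffusion_operator(domain)
  for (i in seq_len(iterations)) x <- as.matrix(W %*% x)
  if (vec) drop(x) else x
}

#' Write / read a domain as a JSON header plus TSV edge list
#'
#' The edge list uses 0-based element ids (columns `u`, `v`).
#'
#' @param domain a domain object.
#' @param dir output directory (created if needed).
#' @return `write_domain` returns `dir` invisibly; `read_domain` returns the
#'   domain (without coordinates, which are reconstructible for meshes via
#'   [build_mesh_domain()]).
#' @export
write_domain <- function(domain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(mode = domain$mode, n_elements = domain$n_elements,
              shape = domain$shape, level = domain$level)
  jsonlite::write_json(hdr[!vapply(hdr, is.null, TRUE)],
                       file.path(dir, "domain.json"), auto_unbox = TRUE)
  ed <- data.frame(u = domain$edges[, 1] - 1L, v = domain$edges[, 2] - 1L)
  write.table(ed, file.path(dir, "edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_domain
#' @export
read_domain <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "domain.json"),
                             simplifyVector = TRUE)
  ed <- read.delim(file.path(dir, "edges.tsv"))
  new_domain(hdr$n_elements, cbind(ed$u + 1L, ed$v + 1L), hdr$mode,
             shape = hdr$shape, level = hdr$level)
}

#' Write / read a scalar field as TSV (element_id 0-based, value)
#' @param values numeric vector over domain elements.
#' @param path TSV file path.
#' @export
write_field <- function(values, path) {
  write.table(data.frame(element_id = seq_along(values) - 1L,
                         value = values),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  d <- read.delim(path)
  v <- d$value[order(d$element_id)]
  v
}
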