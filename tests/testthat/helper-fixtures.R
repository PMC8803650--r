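# Shared fixtures and independent oracles, all built in code.

# Brute-force TFCE: connected components recomputed from scratch at every
# threshold of the h_k = k * dh grid. Independent of the union-find path.
tfce_brute <- function(stat, domain, E = 0.5, H = 2, dh) {
  n <- domain$n_elements
  edges <- domain$edges
  one_side <- function(v, sgn) {
    out <- numeric(n)
    hmax <- max(v)
    if (hmax <= 0) return(out)
    for (k in seq_len(ceiling(hmax / dh - 1e-12))) {
      h <- k * dh
      act <- which(v >= h)
      if (!length(act)) next
      sub <- edges[edges[, 1] %in% act & edges[, 2] %in% act, ,
                   drop = FALSE]
      g <- igraph::make_empty_graph(length(act), directed = FALSE)
      if (nrow(sub) > 0) {
        idx <- matrix(match(as.vector(sub), act), ncol = 2)
        g <- igraph::add_edges(g, as.vector(t(idx)))
      }
      comp <- igraph::components(g)
      sizes <- comp$csize[comp$membership]
      out[act] <- out[act] + sgn * sizes^E * h^H * dh
    }
    out
  }
  one_side(pmax(stat, 0), 1) + one_side(pmax(-stat, 0), -1)
}

# Erdos-Renyi style random domain (surface mode, no coordinates needed for
# TFCE) with n nodes and edge probability p.
random_graph_domain <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  ctcov:::new_domain(n, pairs[keep, , drop = FALSE], "surface")
}

# One-element domain (isolated node).
isolated_domain <- function() {
  build_lattice_domain(c(1, 1, 1), array(TRUE, c(1, 1, 1)))
}

# Small shared mesh + parcellation for the expensive suites; built once.
shared_mesh <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_mesh_domain(3)
    val
  }
})
shared_parcellation <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_parcellation(shared_mesh(), 50,
                                                rng_seed = 2)
    val
  }
})

# Pooled two-sample t statistic, closed form (independent oracle).
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
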