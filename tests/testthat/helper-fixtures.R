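# Shared fixture builders. Everything is generated in code at test time.

# Digitized sphere mask of radius r (mm) centred in a cubic grid.
sphere_mask <- function(r, n = 2 * ceiling(r) + 9, spacing = c(1, 1, 1)) {
  g <- atrialscar:::grid_coords(rep(n, 3), spacing, c(0, 0, 0))
  list(mask = sqrt(g$X^2 + g$Y^2 + g$Z^2) <= r, center = g$center,
       spacing = spacing, dims = rep(n, 3))
}

# Small smoke-scale phantom configuration (fast to generate and mesh).
small_phantom_config <- function(seed = 1L, ...) {
  args <- list(grid_shape = c(36, 36, 36), cavity_radius_mm = 10,
               cavity_irregularity = 1.5, n_scar_patches = 3,
               scar_area_fraction = 0.25, noise_sigma = 8,
               seg_error_mm = 2, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

# Tiny patch geometry + architecture for fast network tests.
tiny_msp_config <- function(n_scales = 1L, R = 0) {
  msp_config(dims = c(5, 5, 7), n_scales = n_scales, base_spacing_mm = 1,
             shift_R_mm = R)
}

tiny_arch <- function() net_config(channels = c(4, 8), d_feat = 8, hidden = 8)

# Synthetic two-class patch set: class-1 patches brighter by `sep` (in SD
# units of the unit-variance noise).
separable_patches <- function(n, msp_cfg, sep = 5, seed = 1) {
  nvox <- prod(msp_cfg$dims)
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- lapply(seq_len(msp_cfg$n_scales), function(s)
      matrix(stats::rnorm(n * nvox, mean = sep * y), n, nvox))
    list(X = X, y = y)
  })
}

# Independent shortest-path oracle (Bellman-Ford over the mesh edge graph).
brute_force_geodesic <- function(mesh, from) {
  n <- nrow(mesh$vertices)
  w <- sqrt(rowSums((mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
                     mesh$vertices[mesh$edges[, 2], , drop = FALSE])^2))
  dist <- rep(Inf, n)
  dist[from] <- 0
  for (iter in seq_len(n)) {
    changed <- FALSE
    for (e in seq_len(nrow(mesh$edges))) {
      i <- mesh$edges[e, 1]; j <- mesh$edges[e, 2]
      if (dist[i] + w[e] < dist[j]) { dist[j] <- dist[i] + w[e]; changed <- TRUE }
      if (dist[j] + w[e] < dist[i]) { dist[i] <- dist[j] + w[e]; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# Exhaustive-enumeration minimum of a graph energy (<= ~16 nodes).
brute_force_min_energy <- function(graph) {
  n <- nrow(graph$t_cost)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    l <- as.integer(intToBits(code)[1:n])
    e <- graph_energy(graph, l)
    if (e < best) best <- e
  }
  best
}

# Random small surface-like graph model for min-cut oracle tests.
random_graph_model <- function(n_nodes, seed) {
  withr::with_seed(seed, {
    lhat <- stats::runif(n_nodes)
    # random sparse symmetric edge set
    m <- max(1L, rpois(1, n_nodes))
    ed <- unique(t(apply(matrix(sample(n_nodes, 2 * m, replace = TRUE),
                                ncol = 2), 1, sort)))
    ed <- ed[ed[, 1] != ed[, 2], , drop = FALSE]
    if (nrow(ed) == 0) ed <- matrix(c(1L, 2L), 1)
    graph_model(lhat, ed, stats::runif(nrow(ed)), lambda = stats::runif(1, 0, 2))
  })
}
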