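# Shared fixtures: all synthetic, built in code at test time.

# Reduced-grid phantom: same geometry as the default (ventricle flanked by
# projection/association bundles) on a 24 x 24 x 12 grid, for fast tensor fits.
small_phantom_config <- function(perivascular_delta = 0.24, snr = Inf, seed = 1L, ...) {
  ext <- function(x) list(x = x, y = c(4, 19), z = c(1, 10))
  phantom_config(
    grid_shape = c(24L, 24L, 12L),
    bundles = list(
      projection_L  = list(extent = ext(c(6, 8)),   axis = "z", lambda_par = 1.2, lambda_perp = 0.3),
      projection_R  = list(extent = ext(c(15, 17)), axis = "z", lambda_par = 1.2, lambda_perp = 0.3),
      association_L = list(extent = ext(c(2, 4)),   axis = "y", lambda_par = 1.2, lambda_perp = 0.3),
      association_R = list(extent = ext(c(19, 21)), axis = "y", lambda_par = 1.2, lambda_perp = 0.3)
    ),
    ventricle = list(extent = list(x = c(10, 13), y = c(6, 17), z = c(2, 9)), d = 3.0),
    perivascular_delta = perivascular_delta, snr = snr, seed = seed, ...
  )
}

# Build a dwi_volume with every voxel carrying the same given tensor
# (3x3 symmetric), straight from the Stejskal-Tanner forward model.
dwi_from_tensor <- function(D, bvecs = gradient_scheme(16), b = 1000,
                            grid = c(3L, 3L, 3L), s0 = 1000) {
  bvals <- c(0, rep(b, nrow(bvecs)))
  g <- rbind(c(0, 0, 0), bvecs)
  att <- vapply(seq_len(nrow(g)), function(i)
    exp(-1e-3 * bvals[i] * drop(g[i, ] %*% D %*% g[i, ])), numeric(1))
  sig <- array(rep(s0 * att, each = prod(grid)), c(grid, length(bvals)))
  dwi_volume(sig, bvals, g, c(2, 2, 2))
}

rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1], -axis[2], axis[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

random_psd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- crossprod(A) / 3
  (S + t(S)) / 2
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall)
floyd_warshall <- function(d) {
  n <- nrow(d)
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

adj_of <- function(g) as.matrix(igraph::as_adjacency_matrix(g))

# straight z-axis bundle phantom joining regions 1 and 2
straight_bundle_phantom <- function() {
  generate_tract_phantom(2, list(list(regions = c(1, 2),
                                      points = cbind(10, 10, seq(2, 37)))))
}
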