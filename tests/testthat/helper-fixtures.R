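# shared helpers: tiny deterministic configurations used across test files

# fast, quiet parameter set for dynamics tests (overridable defaults)
test_params <- function(...) {
  args <- utils::modifyList(
    list(gamma_m = 0.5, A_M = 0.1, beta = 1, De_core = 0.3, De_rep = 0.3,
         noise_amp = 0, dt = 0.004),
    list(...))
  do.call(sim_params, args)
}

# unit icosahedron vertices (12 points, known hull: 20 facets, 30 edges)
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  m <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  m / sqrt(1 + phi^2)
}

# points approximately uniform on a sphere of radius R (deterministic given seed)
sphere_points <- function(n, R = 1) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  R * u / sqrt(rowSums(u^2))
}

# undirected edge set of a facet matrix (rows a, b, c), sorted pairs
facet_edges <- function(fac) {
  e <- rbind(fac[, 1:2], fac[, 2:3], fac[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  unique(as.data.frame(e))
}

# brute-force all-pairs neighbour oracle
brute_pairs <- function(pos, cutoff) {
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  out <- data.frame(i = pmin(idx[, 1], idx[, 2]), j = pmax(idx[, 1], idx[, 2]))
  out[order(out$i, out$j), , drop = FALSE]
}

# a hand-positioned aggregate of ball-shaped cells at given centres/types;
# no relaxation, structure computed on demand
toy_aggregate <- function(centres, types, n_el = 20, params = test_params(),
                          radius = 1.2) {
  el <- do.call(rbind, lapply(seq_len(nrow(centres)), function(c) {
    pos <- sphere_points(n_el, radius)  # shell: every element is cortex
    data.frame(cell = c, x = pos[, 1] + centres[c, 1],
               y = pos[, 2] + centres[c, 2], z = pos[, 3] + centres[c, 3])
  }))
  el$element <- seq_len(nrow(el))
  new_aggregate(el, data.frame(cell = seq_len(nrow(centres)), type = types),
                params)
}
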