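test_that("cortex allocation follows the per-sector 80% rule", {
  # single element: it is the maximum of its sector
  expect_equal(allocate_cortex(matrix(c(1, 0, 0), 1, 3), centre = c(0, 0, 0)),
               "cortex")
  # uniform spherical shell: every radius equals its sector maximum
  set.seed(7)
  sh <- sphere_points(120, R = 2)
  expect_true(all(allocate_cortex(sh, centre = c(0, 0, 0)) == "cortex"))
})

test_that("cortex allocation matches a brute-force per-sector scan", {
  set.seed(8)
  pos <- matrix(runif(600, -1, 1), ncol = 3)
  centre <- colMeans(pos)
  got <- allocate_cortex(pos, centre, radius_fraction = 0.8)
  # independent R implementation of the 4-band x 8-slice partition
  d <- sweep(pos, 2, centre)
  r <- sqrt(rowSums(d^2))
  band <- pmin(pmax(floor((d[, 3] / pmax(r, 1e-300) + 1) * 2), 0), 3)
  phi <- atan2(d[, 2], d[, 1]) + pi
  slice <- pmin(pmax(floor(phi * 8 / (2 * pi)), 0), 7)
  sec <- band * 8 + slice
  rmax <- ave(r, sec, FUN = max)
  want <- ifelse(r >= rmax | r > 0.8 * rmax, "cortex", "cytoplasm")
  expect_equal(got, want)
  # idempotence: same input, same labels
  expect_equal(allocate_cortex(pos, centre, 0.8), got)
})

test_that("cortex triangulation is a closed surface with correct counts", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tr <- triangulate_cortex(tet, centre = colMeans(tet))
  expect_equal(nrow(tr), 4)
  expect_equal(nrow(facet_edges(as.matrix(tr[, 1:3]))), 6)  # V - E + F = 2

  ico <- icosahedron()
  tr2 <- triangulate_cortex(ico, centre = c(0, 0, 0))
  expect_equal(nrow(tr2), 20)
  expect_equal(nrow(facet_edges(as.matrix(tr2[, 1:3]))), 30)

  expect_error(triangulate_cortex(tet[1:3, ]), "at least 4")
})

test_that("triangulated sphere area approaches 4 pi R^2", {
  set.seed(9)
  R <- 1.7
  pts <- sphere_points(500, R)
  tr <- triangulate_cortex(pts, centre = c(0, 0, 0))
  expect_equal(sum(tr$area), 4 * pi * R^2, tolerance = 0.02)
})

test_that("closed-surface topology holds after simulation retriangulation", {
  set.seed(10)
  cell <- single_cell(40, test_params(), relax_time = 2)
  s <- cell$structure
  fac <- s$facets
  expect_gt(nrow(fac), 0)
  ed <- rbind(fac[, 1:2], fac[, 2:3], fac[, c(3, 1)])
  ed <- t(apply(ed, 1, sort))
  tab <- table(paste(ed[, 1], ed[, 2]))
  expect_true(all(tab == 2))  # every edge shared by exactly 2 facets
  v <- length(unique(as.vector(fac)))
  e <- length(tab)
  f <- nrow(fac)
  expect_equal(v - e + f, 2)
  # every mesh vertex is a cortex element appearing in >= 3 facets
  expect_true(all(s$etype[unique(as.vector(fac))] == 1))
  counts <- table(as.vector(fac))
  expect_true(all(counts >= 3))
})

test_that("interface labels follow adhesive contacts between cells", {
  p <- test_params(A_M = 0.2)
  # isolated cell: no labels
  set.seed(11)
  solo <- single_cell(30, p, relax_time = 1)
  expect_true(all(element_table(solo)$label == "none"))

  # same-type doublet in contact: same_type labels on both cells
  agg <- toy_aggregate(rbind(c(0, 0, 0), c(2.6, 0, 0)), types = c(1L, 1L),
                       params = p)
  et <- label_interface_elements(agg)
  lab1 <- et$label[et$cell == 1]
  lab2 <- et$label[et$cell == 2]
  expect_true(any(lab1 == "same_type") && any(lab2 == "same_type"))
  expect_false(any(et$label %in% c("other_type", "both")))

  # three cells in a row, types 1-1-2: middle carries both labels, disjoint
  agg3 <- toy_aggregate(rbind(c(-2.6, 0, 0), c(0, 0, 0), c(2.6, 0, 0)),
                        types = c(1L, 1L, 2L), params = p)
  et3 <- label_interface_elements(agg3)
  mid <- et3[et3$cell == 2, ]
  expect_true(any(mid$label == "same_type"))
  expect_true(any(mid$label == "other_type"))
  # the two labelled zones sit on opposite sides of the middle cell
  expect_true(all(mid$x[mid$label == "same_type"] < 0))
  expect_true(all(mid$x[mid$label == "other_type"] > 0))
})

test_that("no adhesive interaction means no labels", {
  agg <- toy_aggregate(rbind(c(0, 0, 0), c(2.6, 0, 0)), types = c(1L, 1L),
                       params = test_params(A_M = 0))
  expect_true(all(label_interface_elements(agg)$label == "none"))
})

test_that("cortical tension magnitudes scale with beta on interface edges", {
  centres <- rbind(c(0, 0, 0), c(2.4, 0, 0))
  base <- toy_aggregate(centres, types = c(1L, 1L),
                        params = test_params(A_M = 0.2, gamma_m = 1))
  f_full <- apply_cortical_tension(base)
  zero <- base
  zero$params$beta <- beta_matrix(0, 0, 0)
  f_zero <- apply_cortical_tension(zero)
  agg <- update_structure(base)
  lab <- agg$structure$label
  diff <- sqrt(rowSums((as.matrix(f_full[, 2:4]) - as.matrix(f_zero[, 2:4]))^2))
  # only labelled (interface) elements feel the factor
  expect_true(all(diff[lab == 0] < 1e-12))
  expect_true(any(diff[lab > 0] > 1e-6))
})

test_that("tension forces sum to zero and act along triangulation edges", {
  set.seed(12)
  cell <- single_cell(30, test_params(gamma_m = 0.8), relax_time = 1)
  ft <- apply_cortical_tension(cell)
  expect_lt(max(abs(colSums(as.matrix(ft[, 2:4])))), 1e-9)
})

test_that("adhesion density normalisation is mean-one and tracks crowding", {
  p <- test_params()
  # uniform shell: factors near 1
  set.seed(13)
  agg <- toy_aggregate(matrix(0, 1, 3), types = 1L, n_el = 80, params = p)
  f <- density_normalized_adhesion(agg)
  expect_equal(mean(f$adh_factor), 1, tolerance = 0.05)
  expect_true(all(f$adh_factor > 0.1 & f$adh_factor < 4))

  # doubled local density: local factors about half the sparse ones
  set.seed(14)
  sparse <- sphere_points(40, 2)
  dense_cap <- sphere_points(160, 2)
  dense_cap <- dense_cap[dense_cap[, 3] > 1.2, , drop = FALSE]
  pos <- rbind(sparse[sparse[, 3] <= 1.0, ], dense_cap)
  el <- data.frame(element = seq_len(nrow(pos)), cell = 1L,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3])
  agg2 <- new_aggregate(el, data.frame(cell = 1L, type = 1L), p)
  f2 <- density_normalized_adhesion(agg2)$adh_factor
  in_cap <- pos[, 3] > 1.2
  ratio <- mean(f2[in_cap]) / mean(f2[!in_cap])
  expect_lt(ratio, 0.75)  # crowded cap gets clearly reduced adhesion weight
})

test_that("cortex reallocation keeps elements from escaping a relaxed cell", {
  set.seed(15)
  p <- test_params(noise_amp = 0.3)
  cell <- single_cell(30, p, relax_time = 1)
  r0 <- {
    pos <- as.matrix(cell$elements[, c("x", "y", "z")])
    max(sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2)))
  }
  cell <- simulate_steps(cell, 3000)
  pos <- as.matrix(cell$elements[, c("x", "y", "z")])
  r1 <- max(sqrt(rowSums(sweep(pos, 2, colMeans(pos))^2)))
  expect_lt(r1, r0 + 1.5)  # bounded: no runaway elements
})
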