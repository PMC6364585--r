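make_cells <- function(pos, types, free = NULL) {
  tibble::tibble(cell = seq_len(nrow(pos)), type = types,
                 x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 free_area = free %||% rep(1, nrow(pos)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("radius measure matches direct arithmetic", {
  expect_equal(radius_measure(make_cells(matrix(c(3, 1, 2), 1, 3), 1L)), 0)
  two <- make_cells(rbind(c(0, 0, 0), c(4, 0, 0)), c(1L, 1L))
  expect_equal(radius_measure(two), 2)
  set.seed(30)
  pos <- matrix(rnorm(90), ncol = 3)
  types <- rep(c(1L, 2L), length.out = 30)
  cells <- make_cells(pos, types)
  sel <- types == 1
  com <- colMeans(pos[sel, ])
  expect_equal(radius_measure(cells),
               mean(sqrt(rowSums(sweep(pos[sel, ], 2, com)^2))))
  expect_error(radius_measure(make_cells(pos, rep(2L, 30))), "no cells")
})

test_that("neighbour measure counts like-like contact edges", {
  pos <- matrix(rnorm(12), ncol = 3)
  tri <- tibble::tibble(cell_a = c(1, 1, 2), cell_b = c(2, 3, 3))
  expect_equal(neighbour_measure(make_cells(pos, rep(1L, 4)), tri), 3)
  expect_equal(neighbour_measure(make_cells(pos, rep(2L, 4)), tri), 0)
  set.seed(31)
  n <- 25
  types <- sample(c(1L, 2L), n, replace = TRUE)
  edges <- tibble::tibble(cell_a = sample(n, 60, replace = TRUE),
                          cell_b = sample(n, 60, replace = TRUE))
  edges <- edges[edges$cell_a < edges$cell_b, ]
  cells <- make_cells(matrix(rnorm(3 * n), ncol = 3), types)
  expect_equal(neighbour_measure(cells, edges),
               sum(types[edges$cell_a] == 1 & types[edges$cell_b] == 1))
})

test_that("surface measure is the outer type's share of free surface", {
  pos <- matrix(rnorm(12), ncol = 3)
  expect_equal(surface_measure(make_cells(pos, rep(2L, 4))), 1)
  # mirror-symmetric 1:1 free areas
  cells <- make_cells(pos, c(1L, 1L, 2L, 2L), free = c(2, 3, 2, 3))
  expect_equal(surface_measure(cells), 0.5)
  cells2 <- make_cells(pos, c(1L, 2L, 2L, 2L), free = c(1, 2, 3, 4))
  expect_equal(surface_measure(cells2), 0.9)
  expect_error(surface_measure(make_cells(pos, rep(2L, 4), free = rep(0, 4))),
               "no free surface")
})

test_that("permutation null matches exhaustive enumeration on a small graph", {
  # complete graph on 4 cells, 2 of type 1: every labelling has exactly
  # C(2,2) = 1 like-like edge, so E(X_n) = 1 with zero variance
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  cells <- make_cells(pos, c(1L, 1L, 2L, 2L))
  cg <- tidyr::crossing(cell_a = 1:4, cell_b = 1:4) |>
    dplyr::filter(.data$cell_a < .data$cell_b)
  set.seed(32)
  null <- randomized_null(cells, cg, n_shuffles = 500)
  expect_equal(null$mean[null$measure == "X_n"], 1)
  expect_equal(null$sd[null$measure == "X_n"], 0)

  # X_r null: compare to exhaustive mean over all C(4,2) = 6 labellings
  combos <- utils::combn(4, 2)
  xr_all <- apply(combos, 2, function(sel) {
    com <- colMeans(pos[sel, ])
    mean(sqrt(rowSums(sweep(pos[sel, , drop = FALSE], 2, com)^2)))
  })
  expect_equal(null$mean[null$measure == "X_r"], mean(xr_all), tolerance = 0.02)
  expect_gte(null$mean[null$measure == "X_r"], null$min[null$measure == "X_r"])
  expect_lte(null$mean[null$measure == "X_r"], null$max[null$measure == "X_r"])
})

test_that("randomized_null leaves its inputs untouched", {
  set.seed(33)
  fx <- generate_labelled_aggregate(20, arrangement = "shuffled")
  cells0 <- fx$cells
  contacts0 <- fx$contacts
  invisible(randomized_null(fx$cells, fx$contacts, n_shuffles = 100))
  expect_identical(fx$cells, cells0)
  expect_identical(fx$contacts, contacts0)
})

test_that("sorting index standardises against the null as defined", {
  expect_equal(sorting_index(5, 5, 2), 0)
  expect_equal(sorting_index(5 + 3 * 2, 5, 2, orientation = 1), 1)
  expect_equal(sorting_index(5 - 3 * 2, 5, 2, orientation = -1), 1)
  expect_error(sorting_index(1, 1, 0), "degenerate")
})

test_that("sorted fixtures score near 1 and shuffled fixtures near 0", {
  set.seed(34)
  fx <- generate_labelled_aggregate(30, arrangement = "sorted")
  si <- sorting_indices(fx$cells, fx$contacts, n_shuffles = 400)
  expect_true(all(si$index > 0.8))

  means <- replicate(8, {
    fx2 <- generate_labelled_aggregate(30, arrangement = "shuffled")
    mean(sorting_indices(fx2$cells, fx2$contacts, n_shuffles = 150)$index)
  })
  expect_lt(abs(mean(means)), 0.15)
})

test_that("expected sorting index over fresh shuffles is near zero", {
  set.seed(35)
  fx <- generate_labelled_aggregate(24, arrangement = "shuffled")
  null <- randomized_null(fx$cells, fx$contacts, n_shuffles = 1000)
  s <- attr(null, "samples")
  # standardising the null samples against the null itself centres them at 0
  for (m in colnames(s)) {
    idx <- (s[, m] - null$mean[null$measure == m]) /
      (3 * null$sd[null$measure == m])
    expect_lt(abs(mean(idx)), 0.05)
  }
})

test_that("cell contact graph from a simulated aggregate finds touching cells", {
  p <- test_params(A_M = 0.1)
  far <- toy_aggregate(rbind(c(0, 0, 0), c(12, 0, 0)), c(1L, 2L), params = p)
  expect_equal(nrow(cell_contact_graph(far)), 0)
  row3 <- toy_aggregate(rbind(c(0, 0, 0), c(2.6, 0, 0), c(5.2, 0, 0)),
                        c(1L, 1L, 2L), params = p)
  cg <- cell_contact_graph(row3)
  expect_equal(nrow(cg), 2)
  expect_equal(cg$cell_a, c(1, 2))
  expect_equal(cg$cell_b, c(2, 3))
})

test_that("sorting report over a trajectory carries indices and time scale", {
  set.seed(36)
  # a miniature trajectory assembled from fixture snapshots
  snaps <- dplyr::bind_rows(lapply(1:3, function(s) {
    fx <- generate_labelled_aggregate(12, arrangement = "sorted")
    cf <- fx$cells
    cf$snapshot <- s
    cf$time <- 10 * s
    attr(cf, "contacts") <- fx$contacts
    cf
  }))
  contacts <- dplyr::bind_rows(lapply(1:3, function(s) {
    ct <- attr(snaps, "contacts")
    fx <- generate_labelled_aggregate(12, arrangement = "sorted")
    ct <- fx$contacts
    ct$snapshot <- s
    ct$time <- 10 * s
    ct
  }))
  traj <- structure(list(snapshots = snaps, contacts = contacts,
                         events = tibble::tibble(),
                         lp = lifecycle_params(tau_C = 20)),
                    class = "sce_trajectory")
  rep <- sorting_report(traj, n_shuffles = 100)
  expect_s3_class(rep, "sce_sorting_report")
  expect_equal(sort(unique(rep$measure)), c("X_n", "X_r", "X_s"))
  expect_equal(unique(rep$T_over_tau), c(0.5, 1, 1.5))
  td <- tidy(rep)
  expect_true(all(c("index", "null_mean", "null_sd") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$final_n_cells, 12)
})
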