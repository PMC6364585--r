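test_that("fixture arrangements produce the intended spatial label patterns", {
  set.seed(50)
  fx <- generate_labelled_aggregate(30, arrangement = "sorted")
  cells <- fx$cells
  r <- sqrt(cells$x^2 + cells$y^2 + cells$z^2)
  expect_lt(mean(r[cells$type == 1]), mean(r[cells$type == 2]))
  expect_equal(sum(cells$type == 1), 15)

  sh <- generate_labelled_aggregate(30, arrangement = "shell")
  expect_true(all(sh$cells$free_area[sh$cells$type == 1] == 0))
  expect_equal(surface_measure(sh$cells), 1)

  expect_error(generate_labelled_aggregate(1), "n_cells")
  expect_error(generate_labelled_aggregate(10, type_ratio = 1,
                                           arrangement = "sorted"),
               "both types")
})

test_that("single-type fixtures put the whole free surface on that type", {
  set.seed(51)
  fx <- generate_labelled_aggregate(12, type_ratio = 0, arrangement = "shuffled")
  expect_equal(surface_measure(fx$cells, outer_type = 2), 1)
  fx1 <- generate_labelled_aggregate(12, type_ratio = 1, arrangement = "shuffled")
  expect_equal(surface_measure(fx1$cells, outer_type = 2), 0)
})

test_that("fixture generation is reproducible under a seed", {
  mk <- function() {
    set.seed(52)
    generate_labelled_aggregate(15, arrangement = "shuffled")
  }
  expect_identical(mk()$cells, mk()$cells)
  expect_identical(mk()$contacts, mk()$contacts)
})

test_that("fixture contact graphs connect touching sphere packings", {
  set.seed(53)
  fx <- generate_labelled_aggregate(20, arrangement = "shuffled")
  expect_gt(nrow(fx$contacts), 10)
  expect_true(all(fx$contacts$cell_a < fx$contacts$cell_b))
  d <- as.matrix(dist(as.matrix(fx$cells[, c("x", "y", "z")])))
  dc <- d[cbind(fx$contacts$cell_a, fx$contacts$cell_b)]
  expect_true(all(dc <= 1.35))
})

test_that("trajectory files round-trip losslessly with a schema header", {
  set.seed(54)
  snaps <- dplyr::bind_rows(lapply(1:10, function(s) {
    fx <- generate_labelled_aggregate(8)
    cf <- fx$cells
    cf$snapshot <- s
    cf$time <- s * 2.5
    cf
  }))
  traj <- list(snapshots = snaps,
               contacts = tibble::tibble(cell_a = 1L, cell_b = 2L,
                                         snapshot = 1L, time = 2.5),
               events = tibble::tibble())
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  expect_equal(readLines(path, n = 1), "#scemsort-trajectory v1")
  back <- read_trajectory(path)
  expect_equal(back$snapshots, snaps)
  expect_equal(back$contacts, traj$contacts)
  expect_equal(nrow(back$events), 0)
  expect_equal(max(back$snapshots$snapshot), 10)
  expect_true(all(diff(unique(back$snapshots$time)) > 0))

  # empty trajectory: valid file, empty tables
  p2 <- tempfile()
  write_trajectory(list(snapshots = tibble::tibble(),
                        contacts = tibble::tibble(),
                        events = tibble::tibble()), p2)
  b2 <- read_trajectory(p2)
  expect_equal(nrow(b2$snapshots), 0)

  # schema mismatch is an explicit error
  p3 <- tempfile()
  writeLines(c("#scemsort-trajectory v99", "x"), p3)
  expect_error(read_trajectory(p3), "schema mismatch")
})

test_that("trajectory files can carry the final element table", {
  set.seed(55)
  agg <- toy_aggregate(rbind(c(0, 0, 0), c(2.5, 0, 0)), c(1L, 2L),
                       params = test_params(A_M = 0.1))
  traj <- list(snapshots = tibble::tibble(), contacts = tibble::tibble(),
               events = tibble::tibble(), aggregate = agg)
  path <- tempfile()
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(nrow(back$elements), nrow(agg$elements))
  expect_equal(back$cells$type, c(1L, 2L))
  expect_equal(back$elements$x, agg$elements$x)
})

test_that("run configurations are read, validated and echoed", {
  cfg <- tempfile(fileext = ".yml")
  writeLines(c("seed: 7",
               "scale: test",
               "params:",
               "  gamma_m: 1.2",
               "  A_M: 0.2",
               "  beta: 0.5",
               "lifecycle:",
               "  tau_C: 50",
               "  stop_at: 12"), cfg)
  rc <- read_run_config(cfg)
  expect_equal(rc$seed, 7)
  expect_equal(rc$params$gamma_m, 1.2)
  expect_equal(rc$params$beta[1, 1], 0.5)
  expect_equal(rc$lifecycle$tau_C, 50)
  expect_equal(rc$preset$n_shuffles, 1000L)
  echoed <- paste(echo_config(rc, con = textConnection(NULL, "w")), collapse = "\n")
  expect_match(echoed, "gamma_m: 1.2")
  expect_match(echoed, "tau_C: 50")
  expect_match(echoed, "seed: 7")

  writeLines(c("seed: 1", "params:", "  nope: 3"), cfg)
  expect_error(read_run_config(cfg), "unknown params")
  writeLines(c("params:", "  gamma_m: 1"), cfg)
  expect_error(read_run_config(cfg), "seed")
})

test_that("mesh export writes a well-formed OFF file", {
  set.seed(56)
  cell <- single_cell(30, test_params(), relax_time = 0.5)
  path <- tempfile(fileext = ".off")
  write_mesh_off(cell, path)
  lines <- readLines(path)
  expect_equal(lines[1], "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_equal(length(lines), 2 + counts[1] + counts[2])
  facet_rows <- lines[(3 + counts[1]):(2 + counts[1] + counts[2])]
  expect_true(all(grepl("^3 ", facet_rows)))
})
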