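#' Cell growth and division parameters
#'
#' @param tau_C Cell-cycle time: the element count of a growing cell doubles
#'   over one `tau_C`, so cell number also doubles roughly every `tau_C`.
#' @param target_elements Element count at which a cell is mature and
#'   divides (daughters start near half this).
#' @param division_mode `"symmetric"` (daughters inherit the parent type) or
#'   `"asymmetric"` (with probability `p_switch` the division produces one
#'   cell of each type, assigned to the daughters at random).
#' @param p_switch Probability of a type-splitting division in asymmetric
#'   mode (0.5 by default).
#' @param start_at,stop_at Cell counts bracketing an aggregate growth run.
#' @return A list of class `sce_lifecycle`.
#' @export
lifecycle_params <- function(tau_C = 100, target_elements = 40,
                             division_mode = c("symmetric", "asymmetric"),
                             p_switch = 0.5, start_at = 10, stop_at = 30) {
  division_mode <- match.arg(division_mode)
  stopifnot(tau_C > 0, target_elements >= 8, p_switch >= 0, p_switch <= 1,
            stop_at >= start_at, start_at >= 1)
  structure(list(tau_C = tau_C, target_elements = as.integer(target_elements),
                 division_mode = division_mode, p_switch = p_switch,
                 start_at = as.integer(start_at), stop_at = as.integer(stop_at)),
            class = "sce_lifecycle")
}

#' Insert new elements into a growing cell
#'
#' New cytoplasm elements appear near the cell's centre of mass with a small
#' random offset, never beyond `target_elements`.
#'
#' @param agg An `sce_aggregate`.
#' @param cell Cell id to grow.
#' @param n_insert Number of elements to insert (default 1).
#' @param lp A [lifecycle_params()] object (supplies `target_elements`).
#' @return The aggregate with inserted elements (structure invalidated).
#' @export
grow_cell <- function(agg, cell, n_insert = 1, lp = lifecycle_params()) {
  stopifnot(inherits(agg, "sce_aggregate"))
  members <- agg$elements$cell == cell
  n_now <- sum(members)
  n_insert <- min(n_insert, max(0L, lp$target_elements - n_now))
  if (n_insert == 0) return(agg)
  com <- colMeans(agg$elements[members, c("x", "y", "z")])
  off <- random_ball(n_insert, radius = 0.3 * agg$params$re)
  new_el <- tibble::tibble(
    element = max(agg$elements$element) + seq_len(n_insert),
    cell = as.integer(cell),
    x = com[1] + off[, 1], y = com[2] + off[, 2], z = com[3] + off[, 3])
  agg$elements <- dplyr::bind_rows(agg$elements, new_el)
  agg$structure <- NULL
  agg
}

#' Divide a cell by a random plane through its centre of mass
#'
#' Elements are partitioned by a uniformly random plane; planes leaving a
#' daughter with fewer than 4 elements are redrawn. The new cell receives
#' the next free cell id. Element count is conserved. Daughter types follow
#' `lp$division_mode`.
#'
#' @param agg An `sce_aggregate`.
#' @param cell Cell id to divide.
#' @param lp A [lifecycle_params()] object.
#' @return The aggregate with one more cell (structure invalidated).
#' @export
divide_cell <- function(agg, cell, lp = lifecycle_params()) {
  stopifnot(inherits(agg, "sce_aggregate"))
  members <- which(agg$elements$cell == cell)
  if (length(members) < 8) stop("cell too small to divide (needs >= 8 elements)")
  pos <- as.matrix(agg$elements[members, c("x", "y", "z")])
  com <- colMeans(pos)
  for (try in 1:50) {
    nrm <- rnorm(3)
    nrm <- nrm / sqrt(sum(nrm^2))
    side <- drop(sweep(pos, 2, com) %*% nrm) >= 0
    if (sum(side) >= 4 && sum(!side) >= 4) break
    if (try == 50) stop("could not find a valid division plane")
  }
  new_id <- max(agg$cells$cell) + 1L
  agg$elements$cell[members[!side]] <- new_id
  parent_type <- agg$cells$type[agg$cells$cell == cell]
  if (lp$division_mode == "asymmetric" && runif(1) < lp$p_switch) {
    types <- sample(c(1L, 2L))   # one daughter of each type, order random
    agg$cells$type[agg$cells$cell == cell] <- types[1]
    new_type <- types[2]
  } else {
    new_type <- parent_type
  }
  agg$cells <- dplyr::bind_rows(agg$cells,
                                tibble::tibble(cell = new_id, type = new_type))
  agg$structure <- NULL
  agg
}

#' Seed a relaxed multi-cell aggregate
#'
#' Builds an `n_cells` aggregate by placing packed cell centres, filling
#' each cell with a ball of elements, relaxing the whole system, and then
#' assigning cell types (type 1 is the type expected to sort inward).
#'
#' @param n_cells Number of cells.
#' @param params A [sim_params()] object.
#' @param elements_per_cell Elements per cell at seeding.
#' @param type_ratio Fraction of cells of type 1 (default 0.5).
#' @param relax_time Whole-aggregate relaxation horizon (time units).
#' @return A relaxed `sce_aggregate` with shuffled type labels.
#' @export
seed_aggregate <- function(n_cells = 10, params = sim_params(),
                           elements_per_cell = 20, type_ratio = 0.5,
                           relax_time = 10) {
  stopifnot(n_cells >= 1, type_ratio >= 0, type_ratio <= 1)
  cell_r <- 0.62 * elements_per_cell^(1 / 3) * params$re
  centres <- packed_centres(n_cells, spacing = 2 * cell_r)
  el <- purrr::map(seq_len(n_cells), function(c) {
    pos <- random_ball_spaced(elements_per_cell, radius = cell_r,
                              dmin = 0.7 * params$re)
    tibble::tibble(cell = as.integer(c),
                   x = pos[, 1] + centres[c, 1],
                   y = pos[, 2] + centres[c, 2],
                   z = pos[, 3] + centres[c, 3])
  }) |> dplyr::bind_rows()
  el$element <- seq_len(nrow(el))
  n1 <- round(type_ratio * n_cells)
  types <- sample(c(rep(1L, n1), rep(2L, n_cells - n1)))
  agg <- new_aggregate(el, tibble::tibble(cell = seq_len(n_cells), type = types),
                       params)
  if (relax_time > 0)
    agg <- simulate_steps(agg, ceiling(relax_time / params$dt))
  agg
}

# roughly close-packed centres: random in a ball, then short repulsive
# relaxation to even out spacing
packed_centres <- function(n, spacing) {
  if (n == 1) return(matrix(0, 1, 3))
  R <- spacing * (n / 2)^(1 / 3)
  x <- random_ball(n, R)
  for (it in 1:200) {
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      close <- which(d[i, ] < spacing)
      if (length(close)) {
        dir <- sweep(x[close, , drop = FALSE], 2, x[i, ], FUN = "-")
        dn <- sqrt(rowSums(dir^2))
        push <- (spacing - dn) / pmax(dn, 1e-9)
        f[i, ] <- -colSums(dir * push) * 0.2
      }
      # weak central pull keeps the packing compact
      f[i, ] <- f[i, ] - 0.02 * x[i, ]
    }
    x <- x + f
    if (max(abs(f)) < 1e-4) break
  }
  x
}

#' Grow an aggregate to a target cell count
#'
#' Interleaves Langevin dynamics (in chunks), stochastic element insertion
#' calibrated so a cell's element count doubles over one `tau_C`, and cell
#' division when a cell reaches `target_elements`, until `stop_at` cells
#' exist. Snapshots of the cell table and contact graph are recorded at the
#' requested interval; after the target count is reached the final state is
#' recorded.
#'
#' @param agg A starting `sce_aggregate` (typically from [seed_aggregate()]).
#' @param lp A [lifecycle_params()] object.
#' @param snapshot_interval Time between recorded snapshots.
#' @param chunk_time Dynamics chunk between growth/division bookkeeping.
#' @param max_time Non-termination guard (time units).
#' @return A list of class `sce_trajectory`: `aggregate` (final state),
#'   `snapshots` (tibble of per-cell records with snapshot index and time),
#'   `contacts` (tibble of cell contact pairs per snapshot), and `events`
#'   (division log).
#' @export
run_to_cell_count <- function(agg, lp = lifecycle_params(),
                              snapshot_interval = 10, chunk_time = 0.5,
                              max_time = 10 * lp$tau_C) {
  stopifnot(inherits(agg, "sce_aggregate"), inherits(lp, "sce_lifecycle"))
  chunk_steps <- max(1L, ceiling(chunk_time / agg$params$dt))
  chunk_dt <- chunk_steps * agg$params$dt
  t_start <- agg$time
  snaps <- list()
  contacts <- list()
  events <- list()
  next_snap <- agg$time
  snap_i <- 0L

  take_snapshot <- function(agg) {
    agg <- update_structure(agg)
    snap_i <<- snap_i + 1L
    cf <- cell_frame(agg)
    cf$snapshot <- snap_i
    cf$time <- agg$time
    snaps[[snap_i]] <<- cf
    cg <- cell_contact_graph(agg)
    if (nrow(cg)) {
      cg$snapshot <- snap_i
      cg$time <- agg$time
    }
    contacts[[snap_i]] <<- cg
    agg
  }

  repeat {
    if (agg$time >= next_snap - 1e-9) {
      agg <- take_snapshot(agg)
      next_snap <- next_snap + snapshot_interval
    }
    if (nrow(agg$cells) >= lp$stop_at) break
    if (agg$time - t_start > max_time)
      stop("run_to_cell_count: max_time reached before the target cell count")
    agg <- simulate_steps(agg, chunk_steps)
    # growth: expected insertions n * ln2 * dt / tau_C per cell
    counts <- table(agg$elements$cell)
    for (c in agg$cells$cell) {
      n_now <- counts[[as.character(c)]]
      if (n_now >= lp$target_elements) next
      lambda <- n_now * log(2) * chunk_dt / lp$tau_C
      k <- rpois(1, lambda)
      if (k > 0) agg <- grow_cell(agg, c, n_insert = k, lp = lp)
    }
    # division of mature cells
    counts <- table(agg$elements$cell)
    for (c in agg$cells$cell) {
      if (nrow(agg$cells) >= lp$stop_at) break
      if (counts[[as.character(c)]] >= lp$target_elements) {
        old_types <- agg$cells$type
        agg <- divide_cell(agg, c, lp = lp)
        events[[length(events) + 1]] <- tibble::tibble(
          time = agg$time, parent = as.integer(c),
          daughter = max(agg$cells$cell),
          parent_type = old_types[c],
          type_switched = !all(agg$cells$type[c(c, max(agg$cells$cell))] ==
                                 old_types[c]))
      }
    }
  }
  agg <- take_snapshot(agg)
  structure(list(aggregate = agg,
                 snapshots = dplyr::bind_rows(snaps),
                 contacts = dplyr::bind_rows(contacts),
                 events = dplyr::bind_rows(events),
                 lp = lp),
            class = "sce_trajectory")
}

#' @export
print.sce_trajectory <- function(x, ...) {
  cat("<sce_trajectory> ", nrow(x$aggregate$cells), " cells, ",
      max(x$snapshots$snapshot), " snapshots, ",
      nrow(x$events), " divisions, t = ", signif(x$aggregate$time, 4),
      "\n", sep = "")
  invisible(x)
}
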