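#' Per-cell summary table of an aggregate
#'
#' One row per cell: type, centre of mass (unweighted mean of element
#' positions), element count, total cortical surface area and free surface
#' area (facets not at any cell-cell interface). This is the tabular
#' currency of the sorting measures, shared with fixture generators.
#'
#' @param agg An `sce_aggregate`.
#' @return A tibble with columns `cell`, `type`, `x`, `y`, `z`,
#'   `n_elements`, `area`, `free_area`.
#' @export
cell_frame <- function(agg) {
  agg <- update_structure(agg)
  s <- agg$structure
  cc <- cell_centres(agg)
  cc$area <- s$cell_area
  cc$free_area <- s$cell_area - s$cell_interface_area
  cc
}

#' Cell contact graph
#'
#' Two cells are neighbours if at least one element of one lies within the
#' interaction cutoff of an element of the other (counted even where the
#' force is zero).
#'
#' @param x An `sce_aggregate` or `sce_fixture`.
#' @return A tibble of undirected cell pairs, columns `cell_a < cell_b`.
#' @export
cell_contact_graph <- function(x) UseMethod("cell_contact_graph")

#' @export
cell_contact_graph.sce_aggregate <- function(x) {
  x <- update_structure(x)
  p <- x$structure$pairs
  ca <- x$elements$cell[p[, 1]]
  cb <- x$elements$cell[p[, 2]]
  keep <- ca != cb
  tibble::tibble(cell_a = pmin(ca[keep], cb[keep]),
                 cell_b = pmax(ca[keep], cb[keep])) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$cell_a, .data$cell_b)
}

#' @export
cell_contact_graph.sce_fixture <- function(x) x$contacts

#' Radius sorting measure
#'
#' Mean distance of all inner-type cells from the centre of mass of that
#' cell type. Small values indicate central aggregation of the inner type.
#'
#' @param cells A cell table (see [cell_frame()]) with `cell`, `type`, `x`,
#'   `y`, `z`.
#' @param inner_type The cell type expected to sort to the centre (1).
#' @return The measure `X_r` (a length).
#' @export
radius_measure <- function(cells, inner_type = 1) {
  sel <- cells$type == inner_type
  if (!any(sel)) stop("radius measure undefined: no cells of the inner type")
  x <- as.matrix(cells[sel, c("x", "y", "z")])
  com <- colMeans(x)
  mean(sqrt(rowSums(sweep(x, 2, com)^2)))
}

#' Neighbour sorting measure
#'
#' Number of contact-graph edges joining two inner-type cells.
#'
#' @param cells A cell table with `cell` and `type`.
#' @param contacts A contact table with `cell_a`, `cell_b`.
#' @inheritParams radius_measure
#' @return The count `X_n`.
#' @export
neighbour_measure <- function(cells, contacts, inner_type = 1) {
  t_of <- setNames(cells$type, cells$cell)
  sum(t_of[as.character(contacts$cell_a)] == inner_type &
        t_of[as.character(contacts$cell_b)] == inner_type)
}

#' Surface sorting measure
#'
#' Fraction of the aggregate's free surface area (cell surface not at any
#' cell-cell interface) contributed by the outer type.
#'
#' @param cells A cell table with `type` and `free_area`.
#' @param outer_type The cell type expected to sort to the outside (2).
#' @return The fraction `X_s` in `[0, 1]`.
#' @export
surface_measure <- function(cells, outer_type = 2) {
  tot <- sum(cells$free_area)
  if (tot <= 0) stop("surface measure undefined: no free surface")
  sum(cells$free_area[cells$type == outer_type]) / tot
}

#' All three sorting measures
#'
#' @inheritParams neighbour_measure
#' @param outer_type The type expected outside (2); the inner type is
#'   `inner_type`.
#' @return A tibble with columns `measure` (`X_r`, `X_n`, `X_s`) and `value`.
#' @export
sorting_measures <- function(cells, contacts, inner_type = 1, outer_type = 2) {
  tibble::tibble(
    measure = c("X_r", "X_n", "X_s"),
    value = c(radius_measure(cells, inner_type),
              neighbour_measure(cells, contacts, inner_type),
              surface_measure(cells, outer_type)))
}

#' Randomised-reassignment null distribution of the sorting measures
#'
#' Repeatedly permutes the cell-type labels over the fixed spatial
#' configuration (preserving the type counts), recomputing all three
#' measures each time, and summarises the resulting null distributions.
#' The input tables are untouched.
#'
#' @inheritParams sorting_measures
#' @param n_shuffles Number of label permutations (production default 1e4).
#' @return A tibble (class `sce_null`) with `measure`, `mean`, `sd`, `min`,
#'   `max`, `n_shuffles`; the raw samples are in `attr(, "samples")`
#'   (an `n_shuffles` x 3 matrix).
#' @export
randomized_null <- function(cells, contacts, n_shuffles = 1e4,
                            inner_type = 1, outer_type = 2) {
  if (n_shuffles < 2) stop("n_shuffles must be at least 2")
  stopifnot(nrow(cells) >= 2)
  types <- cells$type
  if (length(unique(types)) < 2)
    stop("randomised null needs both cell types present")
  pos <- as.matrix(cells[, c("x", "y", "z")])
  idx <- match(seq_len(nrow(cells)), cells$cell)  # cell id -> row
  ea <- match(contacts$cell_a, cells$cell)
  eb <- match(contacts$cell_b, cells$cell)
  free <- cells$free_area
  tot_free <- sum(free)
  samples <- matrix(NA_real_, n_shuffles, 3,
                    dimnames = list(NULL, c("X_r", "X_n", "X_s")))
  for (s in seq_len(n_shuffles)) {
    t_s <- sample(types)
    inner <- t_s == inner_type
    xin <- pos[inner, , drop = FALSE]
    com <- colMeans(xin)
    samples[s, 1] <- mean(sqrt(rowSums(sweep(xin, 2, com)^2)))
    samples[s, 2] <- sum(t_s[ea] == inner_type & t_s[eb] == inner_type)
    samples[s, 3] <- sum(free[t_s == outer_type]) / tot_free
  }
  out <- tibble::tibble(
    measure = colnames(samples),
    mean = unname(colMeans(samples)),
    sd = unname(apply(samples, 2, sd)),
    min = unname(apply(samples, 2, min)),
    max = unname(apply(samples, 2, max)),
    n_shuffles = n_shuffles)
  attr(out, "samples") <- samples
  class(out) <- c("sce_null", class(out))
  out
}

#' Sorting index
#'
#' Standardises a sorting measure against its permutation null:
#' `S = orientation * (X - E(X)) / (3 * sd(X))`. Values near 0 indicate a
#' randomly mixed system and values near 1 a sorted system. The radius
#' measure uses orientation -1 (sorted systems have a *small* inner-type
#' radius); the neighbour and surface measures use +1.
#'
#' @param x Measured value(s).
#' @param null_mean,null_sd Null mean and standard deviation.
#' @param orientation +1 or -1 (see above).
#' @return The sorting index (unbounded, but typically in `[0, 1]`).
#' @export
sorting_index <- function(x, null_mean, null_sd, orientation = 1) {
  if (any(null_sd <= 0)) stop("degenerate null: sd must be positive")
  orientation * (x - null_mean) / (3 * null_sd)
}

measure_orientation <- c(X_r = -1, X_n = 1, X_s = 1)

#' Sorting indices of a configuration
#'
#' Convenience: measures, permutation null and indices in one call.
#'
#' @inheritParams randomized_null
#' @return A tibble with one row per measure: `value`, null summaries and
#'   `index`.
#' @export
sorting_indices <- function(cells, contacts, n_shuffles = 1e3,
                            inner_type = 1, outer_type = 2) {
  m <- sorting_measures(cells, contacts, inner_type, outer_type)
  null <- randomized_null(cells, contacts, n_shuffles, inner_type, outer_type)
  out <- dplyr::left_join(m, null, by = "measure")
  out$index <- sorting_index(out$value, out$mean, out$sd,
                             measure_orientation[out$measure])
  out
}

#' Sorting report over a growth trajectory
#'
#' Computes the three sorting measures, their permutation nulls and the
#' sorting indices for every recorded snapshot of a growth run.
#'
#' @param traj An `sce_trajectory` from [run_to_cell_count()].
#' @param n_shuffles Permutations per snapshot.
#' @param tau_C Cell-cycle time used to express time as `T / tau_C`
#'   (defaults to the trajectory's own).
#' @return A tibble (class `sce_sorting_report`) with one row per snapshot
#'   and measure.
#' @export
sorting_report <- function(traj, n_shuffles = 1e3, tau_C = traj$lp$tau_C) {
  stopifnot(inherits(traj, "sce_trajectory"))
  snaps <- split(traj$snapshots, traj$snapshots$snapshot)
  cons <- if (nrow(traj$contacts)) split(traj$contacts, traj$contacts$snapshot) else list()
  out <- purrr::map(snaps, function(cf) {
    sn <- cf$snapshot[1]
    ct <- cons[[as.character(sn)]]
    if (is.null(ct)) ct <- tibble::tibble(cell_a = integer(), cell_b = integer())
    res <- tryCatch(sorting_indices(cf, ct, n_shuffles = n_shuffles),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    res$snapshot <- sn
    res$time <- cf$time[1]
    res$n_cells <- nrow(cf)
    res
  }) |> dplyr::bind_rows()
  out$T_over_tau <- out$time / tau_C
  class(out) <- c("sce_sorting_report", class(out))
  out
}

#' @export
#' @method tidy sce_sorting_report
tidy.sce_sorting_report <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "snapshot", "time", "T_over_tau",
                "n_cells", "measure", "value", null_mean = "mean",
                null_sd = "sd", "index")
}

#' @export
#' @method glance sce_sorting_report
glance.sce_sorting_report <- function(x, ...) {
  fin <- dplyr::filter(x, .data$snapshot == max(.data$snapshot))
  tibble::tibble(
    n_snapshots = max(x$snapshot), final_time = fin$time[1],
    final_n_cells = fin$n_cells[1],
    S_r = fin$index[fin$measure == "X_r"],
    S_n = fin$index[fin$measure == "X_n"],
    S_s = fin$index[fin$measure == "X_s"])
}

#' @export
#' @method autoplot sce_sorting_report
autoplot.sce_sorting_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$T_over_tau, y = .data$index,
                                       colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(T / tau[C]), y = "sorting index",
                  colour = NULL, title = "Sorting indices over growth") +
    ggplot2::theme_minimal()
}
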