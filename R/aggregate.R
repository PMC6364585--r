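#' Construct an aggregate from element and cell tables
#'
#' An `sce_aggregate` holds the full state of a simulation: an element table
#' (positions, owning cell), a cell table (cell id, cell type 1 or 2), the
#' parameter set and the simulation clock. Derived structure (cortex labels,
#' triangulation, interface labels, areas) is computed on demand by
#' [update_structure()] and cached.
#'
#' @param elements A data frame with columns `element`, `cell`, `x`, `y`, `z`.
#' @param cells A data frame with columns `cell`, `type` (1 or 2).
#' @param params A [sim_params()] object.
#' @param time Simulation clock (default 0).
#' @return An object of class `sce_aggregate`.
#' @export
new_aggregate <- function(elements, cells, params, time = 0) {
  elements <- tibble::as_tibble(elements)
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("element", "cell", "x", "y", "z") %in% names(elements)),
            all(c("cell", "type") %in% names(cells)),
            all(elements$cell %in% cells$cell),
            all(cells$type %in% c(1L, 2L)))
  cells <- dplyr::arrange(cells, .data$cell)
  if (!identical(as.integer(cells$cell), seq_len(nrow(cells))))
    stop("cell ids must be consecutive integers 1..n_cells")
  agg <- structure(list(elements = elements, cells = cells,
                        params = params, time = time, structure = NULL),
                   class = "sce_aggregate")
  agg
}

#' Create a single relaxed cell
#'
#' Places `n_elements` elements uniformly in a ball sized for unit element
#' spacing and relaxes them with the full model (cortex, tension network)
#' until the cloud is mechanically settled.
#'
#' @param n_elements Number of elements in the cell.
#' @param params A [sim_params()] object.
#' @param type Cell type (1 or 2).
#' @param centre Cell centre, length-3 numeric.
#' @param relax_time Relaxation horizon in time units (0 to skip).
#' @return An `sce_aggregate` with one cell.
#' @examples
#' \donttest{
#' set.seed(1)
#' cell <- single_cell(40, sim_params(gamma_m = 0.5, A_M = 0))
#' }
#' @export
single_cell <- function(n_elements, params, type = 1L, centre = c(0, 0, 0),
                        relax_time = 10) {
  stopifnot(n_elements >= 4)
  pos <- random_ball_spaced(n_elements,
                            radius = 0.62 * n_elements^(1 / 3) * params$re,
                            dmin = 0.7 * params$re)
  elements <- tibble::tibble(
    element = seq_len(n_elements), cell = 1L,
    x = pos[, 1] + centre[1], y = pos[, 2] + centre[2], z = pos[, 3] + centre[3])
  agg <- new_aggregate(elements, tibble::tibble(cell = 1L, type = as.integer(type)),
                       params)
  if (relax_time > 0)
    agg <- simulate_steps(agg, n_steps = ceiling(relax_time / params$dt))
  agg
}

# uniform sample in a ball (rejection-free: radius by cube-root transform)
random_ball <- function(n, radius) {
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * runif(n)^(1 / 3)
  u * r
}

# ball sample with a minimum pairwise separation (dart throwing with a
# gradually relaxed exclusion radius), so freshly built cells start without
# overlapping cores that would trip the displacement guard
random_ball_spaced <- function(n, radius, dmin = 0.7) {
  out <- matrix(NA_real_, n, 3)
  k <- 0L
  tries <- 0L
  while (k < n) {
    cand <- random_ball(1, radius)
    ok <- k == 0L ||
      min(rowSums(sweep(out[seq_len(k), , drop = FALSE], 2, cand)^2)) >= dmin^2
    if (ok) {
      k <- k + 1L
      out[k, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 200L * n) {  # too dense: relax the exclusion radius
      dmin <- dmin * 0.9
      tries <- 0L
    }
  }
  out
}

#' @export
print.sce_aggregate <- function(x, ...) {
  cat("<sce_aggregate> ", nrow(x$cells), " cell(s), ", nrow(x$elements),
      " elements, t = ", signif(x$time, 4), "\n", sep = "")
  tt <- table(factor(x$cells$type, levels = 1:2))
  cat("  cell types: ", tt[1], " of type 1, ", tt[2], " of type 2\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sce_aggregate <- function(x, ...) as.data.frame(element_table(x))

#' Element table of an aggregate
#'
#' Returns the per-element state as a tibble, including the owning cell's
#' type and, when structure is current, the element type (cytoplasm/cortex)
#' and interface label.
#'
#' @param agg An `sce_aggregate`.
#' @return A tibble with one row per element.
#' @export
element_table <- function(agg) {
  stopifnot(inherits(agg, "sce_aggregate"))
  el <- dplyr::left_join(agg$elements,
                         dplyr::select(agg$cells, cell = "cell", cell_type = "type"),
                         by = "cell")
  if (!is.null(agg$structure)) {
    el$etype <- c("cytoplasm", "cortex")[agg$structure$etype + 1L]
    el$label <- c("none", "same_type", "other_type", "both")[agg$structure$label + 1L]
  }
  el
}

positions_matrix <- function(agg) {
  as.matrix(agg$elements[, c("x", "y", "z")])
}

#' Recompute the derived structure of an aggregate
#'
#' Runs, in order: cortex allocation (32-sector rule), spherical-Delaunay
#' triangulation of each cell's cortex, neighbour search, interface
#' labelling from adhesive inter-cell contacts, facet areas and the
#' density-normalisation factors for adhesion. The result is cached on the
#' aggregate and invalidated by any position change.
#'
#' @param agg An `sce_aggregate`.
#' @return The aggregate with an up-to-date `$structure`.
#' @export
update_structure <- function(agg) {
  stopifnot(inherits(agg, "sce_aggregate"))
  agg$structure <- cpp_structure(positions_matrix(agg),
                                 as.integer(agg$elements$cell),
                                 as.integer(agg$cells$type),
                                 pars_for_cpp(agg$params))
  agg
}

#' Allocate cortex elements of one cell
#'
#' Partitions the sphere about the centre of mass into 32 equal-solid-angle
#' sectors (4 equal-area polar bands x 8 azimuthal slices) and labels as
#' cortex every element whose radius exceeds `radius_fraction` (default
#' 0.80) of the maximum radius in its sector; each sector's outermost
#' element is always cortex. Re-application on fixed positions is
#' idempotent.
#'
#' @param positions An n x 3 matrix of element positions (one cell).
#' @param centre Centre of mass; defaults to the column means.
#' @param radius_fraction Allocation threshold in (0, 1).
#' @return A character vector, `"cortex"` or `"cytoplasm"` per element.
#' @export
allocate_cortex <- function(positions, centre = colMeans(positions),
                            radius_fraction = 0.8) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 1,
            radius_fraction > 0, radius_fraction < 1)
  lab <- cpp_allocate_cortex(positions, as.numeric(centre), radius_fraction)
  c("cytoplasm", "cortex")[lab + 1L]
}

#' Triangulate the cortex of one cell
#'
#' Takes the convex hull of the cortex element positions, a closed
#' triangulated surface (V - E + F = 2) equivalent to the spherical Delaunay
#' triangulation for the near-convex cells simulated here; tension edges are
#' therefore tangential to the cell surface. Cortex elements lying strictly
#' inside the hull (inner layers of a thick cortex band) are not mesh
#' vertices and carry no tension.
#'
#' @param positions An n x 3 matrix of cortex element positions (n >= 4,
#'   not coplanar).
#' @param centre Projection centre; defaults to the column means.
#' @return A tibble of facets with vertex indices `a`, `b`, `c` (rows of
#'   `positions`) and the facet `area` computed from the unprojected
#'   positions.
#' @export
triangulate_cortex <- function(positions, centre = colMeans(positions)) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 4)
    stop("triangulation needs at least 4 cortex elements")
  k <- seq_len(nrow(positions))
  u <- positions + 1e-9 * cbind(sin(0.7 * k), cos(1.3 * k), sin(2.1 * k))
  fac <- cpp_convex_hull(u)
  area <- vapply(seq_len(nrow(fac)), function(f) {
    e1 <- positions[fac[f, 2], ] - positions[fac[f, 1], ]
    e2 <- positions[fac[f, 3], ] - positions[fac[f, 1], ]
    0.5 * sqrt(sum(crossprod3(e1, e2)^2))
  }, numeric(1))
  tibble::tibble(a = fac[, 1], b = fac[, 2], c = fac[, 3], area = area)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Label cortex elements at cell-cell interfaces
#'
#' A cortex element is labelled by the type of any neighbouring cell whose
#' cortex it shares an adhesive interaction with (within the interaction
#' cutoff): `same_type`, `other_type`, `both` at triple contacts, or `none`.
#'
#' @param agg An `sce_aggregate`.
#' @return The element table with `etype` and `label` columns.
#' @export
label_interface_elements <- function(agg) {
  agg <- update_structure(agg)
  element_table(agg)
}

#' Per-element cortical tension forces
#'
#' Every edge of the cortical triangulation carries an attractive force of
#' constant magnitude `gamma_m`, reduced to `beta[t, t'] * gamma_m` on edges
#' whose two endpoints share an interface label (the applicable `beta` is
#' that of the cell-type pair at the interface; the smaller factor wins at
#' triple contacts).
#'
#' @param agg An `sce_aggregate`.
#' @return A tibble with per-element tension force components.
#' @export
apply_cortical_tension <- function(agg) {
  f <- force_list(agg)
  tibble::tibble(element = agg$elements$element,
                 fx = f$tension[, 1], fy = f$tension[, 2], fz = f$tension[, 3])
}

#' Density-normalisation factors for adhesion
#'
#' Each cortex element's adhesive force is scaled by its share of the cell
#' surface (one-third of the summed areas of its incident facets) divided by
#' the cell mean of that share, so adhesion per unit surface area does not
#' depend on local element crowding. Cytoplasm elements get factor 1.
#'
#' @param agg An `sce_aggregate`.
#' @return A tibble with columns `element` and `adh_factor`.
#' @export
density_normalized_adhesion <- function(agg) {
  agg <- update_structure(agg)
  tibble::tibble(element = agg$elements$element,
                 adh_factor = agg$structure$adh_factor)
}

force_list <- function(agg) {
  stopifnot(inherits(agg, "sce_aggregate"))
  cpp_forces(positions_matrix(agg), as.integer(agg$elements$cell),
             as.integer(agg$cells$type), pars_for_cpp(agg$params))
}

#' Total force on every element
#'
#' Sums intra-cell Morse interactions, inter-cell repulsion/adhesion
#' (density-normalised) and cortical tension edge forces. All pairwise
#' contributions are equal and opposite, so the aggregate's net internal
#' force is zero to machine precision.
#'
#' @param agg An `sce_aggregate`.
#' @return A tibble with total and per-contribution force components.
#' @export
total_forces <- function(agg) {
  f <- force_list(agg)
  tibble::tibble(
    element = agg$elements$element, cell = agg$elements$cell,
    fx = f$total[, 1], fy = f$total[, 2], fz = f$total[, 3],
    morse_fx = f$morse[, 1], morse_fy = f$morse[, 2], morse_fz = f$morse[, 3],
    tension_fx = f$tension[, 1], tension_fy = f$tension[, 2],
    tension_fz = f$tension[, 3])
}

#' Advance the aggregate by overdamped Langevin steps
#'
#' Explicit Euler-Maruyama update `x <- x + (dt / gamma) * (F + zeta)` with
#' i.i.d. Gaussian `zeta` of standard deviation `noise_amp` per component.
#' Structure (cortex allocation, triangulation, labels) is refreshed every
#' `realloc_stride` steps. Aborts with a step-size error if any element
#' moves more than `re / 2` in one step.
#'
#' @param agg An `sce_aggregate`.
#' @param n_steps Number of steps to take.
#' @param record_stride If positive, record the aggregate interface
#'   proportion every this many steps (retrievable via `attr(, "trace")`).
#' @return The advanced aggregate; the clock moves by `n_steps * dt`.
#' @export
simulate_steps <- function(agg, n_steps, record_stride = 0) {
  stopifnot(inherits(agg, "sce_aggregate"), n_steps >= 0)
  if (n_steps == 0) return(update_structure(agg))
  out <- cpp_simulate(positions_matrix(agg), as.integer(agg$elements$cell),
                      as.integer(agg$cells$type), pars_for_cpp(agg$params),
                      as.integer(n_steps), as.integer(record_stride), agg$time)
  agg$elements$x <- out$pos[, 1]
  agg$elements$y <- out$pos[, 2]
  agg$elements$z <- out$pos[, 3]
  agg$time <- out$time
  agg$structure <- out$structure
  attr(agg, "trace") <- tibble::tibble(time = out$trace_time, I_P = out$trace_ip)
  attr(agg, "max_displacement") <- out$max_displacement
  agg
}

#' Single Langevin step
#'
#' Convenience wrapper for one step of [simulate_steps()].
#'
#' @inheritParams simulate_steps
#' @return The advanced aggregate.
#' @export
langevin_step <- function(agg) simulate_steps(agg, 1L)

#' Find element pairs within a cutoff distance
#'
#' Uniform-grid (cell list) neighbour search: returns every unordered pair
#' of points separated by at most `cutoff`, each pair once.
#'
#' @param positions An n x 3 matrix of positions.
#' @param cutoff Positive interaction radius.
#' @return A tibble with columns `i`, `j` (`i < j`).
#' @export
find_neighbours <- function(positions, cutoff) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, cutoff > 0)
  p <- cpp_neighbour_pairs(positions, cutoff)
  tibble::tibble(i = p[, 1], j = p[, 2]) |> dplyr::arrange(.data$i, .data$j)
}

#' Centres of mass of all cells
#'
#' @param agg An `sce_aggregate`.
#' @return A tibble with `cell`, `type`, `x`, `y`, `z` and `n_elements`.
#' @export
cell_centres <- function(agg) {
  stopifnot(inherits(agg, "sce_aggregate"))
  agg$elements |>
    dplyr::group_by(cell = .data$cell) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     n_elements = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(dplyr::select(agg$cells, cell = "cell", type = "type"),
                     by = "cell") |>
    dplyr::relocate("cell", "type")
}

#' Export the cortical tension network as an OFF polygon mesh
#'
#' Writes the triangulated cortex surfaces of all cells to a single OFF
#' file for external visualisation.
#'
#' @param agg An `sce_aggregate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(agg, path) {
  agg <- update_structure(agg)
  s <- agg$structure
  pos <- positions_matrix(agg)
  used <- sort(unique(as.vector(s$facets)))
  remap <- match(seq_len(nrow(pos)), used)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", length(used), nrow(s$facets)), con)
  writeLines(sprintf("%.8g %.8g %.8g", pos[used, 1], pos[used, 2], pos[used, 3]), con)
  writeLines(sprintf("3 %d %d %d", remap[s$facets[, 1]] - 1L,
                     remap[s$facets[, 2]] - 1L, remap[s$facets[, 3]] - 1L), con)
  invisible(path)
}
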