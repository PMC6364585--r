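#' Linear force balance prediction of the interface proportion
#'
#' The analytic doublet model balances cortical and interfacial tension at
#' the contact line (neglecting adhesion), giving a contact angle
#' \eqn{\beta = \cos(\theta / 2)} and interface proportion
#' \eqn{I_P = (1 - \beta) / (3 - \beta)}.
#'
#' @param beta Interfacial tension factor(s) in `[0, 1]`.
#' @return Predicted interface proportion(s): 0 at `beta = 1`, 1/3 (two
#'   hemispheres) at `beta = 0`.
#' @examples
#' lfb_interface_proportion(c(0.5, 0.75, 1)) # 0.20, 0.11, 0.00
#' @export
lfb_interface_proportion <- function(beta) {
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  (1 - beta) / (3 - beta)
}

#' Interfacial tension factor from the doublet contact angle
#'
#' @param theta Contact angle(s) in radians, in `[0, pi]`.
#' @return `cos(theta / 2)`.
#' @export
lfb_beta_from_angle <- function(theta) {
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  cos(theta / 2)
}

#' Build and relax a cell doublet
#'
#' Follows the divide-then-relax protocol: a single cell of `2 * n_elements`
#' elements is created and relaxed, divided through its centre of mass into
#' two identical-type daughters, and the doublet is then relaxed without
#' growth or division until the windowed mean interface proportion changes
#' by less than `tol` per window (or `max_time` is reached).
#'
#' @param params A [sim_params()] object (its `beta`, `A_M`, `gamma_m`
#'   define the doublet's mechanics).
#' @param n_elements Elements per daughter cell.
#' @param relax_single Relaxation horizon for the parent cell (time units).
#' @param window Averaging/convergence window (time units).
#' @param max_time Maximum doublet relaxation horizon (time units).
#' @param tol Convergence threshold on the change of the windowed mean
#'   interface proportion (absolute).
#' @return The relaxed two-cell `sce_aggregate`, with attributes
#'   `I_P` (final-window mean interface proportion), `converged`, and
#'   `trace` (tibble of interface proportion over time).
#' @export
make_doublet <- function(params, n_elements = 60, relax_single = 10,
                         window = 10, max_time = 150, tol = 0.005) {
  agg <- single_cell(2 * n_elements, params, type = 1L,
                     relax_time = relax_single)
  agg <- divide_cell(agg, cell = 1L)
  steps_per_window <- ceiling(window / params$dt)
  rec <- max(1L, steps_per_window %/% 20L)
  trace <- NULL
  ip_prev <- Inf
  converged <- FALSE
  ip_mean <- NA_real_
  while (agg$time < max_time) {
    agg <- simulate_steps(agg, steps_per_window, record_stride = rec)
    w <- attr(agg, "trace")
    trace <- dplyr::bind_rows(trace, w)
    ip_mean <- mean(w$I_P)
    if (is.finite(ip_prev) && abs(ip_mean - ip_prev) < tol) {
      converged <- TRUE
      break
    }
    ip_prev <- ip_mean
  }
  attr(agg, "trace") <- trace
  attr(agg, "I_P") <- ip_mean
  attr(agg, "converged") <- converged
  agg
}

#' Measure the interface proportion of a doublet (or aggregate)
#'
#' The interface area is the sum of the areas of all cortical triangulation
#' facets whose three vertex elements each hold an adhesive interaction with
#' the neighbouring cell; the interface proportion `I_P` is that sum divided
#' by the total facet area of all cells.
#'
#' @param agg An `sce_aggregate`.
#' @return A one-row tibble (class `sce_doublet`) with `I_P`,
#'   `interface_area`, `total_surface_area`, and the governing `beta`,
#'   `A_M`, `gamma_m` and `alpha = A_M / gamma_m`.
#' @export
measure_interface_proportion <- function(agg) {
  agg <- update_structure(agg)
  s <- agg$structure
  total <- sum(s$cell_area)
  iface <- sum(s$cell_interface_area)
  out <- tibble::tibble(
    I_P = if (total > 0) iface / total else 0,
    interface_area = iface, total_surface_area = total,
    beta = agg$params$beta[1, 1], A_M = agg$params$A_M[1, 1],
    gamma_m = agg$params$gamma_m,
    alpha = agg$params$A_M[1, 1] / max(agg$params$gamma_m, 1e-12))
  class(out) <- c("sce_doublet", class(out))
  out
}

#' Scan doublet behaviour over a parameter grid
#'
#' Runs independently seeded doublet relaxations for every combination of
#' the supplied `beta`, `A_M` and `gamma_m` values and returns a tidy table
#' of interface proportions, alongside the linear-force-balance prediction.
#' Individual run failures are recorded (`ok = FALSE`) and the scan
#' continues.
#'
#' @param beta,A_M,gamma_m Numeric vectors; the scan covers their full
#'   crossing.
#' @param n_seeds Repeats per grid point (distinct RNG substreams).
#' @param n_elements Elements per daughter cell.
#' @param ... Further arguments passed to [make_doublet()].
#' @param base_params A [sim_params()] object supplying all non-scanned
#'   parameters.
#' @return A tibble (class `sce_doublet_scan`) with one row per run.
#' @export
scan_phase_diagram <- function(beta = c(0.5, 0.75, 1), A_M = 0.2,
                               gamma_m = 1.2, n_seeds = 3, n_elements = 60,
                               base_params = sim_params(), ...) {
  grid <- tidyr::crossing(beta = beta, A_M = A_M, gamma_m = gamma_m,
                          seed_rep = seq_len(n_seeds))
  res <- purrr::pmap(grid, function(beta, A_M, gamma_m, seed_rep) {
    p <- base_params
    p$beta <- beta_matrix(beta, beta, beta)
    p$A_M <- adhesion_matrix(A_M)
    p$gamma_m <- gamma_m
    out <- tryCatch({
      d <- make_doublet(p, n_elements = n_elements, ...)
      tibble::tibble(I_P = attr(d, "I_P"),
                     I_P_final = measure_interface_proportion(d)$I_P,
                     converged = attr(d, "converged"), ok = TRUE)
    }, error = function(e) {
      tibble::tibble(I_P = NA_real_, I_P_final = NA_real_,
                     converged = NA, ok = FALSE)
    })
    dplyr::bind_cols(tibble::tibble(beta = beta, A_M = A_M,
                                    gamma_m = gamma_m, seed_rep = seed_rep),
                     out)
  }) |> dplyr::bind_rows()
  res$alpha <- res$A_M / pmax(res$gamma_m, 1e-12)
  res$I_P_lfb <- lfb_interface_proportion(res$beta)
  class(res) <- c("sce_doublet_scan", class(res))
  res
}

#' @export
#' @method autoplot sce_doublet_scan
autoplot.sce_doublet_scan <- function(object, ...) {
  betas <- seq(0, 1, by = 0.01)
  lfb <- tibble::tibble(beta = betas, I_P = lfb_interface_proportion(betas))
  summ <- object |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$beta, .data$A_M, .data$gamma_m) |>
    dplyr::summarise(I_P_mean = mean(.data$I_P), I_P_sd = sd(.data$I_P),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$beta, y = .data$I_P_mean)) +
    ggplot2::geom_line(data = lfb, ggplot2::aes(y = .data$I_P),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$I_P_mean - .data$I_P_sd,
      ymax = .data$I_P_mean + .data$I_P_sd,
      colour = factor(.data$gamma_m), shape = factor(.data$A_M))) +
    ggplot2::labs(x = expression(beta), y = expression(I[P]),
                  colour = expression(gamma[m]), shape = expression(A[M]),
                  title = "Doublet interface proportion vs linear force balance") +
    ggplot2::theme_minimal()
}

#' @export
#' @method tidy sce_doublet_scan
tidy.sce_doublet_scan <- function(x, ...) {
  x |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$beta, .data$A_M, .data$gamma_m, .data$alpha) |>
    dplyr::summarise(n = dplyr::n(), I_P_mean = mean(.data$I_P),
                     I_P_sd = sd(.data$I_P),
                     I_P_lfb = .data$I_P_lfb[1], .groups = "drop") |>
    dplyr::mutate(offset = .data$I_P_mean - .data$I_P_lfb)
}
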