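#' Morse interaction parameters
#'
#' Bundle the parameters of a Morse potential
#' \eqn{V(r) = D_e (e^{-2a(r - r_e)} - 2 e^{-a(r - r_e)} + 1)}, which is 0 at
#' its minimum `re` and approaches `De` at large separation. Interactions in
#' the dynamics are truncated at `cutoff`: the *force* is zero beyond it,
#' which shifts the potential there by an additive constant that overdamped
#' dynamics never see.
#'
#' @param De Well depth (energy; also the asymptotic energy as `r` grows).
#' @param a Inverse-length range parameter.
#' @param re Equilibrium separation (the length unit of the model; default 1).
#' @param cutoff Truncation radius; must exceed `re`.
#' @return An object of class `morse_params`.
#' @examples
#' p <- morse_params(De = 1, a = 2)
#' morse_potential(seq(0.8, 2.5, by = 0.1), p)
#' @export
morse_params <- function(De, a, re = 1, cutoff = 2.5 * re) {
  stopifnot(De >= 0, a > 0, re > 0, cutoff > re)
  structure(list(De = De, a = a, re = re, cutoff = cutoff),
            class = "morse_params")
}

#' Morse potential energy
#'
#' @param r Separation(s); must be positive.
#' @param p A [morse_params()] object.
#' @return Energy value(s): 0 at `r = re`, approaching `De` as `r` grows;
#'   constant (`V(cutoff)`) beyond the cutoff, where the force vanishes.
#' @export
morse_potential <- function(r, p) {
  stopifnot(inherits(p, "morse_params"))
  if (any(r <= 0)) stop("separation r must be positive")
  v <- function(x) p$De * (exp(-2 * p$a * (x - p$re)) - 2 * exp(-p$a * (x - p$re)) + 1)
  out <- v(pmin(r, p$cutoff))
  out
}

#' Morse force (signed magnitude, positive = repulsive)
#'
#' Returns \eqn{-dV/dr}: positive below the equilibrium separation
#' (repulsion), negative between `re` and the cutoff (attraction), zero at
#' `re` and beyond the cutoff. The maximum attractive force is
#' \eqn{a D_e / 2}, attained at \eqn{r = r_e + \ln 2 / a}; this relation is
#' used to convert a target maximum adhesive force \eqn{A_M} into a well
#' depth \eqn{D_e = 2 A_M / a}.
#'
#' @inheritParams morse_potential
#' @return Signed force value(s).
#' @export
morse_force <- function(r, p) {
  stopifnot(inherits(p, "morse_params"))
  if (any(r <= 0)) stop("separation r must be positive")
  e1 <- exp(-p$a * (r - p$re))
  out <- 2 * p$a * p$De * (e1^2 - e1)
  out[r > p$cutoff] <- 0
  out
}

#' Build a symmetric 2x2 interfacial tension factor matrix
#'
#' Interfacial tension at a like-type interface of type-t cells is
#' `beta[t, t] * gamma_m`; at an unlike interface it is `beta[1, 2] * gamma_m`.
#' Sorting studies conventionally vary `beta11` (type 1 sorts inward) while
#' holding `beta12 = beta22 = 1`.
#'
#' @param beta11,beta12,beta22 Factors in `[0, 1]`.
#' @return A symmetric 2x2 matrix.
#' @export
beta_matrix <- function(beta11 = 1, beta12 = 1, beta22 = 1) {
  stopifnot(all(c(beta11, beta12, beta22) >= 0), all(c(beta11, beta12, beta22) <= 1))
  matrix(c(beta11, beta12, beta12, beta22), 2, 2)
}

#' Build a symmetric 2x2 adhesion magnitude matrix
#'
#' `A_M[t1, t2]` is the maximum attractive force of the adhesive cortex-cortex
#' interaction between cells of types `t1` and `t2`. Differential-adhesion
#' studies use `adhesion_matrix(A1, sqrt(A1 * A2), A2)` or simply scale
#' `A22 = R * A11`.
#'
#' @param A11,A12,A22 Non-negative maximum adhesive forces.
#' @return A symmetric 2x2 matrix.
#' @export
adhesion_matrix <- function(A11 = 0.2, A12 = A11, A22 = A11) {
  stopifnot(A11 >= 0, A12 >= 0, A22 >= 0)
  matrix(c(A11, A12, A12, A22), 2, 2)
}

#' Simulation parameters for the subcellular element model
#'
#' All quantities are in reduced units: the element equilibrium separation
#' `re` is the length unit and the drag coefficient `gamma_drag` the
#' time/force normalisation, both 1 by default. Forces (`gamma_m`, `A_M`,
#' `noise_amp`) are therefore directly comparable to the dimensionless
#' ratios `alpha = A_M / gamma_m` and `beta` used throughout.
#'
#' @param gamma_m Cortical tension: constant attractive force on every edge
#'   of the cortical triangulation. The high-tension regime is around 1.2,
#'   the low-tension regime around 0.01.
#' @param A_M Adhesion magnitude: maximum attractive force of the inter-cell
#'   cortex-cortex interaction. Scalar (same for all type pairs) or a 2x2
#'   matrix from [adhesion_matrix()].
#' @param beta Interfacial tension factor(s): scalar (applied to every
#'   interface) or a 2x2 matrix from [beta_matrix()].
#' @param De_core,a_core Morse well depth and range of the intra-cell
#'   element-element interaction.
#' @param De_rep,a_rep Morse parameters of the inter-cell repulsive-only
#'   core (the attractive branch is zeroed), which keeps cells from
#'   interpenetrating.
#' @param rep_cap Ceiling on the inter-cell repulsive force, so transient
#'   overlaps (e.g. right after division) relax smoothly instead of
#'   tripping the displacement guard; does not move the repulsive wall.
#' @param a_adh Range parameter of the adhesive Morse branch; the well depth
#'   is derived from `A_M` as `2 * A_M / a_adh` so that the peak attraction
#'   equals `A_M`.
#' @param re Element equilibrium separation (length unit).
#' @param cutoff_core Truncation radius of the intra-cell Morse interaction
#'   and the inter-cell repulsive core; short (1.5 `re`) so that cohesion is
#'   effectively nearest-neighbour.
#' @param cutoff_adh Truncation radius of the adhesive inter-cell force.
#' @param label_cutoff Distance within which a cortex element "shares an
#'   adhesive interaction" with another cell's cortex and is labelled as
#'   interface; interface labels drive the interfacial tension scaling.
#' @param measure_cutoff Tighter contact distance defining a *bound*
#'   adhesive pair for interface-area measurement: interface facets are
#'   those whose three vertices each hold a contact below this separation
#'   (near the adhesive well minimum `re + log(2) / a_adh`), which excludes
#'   proximal-but-unbound neighbours at the repulsive wall.
#' @param noise_amp Standard deviation of the Gaussian random force applied
#'   per component per step (thermal jitter; small compared with tension).
#' @param dt Time step of the explicit Euler-Maruyama update. A guard aborts
#'   if any per-step displacement exceeds `re / 2`.
#' @param gamma_drag Drag coefficient of the overdamped update.
#' @param radius_fraction Cortex allocation threshold: elements whose radius
#'   exceeds this fraction of their sector's maximum are cortex (0.80).
#' @param n_sectors Number of equal-solid-angle sectors used for cortex
#'   allocation; fixed at 32 (4 equal-area polar bands x 8 azimuthal slices).
#' @param realloc_stride Re-run cortex allocation and retriangulation every
#'   this many steps (1 = every step).
#' @return A list of class `sce_params`.
#' @examples
#' p <- sim_params(gamma_m = 1.2, A_M = 0.2, beta = 0.5)
#' @export
sim_params <- function(gamma_m = 1.2, A_M = 0.2, beta = 1,
                       De_core = 0.2, a_core = 4, De_rep = 0.2, a_rep = 4,
                       a_adh = 4, rep_cap = 20, re = 1, cutoff_core = 1.5 * re,
                       cutoff_adh = 2 * re, label_cutoff = 1.4 * re,
                       measure_cutoff = 1.05 * re,
                       noise_amp = 0.3, dt = 0.005, gamma_drag = 1,
                       radius_fraction = 0.8, n_sectors = 32,
                       realloc_stride = 1) {
  if (length(A_M) == 1) A_M <- adhesion_matrix(A_M)
  if (length(beta) == 1) beta <- beta_matrix(beta, beta, beta)
  stopifnot(is.matrix(A_M), dim(A_M) == c(2, 2), isSymmetric(A_M),
            is.matrix(beta), dim(beta) == c(2, 2), isSymmetric(beta),
            all(beta >= 0), all(beta <= 1),
            gamma_m >= 0, gamma_drag > 0, dt > 0,
            radius_fraction > 0, radius_fraction < 1,
            cutoff_core > re, cutoff_adh > re, label_cutoff > re, re > 0)
  if (n_sectors != 32)
    stop("the cortex allocation uses a fixed 32-sector equal-solid-angle partition")
  structure(list(
    gamma_m = gamma_m, A_M = A_M, beta = beta,
    De_core = De_core, a_core = a_core, De_rep = De_rep, a_rep = a_rep,
    a_adh = a_adh, rep_cap = rep_cap, re = re, cutoff_core = cutoff_core,
    cutoff_adh = cutoff_adh, label_cutoff = label_cutoff,
    measure_cutoff = measure_cutoff,
    noise_amp = noise_amp, dt = dt, gamma_drag = gamma_drag,
    radius_fraction = radius_fraction, n_sectors = n_sectors,
    realloc_stride = as.integer(realloc_stride)
  ), class = "sce_params")
}

#' @export
print.sce_params <- function(x, ...) {
  cat("<sce_params> reduced units (re = ", x$re, ", gamma_drag = ", x$gamma_drag, ")\n", sep = "")
  cat("  cortical tension gamma_m:", x$gamma_m, "\n")
  cat("  adhesion A_M:", paste(signif(x$A_M[c(1, 2, 4)], 3), collapse = "/"),
      "(11/12/22), alpha =", signif(x$A_M[1, 1] / max(x$gamma_m, 1e-12), 3), "\n")
  cat("  interfacial tension factors beta:",
      paste(signif(x$beta[c(1, 2, 4)], 3), collapse = "/"), "(11/12/22)\n")
  cat("  Morse core: De =", x$De_core, "a =", x$a_core,
      "| cutoffs =", x$cutoff_core, "/", x$cutoff_adh,
      "| dt =", x$dt, "| noise =", x$noise_amp, "\n")
  invisible(x)
}

#' Tabulate the element-pair interaction rules
#'
#' A readable view of which potential applies between element types within
#' and across cells: intra-cell pairs interact through the full Morse core;
#' inter-cell pairs involving a cytoplasm element are repulsive-only; and
#' inter-cell cortex-cortex pairs add the adhesive attractive branch whose
#' peak force is `A_M` for the cell-type pair.
#'
#' @param params A [sim_params()] object.
#' @return A tibble with one row per (type, type, same-cell) combination.
#' @export
interaction_table <- function(params) {
  stopifnot(inherits(params, "sce_params"))
  tibble::tribble(
    ~etype_a,    ~etype_b,    ~same_cell, ~potential,        ~De,                ~a,
    "cytoplasm", "cytoplasm", TRUE,       "morse",           params$De_core,     params$a_core,
    "cytoplasm", "cortex",    TRUE,       "morse",           params$De_core,     params$a_core,
    "cortex",    "cortex",    TRUE,       "morse + tension", params$De_core,     params$a_core,
    "cytoplasm", "cytoplasm", FALSE,      "repulsive-only",  params$De_rep,      params$a_rep,
    "cytoplasm", "cortex",    FALSE,      "repulsive-only",  params$De_rep,      params$a_rep,
    "cortex",    "cortex",    FALSE,      "repulsion + adhesion",
    2 * params$A_M[1, 1] / params$a_adh, params$a_adh
  )
}

# flatten to the list layout the C++ core expects
pars_for_cpp <- function(params) {
  list(re = params$re, cutoff_core = params$cutoff_core,
       cutoff_adh = params$cutoff_adh, label_cutoff = params$label_cutoff,
       measure_cutoff = params$measure_cutoff,
       De_core = params$De_core, a_core = params$a_core,
       De_rep = params$De_rep, a_rep = params$a_rep,
       a_adh = params$a_adh, rep_cap = params$rep_cap,
       A_M = params$A_M, beta = params$beta,
       gamma_m = params$gamma_m, noise_amp = params$noise_amp,
       dt = params$dt, gamma_drag = params$gamma_drag,
       radius_fraction = params$radius_fraction,
       realloc_stride = params$realloc_stride,
       edge_label_rule = params$edge_label_rule %||% 0L)
}

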