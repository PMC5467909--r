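# Closed-form reference solutions used to validate the finite-element
# pipeline: series-resistor layered slab, the Maxwell homogeneous sphere in
# a uniform field, and the shelled (necrotic-core) sphere reduced to an
# equivalent homogeneous conductivity.

#' Series-resistor solution for a layered slab
#'
#' A stack of homogeneous layers between two equipotential plates carries a
#' uniform current density `J = dV / sum(d_i / sigma_i)` (thicknesses in
#' metres internally; arguments in mm); each layer then sees the field
#' `E_i = J / sigma_i`, and the total current is `I = J * area`.
#'
#' @param layers two-column matrix or data.frame: thickness (mm) and
#'   conductivity (S/m) per layer.
#' @param delta_V plate potential difference (V).
#' @param area_mm2 plate area (mm^2), used for the total current.
#' @return list with per-layer `E_Vpm`, the shared `J_Apm2`, and the total
#'   current `I_A`.
#' @export
slab_series_field <- function(layers, delta_V = 1, area_mm2 = NULL) {
  layers <- as.matrix(layers)
  d_m <- layers[, 1] / 1000
  sig <- layers[, 2]
  if (any(d_m <= 0) || any(sig <= 0)) {
    stop("thicknesses and conductivities must be positive")
  }
  J <- delta_V / sum(d_m / sig)
  out <- list(E_Vpm = J / sig, J_Apm2 = J)
  if (!is.null(area_mm2)) out$I_A <- J * area_mm2 * 1e-6
  out
}

#' Interior field of a homogeneous sphere in a uniform applied field
#'
#' A sphere of conductivity `sigma_i` embedded in an infinite medium of
#' conductivity `sigma_e` under a far uniform field `E0` carries the uniform
#' interior field `E_in = 3 sigma_e / (sigma_i + 2 sigma_e) * E0`.
#'
#' @param sigma_i,sigma_e conductivities (S/m).
#' @param E0 applied far-field strength (V/m).
#' @return interior field magnitude (V/m).
#' @export
sphere_in_uniform_field <- function(sigma_i, sigma_e, E0 = 1) {
  stopifnot(sigma_i >= 0, sigma_e > 0)
  3 * sigma_e / (sigma_i + 2 * sigma_e) * E0
}

#' Equivalent conductivity of a shelled sphere
#'
#' A concentric core/shell sphere is electrically indistinguishable from the
#' outside from a homogeneous sphere of conductivity
#' `sigma_eq = sigma_s * (sigma_c + 2 sigma_s + 2 v (sigma_c - sigma_s)) /
#'            (sigma_c + 2 sigma_s -   v (sigma_c - sigma_s))`
#' with volume fraction `v = (r_core / r_outer)^3`.
#'
#' @param sigma_core,sigma_shell conductivities (S/m).
#' @param r_core,r_outer radii (any common unit).
#' @return equivalent homogeneous conductivity (S/m).
#' @export
shelled_sphere_equivalent_sigma <- function(sigma_core, sigma_shell,
                                            r_core, r_outer) {
  stopifnot(r_core > 0, r_core < r_outer, sigma_core > 0, sigma_shell > 0)
  v <- (r_core / r_outer)^3
  ds <- sigma_core - sigma_shell
  sigma_shell * (sigma_core + 2 * sigma_shell + 2 * v * ds) /
    (sigma_core + 2 * sigma_shell - v * ds)
}

#' Shelled sphere in a uniform field
#'
#' Reduces the necrotic-tumor geometry (well conducting core inside a less
#' conductive active shell) to its equivalent homogeneous sphere. The
#' volume-averaged field over the whole tumor equals the uniform interior
#' field of the equivalent sphere (both are fixed by the matched exterior
#' potential); the core field is approximated by nesting the homogeneous
#' formula once more with the shell as the surrounding medium.
#'
#' @param sigma_core,sigma_shell,sigma_ext conductivities (S/m).
#' @param r_core,r_outer radii (common unit).
#' @param E0 applied far-field strength (V/m).
#' @return list with `sigma_eq` (S/m), `E_avg_Vpm` (volume-averaged tumor
#'   field), and `E_core_Vpm` (nested-approximation core field).
#' @export
shelled_sphere_in_uniform_field <- function(sigma_core, sigma_shell,
                                            sigma_ext, r_core, r_outer,
                                            E0 = 1) {
  sigma_eq <- shelled_sphere_equivalent_sigma(sigma_core, sigma_shell,
                                              r_core, r_outer)
  E_avg <- sphere_in_uniform_field(sigma_eq, sigma_ext, E0)
  E_core <- sphere_in_uniform_field(sigma_core, sigma_shell, E_avg)
  list(sigma_eq = sigma_eq, E_avg_Vpm = E_avg, E_core_Vpm = E_core)
}
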