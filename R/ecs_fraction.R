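# Steady-state extracellular volume-fraction (fo) solver.
#
# Tissue is modelled as a fixed total volume w_tot shared by the
# extracellular space (ECS, fraction fo) and intracellular space (ICS,
# fraction fi = 1 - fo). The ICS traps impermeants x_i of mean charge z; the
# ECS traps a small amount x_o of uncharged impermeants which prevents fo
# from collapsing to zero. At a prescribed membrane voltage V and added bath
# osmolyte s_o, the stable fo satisfies the osmotic fixed point
#
#   fo = 1 - (1 - z) x_i / { w_tot [ c_o(s_o) - 2 Cl_o exp(FV/RT) + x_o/(fo w_tot) ] }
#
# with c_o(s_o) the total bath osmolarity. Only ratios of x_i, x_o, w_tot
# matter; x_i = 1 arbitrary unit is the default.

#' Calibrate the total tissue volume from a reference condition
#'
#' Computes the stable cell volume at a reference medium and voltage via
#' [steady_state_cell_volume()] and fixes the total (ECS + ICS) volume so
#' that the ECS takes an initial fraction `fo_init` of it:
#' w_tot = w_ref / (1 - fo_init).
#'
#' @param x_i Intracellular impermeant amount (arbitrary units).
#' @param z Mean impermeant charge.
#' @param media Reference [media_composition()].
#' @param V_ref_mV Reference membrane voltage in mV.
#' @param fo_init Initial ECS fraction in (0, 1).
#' @param T_K Absolute temperature in K.
#' @return Total volume w_tot (same units as the reference cell volume).
#' @examples
#' calibrate_total_volume(1, -1, media_normal(), -48, 0.3)
#' @export
calibrate_total_volume <- function(x_i, z, media = media_normal(),
                                   V_ref_mV = -48, fo_init = 0.3, T_K = 298) {
  if (fo_init < 0 || fo_init >= 1) stop("`fo_init` must lie in [0, 1)")
  w_ref <- steady_state_cell_volume(x_i, z, media_osmolarity(media),
                                    media$Cl_o, V_ref_mV, T_K)
  w_ref / (1 - fo_init)
}

#' Parameters of the steady-state volume-fraction model
#'
#' Bundles the impermeant amounts, reference medium, and calibrated total
#' volume used by [solve_fo()]. The ECS impermeant amount defaults to
#' x_i / 50; the reference geometry is calibrated at the normal medium,
#' V = -48 mV, initial ECS fraction 0.3.
#'
#' @param x_i Intracellular impermeant amount (arbitrary units, > 0).
#' @param z Mean impermeant charge (<= 0).
#' @param xo_ratio ECS impermeant amount as a fraction of `x_i`.
#' @param media Bath [media_composition()] before osmolyte addition.
#' @param V_ref_mV Reference voltage for calibration, mV.
#' @param fo_init Initial ECS fraction used to calibrate w_tot.
#' @param T_K Absolute temperature in K.
#' @return An object of class `volume_model_params`.
#' @examples
#' p <- volume_model_params()
#' solve_fo(p, s_o = 0, V_mV = -48)$fo
#' @export
volume_model_params <- function(x_i = 1, z = -1, xo_ratio = 1 / 50,
                                media = media_normal(), V_ref_mV = -48,
                                fo_init = 0.3, T_K = 298) {
  if (x_i <= 0) stop("`x_i` must be > 0")
  if (z > 0) stop("`z` must be <= 0")
  if (xo_ratio < 0) stop("`xo_ratio` must be >= 0")
  w_tot <- calibrate_total_volume(x_i, z, media, V_ref_mV, fo_init, T_K)
  structure(list(x_i = x_i, z = z, x_o = xo_ratio * x_i, media = media,
                 V_ref_mV = V_ref_mV, fo_init = fo_init, T_K = T_K,
                 w_tot = w_tot),
            class = "volume_model_params")
}

#' @export
print.volume_model_params <- function(x, ...) {
  cat("Volume-fraction model: x_i =", x$x_i, " z =", x$z,
      " x_o =", x$x_o, " w_tot =", signif(x$w_tot, 6),
      " (fo_init =", x$fo_init, "at", x$V_ref_mV, "mV)\n")
  invisible(x)
}

#' Solve for the steady-state ECS volume fraction
#'
#' Finds the ECS fraction fo in (0, 1) satisfying the osmotic fixed point
#' described in the package vignette. The fixed point is equivalent to the
#' quadratic B fo^2 + (C - B + A) fo - C = 0 with
#' A = (1 - z) x_i / w_tot, B = c_o(s_o) - 2 Cl_o exp(FV/RT),
#' C = x_o / w_tot, which is solved in closed form; a bracketing root search
#' on the fixed-point residual is used as a fallback when the quadratic is
#' degenerate.
#'
#' @param params A [volume_model_params()] object.
#' @param s_o Added uncharged osmolyte concentration in mOsm (>= 0).
#' @param V_mV Membrane voltage in mV.
#' @return An object of class `fo_solution`: a list with `fo`, `fi = 1 - fo`,
#'   the impermeant osmolarities `osm_ecs` = x_o/(fo w_tot) and
#'   `osm_ics` = x_i/(fi w_tot) in mM, and the inputs `s_o`, `V_mV`.
#' @examples
#' p <- volume_model_params()
#' solve_fo(p, 0, -48)$fo  # ~0.32
#' solve_fo(p, 0, -10)$fo  # ~0.02
#' @export
solve_fo <- function(params, s_o = 0, V_mV = -48) {
  stopifnot(inherits(params, "volume_model_params"))
  if (s_o < 0) stop("`s_o` must be >= 0")
  media <- params$media
  c_o <- media_osmolarity(media, s_extra = s_o)
  A <- (1 - params$z) * params$x_i / params$w_tot
  B <- c_o - 2 * media$Cl_o * chloride_partition_ratio(V_mV, params$T_K)
  C <- params$x_o / params$w_tot

  fo <- solve_fo_quadratic(A, B, C)
  if (is.na(fo)) {
    # degenerate quadratic: bracketed search on the fixed-point residual
    resid <- function(f) f - (1 - A / (B + C / f))
    lo <- 1e-12; hi <- 1 - 1e-12
    if (resid(lo) * resid(hi) > 0)
      stop("no ECS fraction in (0, 1): fixed-point residual does not change ",
           "sign on (0, 1); A=", signif(A, 4), " B=", signif(B, 4),
           " C=", signif(C, 4))
    fo <- stats::uniroot(resid, c(lo, hi), tol = 1e-14)$root
  }
  structure(list(fo = fo, fi = 1 - fo,
                 osm_ecs = params$x_o / (fo * params$w_tot),
                 osm_ics = params$x_i / ((1 - fo) * params$w_tot),
                 s_o = s_o, V_mV = V_mV),
            class = "fo_solution")
}

# closed-form root of B f^2 + (C - B + A) f - C = 0 in (0, 1);
# returns NA when the quadratic route does not apply (B <= 0 with no
# admissible root), errors when no root exists at all.
solve_fo_quadratic <- function(A, B, C) {
  b1 <- C - B + A
  if (abs(B) < 1e-300) {
    if (b1 <= 0) return(NA_real_)
    f <- C / b1
    if (f > 0 && f < 1) return(f)
    stop("no ECS fraction in (0, 1): linear-limit root f = ", signif(f, 4))
  }
  disc <- b1^2 + 4 * B * C
  if (disc < 0) return(NA_real_)
  r <- sqrt(disc)
  roots <- c((-b1 - r) / (2 * B), (-b1 + r) / (2 * B))
  inside <- roots[roots > 0 & roots < 1]
  if (length(inside) == 0) {
    if (B < 0) return(NA_real_)
    stop("no ECS fraction in (0, 1): quadratic roots ",
         paste(signif(roots, 4), collapse = ", "))
  }
  if (length(inside) == 2) {
    warning("two admissible ECS fractions; returning the larger root ",
            "(continuous with the high-osmolyte limit)")
    return(max(inside))
  }
  inside
}

#' Impermeant osmolarities at a given ECS fraction
#'
#' @param params A [volume_model_params()] object.
#' @param fo ECS volume fraction, strictly inside (0, 1).
#' @return A list with `osm_ecs` = x_o/(fo w_tot) and
#'   `osm_ics` = x_i/((1 - fo) w_tot), both in mM.
#' @export
impermeant_osmolarities <- function(params, fo) {
  stopifnot(inherits(params, "volume_model_params"))
  if (fo <= 0 || fo >= 1) stop("`fo` must lie strictly inside (0, 1)")
  list(osm_ecs = params$x_o / (fo * params$w_tot),
       osm_ics = params$x_i / ((1 - fo) * params$w_tot))
}

#' @export
print.fo_solution <- function(x, ...) {
  cat(sprintf(
    "ECS fraction fo = %.4f (fi = %.4f) at V = %g mV, s_o = %g mOsm\n",
    x$fo, x$fi, x$V_mV, x$s_o))
  cat(sprintf("  impermeant osmolarity: ECS %.3g mM, ICS %.3g mM\n",
              x$osm_ecs, x$osm_ics))
  invisible(x)
}
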