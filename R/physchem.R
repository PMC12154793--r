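# Physical constants, SGSE encoding physics, and closed-form
# electrochemical / osmotic relations.
#
# Unit conventions at every interface:
#   concentrations mM, voltages mV, times ms, gradients T/m,
#   diffusivities um^2/ms, b-values ms/um^2, rates 1/s, temperatures K.
# SI is used internally; all conversion factors live in this file.

#' Physical constants
#'
#' Faraday constant, molar gas constant, and the proton gyromagnetic ratio
#' used throughout the package. The gyromagnetic ratio defaults to that of
#' 1H and can be overridden for other nuclei.
#'
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1. Default is the 1H value.
#' @return A list with elements `faraday` (C/mol), `gas` (J mol^-1 K^-1) and
#'   `gamma` (rad s^-1 T^-1).
#' @examples
#' nmr_constants()$gamma
#' @export
nmr_constants <- function(gamma = 2.6752218744e8) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("`gamma` must be a single positive number (rad s^-1 T^-1)")
  list(faraday = 96485.33212, gas = 8.314462618, gamma = gamma)
}

# thermal voltage RT/F in mV
thermal_voltage_mV <- function(T_K, const = nmr_constants()) {
  if (!is.numeric(T_K) || any(T_K <= 0)) stop("temperature must be > 0 K")
  1000 * const$gas * T_K / const$faraday
}

#' SGSE b-value from the static-gradient formula
#'
#' For a static-gradient spin echo the diffusion weighting is set by the
#' half-echo time tau: b = (2/3) gamma^2 g^2 tau^3.
#'
#' @param tau_ms Half-echo time in ms (scalar or vector, must be >= 0).
#' @param g Static gradient strength in T/m (> 0).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @return b-value(s) in ms/um^2.
#' @examples
#' b_value(0.735, g = 15.3) # ~4.435 ms/um^2
#' @export
b_value <- function(tau_ms, g, gamma = nmr_constants()$gamma) {
  if (any(!is.finite(tau_ms)) || any(tau_ms < 0)) stop("`tau_ms` must be >= 0")
  if (!is.numeric(g) || length(g) != 1L || g <= 0) stop("`g` must be > 0 (T/m)")
  tau_s <- tau_ms * 1e-3
  b_si <- (2 / 3) * gamma^2 * g^2 * tau_s^3 # s/m^2
  b_si * 1e-9                               # -> ms/um^2
}

#' Dephasing and diffusion length scales of SGSE encoding
#'
#' The dephasing length l_g = (D0/(gamma g))^(1/3) is the scale over which
#' freely diffusing spins dephase by about one cycle in the static gradient;
#' the diffusion length l_d = sqrt(D0 tau) is the free displacement scale
#' during one encoding period. Compartments appear restricted when the
#' structural length between bounding surfaces is below these scales.
#'
#' @param D0 Free water diffusivity in um^2/ms (> 0).
#' @param g Static gradient in T/m (> 0).
#' @param tau_ms Half-echo time in ms (>= 0; only l_d depends on it).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @return A list with `l_g` and `l_d`, both in um.
#' @examples
#' length_scales(D0 = 2.15, g = 15.3, tau_ms = 0.735)
#' @export
length_scales <- function(D0, g, tau_ms = 0, gamma = nmr_constants()$gamma) {
  if (!is.numeric(D0) || D0 <= 0) stop("`D0` must be > 0 (um^2/ms)")
  if (!is.numeric(g) || g <= 0) stop("`g` must be > 0 (T/m)")
  if (any(tau_ms < 0)) stop("`tau_ms` must be >= 0")
  D0_si <- D0 * 1e-9 # m^2/s
  l_g <- (D0_si / (gamma * g))^(1 / 3) * 1e6 # um
  l_d <- sqrt(D0 * tau_ms)                   # um^2/ms * ms under sqrt -> um
  list(l_g = l_g, l_d = l_d)
}

#' Van't Hoff osmotic pressure
#'
#' Ideal-solution osmotic pressure pi = c R T for a solute concentration c.
#' Used for order-of-magnitude estimates of the pressure exerted by
#' membrane-impermeant solutes.
#'
#' @param c_mM Solute concentration in mM (>= 0).
#' @param T_K Absolute temperature in K.
#' @return Osmotic pressure in kPa.
#' @examples
#' vant_hoff_pressure(40, 298) # on the order of 100 kPa
#' @export
vant_hoff_pressure <- function(c_mM, T_K = 298) {
  if (any(c_mM < 0)) stop("`c_mM` must be >= 0")
  if (any(T_K <= 0)) stop("`T_K` must be > 0")
  const <- nmr_constants()
  # mM == mol/m^3, so c R T is in Pa
  c_mM * const$gas * T_K / 1000
}

#' Nernst chloride partition ratio
#'
#' Ratio of intracellular to extracellular chloride at electrochemical
#' equilibrium across a membrane held at voltage V: Cl_i/Cl_o = exp(F V / R T).
#'
#' @param V_mV Membrane voltage in mV (negative = cell interior negative).
#' @param T_K Absolute temperature in K.
#' @return Dimensionless partition ratio; 1 at V = 0.
#' @examples
#' chloride_partition_ratio(-48) # ~0.15
#' chloride_partition_ratio(-10) # ~0.68
#' @export
chloride_partition_ratio <- function(V_mV, T_K = 298) {
  exp(V_mV / thermal_voltage_mV(T_K))
}

#' Steady-state cell volume from impermeant content and chloride partition
#'
#' For a cell containing x moles of impermeant solute of mean charge z,
#' bathed in media of total osmolarity c_o with chloride Cl_o, at membrane
#' voltage V, the osmotically stable volume is
#' w = (1 - z) x / (c_o - 2 Cl_o exp(F V / R T)).
#'
#' @param x Impermeant amount (arbitrary mole units; w is linear in x).
#' @param z Mean impermeant charge (dimensionless, typically negative).
#' @param c_o Total bath osmolarity in mM.
#' @param Cl_o Bath chloride concentration in mM.
#' @param V_mV Membrane voltage in mV.
#' @param T_K Absolute temperature in K.
#' @return Cell volume in units of x / mM.
#' @examples
#' steady_state_cell_volume(1, -1, 264, 132, -48)
#' @export
steady_state_cell_volume <- function(x, z, c_o, Cl_o, V_mV, T_K = 298) {
  if (any(x < 0)) stop("`x` must be >= 0")
  denom <- c_o - 2 * Cl_o * chloride_partition_ratio(V_mV, T_K)
  if (any(denom <= 0))
    stop("no stable volume: c_o - 2 Cl_o exp(FV/RT) must be positive ",
         "(denominator = ", paste(signif(denom, 4), collapse = ", "), ")")
  (1 - z) * x / denom
}

#' Osmolyte concentration that recovers cell volume after depolarization
#'
#' Added impermeant osmolyte concentration for which the stable cell volume
#' at a depolarized voltage V_off equals the volume at the polarized voltage
#' V_on: s_o = -2 Cl_o [exp(F V_on / R T) - exp(F V_off / R T)].
#'
#' @param Cl_o Bath chloride concentration in mM.
#' @param V_on_mV Polarized (pump-on) membrane voltage in mV.
#' @param V_off_mV Depolarized (pump-off) membrane voltage in mV.
#' @param T_K Absolute temperature in K.
#' @return Required osmolyte concentration in mOsm (linear in Cl_o,
#'   antisymmetric in the two voltages).
#' @examples
#' recovery_osmolarity(132, -48, -10) # ~138 mOsm
#' @export
recovery_osmolarity <- function(Cl_o, V_on_mV, V_off_mV, T_K = 298) {
  -2 * Cl_o * (chloride_partition_ratio(V_on_mV, T_K) -
                 chloride_partition_ratio(V_off_mV, T_K))
}

#' Bath media composition
#'
#' Ionic and osmolyte composition of the bathing medium. The bath must be
#' electroneutral: Na_o + K_o = Cl_o + g_o, where g_o is a monovalent
#' impermeant anion (e.g. gluconate) and s_o an uncharged osmolyte
#' (e.g. sucrose).
#'
#' @param Na_o,K_o,Cl_o Sodium, potassium and chloride concentrations in mM.
#' @param s_o Uncharged osmolyte concentration in mM.
#' @param g_o Monovalent impermeant anion concentration in mM.
#' @return An object of class `media_composition`.
#' @examples
#' media_normal()
#' media_composition(Na_o = 0, K_o = 4, Cl_o = 4, s_o = 256) # NaCl -> sucrose
#' @export
media_composition <- function(Na_o, K_o, Cl_o, s_o = 0, g_o = 0) {
  vals <- c(Na_o = Na_o, K_o = K_o, Cl_o = Cl_o, s_o = s_o, g_o = g_o)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all media concentrations must be finite and >= 0")
  if (abs((Na_o + K_o) - (Cl_o + g_o)) > 1e-8 * max(1, Na_o + K_o))
    stop("bath is not electroneutral: Na_o + K_o must equal Cl_o + g_o")
  structure(as.list(vals), class = "media_composition")
}

#' @rdname media_composition
#' @details `media_normal()` is the reference medium: 128 mM NaCl plus
#'   4 mM KCl (Na_o = 128, K_o = 4, Cl_o = 132 mM), no added osmolytes.
#' @export
media_normal <- function() media_composition(Na_o = 128, K_o = 4, Cl_o = 132)

#' Total osmolarity of a medium
#'
#' @param media A [media_composition()] object.
#' @param s_extra Additional uncharged osmolyte in mM (default 0).
#' @return Total osmolarity Na_o + K_o + Cl_o + s_o + g_o + s_extra in mM.
#' @export
media_osmolarity <- function(media, s_extra = 0) {
  stopifnot(inherits(media, "media_composition"))
  media$Na_o + media$K_o + media$Cl_o + media$s_o + media$g_o + s_extra
}

#' @export
print.media_composition <- function(x, ...) {
  cat("Bath medium (mM): Na", x$Na_o, " K", x$K_o, " Cl", x$Cl_o,
      " osmolyte", x$s_o, " impermeant anion", x$g_o,
      " | total", media_osmolarity(x), "mOsm\n")
  invisible(x)
}
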