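# Finite-difference pump-leak model (PLM) of cell volume and voltage.
#
# A single cell with membrane permeabilities to Na+, K+ and Cl- and an
# electrogenic Na+/K+-ATPase (3 Na+ out : 2 K+ in) is bathed in a medium of
# fixed composition. Each forward-Euler step:
#   1. updates intracellular ion amounts by (passive + pump) fluxes * dt;
#   2. recomputes the membrane voltage from the net intracellular charge
#      and the (constant) membrane capacitance;
#   3. resets the cell volume so that intracellular and extracellular
#      osmolarities are exactly equal (water permeability is taken as much
#      larger than ion permeability and is not modelled explicitly).
#
# Units are normalized per cell: volume in units of the initial cell volume
# (w0 = 1), ion amounts in mM * w0 (so concentration = amount / volume),
# permeabilities in 1/s (membrane area absorbed), pump rate in mM * w0 / s.
# The capacitance enters through `beta_mV_per_mM`, the voltage produced per
# unit of net charge-concentration imbalance; its default softens the
# membrane charging stiffness while leaving the charge imbalance at the
# resting voltage far below 1% of total osmolarity, so steady-state volumes
# and voltages are insensitive to it (checked in the test suite).

#' Pump-leak model parameters
#'
#' @param P_Na,P_K,P_Cl Membrane permeabilities in 1/s (area absorbed;
#'   >= 0). The defaults give the resting-cell ordering P_K > P_Cl > P_Na.
#' @param pump_rate Na+/K+-ATPase turnover scale in mM/s per unit cell
#'   volume; 3 Na+ leave and 2 K+ enter per cycle. Set with
#'   [calibrate_pump_rate()] for pump-on scenarios, 0 for pump-off.
#' @param K_m_pump Michaelis constant (mM) of the pump's dependence on
#'   intracellular Na+; makes the pump shut down when the cell runs out of
#'   sodium (as in sodium-free media).
#' @param beta_mV_per_mM Voltage produced per unit net charge-concentration
#'   (mV per mM), i.e. F w0 / C_m in the normalized units.
#' @param x_i Impermeant amount trapped in the cell (mM * w0).
#' @param z Mean impermeant charge.
#' @param dt Timestep in s.
#' @param t_end Total simulated time in s.
#' @param T_K Absolute temperature in K.
#' @param flux_law `"ghk"` (Goldman-Hodgkin-Katz, default) or `"linear"`
#'   (plain driving-force) passive flux law; both vanish exactly at the
#'   Nernst equilibrium.
#' @return An object of class `plm_params`.
#' @export
plm_params <- function(P_Na = 0.02, P_K = 0.2, P_Cl = 0.1,
                       pump_rate = 0, K_m_pump = 10,
                       beta_mV_per_mM = 25,
                       x_i = 100, z = -1,
                       dt = 0.02, t_end = 2000, T_K = 298,
                       flux_law = c("ghk", "linear")) {
  flux_law <- match.arg(flux_law)
  if (any(c(P_Na, P_K, P_Cl) < 0)) stop("permeabilities must be >= 0")
  if (pump_rate < 0) stop("`pump_rate` must be >= 0")
  if (dt <= 0 || t_end < dt) stop("need dt > 0 and t_end >= dt")
  if (x_i <= 0) stop("`x_i` must be > 0")
  structure(list(P_Na = P_Na, P_K = P_K, P_Cl = P_Cl,
                 pump_rate = pump_rate, K_m_pump = K_m_pump,
                 beta_mV_per_mM = beta_mV_per_mM, x_i = x_i, z = z,
                 dt = dt, t_end = t_end, T_K = T_K, flux_law = flux_law),
            class = "plm_params")
}

#' Passive transmembrane ion flux
#'
#' Flux (positive into the cell) of an ion with valence `q` down its
#' electrochemical gradient. The default Goldman-Hodgkin-Katz form is
#' flux = -P (c_i - c_o exp(-q F V / R T)) * phi, with the voltage factor
#' phi = (q F V / R T) / (1 - exp(-q F V / R T)); the `"linear"` law drops
#' phi. Both laws are exactly zero at the Nernst equilibrium
#' c_i = c_o exp(-q F V / R T).
#'
#' @param q Ion valence (+1 for Na+/K+, -1 for Cl-).
#' @param c_i,c_o Intracellular and extracellular concentrations in mM.
#' @param P Permeability in 1/s.
#' @param V_mV Membrane voltage in mV.
#' @param T_K Absolute temperature in K.
#' @param flux_law `"ghk"` or `"linear"`.
#' @return Flux in mM/s (per unit cell volume), positive into the cell.
#' @export
passive_flux <- function(q, c_i, c_o, P, V_mV, T_K = 298,
                         flux_law = c("ghk", "linear")) {
  flux_law <- match.arg(flux_law)
  if (any(c_i < 0) || any(c_o < 0)) stop("concentrations must be >= 0")
  u <- q * V_mV / thermal_voltage_mV(T_K)
  phi <- if (flux_law == "ghk") ifelse(abs(u) < 1e-12, 1, u / (1 - exp(-u)))
         else 1
  -P * (c_i - c_o * exp(-u)) * phi
}

#' Consistent initial state for the pump-leak model
#'
#' Builds an initial intracellular state at unit volume that satisfies
#' electroneutrality and osmotic balance with the given medium:
#' Na_i + K_i = (c_o - x_i)/2 + x_i and Cl_i = Na_i + K_i - x_i (for z = -1).
#'
#' @param params A [plm_params()] object.
#' @param media A [media_composition()].
#' @param Na_i Initial intracellular sodium concentration in mM.
#' @return A list with `n_Na`, `n_K`, `n_Cl` (mM * w0), `w`, `V_mV`, `t`.
#' @export
plm_initial_state <- function(params, media, Na_i = 10) {
  c_o <- media_osmolarity(media)
  X <- params$x_i # at w = 1
  # z = -1: cations = (c_o + (1 - z) X ... solve the two balances
  cat_tot <- (c_o - (1 + params$z) * X) / 2
  Cl_i <- cat_tot + params$z * X
  if (Cl_i < 0 || cat_tot <= 0 || Na_i > cat_tot)
    stop("no consistent initial state: reduce `x_i` or `Na_i`")
  list(n_Na = Na_i, n_K = cat_tot - Na_i, n_Cl = Cl_i, w = 1,
       V_mV = 0, t = 0)
}

#' Run the pump-leak model
#'
#' Forward-Euler integration of the pump-leak model (see the package
#' vignette for the update rule). If a step would drive an ion amount
#' negative, the step is retried with a halved dt (up to 40 halvings,
#' then an error advises a smaller dt).
#'
#' @param params A [plm_params()] object.
#' @param media A [media_composition()].
#' @param initial Optional initial state from [plm_initial_state()].
#' @param record_every Record every k-th step in the trace (default sized
#'   to ~400 rows).
#' @return An object of class `plm_trace`: a list with `trace` (data frame
#'   with t_s, w, V_mV, Na_i_mM, K_i_mM, Cl_i_mM), `final` (final state),
#'   `params`, `media`.
#' @examples
#' pars <- plm_params(pump_rate = 0, t_end = 5)
#' run <- plm_run(pars, media_normal())
#' tail(run$trace)
#' @export
plm_run <- function(params, media, initial = NULL, record_every = NULL) {
  stopifnot(inherits(params, "plm_params"),
            inherits(media, "media_composition"))
  if (is.null(initial)) initial <- plm_initial_state(params, media)
  n_steps <- ceiling(params$t_end / params$dt)
  if (is.null(record_every)) record_every <- max(1L, n_steps %/% 400L)

  ut <- thermal_voltage_mV(params$T_K)
  c_o <- media_osmolarity(media)
  Na_o <- media$Na_o; K_o <- media$K_o; Cl_o <- media$Cl_o
  beta <- params$beta_mV_per_mM
  x_i <- params$x_i; z <- params$z
  ghk <- params$flux_law == "ghk"
  p_max <- params$pump_rate; K_m <- params$K_m_pump

  nNa <- initial$n_Na; nK <- initial$n_K; nCl <- initial$n_Cl
  w <- initial$w; t_now <- initial$t
  V <- beta * (nNa + nK - nCl + z * x_i)

  n_rec <- n_steps %/% record_every + 1L
  rec <- matrix(NA_real_, n_rec + 1L, 6)
  ri <- 1L
  rec[ri, ] <- c(t_now, w, V, nNa / w, nK / w, nCl / w)

  phi_fun <- function(u) if (abs(u) < 1e-12) 1 else u / (1 - exp(-u))

  for (s in seq_len(n_steps)) {
    dt <- params$dt
    repeat {
      cNa <- nNa / w; cK <- nK / w; cCl <- nCl / w
      u <- V / ut
      if (ghk) {
        phi_p <- phi_fun(u); phi_m <- phi_fun(-u)
      } else {
        phi_p <- 1; phi_m <- 1
      }
      pump <- p_max * cNa / (cNa + K_m)
      jNa <- -params$P_Na * (cNa - Na_o * exp(-u)) * phi_p - 3 * pump
      jK <- -params$P_K * (cK - K_o * exp(-u)) * phi_p + 2 * pump
      jCl <- -params$P_Cl * (cCl - Cl_o * exp(u)) * phi_m
      nNa2 <- nNa + dt * jNa
      nK2 <- nK + dt * jK
      nCl2 <- nCl + dt * jCl
      if (nNa2 >= 0 && nK2 >= 0 && nCl2 >= 0) break
      dt <- dt / 2
      if (dt < params$dt / 2^40)
        stop("ion amount went negative; use a smaller `dt`")
    }
    nNa <- nNa2; nK <- nK2; nCl <- nCl2
    t_now <- t_now + dt
    V <- beta * (nNa + nK - nCl + z * x_i)
    w <- (nNa + nK + nCl + x_i) / c_o # osmotic balance, exact at step end
    if (s %% record_every == 0L) {
      ri <- ri + 1L
      rec[ri, ] <- c(t_now, w, V, nNa / w, nK / w, nCl / w)
    }
  }
  if (rec[ri, 1] < t_now) {
    ri <- ri + 1L
    rec[ri, ] <- c(t_now, w, V, nNa / w, nK / w, nCl / w)
  }
  trace <- as.data.frame(rec[seq_len(ri), , drop = FALSE])
  names(trace) <- c("t_s", "w", "V_mV", "Na_i_mM", "K_i_mM", "Cl_i_mM")
  structure(list(trace = trace,
                 final = list(n_Na = nNa, n_K = nK, n_Cl = nCl, w = w,
                              V_mV = V, t = t_now),
                 params = params, media = media),
            class = "plm_trace")
}

#' @export
print.plm_trace <- function(x, ...) {
  f <- x$final
  cat(sprintf("Pump-leak run to t = %g s: w = %.4f, V = %.2f mV\n",
              f$t, f$w, f$V_mV))
  invisible(x)
}

#' Steady-state test by time extension
#'
#' A run is at steady state if extending the total time tenfold leaves the
#' final volume and voltage unchanged to a relative tolerance.
#'
#' @param trace_t A `plm_trace` run to time t.
#' @param trace_10t The same system run to 10 t.
#' @param tol Relative tolerance (default 1e-4). Voltage changes are
#'   measured relative to max(|V|, 1 mV) so near-zero voltages do not
#'   inflate the relative change.
#' @return TRUE if both final volume and voltage are unchanged within `tol`.
#' @export
detect_steady_state <- function(trace_t, trace_10t, tol = 1e-4) {
  stopifnot(inherits(trace_t, "plm_trace"), inherits(trace_10t, "plm_trace"))
  f1 <- trace_t$final; f2 <- trace_10t$final
  dw <- abs(f2$w - f1$w) / abs(f1$w)
  dV <- abs(f2$V_mV - f1$V_mV) / max(abs(f1$V_mV), 1)
  dw < tol && dV < tol
}

# steady-state final voltage for a given pump rate (helper)
plm_steady_voltage <- function(params, media, pump_rate) {
  params$pump_rate <- pump_rate
  plm_run(params, media)$final$V_mV
}

#' Calibrate the pump rate to a target resting voltage
#'
#' Root-finds the pump rate whose steady-state membrane voltage in the
#' given medium equals `V_target_mV`.
#'
#' @param params A [plm_params()] object (its pump_rate is ignored).
#' @param media A [media_composition()], typically [media_normal()].
#' @param V_target_mV Target steady-state voltage in mV.
#' @param bracket Pump-rate search interval in mM/s.
#' @param tol_mV Voltage tolerance in mV.
#' @return The calibrated pump rate (mM/s).
#' @export
calibrate_pump_rate <- function(params, media = media_normal(),
                                V_target_mV = -48,
                                bracket = c(1e-4, 20), tol_mV = 0.1) {
  g <- function(p) plm_steady_voltage(params, media, p) - V_target_mV
  g_lo <- g(bracket[1]); g_hi <- g(bracket[2])
  if (g_lo * g_hi > 0)
    stop(sprintf(
      "target voltage %g mV not bracketed: achievable range ~[%.2f, %.2f] mV",
      V_target_mV, min(g_lo, g_hi) + V_target_mV,
      max(g_lo, g_hi) + V_target_mV))
  # tolerance on the rate translated through a secant slope estimate
  slope <- abs(g_hi - g_lo) / diff(bracket)
  stats::uniroot(g, bracket, tol = max(tol_mV / slope / 10, 1e-10))$root
}

#' Media presets for the perturbation battery
#'
#' Named bath media matching the perturbation experiments: `normal`
#' (128 mM NaCl + 4 mM KCl), `plus100` (normal + 100 mOsm uncharged
#' osmolyte), `sucrose` (NaCl fully replaced by 256 mM uncharged osmolyte,
#' KCl retained), `gluconate` (NaCl replaced by 128 mM sodium salt of a
#' monovalent impermeant anion, KCl retained).
#'
#' @return A named list of [media_composition()] objects.
#' @export
plm_media_presets <- function() {
  list(normal = media_normal(),
       plus100 = media_composition(128, 4, 132, s_o = 100),
       sucrose = media_composition(0, 4, 4, s_o = 256),
       gluconate = media_composition(128, 4, 4, g_o = 128))
}

#' Run the pump on/off x media perturbation battery
#'
#' Runs the pump-leak model for every combination of pump state (on at the
#' calibrated rate, off) and media preset, and reports the percent change
#' in steady-state cell volume and the voltage relative to the
#' (normal media, pump on) baseline. Steady state is assessed by the
#' tenfold-time-extension test; conditions that fail it (normal media with
#' the pump off swells without bound) are flagged.
#'
#' @param params A [plm_params()] object; `pump_rate` is taken as the
#'   calibrated pump-on rate (calibrated internally if 0).
#' @param media_list Media presets, default [plm_media_presets()].
#' @param check_steady Run the 10x-time steady-state test for each
#'   condition (default TRUE; the 10x runs dominate the cost).
#' @return A data frame with columns `media`, `pump`, `w`, `V_mV`,
#'   `dvol_pct` (percent volume change vs baseline), `dV_mV` (voltage
#'   change vs baseline), `steady`.
#' @export
run_perturbation_battery <- function(params,
                                     media_list = plm_media_presets(),
                                     check_steady = TRUE) {
  stopifnot(inherits(params, "plm_params"))
  rate_on <- params$pump_rate
  if (rate_on <= 0)
    rate_on <- calibrate_pump_rate(params, media_list$normal)
  grid <- expand.grid(media = names(media_list), pump = c("on", "off"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- media_list[[grid$media[i]]]
    params$pump_rate <- if (grid$pump[i] == "on") rate_on else 0
    run <- plm_run(params, m)
    steady <- NA
    if (check_steady) {
      params10 <- params; params10$t_end <- 10 * params$t_end
      steady <- detect_steady_state(run, plm_run(params10, m))
    }
    data.frame(media = grid$media[i], pump = grid$pump[i],
               w = run$final$w, V_mV = run$final$V_mV, steady = steady)
  })
  out <- do.call(rbind, res)
  base <- out[out$media == "normal" & out$pump == "on", ]
  out$dvol_pct <- 100 * (out$w - base$w) / base$w
  out$dV_mV <- out$V_mV - base$V_mV
  out[, c("media", "pump", "w", "V_mV", "dvol_pct", "dV_mV", "steady")]
}
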