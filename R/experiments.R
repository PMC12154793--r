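# Scenario runners: osmolyte and ECS-fraction sweeps, the long-mixing-time
# multiexponentiality check, noisy-fixture generation, and a one-call
# driver that writes every sweep to CSV.

# per-site ADC assignment for the named sweep variants; the ECS diffusivity
# may be tied to fo (tortuosity-like scaling used in NODDI-type models)
resolve_adc <- function(variant, fo) {
  switch(variant,
    baseline = c(1, 1, 0.1),
    fast_ics = c(1, 1.5, 0.1),
    slow_ics = c(1, 0.5, 0.1),
    fo_scaled_ecs = c(1.7 * fo, 1, 0.1),
    stop("unknown ADC variant: '", variant,
         "' (use baseline, fast_ics, slow_ics or fo_scaled_ecs)")
  )
}

# one pipeline evaluation: fractions -> simulate -> DEXR fit -> summaries
run_pipeline_point <- function(fa, adc_variant, model, k_t, k_g, k, R1,
                               protocol) {
  if (model == "3xm") {
    adc <- resolve_adc(adc_variant, fa)
    sys <- system_three_site(fa, ADC = adc, R1 = R1)
    spec <- exchange_three_site(k_t, k_g)
  } else {
    adc3 <- resolve_adc(adc_variant, fa)
    sys <- system_two_site(fa, ADC = c(adc3[1], adc3[3]), R1 = R1)
    spec <- exchange_two_site(k)
  }
  tab <- simulate_dexsy(sys, spec, protocol)
  eig <- exchange_eigenvalues(spec, sys$f)
  list(axr = estimate_axr(tab)$AXR, adc = predict_adc(sys),
       lambda2 = eig[2], lambda3 = eig[length(eig)])
}

#' Sweep osmolyte concentration at fixed voltages
#'
#' For each (voltage, osmolyte) pair: solve the ECS fraction, build the
#' compartment system (equal ICS split for three sites), simulate the
#' two-encoding DEXSY protocol, estimate the AXR, and predict the
#' fraction-weighted ADC. Deterministic (noiseless signals).
#'
#' @param voltages Membrane voltages in mV.
#' @param so_grid Added osmolyte concentrations in mOsm.
#' @param adc_variant One of `"baseline"` (ADC = 1, 1, 0.1 um^2/ms),
#'   `"fast_ics"` (1, 1.5, 0.1), `"slow_ics"` (1, 0.5, 0.1) or
#'   `"fo_scaled_ecs"` (1.7 fo, 1, 0.1).
#' @param model `"3xm"` or `"2xm"` (the two-site model uses the ECS and
#'   restricted-ICS diffusivities).
#' @param k_t,k_g Three-site transmembrane and geometric rates, 1/s.
#' @param k Two-site exchange rate, 1/s.
#' @param R1 Spin-lattice rate for all sites, 1/s.
#' @param params A [volume_model_params()] object.
#' @param protocol A [dexsy_protocol()].
#' @return A data frame with one row per (voltage, s_o):
#'   `voltage_mV`, `so_mOsm`, `fo`, `osm_ecs_mM`, `osm_ics_mM`,
#'   `ADC_um2_ms`, `AXR_per_s`, `lambda2_per_s`, `lambda3_per_s`.
#' @examples
#' \donttest{
#' sw <- run_osmolyte_sweep(so_grid = c(0, 50, 100))
#' sw[, c("voltage_mV", "so_mOsm", "fo", "AXR_per_s")]
#' }
#' @export
run_osmolyte_sweep <- function(voltages = c(-48, -10),
                               so_grid = seq(0, 150, by = 5),
                               adc_variant = "baseline", model = "3xm",
                               k_t = 300, k_g = 30, k = 300, R1 = 1,
                               params = volume_model_params(),
                               protocol = dexsy_protocol_default()) {
  if (length(so_grid) == 0 || length(voltages) == 0)
    stop("`voltages` and `so_grid` must be non-empty")
  model <- match.arg(model, c("3xm", "2xm"))
  grid <- expand.grid(so = so_grid, V = voltages)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sol <- solve_fo(params, grid$so[i], grid$V[i])
    pt <- run_pipeline_point(sol$fo, adc_variant, model, k_t, k_g, k, R1,
                             protocol)
    data.frame(voltage_mV = grid$V[i], so_mOsm = grid$so[i], fo = sol$fo,
               osm_ecs_mM = sol$osm_ecs, osm_ics_mM = sol$osm_ics,
               ADC_um2_ms = pt$adc, AXR_per_s = pt$axr,
               lambda2_per_s = pt$lambda2, lambda3_per_s = pt$lambda3)
  })
  do.call(rbind, rows)
}

#' Sweep the ECS fraction directly
#'
#' Sets the site fractions by hand over a dense fo grid (bypassing the
#' osmotic solver) to isolate how the AXR and ADC depend on the ECS
#' fraction. The fraction-weighted eigenvalue reference
#' (fb + fc) lambda2 + fa lambda3 is included for the three-site model.
#'
#' @param fo_grid ECS fractions, strictly inside (0, 1).
#' @inheritParams run_osmolyte_sweep
#' @return A data frame with columns `fo`, `ADC_um2_ms`, `AXR_per_s`,
#'   `lambda2_per_s`, `lambda3_per_s`, `AXR_weighted_per_s`.
#' @export
run_fo_sweep <- function(fo_grid = seq(0.01, 0.99, by = 0.01),
                         adc_variant = "baseline", model = "3xm",
                         k_t = 300, k_g = 30, k = 300, R1 = 1,
                         protocol = dexsy_protocol_default()) {
  if (any(fo_grid <= 0 | fo_grid >= 1))
    stop("`fo_grid` must lie strictly inside (0, 1)")
  model <- match.arg(model, c("3xm", "2xm"))
  rows <- lapply(fo_grid, function(fo) {
    pt <- run_pipeline_point(fo, adc_variant, model, k_t, k_g, k, R1,
                             protocol)
    data.frame(fo = fo, ADC_um2_ms = pt$adc, AXR_per_s = pt$axr,
               lambda2_per_s = pt$lambda2, lambda3_per_s = pt$lambda3,
               AXR_weighted_per_s = (1 - fo) * pt$lambda2 + fo * pt$lambda3)
  })
  do.call(rbind, rows)
}

#' Single-rate adequacy check on a dense mixing-time grid
#'
#' Simulates DEXR signals on a log-spaced mixing-time grid spanning the
#' slow-to-fast exchange regimes for a set of (voltage, osmolyte)
#' conditions, fits the single-rate model, and reports the fit RMS relative
#' to the signal range together with the eigenmode reference curve
#' (fb + fc) exp(-lambda2 tm) + fa exp(-lambda3 tm). A small relative RMS
#' means the three-site DEXR signal is effectively monoexponential.
#'
#' @param conditions Data frame with columns `V_mV` and `so`.
#' @param tm_ms Mixing-time grid in ms (default 100 log-spaced points,
#'   0.2 to 400 ms).
#' @inheritParams run_osmolyte_sweep
#' @return A list with `summary` (per-condition data frame: fo, lambda2,
#'   lambda3, AXR, rel_rms) and `curves` (per-condition data frames with
#'   tm_ms, dexr, fitted, eigenmode).
#' @export
run_multiexponential_check <- function(conditions = data.frame(
                                         V_mV = c(-10, -48, -48),
                                         so = c(0, 0, 100)),
                                       tm_ms = 10^seq(log10(0.2), log10(400),
                                                      length.out = 100),
                                       adc_variant = "baseline",
                                       k_t = 300, k_g = 30, R1 = 1,
                                       params = volume_model_params(),
                                       g = 15.3) {
  protocol <- dexsy_protocol(list(sgse_encoding(0.200, 0.735, g),
                                  sgse_encoding(0.593, 0.580, g)), tm_ms)
  curves <- list()
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    V <- conditions$V_mV[i]; so <- conditions$so[i]
    sol <- solve_fo(params, so, V)
    sys <- system_three_site(sol$fo, ADC = resolve_adc(adc_variant, sol$fo),
                             R1 = R1)
    spec <- exchange_three_site(k_t, k_g)
    tab <- simulate_dexsy(sys, spec, protocol)
    fit <- estimate_axr(tab)
    eig <- exchange_eigenvalues(spec, sys$f)
    t_s <- tm_ms * 1e-3
    eigenmode <- (1 - sol$fo) * exp(-eig[2] * t_s) +
      sol$fo * exp(-eig[3] * t_s)
    curves[[i]] <<- data.frame(tm_ms = fit$tm_ms, dexr = fit$dexr_signal,
                               fitted = fit$fitted, eigenmode = eigenmode)
    data.frame(V_mV = V, so = so, fo = sol$fo, lambda2_per_s = eig[2],
               lambda3_per_s = eig[3], AXR_per_s = fit$AXR,
               rel_rms = sqrt(mean((fit$dexr_signal - fit$fitted)^2)) /
                 diff(range(fit$dexr_signal)))
  })
  list(summary = do.call(rbind, rows), curves = curves)
}

#' Add Gaussian noise to a signal table
#'
#' Additive, seed-reproducible Gaussian noise for fixture generation and
#' robustness studies (the headline simulations are noiseless).
#'
#' @param table A `signal_table` data frame with a `signal` column.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return The table with noise added to `signal`.
#' @export
add_noise <- function(table, sigma, seed = 1) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (!"signal" %in% names(table)) stop("`table` must have a `signal` column")
  if (sigma == 0) return(table)
  set.seed(seed)
  table$signal <- table$signal + stats::rnorm(nrow(table), sd = sigma)
  table
}

#' Regenerate every sweep and write CSV outputs
#'
#' Runs the ECS-fraction sweep, the two- and three-site osmolyte and
#' fo sweeps (all ADC variants), the single-rate adequacy check, and
#' (optionally) the pump-leak perturbation battery, writing one CSV per
#' experiment plus a plain-text log of the resolved parameters. Noiseless
#' pipelines are deterministic, so reruns are idempotent.
#'
#' @param out_dir Output directory (created if missing).
#' @param so_grid Osmolyte grid in mOsm.
#' @param fo_grid ECS-fraction grid.
#' @param include_plm Run the pump-leak battery (adds ~1 min).
#' @param params A [volume_model_params()] object.
#' @return Invisibly, the vector of files written.
#' @export
run_all <- function(out_dir, so_grid = seq(0, 150, by = 5),
                    fo_grid = seq(0.01, 0.99, by = 0.01),
                    include_plm = FALSE,
                    params = volume_model_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  fo_tab <- do.call(rbind, lapply(c(-48, -10), function(V)
    do.call(rbind, lapply(so_grid, function(so) {
      s <- solve_fo(params, so, V)
      data.frame(voltage_mV = V, so_mOsm = so, fo = s$fo,
                 osm_ecs_mM = s$osm_ecs, osm_ics_mM = s$osm_ics)
    }))))
  put(fo_tab, "ecs_fraction_sweep.csv")

  put(run_fo_sweep(fo_grid, model = "2xm"), "fo_sweep_2xm.csv")
  put(run_fo_sweep(fo_grid, model = "3xm"), "fo_sweep_3xm.csv")
  put(run_osmolyte_sweep(so_grid = so_grid, model = "2xm", params = params),
      "osmolyte_sweep_2xm.csv")
  for (v in c("baseline", "fast_ics", "slow_ics", "fo_scaled_ecs"))
    put(run_osmolyte_sweep(so_grid = so_grid, adc_variant = v,
                           params = params),
        paste0("osmolyte_sweep_3xm_", v, ".csv"))
  put(run_multiexponential_check(params = params)$summary,
      "single_rate_check.csv")

  if (include_plm) {
    put(run_perturbation_battery(plm_params()), "plm_battery.csv")
  }

  log_path <- file.path(out_dir, "run_info.txt")
  writeLines(c(paste("dexsim", as.character(utils::packageVersion("dexsim"))),
               paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste("so_grid:", paste(range(so_grid), collapse = "-"),
                     "by", if (length(so_grid) > 1) diff(so_grid[1:2]) else 0),
               paste("fo_grid:", paste(range(fo_grid), collapse = "-")),
               paste("w_tot:", params$w_tot),
               paste("x_i:", params$x_i, "x_o:", params$x_o,
                     "z:", params$z)),
             log_path)
  invisible(c(files, log_path))
}
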