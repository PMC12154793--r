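# Shared fixtures built in code: the reference gray-matter systems and
# protocol used across tests.

ref_params <- function() volume_model_params()

ref_protocol <- function() dexsy_protocol_default()

# three-site system at the solved ECS fraction for (s_o, V)
ref_system_3xm <- function(V_mV = -48, s_o = 0, ADC = c(1, 1, 0.1)) {
  fa <- solve_fo(ref_params(), s_o, V_mV)$fo
  system_three_site(fa, ADC = ADC, R1 = 1)
}

ref_spec_3xm <- function() exchange_three_site(k_t = 300, k_g = 30)

# fast pump-leak settings for unit tests (short horizon unless overridden)
quick_plm <- function(...) {
  args <- list(...)
  if (is.null(args$t_end)) args$t_end <- 200
  do.call(plm_params, args)
}
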