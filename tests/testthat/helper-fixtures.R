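# Shared fixtures, computed lazily and memoized across test files.
# Everything is generated in code from the shipped nominal parameters.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_params <- function() fx_get("params", function() nominal_params())

fx_state <- function() fx_get("state", function()
  steady_state(fx_params(), n_cycles = 30, rtol = 1e-6, atol = 1e-6))

fx_sim <- function() fx_get("sim", function()
  simulate_model(fx_params(), n_cycles = 20, rtol = 1e-6, atol = 1e-6))

# noise-free and noisy datasets for all four designs (shared truth)
fx_nf <- function(design) fx_get("nf", function()
  generate_study_data(fx_params(), seed = 101, noisy = FALSE,
                      init_state = fx_state()))[[design]]

fx_noisy <- function(design) fx_get("noisy", function()
  generate_study_data(fx_params(), seed = 202, noisy = TRUE,
                      init_state = fx_state()))[[design]]

# staged subset selection at the small screening scale
fx_selection <- function() fx_get("selection", function()
  subset_selection(fx_params(), K = 20, l = 60, seed = 1))

# DRAM chains on noisy datasets (small study scale). The f4 recovery
# stage uses a tighter observation simulator: the short 5-cycle one
# leaves solver wiggles that pepper the likelihood with spurious local
# minima and defeat the optimization initialization.
fx_chains <- function(design, n_chains = 3, n_iter = 1500, burn = 400) {
  key <- paste0("chains_", design, "_", n_chains, "_", n_iter)
  fx_get(key, function() {
    if (design == "f4") {
      ds <- generate_study_data(fx_params(), designs = "f4", seed = 202,
                                obs_opts = list(n_cycles = 10, rtol = 1e-5,
                                                atol = 1e-5),
                                init_state = fx_state())[[design]]
      starts <- initialize_starts(ds, cv_reference_subset(), fx_params(),
                                  n_starts = 2, seed = 33, maxit = 300,
                                  n_restarts = 4, n_hops = 6,
                                  init_state = fx_state())
    } else {
      ds <- fx_noisy(design)
      starts <- initialize_starts(ds, cv_reference_subset(), fx_params(),
                                  n_starts = 1, seed = 33, maxit = 300,
                                  n_restarts = 3, n_hops = 0,
                                  init_state = fx_state())
    }
    lapply(seq_len(n_chains), function(k)
      run_dram(ds, cv_reference_subset(), fx_params(),
               start = starts[[((k - 1) %% length(starts)) + 1]],
               n_iter = n_iter, burn_in = burn, seed = 500 + k,
               adapt_interval = 200, init_state = fx_state()))
  })
}

fx_forecast <- function() fx_get("forecast", function() {
  chains <- fx_chains("f4")
  draws <- sample_posterior_predictive(chains, n_per_chain = 20, seed = 77)
  forecast_uq(draws, fx_params(), chains = chains,
              init_state = fx_state(), seed = 78)
})

# mirror-symmetric variant of the nominal parameters: identical left
# and right heart and a symmetric circulation, so the LV and RV should
# behave identically and the septum stay flat
fx_symmetric_params <- function() fx_get("sym", function() {
  p <- fx_params()
  th <- p$theta
  th["Vw_RV"] <- th["Vw_LV"]
  th["Am_ref_RV"] <- th["Am_ref_LV"]
  th["Vw_RA"] <- th["Vw_LA"]
  th["Am_ref_RA"] <- th["Am_ref_LA"]
  th["Rp_val"] <- th["Ra_val"]
  th["Rt_val"] <- th["Rm_val"]
  th["R_pulm"] <- th["R_sys"]
  th["R_pv"] <- th["R_vc"]
  th["C_pa"] <- th["C_sa"]
  th["C_pv"] <- th["C_sv"]
  iv <- p$config$init_volumes
  iv[c("RA", "RV", "PA", "PV")] <- iv[c("LA", "LV", "SA", "SV")]
  cv_params(th, utils::modifyList(p$config, list(init_volumes = iv)))
})
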