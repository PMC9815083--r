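# shared fixtures built in code

# small, fast generator configuration for unit tests
quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(glucose_levels = c(1e-4, 1e-3, 1e-2, 1),
                   events_per_level = 15L, n_lineages = 1L,
                   artifact_rate = 0, seed = 42L)
  do.call(generator_config, utils::modifyList(defaults, args))
}

# a division-event table from explicit timestamps (single lineage)
make_track <- function(times_min, glucose = 1, lineage = "L1") {
  n <- length(times_min)
  data.frame(lineage_id = lineage,
             cell_id = sprintf("%s_c%03d", lineage, seq_len(n)),
             parent_id = c(sprintf("%s_c000", lineage),
                           sprintf("%s_c%03d", lineage, seq_len(n - 1))),
             generation = seq_len(n),
             division_time_min = times_min,
             glucose_g_per_L = glucose,
             stringsAsFactors = FALSE)
}

# noiseless growth points evaluated on the Monod curve
monod_points <- function(mu_max, ks, S = 10^seq(-5, 1, length.out = 8),
                         mu_sd = 0) {
  data.frame(glucose_g_per_L = S, mu_gm = monod_mu(S, mu_max, ks),
             mu_sd = mu_sd, n_events = 100L, status = "valid")
}
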