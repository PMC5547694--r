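# Memoised growth runs shared across test files (built once per test session).

.mce_run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .mce_run_cache, inherits = FALSE))
    assign(key, expr, envir = .mce_run_cache)
  get(key, envir = .mce_run_cache, inherits = FALSE)
}

# reference-parameter pure-population run used by the event-local stress and
# qualitative-ordering checks
ref_run <- function() cached("ref", {
  run_growth(sim_config(seed = 42, init_n = 250), n_target = 500)
})

# mixed-population runs at a given inheritance probability
mixed_run <- function(q, n_target = 700) cached(paste0("mix", q), {
  cfg <- sim_config(seed = 77, init_n = 250,
                    heredity = heredity_config(enabled = TRUE, q = q))
  run_growth(cfg, n_target = n_target)
})

# steady-state elimination rate: 50-cell windows after a 100-cell burn-in
run_eps <- function(run) {
  elimination_rate(run, window_cells = 50, burn_in = 100)$mean
}

mean_trait <- function(run, row) {
  f <- run$trait_counts[row, ] / sum(run$trait_counts[row, ])
  sum(f * run$config$heredity$grid)
}
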