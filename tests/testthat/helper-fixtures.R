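# Shared builders for small in-code fixtures.

# A generator config with all noise switched off: colonies hit the intake
# target exactly, nothing is hoarded or scattered, no workers die.
noise_free_config <- function(design, seed = 1, rule = "equal_distance",
                              target = c(P = 20, C = 30), ...) {
  generator_config(
    design, intake_target = target, total_intake_cv = 0,
    rule = rule, hoard_frac = 0, hoard_sd = 0,
    scatter_frac = 0, scatter_sd = 0,
    control_ratio_sd = 0,
    death_hazard_fn = function(diet) 0,
    egg_rate_fn = function(diet) 0,
    bin_effect_sd = 0, seed = seed, ...
  )
}

# A hand-built colony_experiment whose per-day dry harvests are exactly
# `harvests` (one row per day) from a single diet, with a flat control
# ratio, plus end-of-experiment hoard/scatter masses.
manual_colony <- function(harvests, diet_label = "1:1", hoard = 0,
                          scatter = 0, ratio = 0.4, colony_id = "X1",
                          deaths = rep(0L, length(harvests)),
                          n_workers = 200) {
  n <- length(harvests)
  wet <- rep(1000, n)
  rec <- data.frame(
    colony_id = colony_id, day = seq_len(n), diet_label = diet_label,
    cube_initial_wet = wet, cube_leftover_dry = wet * ratio - harvests,
    control_wet = 1000, control_dry = 1000 * ratio,
    deaths = deaths, stringsAsFactors = FALSE
  )
  structure(list(
    colony_id = colony_id, treatment = diet_label, kind = "nochoice_2d",
    diet_labels = diet_label, bin_id = "bin1",
    n_workers_initial = n_workers, n_days = n, records = rec,
    hoarded_by_diet = stats::setNames(hoard, diet_label),
    scattered_by_diet = stats::setNames(scatter, diet_label),
    final_workers = n_workers - sum(deaths), eggs = 0L
  ), class = "colony_experiment")
}

# Evaluate the canonical quadratic surface at (P, C); used by grid oracles.
quad_at <- function(b, P, C) {
  full <- c(b0 = 0, bP = 0, bC = 0, bPP = 0, bCC = 0, bPC = 0)
  full[names(b)] <- b
  full[["b0"]] + full[["bP"]] * P + full[["bC"]] * C +
    full[["bPP"]] * P^2 + full[["bCC"]] * C^2 + full[["bPC"]] * P * C
}

# 3-D summaries with energy-percent columns attached.
summaries_3d <- function(experiments) {
  d3 <- diets_3d_standard()
  s <- summarize_intake(experiments, d3)
  s$P <- vapply(d3[s$treatment], `[[`, numeric(1), "p_frac")
  s$C <- vapply(d3[s$treatment], `[[`, numeric(1), "c_frac")
  s$pct_survival <- 100 * s$final_workers / s$n_workers_initial
  s
}
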