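#' Configure the synthetic colony-foraging generator
#'
#' Bundles an experiment design with the ground-truth parameters used to
#' simulate complete feeding experiments: the colony intake target, the rule
#' of compromise active under no-choice confinement, hoarding/scattering
#' fractions of harvested diet, the wet-to-dry evaporation model, the 3-D
#' consumption response surface, worker mortality and egg production.
#' All downstream analysis stages can be validated against these knowns.
#'
#' Defaults are the conditions of the study the package's worked analyses
#' emulate: a carbohydrate-biased intake target of (20, 30) mg P:C
#' (C:P = 1.5), lognormal total-intake noise with CV 0.15, mean hoarded
#' fraction 0.10 (SD 0.078) and scattered fraction 0.052 (SD 0.025) of
#' harvested dry mass, and a consumed-diet surface rising with both protein
#' and carbohydrate energy.
#'
#' @param design An [experiment_design()] object.
#' @param intake_target Length-2 numeric, the regulated cumulative intake
#'   (mg protein, mg carbohydrate) per colony over the experiment.
#' @param total_intake_cv Coefficient of variation of total intake between
#'   colonies (lognormal, mean-preserving).
#' @param rule Rule of compromise for no-choice colonies:
#'   `"equal_distance"` (constant total P+C across rails) or
#'   `"closest_distance"` (orthogonal projection of the target on the rail).
#' @param hoard_frac,hoard_sd Mean and between-colony SD of the hoarded
#'   fraction of harvested dry mass (Beta-distributed per diet colour).
#' @param scatter_frac,scatter_sd Same for the scattered fraction.
#' @param control_ratio,control_ratio_sd Mean dry:wet mass ratio of control
#'   diet cubes and the absolute SD of its daily jitter (Normal).
#' @param surface_coeffs Named numeric `(b0, bP, bC, bPP, bCC, bPC)` giving
#'   the quadratic consumed-diet surface (mg dry mass) over energy-percent
#'   coordinates, used by the 3-D generator.
#' @param noise_sd Gaussian SD (mg) of colony consumption about the surface.
#' @param death_hazard_fn Function of a diet (or diet-like list) returning
#'   the per-day, per-worker death probability. The default is logistic in
#'   composition: for 2-D diets `plogis(-6 + 2.5 * p_mass_frac)`, for 3-D
#'   diets `plogis(-4.5 + 0.02 * p_frac - 0.02 * c_frac)`, so mortality rises
#'   with dietary protein.
#' @param egg_rate_fn Function of a diet returning the Poisson mean egg
#'   count; default follows a protein-by-carbohydrate interaction surface for
#'   3-D diets, truncated at zero, and a constant 5 for 2-D diets.
#' @param bin_effect_sd SD of the colony-source-bin random intercept added to
#'   the mortality logit (3-D generator).
#' @param n_bins Number of source bins colonies are drawn from (round-robin).
#' @param misclass_rate Optional probability that a hoarded/scattered
#'   fragment is attributed to the wrong diet colour when sorting (default 0).
#' @param seed Integer seed; every simulated record derives from it.
#' @return An object of class `generator_config`.
#' @seealso [simulate_experiment()]
#' @export
generator_config <- function(design,
                             intake_target = c(P = 20, C = 30),
                             total_intake_cv = 0.15,
                             rule = c("equal_distance", "closest_distance"),
                             hoard_frac = 0.10, hoard_sd = 0.078,
                             scatter_frac = 0.052, scatter_sd = 0.025,
                             control_ratio = 0.12, control_ratio_sd = 0.02,
                             surface_coeffs = c(b0 = 0, bP = 0.501,
                                                bC = 1.323, bPP = 0,
                                                bCC = -0.011, bPC = 0.009),
                             noise_sd = 10,
                             death_hazard_fn = default_death_hazard,
                             egg_rate_fn = default_egg_rate,
                             bin_effect_sd = 0.3,
                             n_bins = if (design$kind == "nochoice_3d") 8 else 6,
                             misclass_rate = 0,
                             seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  rule <- match.arg(rule)
  if (total_intake_cv < 0) stop("total_intake_cv must be >= 0", call. = FALSE)
  for (p in c(hoard_frac, scatter_frac, control_ratio, misclass_rate))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]", call. = FALSE)
  if (hoard_frac + scatter_frac > 1)
    stop("hoard_frac + scatter_frac must not exceed 1", call. = FALSE)
  structure(list(
    design = design, intake_target = intake_target,
    total_intake_cv = total_intake_cv, rule = rule,
    hoard_frac = hoard_frac, hoard_sd = hoard_sd,
    scatter_frac = scatter_frac, scatter_sd = scatter_sd,
    control_ratio = control_ratio, control_ratio_sd = control_ratio_sd,
    surface_coeffs = surface_coeffs, noise_sd = noise_sd,
    death_hazard_fn = death_hazard_fn, egg_rate_fn = egg_rate_fn,
    bin_effect_sd = bin_effect_sd, n_bins = n_bins,
    misclass_rate = misclass_rate, seed = as.integer(seed)
  ), class = "generator_config")
}

#' @rdname generator_config
#' @param diet A diet object (or diet-like list) as passed by the generator.
#' @export
default_death_hazard <- function(diet) {
  if (!is.null(diet$p_frac) && !is.null(diet$c_frac))
    stats::plogis(-4.5 + 0.02 * diet$p_frac - 0.02 * diet$c_frac)
  else
    stats::plogis(-6 + 2.5 * diet$p_mass_frac)
}

#' @rdname generator_config
#' @export
default_egg_rate <- function(diet) {
  if (!is.null(diet$p_frac) && !is.null(diet$c_frac))
    max(0, 10 - 0.166 * diet$p_frac - 0.400 * diet$c_frac +
          0.020 * diet$p_frac * diet$c_frac)
  else 5
}

## per-colony seed stream: reproducible independent of generation order
colony_seed <- function(seed, i) (seed %% 2147482L) * 1000L + i

## Beta draw parameterized by mean and SD; degenerate SD returns the mean
rbeta_meansd <- function(n, mean, sd) {
  if (sd == 0 || mean == 0 || mean == 1) return(rep(mean, n))
  k <- mean * (1 - mean) / sd^2 - 1
  if (k <= 0) stop("Beta SD too large for mean ", mean, call. = FALSE)
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

## mean-preserving lognormal multiplicative noise with coefficient of
## variation cv (exactly 1 when cv = 0)
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

## daily control dry:wet ratios, clamped away from 0
draw_control_ratios <- function(n_days, mean, sd) {
  pmin(1, pmax(0.02, stats::rnorm(n_days, mean, sd)))
}

## Back-computes the daily cube weighings that would have produced the given
## per-day dry harvests under the evaporation model, and draws daily deaths.
build_day_records <- function(colony_id, diets, per_diet_harvest, n_days,
                              config, hazard, n_workers) {
  n_diet <- length(diets)
  recs <- vector("list", n_diet)
  ## day weights: moderate day-to-day foraging variability, shared across diets
  w <- stats::rgamma(n_days, shape = 5, rate = 1)
  w <- w / sum(w)
  for (j in seq_len(n_diet)) {
    ratio <- draw_control_ratios(n_days, config$control_ratio,
                                 config$control_ratio_sd)
    harvest_day <- per_diet_harvest[j] * w
    wet <- pmax(1000, ceiling(harvest_day / ratio + 100))
    recs[[j]] <- data.frame(
      colony_id = colony_id, day = seq_len(n_days),
      diet_label = diets[[j]]$label,
      cube_initial_wet = wet,
      cube_leftover_dry = wet * ratio - harvest_day,
      control_wet = 1000, control_dry = 1000 * ratio,
      deaths = 0L, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  ## deaths are per colony-day; recorded on the first diet's row
  alive <- n_workers
  deaths <- integer(n_days)
  for (d in seq_len(n_days)) {
    deaths[d] <- stats::rbinom(1, alive, hazard)
    alive <- alive - deaths[d]
  }
  out$deaths[out$diet_label == diets[[1]]$label] <- deaths
  list(records = out, final_workers = alive)
}

## Applies Beta-distributed hoard/scatter fractions to per-diet consumed
## masses, returning harvested/hoarded/scattered such that
## consumed + hoarded + scattered = harvested exactly.
apply_processing <- function(consumed, config) {
  n <- length(consumed)
  h <- rbeta_meansd(n, config$hoard_frac, config$hoard_sd)
  s <- rbeta_meansd(n, config$scatter_frac, config$scatter_sd)
  over <- h + s >= 0.999
  s[over] <- pmax(0, 0.999 - h[over])
  harvested <- consumed / (1 - h - s)
  list(harvested = harvested, hoarded = h * harvested,
       scattered = s * harvested)
}

## Optional colour-sorting misclassification between two diets
misclassify <- function(x, rate) {
  if (rate == 0 || length(x) != 2) return(x)
  moved <- stats::rbinom(2, size = round(x * 1000), prob = rate) / 1000
  x + rev(moved) - moved
}

new_colony_experiment <- function(colony_id, treatment, kind, diets, bin_id,
                                  n_workers, n_days, records, hoarded,
                                  scattered, final_workers, eggs) {
  labs <- vapply(diets, `[[`, character(1), "label")
  names(hoarded) <- names(scattered) <- labs
  structure(list(
    colony_id = colony_id, treatment = treatment, kind = kind,
    diet_labels = labs, bin_id = bin_id,
    n_workers_initial = n_workers, n_days = n_days,
    records = records, hoarded_by_diet = hoarded,
    scattered_by_diet = scattered,
    final_workers = final_workers, eggs = eggs
  ), class = "colony_experiment")
}

#' @export
print.colony_experiment <- function(x, ...) {
  cat(sprintf("colony %s (%s, treatment %s): %d days, %d -> %d workers, %d eggs\n",
              x$colony_id, x$kind, x$treatment, x$n_days,
              x$n_workers_initial, x$final_workers, x$eggs))
  invisible(x)
}

#' Simulate a complete feeding experiment
#'
#' Generates one synthetic experiment (a list of colony records) under the
#' ground truth held in `config`, dispatching on the design kind:
#' choice colonies mix their two available diets to reach a noisy draw of the
#' intake target; no-choice colonies settle on their rail at the point the
#' configured rule of compromise predicts; 3-D colonies consume according to
#' the configured response surface. Daily cube weighings are back-computed
#' through the evaporation model so that the intake-accounting stage can
#' recover the simulated truth, and mass balance
#' (consumed + hoarded + scattered = harvested) holds by construction.
#' Output is reproducible given `config$seed`, with per-colony random
#' streams so colonies do not depend on generation order.
#'
#' @param config A [generator_config()] object.
#' @return A list of `colony_experiment` objects, one per colony.
#' @examples
#' des <- study_designs(analyzable = TRUE)$choice_2d
#' sim <- simulate_experiment(generator_config(des, seed = 42))
#' length(sim)  # 22 colonies
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  switch(config$design$kind,
         choice_2d   = simulate_choice_experiment(config),
         nochoice_2d = simulate_nochoice_experiment(config),
         nochoice_3d = simulate_rmt_experiment(config))
}

#' @rdname simulate_experiment
#' @export
simulate_choice_experiment <- function(config) {
  design <- config$design
  if (design$kind != "choice_2d") stop("design kind must be choice_2d", call. = FALSE)
  target <- config$intake_target
  out <- list()
  i <- 0L
  for (tr in seq_along(design$treatments)) {
    pair <- design$treatments[[tr]]
    trt_name <- names(design$treatments)[tr]
    if (is.null(trt_name)) trt_name <- paste(pair[[1]]$label, "vs", pair[[2]]$label)
    M <- cbind(c(pair[[1]]$p_mass_frac, pair[[1]]$c_mass_frac),
               c(pair[[2]]$p_mass_frac, pair[[2]]$c_mass_frac))
    if (any(solve(M, target) < -1e-9))
      stop(sprintf(
        "infeasible target: (%.3g, %.3g) lies outside the cone of rails %s and %s",
        target[1], target[2], pair[[1]]$label, pair[[2]]$label), call. = FALSE)
    for (r in seq_len(design$replicates)) {
      i <- i + 1L
      set.seed(colony_seed(config$seed, i))
      tdraw <- target * rlnorm_cv(2, config$total_intake_cv)
      m <- solve(M, tdraw)
      if (any(m < 0)) {
        ## a rare extreme draw outside the cone: the colony can only reach
        ## the nearest rail, i.e. it consumes a single diet (NNLS solution)
        cand <- lapply(1:2, function(j) {
          mj <- max(0, sum(tdraw * M[, j]) / sum(M[, j]^2))
          v <- numeric(2); v[j] <- mj
          v
        })
        res <- vapply(cand, function(v)
          sum((M %*% v - tdraw)^2), numeric(1))
        m <- cand[[which.min(res)]]
      }
      proc <- apply_processing(m, config)
      proc$hoarded   <- misclassify(proc$hoarded, config$misclass_rate)
      proc$scattered <- misclassify(proc$scattered, config$misclass_rate)
      p_frac_cons <- sum(m * M[1, ]) / max(sum(m), 1e-12)
      bd <- build_day_records(
        colony_id = sprintf("C%03d", i), diets = pair,
        per_diet_harvest = proc$harvested, n_days = design$n_days,
        config = config,
        hazard = config$death_hazard_fn(list(p_mass_frac = p_frac_cons)),
        n_workers = design$n_workers)
      eggs <- stats::rpois(1, config$egg_rate_fn(list(p_mass_frac = p_frac_cons)))
      out[[i]] <- new_colony_experiment(
        sprintf("C%03d", i), trt_name, "choice_2d", pair,
        bin_id = sprintf("bin%d", (i - 1L) %% config$n_bins + 1L),
        design$n_workers, design$n_days, bd$records,
        proc$hoarded, proc$scattered, bd$final_workers, eggs)
    }
  }
  out
}

#' @rdname simulate_experiment
#' @export
simulate_nochoice_experiment <- function(config) {
  design <- config$design
  if (design$kind != "nochoice_2d") stop("design kind must be nochoice_2d", call. = FALSE)
  target <- config$intake_target
  out <- list()
  i <- 0L
  for (tr in seq_along(design$treatments)) {
    diet <- design$treatments[[tr]]
    rail <- nutritional_rail(diet$p_parts, diet$c_parts)
    pt <- if (config$rule == "equal_distance") {
      sum(target) * rail$direction / sum(rail$direction)
    } else {
      max(0, sum(target * rail$direction)) * rail$direction
    }
    for (r in seq_len(design$replicates)) {
      i <- i + 1L
      set.seed(colony_seed(config$seed, i))
      consumed_pt <- pt * rlnorm_cv(1, config$total_intake_cv)
      total_consumed <- sum(consumed_pt)
      proc <- apply_processing(total_consumed, config)
      bd <- build_day_records(
        colony_id = sprintf("N%03d", i), diets = list(diet),
        per_diet_harvest = proc$harvested, n_days = design$n_days,
        config = config, hazard = config$death_hazard_fn(diet),
        n_workers = design$n_workers)
      eggs <- stats::rpois(1, config$egg_rate_fn(diet))
      out[[i]] <- new_colony_experiment(
        sprintf("N%03d", i), diet$label, "nochoice_2d", list(diet),
        bin_id = sprintf("bin%d", (i - 1L) %% config$n_bins + 1L),
        design$n_workers, design$n_days, bd$records,
        proc$hoarded, proc$scattered, bd$final_workers, eggs)
    }
  }
  out
}

#' @rdname simulate_experiment
#' @export
simulate_rmt_experiment <- function(config) {
  design <- config$design
  if (design$kind != "nochoice_3d") stop("design kind must be nochoice_3d", call. = FALSE)
  b <- config$surface_coeffs
  ## bin random intercepts drawn from a bin-only stream
  set.seed(colony_seed(config$seed, 999L))
  bin_eff <- stats::rnorm(config$n_bins, 0, config$bin_effect_sd)
  out <- list()
  i <- 0L
  n_truncated <- 0L
  for (tr in seq_along(design$treatments)) {
    diet <- design$treatments[[tr]]
    P <- diet$p_frac; C <- diet$c_frac
    mu <- b["b0"] + b["bP"] * P + b["bC"] * C +
      b["bPP"] * P^2 + b["bCC"] * C^2 + b["bPC"] * P * C
    for (r in seq_len(design$replicates)) {
      i <- i + 1L
      set.seed(colony_seed(config$seed, i))
      bin <- (i - 1L) %% config$n_bins + 1L
      total_consumed <- mu + stats::rnorm(1, 0, config$noise_sd)
      if (total_consumed < 0) {
        n_truncated <- n_truncated + 1L
        total_consumed <- 0
      }
      proc <- apply_processing(total_consumed, config)
      eta <- stats::qlogis(config$death_hazard_fn(diet)) + bin_eff[bin]
      bd <- build_day_records(
        colony_id = sprintf("T%03d", i), diets = list(diet),
        per_diet_harvest = proc$harvested, n_days = design$n_days,
        config = config, hazard = stats::plogis(eta),
        n_workers = design$n_workers)
      eggs <- stats::rpois(1, config$egg_rate_fn(diet))
      out[[i]] <- new_colony_experiment(
        sprintf("T%03d", i), diet$label, "nochoice_3d", list(diet),
        bin_id = sprintf("bin%d", bin),
        design$n_workers, design$n_days, bd$records,
        proc$hoarded, proc$scattered, bd$final_workers, eggs)
    }
  }
  if (n_truncated > 0)
    warning(sprintf("%d colony consumption draws were negative and truncated at 0",
                    n_truncated), call. = FALSE)
  out
}

#' Write or read a simulated experiment as delimited-text fixtures
#'
#' `write_fixture` serializes a list of colony experiments to `dir` as
#' `colony_days.csv` (one row per colony x day x diet cube),
#' `colony_end.csv` (one row per colony x diet colour, carrying the sorted
#' hoarded/scattered dry masses and end-of-experiment counts),
#' `diets.csv` (the recipes) and, when `config` is supplied, `truth.yaml`
#' recording the scalar ground-truth parameters. `read_fixture` reconstructs
#' the experiment list; the round trip is lossless.
#'
#' @param experiments List of `colony_experiment` objects.
#' @param dir Output directory (created if needed).
#' @param diets Named list of diet objects covering every label used.
#' @param config Optional [generator_config()] whose scalar parameters are
#'   recorded in `truth.yaml`.
#' @return `write_fixture` returns `dir` invisibly; `read_fixture` returns
#'   `list(experiments, diets)`.
#' @export
write_fixture <- function(experiments, dir, diets, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  days <- if (length(experiments) == 0) {
    data.frame(colony_id = character(), day = integer(),
               diet_label = character(), cube_initial_wet = numeric(),
               cube_leftover_dry = numeric(), control_wet = numeric(),
               control_dry = numeric(), deaths = integer())
  } else do.call(rbind, lapply(experiments, `[[`, "records"))
  utils::write.csv(days, file.path(dir, "colony_days.csv"), row.names = FALSE)
  ends <- if (length(experiments) == 0) {
    data.frame(colony_id = character(), treatment = character(),
               kind = character(), bin_id = character(),
               diet_label = character(), hoarded_dry = numeric(),
               scattered_dry = numeric(), n_workers_initial = integer(),
               n_days = integer(), final_workers = integer(),
               eggs = integer())
  } else do.call(rbind, lapply(experiments, function(e) {
    data.frame(colony_id = e$colony_id, treatment = e$treatment,
               kind = e$kind, bin_id = e$bin_id,
               diet_label = e$diet_labels,
               hoarded_dry = unname(e$hoarded_by_diet),
               scattered_dry = unname(e$scattered_by_diet),
               n_workers_initial = e$n_workers_initial, n_days = e$n_days,
               final_workers = e$final_workers, eggs = e$eggs,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ends, file.path(dir, "colony_end.csv"), row.names = FALSE)
  write_diets(diets, file.path(dir, "diets.csv"))
  if (!is.null(config)) {
    truth <- config[c("intake_target", "total_intake_cv", "rule",
                      "hoard_frac", "hoard_sd", "scatter_frac", "scatter_sd",
                      "control_ratio", "control_ratio_sd", "noise_sd",
                      "bin_effect_sd", "n_bins", "misclass_rate", "seed")]
    truth$intake_target <- as.list(truth$intake_target)
    truth$surface_coeffs <- as.list(config$surface_coeffs)
    yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  need <- c("colony_days.csv", "colony_end.csv", "diets.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0)
    stop("fixture file(s) not found under ", dir, ": ",
         paste(missing, collapse = ", "),
         " (expected colony_days.csv with per-day cube masses,",
         " colony_end.csv with sorted hoard/scatter masses and end counts,",
         " diets.csv with recipes)", call. = FALSE)
  days <- utils::read.csv(file.path(dir, "colony_days.csv"),
                          stringsAsFactors = FALSE)
  ends <- utils::read.csv(file.path(dir, "colony_end.csv"),
                          stringsAsFactors = FALSE)
  diets <- read_diets(file.path(dir, "diets.csv"))
  experiments <- lapply(unique(ends$colony_id), function(id) {
    e <- ends[ends$colony_id == id, , drop = FALSE]
    rec <- days[days$colony_id == id, , drop = FALSE]
    rownames(rec) <- NULL
    new_colony_experiment(
      id, e$treatment[1], e$kind[1], diets[e$diet_label], e$bin_id[1],
      e$n_workers_initial[1], e$n_days[1], rec,
      stats::setNames(e$hoarded_dry, e$diet_label),
      stats::setNames(e$scattered_dry, e$diet_label),
      e$final_workers[1], e$eggs[1])
  })
  list(experiments = experiments, diets = diets)
}
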