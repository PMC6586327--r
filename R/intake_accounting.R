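#' Dry mass harvested from one diet cube
#'
#' Converts one day's cube weighings into dry harvested mass using the
#' evaporation correction from same-day control cubes: the cube's expected
#' dry mass had nothing been harvested is `initial_wet * control_ratio`, and
#' harvest is that expectation minus the observed leftover dry mass.
#' Negative raw values (measurement noise near zero harvest) are clamped to
#' zero with a warning.
#'
#' @param initial_wet Initial wet mass of the offered cube (mg).
#' @param leftover_dry Oven-dried leftover mass (mg).
#' @param control_ratio Dry:wet ratio of control cubes for that day, in
#'   (0, 1].
#' @return Dry harvested mass (mg), vectorized over its arguments.
#' @examples
#' dry_harvest(100, 30, 0.4)  # 10 mg
#' @export
dry_harvest <- function(initial_wet, leftover_dry, control_ratio) {
  if (any(control_ratio <= 0))
    stop("invalid control: control_ratio must be positive", call. = FALSE)
  if (any(control_ratio > 1))
    stop("invalid control: control_ratio cannot exceed 1", call. = FALSE)
  if (any(initial_wet < 0) || any(leftover_dry < 0))
    stop("masses must be nonnegative", call. = FALSE)
  raw <- initial_wet * control_ratio - leftover_dry
  n_neg <- sum(raw < 0)
  if (n_neg > 0)
    warning(sprintf("%d negative computed harvest(s) clamped to 0", n_neg),
            call. = FALSE)
  pmax(0, raw)
}

#' Daily evaporation control ratio
#'
#' @param control_wet,control_dry Wet and oven-dry mass (mg) of the day's
#'   control cube.
#' @return `control_dry / control_wet`, required to lie in (0, 1].
#' @examples
#' control_ratio(100, 40)  # 0.4
#' @export
control_ratio <- function(control_wet, control_dry) {
  if (any(control_wet <= 0))
    stop("invalid control: control_wet must be positive", call. = FALSE)
  r <- control_dry / control_wet
  if (any(r > 1))
    stop("data-quality error: control dry mass exceeds wet mass", call. = FALSE)
  r
}

#' Cumulative per-colony intake summary
#'
#' Converts one colony's daily cube weighings plus its end-of-experiment
#' sorted hoard/scatter masses into cumulative harvested, hoarded, scattered
#' and consumed dry mass, partitioned into nutrients by the diet recipes
#' (dry-mass fractions for 2-D diets; dry-mass and energy fractions for 3-D
#' diets). The mass-balance identity
#' `consumed = harvested - hoarded - scattered` holds exactly per diet and
#' in total. One control ratio is used per day per diet (that row's control
#' cube); rows with missing controls fall back to the colony-wide mean
#' ratio.
#'
#' @param experiment A `colony_experiment` object (see
#'   [simulate_experiment()] / [read_fixture()]).
#' @param recipes Named list of diet objects covering every diet label in
#'   the records.
#' @return An object of class `intake_summary`: a list with `per_diet` (a
#'   data.frame of per-diet cumulative masses and nutrient partitions) and
#'   the colony totals as fields (`harvested_dry`, `hoarded_dry`,
#'   `scattered_dry`, `consumed_dry`, `protein_harvested`,
#'   `carb_harvested`, `protein_consumed`, `carb_consumed`, and for 3-D
#'   diets `energy_consumed`, a named P/C/L triple in joules).
#' @export
summarize_colony <- function(experiment, recipes) {
  rec <- experiment$records
  stopifnot(length(unique(rec$colony_id)) <= 1)
  missing_recipe <- setdiff(unique(rec$diet_label), names(recipes))
  if (length(missing_recipe) > 0)
    stop("no recipe for diet label(s): ",
         paste(missing_recipe, collapse = ", "), call. = FALSE)
  ratio <- rep(NA_real_, nrow(rec))
  has_ctrl <- !is.na(rec$control_wet) & !is.na(rec$control_dry)
  ratio[has_ctrl] <- control_ratio(rec$control_wet[has_ctrl],
                                   rec$control_dry[has_ctrl])
  if (anyNA(ratio)) ratio[is.na(ratio)] <- mean(ratio, na.rm = TRUE)
  harvest <- dry_harvest(rec$cube_initial_wet, rec$cube_leftover_dry, ratio)
  labs <- unique(rec$diet_label)
  per <- lapply(labs, function(lab) {
    h <- sum(harvest[rec$diet_label == lab])
    ho <- unname(experiment$hoarded_by_diet[lab])
    sc <- unname(experiment$scattered_by_diet[lab])
    if (is.na(ho)) ho <- 0
    if (is.na(sc)) sc <- 0
    if (ho + sc > h + 1e-6)
      stop(sprintf(
        "mass-balance error in colony %s, diet %s: hoarded + scattered (%.4g) exceeds harvested (%.4g)",
        experiment$colony_id, lab, ho + sc, h), call. = FALSE)
    d <- recipes[[lab]]
    pf <- if (inherits(d, "diet_3d")) d$mass_frac[["P"]] else d$p_mass_frac
    cf <- if (inherits(d, "diet_3d")) d$mass_frac[["C"]] else d$c_mass_frac
    data.frame(diet_label = lab, harvested_dry = h, hoarded_dry = ho,
               scattered_dry = sc, consumed_dry = h - ho - sc,
               protein_harvested = h * pf, carb_harvested = h * cf,
               protein_consumed = (h - ho - sc) * pf,
               carb_consumed = (h - ho - sc) * cf,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  out <- list(
    colony_id = experiment$colony_id,
    treatment = experiment$treatment,
    kind = experiment$kind,
    bin_id = experiment$bin_id,
    n_days = experiment$n_days,
    n_workers_initial = experiment$n_workers_initial,
    final_workers = experiment$final_workers,
    eggs = experiment$eggs,
    per_diet = per,
    harvested_dry = sum(per$harvested_dry),
    hoarded_dry = sum(per$hoarded_dry),
    scattered_dry = sum(per$scattered_dry),
    consumed_dry = sum(per$consumed_dry),
    protein_harvested = sum(per$protein_harvested),
    carb_harvested = sum(per$carb_harvested),
    protein_consumed = sum(per$protein_consumed),
    carb_consumed = sum(per$carb_consumed)
  )
  if (experiment$kind == "nochoice_3d") {
    d <- recipes[[labs[1]]]
    dens <- c(P = d$energy_density, C = d$energy_density,
              L = 2 * d$energy_density)
    mass <- out$consumed_dry * d$mass_frac
    out$energy_consumed <- mass * dens
  }
  structure(out, class = "intake_summary")
}

#' @export
print.intake_summary <- function(x, ...) {
  cat(sprintf("colony %s (%s): harvested %.3g mg, hoarded %.3g, scattered %.3g, consumed %.3g\n",
              x$colony_id, x$treatment, x$harvested_dry, x$hoarded_dry,
              x$scattered_dry, x$consumed_dry))
  cat(sprintf("  consumed protein %.3g mg, carbohydrate %.3g mg over %d days\n",
              x$protein_consumed, x$carb_consumed, x$n_days))
  invisible(x)
}

#' Summarize every colony of an experiment
#'
#' Applies [summarize_colony()] to each colony and binds the totals into a
#' data.frame with one row per colony, the shape expected by the 2-D
#' geometry and treatment-statistics stages.
#'
#' @param experiments List of `colony_experiment` objects.
#' @param recipes Named list of diet objects.
#' @return A data.frame with one row per colony (columns `colony_id`,
#'   `treatment`, `bin_id`, mass totals, nutrient partitions, worker and egg
#'   counts). The list of full `intake_summary` objects is attached as
#'   attribute `"summaries"`.
#' @export
summarize_intake <- function(experiments, recipes) {
  sums <- lapply(experiments, summarize_colony, recipes = recipes)
  df <- do.call(rbind, lapply(sums, function(s) {
    row <- data.frame(
      colony_id = s$colony_id, treatment = s$treatment, kind = s$kind,
      bin_id = s$bin_id, n_days = s$n_days,
      harvested_dry = s$harvested_dry, hoarded_dry = s$hoarded_dry,
      scattered_dry = s$scattered_dry, consumed_dry = s$consumed_dry,
      protein_harvested = s$protein_harvested,
      carb_harvested = s$carb_harvested,
      protein_consumed = s$protein_consumed,
      carb_consumed = s$carb_consumed,
      n_workers_initial = s$n_workers_initial,
      final_workers = s$final_workers, eggs = s$eggs,
      stringsAsFactors = FALSE)
    if (!is.null(s$energy_consumed)) {
      row$energy_p <- s$energy_consumed[["P"]]
      row$energy_c <- s$energy_consumed[["C"]]
      row$energy_l <- s$energy_consumed[["L"]]
    }
    row
  }))
  rownames(df) <- NULL
  attr(df, "summaries") <- sums
  df
}

#' Percent of harvested diet hoarded and scattered
#'
#' Per-colony percentages of cumulative harvested dry mass that ended up
#' hoarded inside the nest or scattered in the foraging arena. Colonies with
#' zero harvest have undefined percentages; they are returned as `NA` with a
#' warning and should be excluded from means.
#'
#' @param summaries A data.frame from [summarize_intake()] (or a single
#'   `intake_summary`).
#' @return A data.frame with `colony_id`, `hoarded_pct`, `scattered_pct`.
#' @examples
#' ## a colony that harvested 50 mg and hoarded 5 mg shows hoarded_pct = 10
#' @export
percent_processed <- function(summaries) {
  if (inherits(summaries, "intake_summary"))
    summaries <- data.frame(colony_id = summaries$colony_id,
                            harvested_dry = summaries$harvested_dry,
                            hoarded_dry = summaries$hoarded_dry,
                            scattered_dry = summaries$scattered_dry,
                            stringsAsFactors = FALSE)
  h <- summaries$harvested_dry
  zero <- h <= 0
  if (any(zero))
    warning(sprintf("%d colony(ies) with zero harvest: percentages undefined, returned as NA",
                    sum(zero)), call. = FALSE)
  data.frame(
    colony_id = summaries$colony_id,
    hoarded_pct = ifelse(zero, NA_real_, 100 * summaries$hoarded_dry / h),
    scattered_pct = ifelse(zero, NA_real_, 100 * summaries$scattered_dry / h),
    stringsAsFactors = FALSE
  )
}
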