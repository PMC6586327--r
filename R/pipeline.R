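#' Run configuration for the analysis pipeline
#'
#' A run is driven by a small configuration naming either generator
#' parameters (`simulate`) or existing fixture directories (`inputs`) —
#' exactly one of the two — plus the analysis options and a seed recorded
#' in every output.
#'
#' @param seed Integer seed for all randomness in the run.
#' @param outdir Output directory.
#' @param simulate `NULL`, or a list of generator settings: `designs` (a
#'   character subset of `choice_2d`, `nochoice_2d`, `nochoice_3d`),
#'   `analyzable` (drop one choice colony per pairing), and any
#'   [generator_config()] scalar parameter to override (e.g. `hoard_frac`,
#'   `rule`, `total_intake_cv`).
#' @param inputs `NULL`, or a named list of fixture directories keyed by
#'   design kind.
#' @param alpha Significance level used throughout.
#' @param lambda Thin-plate-spline smoothing parameter.
#' @param fmn_quantile Quantile defining the FMN region.
#' @param constrain `"simplex"` or `"hull"` for surface maximization.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = "nutgeom_out", simulate = NULL,
                       inputs = NULL, alpha = 0.05, lambda = 0.001,
                       fmn_quantile = 0.9,
                       constrain = c("simplex", "hull")) {
  if (is.null(simulate) == is.null(inputs))
    stop("config error: exactly one of 'simulate' and 'inputs' must be given",
         call. = FALSE)
  structure(list(
    seed = as.integer(seed), outdir = outdir, simulate = simulate,
    inputs = inputs, alpha = alpha, lambda = lambda,
    fmn_quantile = fmn_quantile, constrain = match.arg(constrain)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path Path to a YAML file with the fields above.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config error: file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$seed))
    stop("config error: missing required field 'seed'", call. = FALSE)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

pipeline_log <- function(...) message("[nutgeom] ", sprintf(...))

fixture_dir <- function(config, kind) {
  if (!is.null(config$inputs)) {
    d <- config$inputs[[kind]]
    if (is.null(d))
      stop("config error: no input fixture for design ", kind, call. = FALSE)
    return(d)
  }
  file.path(config$outdir, "fixtures", kind)
}

build_generator <- function(config, kind) {
  sim <- config$simulate
  designs <- study_designs(analyzable = isTRUE(sim$analyzable))
  args <- sim[setdiff(names(sim), c("designs", "analyzable"))]
  args$design <- designs[[kind]]
  args$seed <- config$seed
  if (!is.null(args$intake_target)) args$intake_target <- unlist(args$intake_target)
  if (!is.null(args$surface_coeffs)) args$surface_coeffs <- unlist(args$surface_coeffs)
  do.call(generator_config, args)
}

## is a fixture for this design kind part of the run? explicit inputs are
## required to exist (read_fixture errors otherwise); simulated fixtures are
## looked up under outdir.
has_fixture <- function(config, kind) {
  if (!is.null(config$inputs)) return(!is.null(config$inputs[[kind]]))
  file.exists(file.path(config$outdir, "fixtures", kind, "colony_days.csv"))
}

#' Simulate fixtures for a run
#'
#' Generates synthetic experiments for every design listed in the run
#' configuration and writes them (with `truth.yaml`) under
#' `<outdir>/fixtures/<kind>/`.
#'
#' @param config A [run_config()] with a `simulate` block.
#' @return Invisibly, the named vector of fixture directories.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$simulate))
    stop("config error: pipeline_simulate needs a 'simulate' block", call. = FALSE)
  kinds <- config$simulate$designs
  if (is.null(kinds)) kinds <- c("choice_2d", "nochoice_2d", "nochoice_3d")
  dirs <- character(0)
  for (kind in kinds) {
    gc <- build_generator(config, kind)
    pipeline_log("simulating %s (%d colonies, seed %d)", kind,
                 n_colonies(gc$design), config$seed)
    sim <- simulate_experiment(gc)
    diets <- if (kind == "nochoice_3d") diets_3d_standard() else diets_2d_standard()
    d <- fixture_dir(config, kind)
    write_fixture(sim, d, diets, gc)
    dirs[kind] <- d
  }
  invisible(dirs)
}

#' Run the 2-D nutritional-geometry analysis
#'
#' Reads (or finds previously simulated) choice and/or no-choice fixtures,
#' runs intake accounting, estimates the intake target from the choice
#' experiment, classifies the rule of compromise from the no-choice intake
#' array, and computes the treatment statistics (harvest/consumption
#' ANOVAs, hoard/scatter paired t-tests, worker-survival GLMM). Writes
#' `intake_target.json`, `rule_of_compromise.json`, `stats_2d.json` and an
#' intake-array figure under the run's output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects.
#' @export
pipeline_analyze_2d <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(seed = config$seed)
  target <- NULL
  if (has_fixture(config, "choice_2d")) {
    choice_dir <- fixture_dir(config, "choice_2d")
    pipeline_log("2-D choice analysis from %s", choice_dir)
    fx <- read_fixture(choice_dir)
    sums <- summarize_intake(fx$experiments, fx$diets)
    target <- estimate_intake_target(sums)
    out$intake_target <- target
    pct <- percent_processed(sums)
    out$percent_processed <- c(
      hoarded_pct_mean = mean(pct$hoarded_pct, na.rm = TRUE),
      hoarded_pct_sd = stats::sd(pct$hoarded_pct, na.rm = TRUE),
      scattered_pct_mean = mean(pct$scattered_pct, na.rm = TRUE),
      scattered_pct_sd = stats::sd(pct$scattered_pct, na.rm = TRUE))
    out$choice_anova <- list(
      total = anova_tukey(sums$harvested_dry, sums$treatment, config$alpha),
      protein = anova_tukey(sums$protein_harvested, sums$treatment, config$alpha),
      carb = anova_tukey(sums$carb_harvested, sums$treatment, config$alpha))
    ## per-pairing colour-sorted hoard/scatter paired t-tests
    out$paired <- list()
    smry <- attr(sums, "summaries")
    for (trt in unique(sums$treatment)) {
      per <- lapply(smry[sums$treatment == trt], `[[`, "per_diet")
      cbias <- vapply(per, function(pd) {
        parts <- vapply(strsplit(pd$diet_label, ":"), function(v)
          as.numeric(v[2]) / as.numeric(v[1]), numeric(1))
        pd$hoarded_dry[which.max(parts)]
      }, numeric(1))
      pbias <- vapply(per, function(pd) {
        parts <- vapply(strsplit(pd$diet_label, ":"), function(v)
          as.numeric(v[2]) / as.numeric(v[1]), numeric(1))
        pd$hoarded_dry[which.min(parts)]
      }, numeric(1))
      out$paired[[paste0("hoard ", trt)]] <-
        tryCatch(paired_ttest(cbias, pbias), error = function(e) NULL)
    }
    jsonlite::write_json(list(
      seed = config$seed, P_T = target$P_T, C_T = target$C_T,
      se = as.list(target$se), ratio_c_over_p = target$ratio_c_over_p,
      ratio_mean_of_ratios = target$ratio_mean_of_ratios,
      n_colonies = target$n_colonies),
      file.path(config$outdir, "intake_target.json"),
      auto_unbox = TRUE, digits = NA)
  }
  if (has_fixture(config, "nochoice_2d")) {
    nc_dir <- fixture_dir(config, "nochoice_2d")
    pipeline_log("2-D no-choice analysis from %s", nc_dir)
    fx <- read_fixture(nc_dir)
    sums <- summarize_intake(fx$experiments, fx$diets)
    if (!is.null(target)) {
      roc <- classify_rule(sums, target)
      out$rule_of_compromise <- roc
      jsonlite::write_json(list(
        seed = config$seed, classification = roc$classification,
        sse_equal_distance = roc$sse_equal_distance,
        sse_closest_distance = roc$sse_closest_distance,
        linearity_r2 = roc$linearity_r2,
        per_rail = roc$per_rail),
        file.path(config$outdir, "rule_of_compromise.json"),
        auto_unbox = TRUE, digits = NA)
      grDevices::png(file.path(config$outdir, "intake_array.png"),
                     width = 700, height = 700)
      plot(roc, summaries_points = sums,
           main = sprintf("2-D intake array (seed %d)", config$seed))
      grDevices::dev.off()
    }
    out$nochoice_anova <- list(
      total = anova_tukey(sums$harvested_dry, sums$treatment, config$alpha),
      protein = anova_tukey(sums$protein_harvested, sums$treatment, config$alpha),
      carb = anova_tukey(sums$carb_harvested, sums$treatment, config$alpha),
      consumed = anova_tukey(sums$consumed_dry, sums$treatment, config$alpha))
    census <- survival_census(fx$experiments, interval = 4)
    out$survival <- withCallingHandlers(
      survival_glmm(census),
      warning = function(w) {
        pipeline_log("survival GLMM: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  stats_out <- list(seed = config$seed)
  for (nm in c("choice_anova", "nochoice_anova")) {
    if (is.null(out[[nm]])) next
    stats_out[[nm]] <- lapply(out[[nm]], function(a) list(
      F = a$F, df = c(a$df_between, a$df_within), p = a$p,
      letters = as.list(a$letters)))
  }
  if (!is.null(out$survival) && !isTRUE(out$survival$degenerate))
    stats_out$survival_tests <- out$survival$tests
  jsonlite::write_json(stats_out, file.path(config$outdir, "stats_2d.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

#' Run the 3-D right-angled mixture-triangle analysis
#'
#' Reads the 3-D fixture, runs intake accounting, fits a pruned
#' second-degree response surface for each response (harvested, consumed,
#' hoarded and scattered diet; percent worker survival; egg count), tests
#' lack of fit, locates maximizing compositions, and — for responses whose
#' overall model is significant at `alpha` — renders thin-plate-spline
#' landscapes and the FMN region of the consumption landscape. Writes a
#' coefficient summary table (`rsm_summary.csv`), `stats_3d.json` and the
#' landscape figures.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `rsm_fit` objects, landscapes and the
#'   FMN region.
#' @export
pipeline_analyze_3d <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  d <- fixture_dir(config, "nochoice_3d")
  pipeline_log("3-D analysis from %s", d)
  fx <- read_fixture(d)
  sums <- summarize_intake(fx$experiments, fx$diets)
  sums$P <- vapply(fx$diets[sums$treatment], `[[`, numeric(1), "p_frac")
  sums$C <- vapply(fx$diets[sums$treatment], `[[`, numeric(1), "c_frac")
  sums$pct_survival <- 100 * sums$final_workers / sums$n_workers_initial
  responses <- c(harvested = "harvested_dry", consumed = "consumed_dry",
                 hoarded = "hoarded_dry", scattered = "scattered_dry",
                 pct_survival = "pct_survival", eggs = "eggs")
  fits <- list(); rows <- list(); landscapes <- list()
  for (nm in names(responses)) {
    f <- fit_rsm(stats::reformulate(c("P", "C"), response = responses[[nm]]),
                 sums, alpha = config$alpha)
    f$max_composition <- maximize_surface(f, constrain = config$constrain)
    fits[[nm]] <- f
    lof_p <- if (is.null(f$lack_of_fit)) NA_real_ else f$lack_of_fit$p
    tab <- f$coef_table
    rows[[nm]] <- data.frame(
      response = nm,
      effect = rownames(tab),
      estimate = tab[, "Estimate"], std_err = tab[, "Std. Error"],
      t = tab[, "t value"], p = tab[, "Pr(>|t|)"],
      overall_p = f$overall_p, r_squared = f$r_squared,
      lack_of_fit_p = lof_p,
      dropped = paste(f$dropped_terms, collapse = ";"),
      max_P = f$max_composition[["P"]], max_C = f$max_composition[["C"]],
      max_L = f$max_composition[["L"]],
      row.names = NULL, stringsAsFactors = FALSE)
    if (f$overall_p <= config$alpha) {
      grid <- tps_landscape(sums$P, sums$C, sums[[responses[[nm]]]],
                            lambda = config$lambda)
      landscapes[[nm]] <- grid
      grDevices::png(file.path(config$outdir,
                               sprintf("landscape_%s.png", nm)),
                     width = 700, height = 700)
      plot(grid, main = sprintf("%s landscape (seed %d)", nm, config$seed))
      grDevices::dev.off()
    } else {
      pipeline_log("overall model for '%s' not significant (p = %.3g): no landscape rendered",
                   nm, f$overall_p)
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(config$outdir, "rsm_summary.csv"),
                   row.names = FALSE)
  fmn <- NULL
  if (!is.null(landscapes$consumed)) {
    fmn <- fmn_region(landscapes$consumed, q = config$fmn_quantile)
    grDevices::png(file.path(config$outdir, "fmn_region.png"),
                   width = 700, height = 700)
    plot(landscapes$consumed, fmn = fmn,
         main = sprintf("FMN region (q = %.2f, seed %d)",
                        config$fmn_quantile, config$seed))
    grDevices::dev.off()
  }
  census <- survival_census(fx$experiments, interval = 1)
  surv <- withCallingHandlers(
    survival_glmm(census),
    warning = function(w) {
      pipeline_log("survival GLMM: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  jsonlite::write_json(list(
    seed = config$seed,
    overall_p = lapply(fits, `[[`, "overall_p"),
    r_squared = lapply(fits, `[[`, "r_squared"),
    dropped_terms = lapply(fits, `[[`, "dropped_terms"),
    max_composition = lapply(fits, function(f) as.list(f$max_composition)),
    fmn_area_pct = if (is.null(fmn)) NULL else fmn$area_pct,
    survival_tests = if (isTRUE(surv$degenerate)) NULL else surv$tests),
    file.path(config$outdir, "stats_3d.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(fits = fits, landscapes = landscapes, fmn = fmn,
                 survival = surv, summaries = sums))
}

#' Collate a run report
#'
#' Reads the JSON artifacts written by the analysis stages under `outdir`
#' and writes a short plain-text `report.txt` summarizing the run.
#'
#' @param outdir Output directory of a previous run.
#' @return Invisibly, the report lines.
#' @export
pipeline_report <- function(outdir) {
  lines <- c("nutgeom run report", strrep("=", 18))
  tf <- file.path(outdir, "intake_target.json")
  if (file.exists(tf)) {
    t <- jsonlite::read_json(tf)
    lines <- c(lines, sprintf(
      "intake target: %.3g mg P, %.3g mg C (C:P = %.3g, n = %d, seed %d)",
      t$P_T, t$C_T, t$ratio_c_over_p, t$n_colonies, t$seed))
  }
  rf <- file.path(outdir, "rule_of_compromise.json")
  if (file.exists(rf)) {
    r <- jsonlite::read_json(rf)
    lines <- c(lines, sprintf(
      "rule of compromise: %s (SSE ED %.4g vs CD %.4g, array R2 %.3f)",
      r$classification, r$sse_equal_distance, r$sse_closest_distance,
      r$linearity_r2))
  }
  sf <- file.path(outdir, "rsm_summary.csv")
  if (file.exists(sf)) {
    s <- utils::read.csv(sf)
    for (nm in unique(s$response)) {
      row <- s[s$response == nm, ][1, ]
      lines <- c(lines, sprintf(
        "3-D %s: overall p %.3g, R2 %.2f, max P:C:L %.1f:%.1f:%.1f",
        nm, row$overall_p, row$r_squared, row$max_P, row$max_C, row$max_L))
    }
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(lines)
}
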