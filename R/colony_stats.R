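#' One-way ANOVA with Tukey HSD and compact letters
#'
#' Classical one-way ANOVA of a colony response across diet treatments,
#' followed by Tukey honest-significant-difference comparisons
#' (studentized-range distribution, via [stats::TukeyHSD()]) and a compact
#' letter display built by the insert-and-absorb algorithm: groups sharing
#' a letter do not differ at `alpha`.
#'
#' @param values Numeric response, one value per colony.
#' @param groups Treatment labels, same length as `values`.
#' @param alpha Significance level for the letters (default 0.05).
#' @return An object of class `anova_tukey` with `F`, `df_between`,
#'   `df_within`, `p`, `group_means`, `tukey` (per-pair difference,
#'   CI and adjusted p) and `letters`.
#' @examples
#' anova_tukey(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("insufficient replication: every group needs at least 2 observations",
         call. = FALSE)
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  at <- stats::anova(fit)
  tk <- stats::TukeyHSD(fit)$g
  k <- nlevels(groups)
  sig <- matrix(FALSE, k, k, dimnames = list(levels(groups), levels(groups)))
  for (row in rownames(tk)) {
    pair <- strsplit(row, "-", fixed = TRUE)[[1]]
    sig[pair[1], pair[2]] <- sig[pair[2], pair[1]] <- tk[row, "p adj"] < alpha
  }
  means <- tapply(values, groups, mean)
  letters <- compact_letters(names(sort(means, decreasing = TRUE)), sig)
  structure(list(
    F = at[1, "F value"], df_between = at[1, "Df"], df_within = at[2, "Df"],
    p = at[1, "Pr(>F)"], group_means = means,
    tukey = as.data.frame(tk), letters = letters[levels(groups)],
    alpha = alpha
  ), class = "anova_tukey")
}

## Compact letter display, insert-and-absorb. `order` gives the groups
## (typically sorted by mean); sig[i, j] TRUE when i and j differ.
compact_letters <- function(order, sig) {
  cols <- list(order)
  k <- length(order)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!sig[order[i], order[j]]) next
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (idx in seq_along(cols)) {
        if (order[i] %in% cols[[idx]] && order[j] %in% cols[[idx]]) {
          a <- setdiff(cols[[idx]], order[i])
          b <- setdiff(cols[[idx]], order[j])
          cols[[idx]] <- a
          cols[[length(cols) + 1]] <- b
          changed <- TRUE
          break
        }
      }
    }
    ## absorb: drop empty columns and columns contained in another
    cols <- cols[vapply(cols, length, integer(1)) > 0]
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      if (!keep[a]) next
      for (b in seq_along(cols)) {
        if (a == b || !keep[b]) next
        if (all(cols[[a]] %in% cols[[b]])) { keep[a] <- FALSE; break }
      }
    }
    cols <- cols[keep]
  }
  out <- stats::setNames(rep("", k), order)
  for (idx in seq_along(cols))
    for (g in cols[[idx]])
      out[g] <- paste0(out[g], letters[idx])
  out
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  disp <- data.frame(mean = as.numeric(x$group_means),
                     letter = x$letters[names(x$group_means)])
  rownames(disp) <- names(x$group_means)
  print(disp)
  invisible(x)
}

#' Paired t-test on colour-sorted diet masses
#'
#' Within-colony comparison of the dry mass of two colour-sorted diet
#' fractions (e.g. hoarded carbohydrate-biased vs hoarded protein-biased
#' diet), via a paired t-test on the per-colony differences.
#'
#' @param mass_a,mass_b Per-colony masses (mg), paired by position.
#' @return An object of class `paired_ttest` with `t`, `df`, `p`,
#'   `mean_difference` and `n_pairs`.
#' @export
paired_ttest <- function(mass_a, mass_b) {
  if (length(mass_a) != length(mass_b))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(mass_a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- mass_a - mass_b
  if (stats::sd(d) == 0) {
    if (mean(d) != 0)
      stop("degenerate variance: differences are constant and nonzero",
           call. = FALSE)
    res <- list(t = 0, df = n - 1, p = 1)
  } else {
    tt <- stats::t.test(mass_a, mass_b, paired = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(c(res, list(mean_difference = mean(d), n_pairs = n)),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("paired t-test: t(%d) = %.4g, p = %.4g (mean difference %.4g mg, n = %d)\n",
              x$df, x$t, x$p, x$mean_difference, x$n_pairs))
  invisible(x)
}

#' Census table of worker survival
#'
#' Builds the alive/dead census table used by [survival_glmm()]: for each
#' colony and census day, the number of workers still alive and the
#' cumulative number dead.
#'
#' @param experiments List of `colony_experiment` objects.
#' @param interval Census interval in days (4 for the 2-D experiments'
#'   every-fourth-day collections, 1 for daily 3-D collections).
#' @return A data.frame with `colony_id`, `treatment`, `bin_id`, `day`,
#'   `alive`, `dead`.
#' @export
survival_census <- function(experiments, interval = 1) {
  do.call(rbind, lapply(experiments, function(e) {
    deaths <- tapply(e$records$deaths, e$records$day, sum)
    days <- as.integer(names(deaths))
    cum <- cumsum(deaths)
    census_days <- days[days %% interval == 0]
    data.frame(
      colony_id = e$colony_id, treatment = e$treatment, bin_id = e$bin_id,
      day = census_days,
      alive = e$n_workers_initial - cum[as.character(census_days)],
      dead = cum[as.character(census_days)],
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' Binomial mixed model of worker survival
#'
#' Fits the proportion of living workers (alive / (alive + dead)) with a
#' binomial-logit generalized linear mixed model: fixed effects of census
#' day (numeric), diet treatment and their interaction, and a random
#' intercept for the source bin colonies were drawn from (Laplace
#' approximation via [lme4::glmer()]). Each term is tested by a
#' likelihood-ratio chi-square against the model without it.
#'
#' @param census A data.frame from [survival_census()] (columns `alive`,
#'   `dead`, `day`, `treatment`, `bin_id`).
#' @return An object of class `survival_glmm` with `fixef` (logit-scale
#'   coefficients and SEs), `ranef_var` (bin variance), `tests` (per-term
#'   chi-square, df, p) and the fitted `model`. If no workers died anywhere
#'   a degenerate-fit warning is issued and an all-alive stub returned.
#' @export
survival_glmm <- function(census) {
  census$treatment <- factor(census$treatment)
  if (sum(census$dead) == 0) {
    warning("degenerate fit: no deaths anywhere; survival is 100%",
            call. = FALSE)
    return(structure(list(
      fixef = NULL, ranef_var = 0, tests = NULL, model = NULL,
      survival = 1, degenerate = TRUE
    ), class = "survival_glmm"))
  }
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  fit <- function(form) {
    lme4::glmer(form, data = census, family = stats::binomial, control = ctrl)
  }
  full    <- fit(cbind(alive, dead) ~ day * treatment + (1 | bin_id))
  no_int  <- fit(cbind(alive, dead) ~ day + treatment + (1 | bin_id))
  no_diet <- fit(cbind(alive, dead) ~ day + (1 | bin_id))
  no_day  <- fit(cbind(alive, dead) ~ treatment + (1 | bin_id))
  lrt <- function(big, small) {
    chi <- max(0, 2 * (as.numeric(stats::logLik(big)) -
                         as.numeric(stats::logLik(small))))
    df <- attr(stats::logLik(big), "df") - attr(stats::logLik(small), "df")
    c(chisq = chi, df = df, p = stats::pchisq(chi, df, lower.tail = FALSE))
  }
  tests <- rbind(
    day = lrt(no_int, no_day),
    treatment = lrt(no_int, no_diet),
    `day:treatment` = lrt(full, no_int)
  )
  sm <- summary(full)$coefficients
  if (any(!is.finite(sm[, "Std. Error"])) || any(sm[, "Std. Error"] > 1e3))
    warning("possible complete separation: some coefficient SEs are huge",
            call. = FALSE)
  vc <- as.data.frame(lme4::VarCorr(full))
  structure(list(
    fixef = sm, ranef_var = vc$vcov[1],
    tests = as.data.frame(tests), model = full,
    fitted_survival = stats::fitted(full), degenerate = FALSE
  ), class = "survival_glmm")
}

#' @export
print.survival_glmm <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("survival GLMM: degenerate (no deaths); survival 100%\n")
    return(invisible(x))
  }
  cat("binomial GLMM of worker survival (logit link, bin random intercept)\n")
  cat(sprintf("  bin variance: %.4g\n", x$ranef_var))
  cat("  likelihood-ratio tests:\n")
  print(round(x$tests, 4))
  invisible(x)
}

#' Daily survival curves by treatment
#'
#' Proportion of the initial workforce still alive on each day,
#' `1 - cumulative deaths / n_initial`, averaged over colonies within each
#' treatment.
#'
#' @param experiments List of `colony_experiment` objects.
#' @return A data.frame with `treatment`, `day`, `prop_alive`.
#' @export
survival_curves <- function(experiments) {
  per_colony <- do.call(rbind, lapply(experiments, function(e) {
    deaths <- tapply(e$records$deaths, e$records$day, sum)
    cum <- cumsum(deaths)
    if (any(cum > e$n_workers_initial))
      stop(sprintf("data error: colony %s has more cumulative deaths than workers",
                   e$colony_id), call. = FALSE)
    data.frame(treatment = e$treatment, day = as.integer(names(deaths)),
               prop = 1 - cum / e$n_workers_initial,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  agg <- stats::aggregate(prop ~ treatment + day, per_colony, mean)
  agg <- agg[order(agg$treatment, agg$day), ]
  names(agg)[3] <- "prop_alive"
  rownames(agg) <- NULL
  agg
}
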