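#' Estimate the colony intake target from choice-experiment data
#'
#' The intake target is the protein:carbohydrate blend colonies self-select
#' when offered two complementary imbalanced diets. It is estimated as the
#' mean per-colony cumulative consumed protein and carbohydrate, with
#' standard errors across colonies. The headline C:P ratio is the ratio of
#' the mean intakes; the mean of per-colony ratios is also reported.
#'
#' @param summaries A data.frame from [summarize_intake()] for a choice
#'   experiment (needs columns `protein_consumed`, `carb_consumed`).
#' @return An object of class `intake_target` with fields `P_T`, `C_T`
#'   (mg), `se` (named SEs), `ratio_c_over_p`, `ratio_mean_of_ratios` and
#'   `n_colonies`.
#' @examples
#' df <- data.frame(protein_consumed = c(19, 21), carb_consumed = c(29, 31))
#' estimate_intake_target(df)  # target (20, 30), ratio 1.5
#' @export
estimate_intake_target <- function(summaries) {
  p <- summaries$protein_consumed
  c_ <- summaries$carb_consumed
  n <- length(p)
  if (n < 2)
    stop("insufficient data: need at least 2 colonies to estimate the intake target",
         call. = FALSE)
  P_T <- mean(p); C_T <- mean(c_)
  structure(list(
    P_T = P_T, C_T = C_T,
    se = c(P = stats::sd(p) / sqrt(n), C = stats::sd(c_) / sqrt(n)),
    ratio_c_over_p = if (P_T > 0) C_T / P_T else NA_real_,
    ratio_mean_of_ratios = mean(ifelse(p > 0, c_ / p, NA_real_)),
    n_colonies = n
  ), class = "intake_target")
}

#' @export
print.intake_target <- function(x, ...) {
  cat(sprintf("intake target: %.3g mg protein, %.3g mg carbohydrate (n = %d colonies)\n",
              x$P_T, x$C_T, x$n_colonies))
  cat(sprintf("  C:P ratio %.3g (ratio of means; mean of per-colony ratios %.3g)\n",
              x$ratio_c_over_p, x$ratio_mean_of_ratios))
  cat(sprintf("  SE: protein %.3g, carbohydrate %.3g mg\n", x$se["P"], x$se["C"]))
  invisible(x)
}

as_target_point <- function(target) {
  if (inherits(target, "intake_target")) c(target$P_T, target$C_T)
  else as.numeric(target)
}

#' Rule-of-compromise predictions on a rail
#'
#' `predict_equal_distance` returns the point on a nutritional rail with the
#' same total intake as the target (`P + C = P_T + C_T`) — the straight-line
#' (generalist) array. `predict_closest_distance` returns the orthogonal
#' projection of the target onto the rail (clamped to a nonnegative
#' multiplier) — the convex (specialist) array. When the target lies on the
#' rail both predictions coincide with it.
#'
#' @param target An `intake_target` or a length-2 numeric `(P_T, C_T)` mg.
#' @param rail A [nutritional_rail()].
#' @return Named numeric `(P, C)` in mg.
#' @examples
#' tgt <- c(20, 30)
#' predict_equal_distance(tgt, nutritional_rail(1, 6))   # (7.14, 42.86)
#' predict_closest_distance(tgt, nutritional_rail(1, 1)) # (25, 25)
#' @export
predict_equal_distance <- function(target, rail) {
  stopifnot(inherits(rail, "nutritional_rail"))
  t <- as_target_point(target)
  pt <- sum(t) * rail$direction / sum(rail$direction)
  stats::setNames(pt, c("P", "C"))
}

#' @rdname predict_equal_distance
#' @export
predict_closest_distance <- function(target, rail) {
  stopifnot(inherits(rail, "nutritional_rail"))
  t <- as_target_point(target)
  pt <- max(0, sum(t * rail$direction)) * rail$direction
  stats::setNames(pt, c("P", "C"))
}

#' Rail-aligned (pythagorean) standard error bar
#'
#' For colonies confined to one rail the intake points vary only along the
#' rail, so their uncertainty is drawn as a single bar through the mean
#' point in the rail direction, with half-length
#' `sqrt(SE_P^2 + SE_C^2)` combining the coordinate standard errors.
#'
#' @param p_values,c_values Per-colony cumulative protein and carbohydrate
#'   intakes (mg) on one rail.
#' @param rail The [nutritional_rail()] the colonies were confined to.
#' @return An object of class `rail_error_bar` with the mean `center`, the
#'   half-length `se_along_rail` (mg), the bar `endpoints` (both on the
#'   rail) and the rail.
#' @export
pythagorean_se <- function(p_values, c_values, rail) {
  stopifnot(inherits(rail, "nutritional_rail"),
            length(p_values) == length(c_values))
  n <- length(p_values)
  if (n < 2)
    stop("insufficient data: need at least 2 colonies for an error bar",
         call. = FALSE)
  se_p <- stats::sd(p_values) / sqrt(n)
  se_c <- stats::sd(c_values) / sqrt(n)
  se <- sqrt(se_p^2 + se_c^2)
  center <- c(mean(p_values), mean(c_values))
  structure(list(
    center = stats::setNames(center, c("P", "C")),
    se_P = se_p, se_C = se_c, se_along_rail = se,
    endpoints = rbind(lo = center - se * rail$direction,
                      hi = center + se * rail$direction),
    rail = rail
  ), class = "rail_error_bar")
}

#' Classify the rule of compromise from a no-choice intake array
#'
#' Compares the observed per-rail mean intake points against the equal-
#' distance predictions (constant total intake) and the closest-distance
#' predictions (projection of the target), classifying the array by the
#' smaller sum of squared errors. When the two SSEs are within a factor of
#' 1.5 of each other the array is called `indeterminate` — the band is wide
#' enough that noise-free arrays are never indeterminate while genuinely
#' ambiguous noisy ones are flagged. Also reported: the R-squared of a
#' straight line through the observed means (a straight-line array is the
#' equal-distance signature) and the across-rail ANOVA of per-colony total
#' intake (non-significant total-intake differences support equal distance).
#'
#' @param summaries A data.frame from [summarize_intake()] for a no-choice
#'   2-D experiment; `treatment` must name the diets in `rails`.
#' @param target An `intake_target` or `(P_T, C_T)` numeric.
#' @param rails Named list of [nutritional_rail()] objects, one per
#'   treatment; defaults to rails parsed from the treatment labels
#'   (`"p:c"`).
#' @return An object of class `rule_of_compromise` with per-rail observed
#'   means and both predictions, `sse_equal_distance`,
#'   `sse_closest_distance`, `linearity_r2`, `total_intake_anova` and
#'   `classification`.
#' @export
classify_rule <- function(summaries, target, rails = NULL) {
  labs <- unique(summaries$treatment)
  if (length(labs) < 3)
    stop("insufficient rails: need at least 3 no-choice diets", call. = FALSE)
  if (is.null(rails)) {
    rails <- lapply(labs, function(l) {
      parts <- as.numeric(strsplit(l, ":", fixed = TRUE)[[1]])
      nutritional_rail(parts[1], parts[2])
    })
    names(rails) <- labs
  }
  t <- as_target_point(target)
  per_rail <- do.call(rbind, lapply(labs, function(l) {
    s <- summaries[summaries$treatment == l, ]
    obs <- c(mean(s$protein_consumed), mean(s$carb_consumed))
    ed <- predict_equal_distance(t, rails[[l]])
    cd <- predict_closest_distance(t, rails[[l]])
    data.frame(rail = l, obs_P = obs[1], obs_C = obs[2],
               ed_P = ed[1], ed_C = ed[2], cd_P = cd[1], cd_C = cd[2],
               n = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(per_rail) <- NULL
  sse_ed <- sum((per_rail$obs_P - per_rail$ed_P)^2 +
                  (per_rail$obs_C - per_rail$ed_C)^2)
  sse_cd <- sum((per_rail$obs_P - per_rail$cd_P)^2 +
                  (per_rail$obs_C - per_rail$cd_C)^2)
  ratio <- if (sse_cd > 0) sse_ed / sse_cd else if (sse_ed > 0) Inf else 1
  classification <-
    if (sse_ed == 0 && sse_cd == 0) "indeterminate"
    else if (ratio < 1 / 1.5) "equal_distance"
    else if (ratio > 1.5) "closest_distance"
    else "indeterminate"
  if (sse_ed == 0 && sse_cd > 0) classification <- "equal_distance"
  if (sse_cd == 0 && sse_ed > 0) classification <- "closest_distance"
  lin <- stats::lm(obs_C ~ obs_P, data = per_rail)
  r2 <- summary(lin)$r.squared
  total <- summaries$protein_consumed + summaries$carb_consumed
  aov_res <- anova_tukey(total, summaries$treatment)
  structure(list(
    per_rail = per_rail, target = stats::setNames(t, c("P", "C")),
    rails = rails,
    sse_equal_distance = sse_ed, sse_closest_distance = sse_cd,
    linearity_r2 = r2, total_intake_anova = aov_res,
    classification = classification
  ), class = "rule_of_compromise")
}

#' @export
print.rule_of_compromise <- function(x, ...) {
  cat("Rule of compromise across", nrow(x$per_rail), "rails\n")
  cat(sprintf("  SSE equal distance:   %.4g mg^2\n", x$sse_equal_distance))
  cat(sprintf("  SSE closest distance: %.4g mg^2\n", x$sse_closest_distance))
  cat(sprintf("  straight-line R2 of the array: %.3f\n", x$linearity_r2))
  cat(sprintf("  total-intake ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$total_intake_anova$df_between, x$total_intake_anova$df_within,
              x$total_intake_anova$F, x$total_intake_anova$p))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' @describeIn classify_rule Plot the intake array: rails, observed per-rail
#'   means with rail-aligned error bars, both rule predictions and the
#'   intake target.
#' @param x A `rule_of_compromise` object.
#' @param summaries_points Optional per-colony summaries used to draw
#'   rail-aligned error bars.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rule_of_compromise <- function(x, summaries_points = NULL, ...) {
  pr <- x$per_rail
  lim <- max(pr$obs_P, pr$obs_C, x$target) * 1.15
  graphics::plot(NA, xlim = c(0, lim), ylim = c(0, lim),
                 xlab = "Protein eaten (mg)", ylab = "Carbohydrate eaten (mg)",
                 asp = 1, ...)
  for (r in x$rails) {
    end <- r$direction * lim * 1.5
    graphics::segments(0, 0, end[1], end[2], col = "grey40")
  }
  o <- order(pr$obs_P)
  graphics::lines(pr$obs_P[o], pr$obs_C[o], lty = 2)
  graphics::points(pr$obs_P, pr$obs_C, pch = 16, col = "darkorange")
  graphics::points(pr$ed_P, pr$ed_C, pch = 1)
  graphics::points(pr$cd_P, pr$cd_C, pch = 2)
  graphics::points(x$target[1], x$target[2], pch = 15, col = "blue", cex = 1.3)
  if (!is.null(summaries_points)) {
    for (l in pr$rail) {
      s <- summaries_points[summaries_points$treatment == l, ]
      if (nrow(s) >= 2) {
        bar <- pythagorean_se(s$protein_consumed, s$carb_consumed, x$rails[[l]])
        graphics::segments(bar$endpoints["lo", 1], bar$endpoints["lo", 2],
                           bar$endpoints["hi", 1], bar$endpoints["hi", 2],
                           col = "darkorange")
      }
    }
  }
  graphics::legend("topright", bty = "n",
                   legend = c("observed", "equal distance", "closest distance",
                              "intake target"),
                   pch = c(16, 1, 2, 15),
                   col = c("darkorange", "black", "black", "blue"))
  invisible(x)
}
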