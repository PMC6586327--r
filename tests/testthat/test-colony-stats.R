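test_that("one-way ANOVA matches hand sums of squares", {
  a <- anova_tukey(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  # SSB = 13.5, MSW = 1 by hand
  expect_equal(a$F, 13.5, tolerance = 1e-9)
  expect_equal(c(a$df_between, a$df_within), c(1, 4))
  same <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0, tolerance = 1e-12)
  # the five-diet, eight-colony layout gives denominator df 35
  set.seed(1)
  a5 <- anova_tukey(rnorm(40), rep(letters[1:5], each = 8))
  expect_equal(c(a5$df_between, a5$df_within), c(4, 35))
  expect_error(anova_tukey(c(1, 2, 3), c("a", "a", "b")),
               "insufficient replication")

  # brute-force oracle on random instances
  set.seed(2)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:6, 1)
    y <- rnorm(k * n)
    g <- rep(paste0("g", 1:k), each = n)
    a <- anova_tukey(y, g)
    gm <- tapply(y, g, mean)
    ssb <- sum(n * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    expect_equal(a$F, (ssb / (k - 1)) / (ssw / (k * n - k)), tolerance = 1e-9)
  }
})

test_that("Tukey letters are consistent with adjusted p-values", {
  set.seed(3)
  y <- c(rnorm(8, 0), rnorm(8, 0.2), rnorm(8, 5), rnorm(8, 5.3), rnorm(8, 15))
  g <- rep(paste0("d", 1:5), each = 8)
  a <- anova_tukey(y, g)
  share <- function(l1, l2)
    length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])) > 0
  for (row in rownames(a$tukey)) {
    pair <- strsplit(row, "-", fixed = TRUE)[[1]]
    sig <- a$tukey[row, "p adj"] < a$alpha
    expect_equal(!share(a$letters[pair[1]], a$letters[pair[2]]), sig,
                 info = row)
  }
})

test_that("Tukey adjusted p decreases as mean separation grows", {
  base <- c(-1, -0.5, 0, 0.5, 1)
  ps <- vapply(c(0.5, 2, 5), function(delta) {
    a <- anova_tukey(c(base, base + delta), rep(c("a", "b"), each = 5))
    a$tukey[1, "p adj"]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("paired t-tests follow the difference distribution", {
  p <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(p$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(p$df, 2)
  expect_equal(p$mean_difference, 2)
  zero <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  expect_error(paired_ttest(c(2, 3, 4), c(1, 2, 3)), "degenerate variance")
  expect_error(paired_ttest(1:3, 1:2), "equal length")
})

test_that("survival GLMM with zero bin variance reduces to the fixed-effect fit", {
  # identical counts in every bin force the variance estimate to zero
  census <- expand.grid(bin_id = paste0("b", 1:3),
                        treatment = c("d1", "d2"), day = c(4, 8, 12))
  census$alive <- ifelse(census$treatment == "d1", 190, 170) -
    2 * census$day
  census$dead <- 200 - census$alive
  census$colony_id <- paste0(census$bin_id, census$treatment)
  fit <- survival_glmm(census)
  expect_lt(fit$ranef_var, 1e-6)
  ref <- stats::glm(cbind(alive, dead) ~ day * factor(treatment),
                    data = census, family = binomial)
  expect_equal(unname(fit$fixef[, "Estimate"]), unname(coef(ref)),
               tolerance = 1e-4)
  expect_true(all(fit$tests$p >= 0 & fit$tests$p <= 1))
})

test_that("survival GLMM flags degenerate all-alive data", {
  census <- data.frame(bin_id = rep(c("b1", "b2"), each = 4),
                       treatment = rep(c("d1", "d2"), 4),
                       day = rep(c(4, 8), 4), alive = 200, dead = 0,
                       colony_id = paste0("c", 1:8))
  expect_warning(fit <- survival_glmm(census), "degenerate fit")
  expect_equal(fit$survival, 1)
})

test_that("diet terms show nominal type-I error when the generator has no diet effect", {
  d <- diets_2d_standard()[c("1:3", "3:1")]
  des <- experiment_design("nochoice_2d", d, replicates = 4, n_workers = 100,
                           n_days = 8)
  reps <- 40
  pvals <- vapply(seq_len(reps), function(r) {
    cfg <- generator_config(des, death_hazard_fn = function(diet) 0.03,
                            bin_effect_sd = 0, seed = 20000 + r)
    sim <- simulate_experiment(cfg)
    census <- survival_census(sim, interval = 4)
    survival_glmm(census)$tests["treatment", "p"]
  }, numeric(1))
  rejections <- sum(pvals < 0.05)
  # exact binomial 99% acceptance band around 0.05
  expect_lte(rejections, qbinom(0.995, reps, 0.05))
})

test_that("survival curves are cumulative-death complements averaged by treatment", {
  e1 <- manual_colony(rep(5, 4), deaths = c(0L, 10L, 0L, 10L), n_workers = 100)
  e2 <- manual_colony(rep(5, 4), deaths = c(0L, 0L, 0L, 0L), n_workers = 100)
  e2$colony_id <- "X2"
  sc <- survival_curves(list(e1, e2))
  expect_equal(sc$prop_alive, (c(1, 0.9, 0.9, 0.8) + 1) / 2, tolerance = 1e-12)
  # no deaths: flat at 1; total die-off day 1: zero thereafter
  expect_equal(survival_curves(list(e2))$prop_alive, rep(1, 4))
  e3 <- manual_colony(rep(5, 3), deaths = c(100L, 0L, 0L), n_workers = 100)
  expect_equal(survival_curves(list(e3))$prop_alive, c(0, 0, 0))
  bad <- manual_colony(rep(5, 2), deaths = c(90L, 20L), n_workers = 100)
  expect_error(survival_curves(list(bad)), "data error")
})
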