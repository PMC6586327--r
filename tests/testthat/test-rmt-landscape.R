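design_points <- function(reps = 5) {
  d3 <- diets_3d_standard()
  data.frame(
    P = rep(vapply(d3, `[[`, numeric(1), "p_frac"), each = reps),
    C = rep(vapply(d3, `[[`, numeric(1), "c_frac"), each = reps)
  )
}

test_that("noise-free surfaces are recovered exactly and pruned correctly", {
  df <- design_points()
  # purely linear truth: both quadratics non-significant and dropped
  df$y <- 5 + 0.4 * df$P + 0.9 * df$C
  # tiny replicate jitter so pure-error df exist without moving group means
  df$y <- df$y + rep(c(-1, 1, 0, -1, 1) * 1e-6, 7)
  f <- fit_rsm(y ~ P + C, df)
  expect_setequal(f$dropped_terms, c("P^2", "C^2"))
  expect_equal(unname(coef(f)[c("b0", "bP", "bC")]), c(5, 0.4, 0.9),
               tolerance = 1e-4)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # full quadratic truth: nothing dropped, R^2 = 1
  df$y <- 2 + 0.5 * df$P + 1.3 * df$C - 0.02 * df$P^2 - 0.01 * df$C^2 +
    0.009 * df$P * df$C + rep(c(-1, 1, 0, -1, 1) * 1e-6, 7)
  f2 <- fit_rsm(y ~ P + C, df)
  expect_length(f2$dropped_terms, 0)
  expect_equal(f2$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(coef(f2)),
               c(2, 0.5, 1.3, -0.02, -0.01, 0.009), tolerance = 1e-4)
  # collinear design is refused
  bad <- data.frame(P = rep(10, 10), C = rep(1:5, 2))
  bad$y <- rnorm(10)
  expect_error(fit_rsm(y ~ P + C, bad), "rank-deficient")
})

test_that("coefficient recovery is unbiased across noisy replicates", {
  truth <- c(b0 = 2, bP = 0.5, bC = 1.3, bPP = -0.02, bCC = -0.011,
             bPC = 0.009)
  set.seed(42)
  ests <- t(vapply(1:100, function(i) {
    df <- design_points()
    df$y <- quad_at(truth, df$P, df$C) + rnorm(nrow(df), 0, 5)
    coef(fit_rsm(y ~ P + C, df, alpha = 1))  # keep all terms
  }, numeric(6)))
  bias <- colMeans(ests) - truth
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_true(all(abs(bias) < 3 * se + 1e-12))
})

test_that("lack of fit decomposes residual error against pure replicate error", {
  df <- design_points(reps = 2)
  set.seed(7)
  df$y <- 10 + 0.3 * df$P + rnorm(nrow(df), 0, 2)
  f <- fit_rsm(y ~ P + C, df, alpha = 1)
  lof <- f$lack_of_fit
  # independent sums-of-squares arithmetic
  key <- paste(df$P, df$C)
  gm <- ave(df$y, key)
  ss_pe <- sum((df$y - gm)^2)
  fitted_at <- predict(f)
  ss_lof <- sum((gm - fitted_at)^2)
  df_pe <- nrow(df) - 7
  df_lof <- 7 - 6
  F_hand <- (ss_lof / df_lof) / (ss_pe / df_pe)
  expect_equal(lof$F, F_hand, tolerance = 1e-9)
  expect_equal(lof$df_lof, df_lof)
  expect_equal(lof$df_pure, df_pe)
  expect_equal(lof$p, pf(F_hand, df_lof, df_pe, lower.tail = FALSE),
               tolerance = 1e-9)
  # df bookkeeping: lof + pure = residual df
  expect_equal(lof$df_lof + lof$df_pure, f$lm$df.residual)

  # design-point means exactly on a plane: zero lack of fit
  df$y <- 1 + 0.2 * df$P + 0.4 * df$C + rep(c(-1, 1), 7)
  fp <- fit_rsm(y ~ P + C, df)
  expect_equal(fp$lack_of_fit$ss_lof, 0, tolerance = 1e-12)
  expect_equal(fp$lack_of_fit$p, 1, tolerance = 1e-9)

  # no replication: error
  un <- design_points(reps = 1)
  un$y <- 1 + 0.2 * un$P + 0.4 * un$C
  expect_error(lack_of_fit(suppressWarnings(fit_rsm(y ~ P + C, un, alpha = 1))),
               "pure error")
})

test_that("simplex maximization handles interior, edge and vertex optima", {
  # rising in both nutrients: pushed to the P + C = 100 edge
  m <- maximize_surface(c(bP = 1, bC = 1))
  expect_equal(m[["L"]], 0, tolerance = 1e-9)
  # concave bowl with interior peak
  m2 <- maximize_surface(c(bP = 2, bC = 2, bPP = -0.05, bCC = -0.05))
  expect_equal(c(m2[["P"]], m2[["C"]]), c(20, 20), tolerance = 1e-9)
  # pure decline: origin vertex
  m3 <- maximize_surface(c(bP = -1, bC = -1))
  expect_equal(c(m3[["P"]], m3[["C"]]), c(0, 0))
  # agreement with brute-force grid over random coefficient draws
  set.seed(11)
  for (i in 1:200) {
    b <- c(b0 = rnorm(1, 0, 5), bP = rnorm(1, 0, 1), bC = rnorm(1, 0, 1),
           bPP = rnorm(1, 0, 0.02), bCC = rnorm(1, 0, 0.02),
           bPC = rnorm(1, 0, 0.02))
    m <- maximize_surface(b)
    g <- expand.grid(P = seq(0, 100, 0.5), C = seq(0, 100, 0.5))
    g <- g[g$P + g$C <= 100, ]
    vmax <- max(quad_at(b, g$P, g$C))
    expect_lte(vmax, m[["value"]] + 1e-9)
    # grid can undershoot a continuous optimum by at most curvature * step^2
    expect_lt(m[["value"]] - vmax, 0.05)
  }
})

test_that("hull-constrained maximization stays inside the design triangle", {
  m <- maximize_surface(c(bP = -1, bC = -1), constrain = "hull")
  expect_equal(c(m[["P"]], m[["C"]]), c(10, 10))
  m2 <- maximize_surface(c(bP = 1, bC = 1), constrain = "hull")
  expect_equal(m2[["P"]] + m2[["C"]], 90, tolerance = 1e-9)
})

test_that("thin-plate splines interpolate design-point means as lambda -> 0", {
  d3 <- diets_3d_standard()
  P <- vapply(d3, `[[`, numeric(1), "p_frac")
  C <- vapply(d3, `[[`, numeric(1), "c_frac")
  set.seed(3)
  vals <- 20 + 0.5 * P + 0.3 * C + rnorm(7, 0, 5)
  g <- tps_landscape(P, C, vals, lambda = 1e-9, resolution = 5)
  preds <- mapply(g$predict, P, C)
  expect_equal(unname(preds), unname(vals), tolerance = 1e-6)
  # replicated points collapse to their means first
  g2 <- tps_landscape(rep(P, each = 2), rep(C, each = 2),
                      rep(vals, each = 2) + rep(c(-1, 1), 7),
                      lambda = 1e-9, resolution = 5)
  expect_equal(unname(mapply(g2$predict, P, C)), unname(vals),
               tolerance = 1e-6)
  # constant responses give a constant surface
  gc_ <- tps_landscape(P, C, rep(7, 7), lambda = 0.001, resolution = 5)
  expect_equal(range(gc_$z, na.rm = TRUE), c(7, 7), tolerance = 1e-8)
  # collinear design points are refused
  expect_error(tps_landscape(c(10, 20, 30), c(10, 20, 30), 1:3),
               "degenerate spline")
})

test_that("thin-plate spline matches an independent augmented-system solve", {
  pts <- data.frame(x = c(10, 60, 20, 40), y = c(15, 10, 60, 35),
                    f = c(3, 7, 2, 9))
  lambda <- 0.01
  g <- tps_landscape(pts$x, pts$y, pts$f, lambda = lambda, resolution = 10)
  # oracle: solve the full (n + 3) augmented KKT system directly
  n <- 4
  eta <- function(r) ifelse(r == 0, 0, r^2 * log(r))
  K <- eta(as.matrix(dist(pts[, 1:2])))
  Tm <- cbind(1, pts$x, pts$y)
  A <- rbind(cbind(K + n * lambda * diag(n), Tm),
             cbind(t(Tm), matrix(0, 3, 3)))
  sol <- solve(A, c(pts$f, 0, 0, 0))
  cc <- sol[1:n]; d <- sol[n + 1:3]
  oracle <- function(px, py) {
    r <- sqrt((px - pts$x)^2 + (py - pts$y)^2)
    d[1] + d[2] * px + d[3] * py + sum(cc * eta(r))
  }
  test_pts <- expand.grid(px = c(5, 25, 50, 70), py = c(5, 20, 45))
  diffs <- mapply(function(px, py) abs(g$predict(px, py) - oracle(px, py)),
                  test_pts$px, test_pts$py)
  expect_lt(max(diffs), 1e-8)
})

test_that("FMN regions cover the right share of the simplex", {
  d3 <- diets_3d_standard()
  P <- vapply(d3, `[[`, numeric(1), "p_frac")
  C <- vapply(d3, `[[`, numeric(1), "c_frac")
  vals <- 80 - 0.02 * (P - 40)^2 - 0.02 * (C - 40)^2
  g <- tps_landscape(P, C, vals, lambda = 0.001, resolution = 2)
  # q = 0 selects the whole simplex
  expect_equal(fmn_region(g, q = 0)$area_pct, 100)
  # single-peaked surface: the q = 0.9 region contains the grid argmax
  fmn <- fmn_region(g, q = 0.9)
  idx <- which(g$z == max(g$z, na.rm = TRUE), arr.ind = TRUE)
  expect_true(fmn$mask[idx])
  # area computed two ways agrees: cell count vs mean of the indicator
  inside <- !is.na(g$z)
  expect_equal(fmn$area_pct,
               100 * mean((g$z >= fmn$threshold)[inside]), tolerance = 1e-12)
  expect_error(fmn_region(g, q = 1), "must lie")
})

test_that("refitting after pruning never increases R-squared and ignores row order", {
  df <- design_points()
  set.seed(21)
  df$y <- 10 + 0.3 * df$P + 0.5 * df$C + rnorm(nrow(df), 0, 8)
  full <- fit_rsm(y ~ P + C, df, alpha = 1)
  pruned <- fit_rsm(y ~ P + C, df, alpha = 0.05)
  expect_lte(pruned$r_squared, full$r_squared + 1e-12)
  shuf <- df[sample(nrow(df)), ]
  expect_equal(coef(fit_rsm(y ~ P + C, shuf)), coef(fit_rsm(y ~ P + C, df)),
               tolerance = 1e-9)
})
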