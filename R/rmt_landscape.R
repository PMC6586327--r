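#' Fit a second-degree response surface on the P:C:L simplex
#'
#' Fits a colony response (diet harvested or consumed, percent worker
#' survival, egg count, ...) as a second-degree polynomial in the protein
#' and carbohydrate energy percentages of the diet. Because the three
#' macronutrient fractions sum to 100, lipid cannot enter the model; lipid
#' effects are read off the simplex geometry (high L where P and C are both
#' low). The full model contains the linear terms, both pure quadratics and
#' the protein-by-carbohydrate cross-product, on raw percentage units.
#' Quadratic terms whose coefficients are not significant at `alpha` are
#' removed simultaneously and the model refit once; linear and
#' cross-product terms are always retained.
#'
#' @param formula A two-sided formula `response ~ P + C` naming the response
#'   column and the protein and carbohydrate percentage columns of `data`
#'   (in that order).
#' @param data A data.frame with those columns, one row per colony.
#' @param alpha Significance level for quadratic-term pruning (default
#'   0.05).
#' @return An object of class `rsm_fit` with components `coefficients` (the
#'   canonical named vector `(b0, bP, bC, bPP, bCC, bPC)`, zeros for dropped
#'   terms), `coef_table` (estimate/SE/t/p for fitted terms), `r_squared`,
#'   `overall_p` (model F test), `dropped_terms`, `lack_of_fit` (see
#'   [lack_of_fit()]; `NULL` without replication), `max_composition` (the
#'   maximizing `(P*, C*, L*)`, see [maximize_surface()]) and the underlying
#'   `lm` fit. Supports `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `simulate` and `plot` methods.
#' @seealso [maximize_surface()], [lack_of_fit()], [tps_landscape()]
#' @export
fit_rsm <- function(formula, data, alpha = 0.05) {
  vars <- all.vars(formula)
  if (length(vars) != 3)
    stop("formula must be of the form response ~ P + C", call. = FALSE)
  yv <- vars[1]; pv <- vars[2]; cv <- vars[3]
  if (!all(vars %in% names(data)))
    stop("data lacks column(s): ",
         paste(setdiff(vars, names(data)), collapse = ", "), call. = FALSE)
  if (!all(is.finite(data[[yv]])))
    stop("response contains non-finite values", call. = FALSE)
  term_names <- c(pv, cv,
                  sprintf("I(%s^2)", pv), sprintf("I(%s^2)", cv),
                  sprintf("I(%s * %s)", pv, cv))
  fit_terms <- function(terms) {
    f <- stats::reformulate(terms, response = yv)
    stats::lm(f, data = data)
  }
  full <- fit_terms(term_names)
  if (anyNA(stats::coef(full))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design: collinear term(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ct <- summary(full)$coefficients
  quad <- term_names[3:4]
  pvals <- ct[quad, "Pr(>|t|)"]
  dropped <- quad[pvals > alpha]
  final <- if (length(dropped) > 0)
    fit_terms(setdiff(term_names, dropped)) else full
  sm <- summary(final)
  fstat <- sm$fstatistic
  overall_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  cf <- stats::coef(final)
  canon <- c(b0 = 0, bP = 0, bC = 0, bPP = 0, bCC = 0, bPC = 0)
  canon["b0"] <- cf["(Intercept)"]
  canon["bP"] <- cf[pv]
  canon["bC"] <- cf[cv]
  if (sprintf("I(%s^2)", pv) %in% names(cf))
    canon["bPP"] <- cf[sprintf("I(%s^2)", pv)]
  if (sprintf("I(%s^2)", cv) %in% names(cf))
    canon["bCC"] <- cf[sprintf("I(%s^2)", cv)]
  canon["bPC"] <- cf[sprintf("I(%s * %s)", pv, cv)]
  obj <- structure(list(
    response_name = yv, p_var = pv, c_var = cv, alpha = alpha,
    coefficients = canon,
    coef_table = sm$coefficients,
    r_squared = sm$r.squared,
    overall_p = unname(overall_p),
    dropped_terms = sub(sprintf("I\\((%s|%s)\\^2\\)", pv, cv), "\\1^2", dropped),
    lm = final, data = data
  ), class = "rsm_fit")
  obj$lack_of_fit <- tryCatch(lack_of_fit(obj), error = function(e) NULL)
  obj$max_composition <- maximize_surface(obj)
  obj
}

eval_quadratic <- function(b, P, C) {
  b[["b0"]] + b[["bP"]] * P + b[["bC"]] * C +
    b[["bPP"]] * P^2 + b[["bCC"]] * C^2 + b[["bPC"]] * P * C
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("Response surface for '%s' (second degree on %%%s, %%%s)\n",
              x$response_name, x$p_var, x$c_var))
  cat(sprintf("  R2 = %.2f, overall p = %.4g", x$r_squared, x$overall_p))
  if (length(x$dropped_terms) > 0)
    cat(", dropped: ", paste(x$dropped_terms, collapse = ", "), sep = "")
  cat("\n")
  if (!is.null(x$lack_of_fit))
    cat(sprintf("  lack of fit: F(%d, %d) = %.3g, p = %.3g\n",
                x$lack_of_fit$df_lof, x$lack_of_fit$df_pure,
                x$lack_of_fit$F, x$lack_of_fit$p))
  m <- x$max_composition
  cat(sprintf("  maximum response at P:C:L = %.1f:%.1f:%.1f\n",
              m[["P"]], m[["C"]], m[["L"]]))
  invisible(x)
}

#' @export
summary.rsm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rsm_fit")
}

#' @export
print.summary.rsm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$fit$coef_table)
  invisible(x)
}

#' @export
coef.rsm_fit <- function(object, ...) object$coefficients

#' @export
residuals.rsm_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
simulate.rsm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)
}

#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$lm, ...))
  if (!all(c(object$p_var, object$c_var) %in% names(newdata))) {
    ## allow canonical P/C column names
    if (all(c("P", "C") %in% names(newdata))) {
      newdata[[object$p_var]] <- newdata$P
      newdata[[object$c_var]] <- newdata$C
    } else stop("newdata must contain columns ", object$p_var, " and ",
                object$c_var, call. = FALSE)
  }
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
plot.rsm_fit <- function(x, resolution = 1, ...) {
  g <- expand.grid(P = seq(0, 100, resolution), C = seq(0, 100, resolution))
  g <- g[g$P + g$C <= 100, ]
  g$z <- eval_quadratic(x$coefficients, g$P, g$C)
  xs <- sort(unique(g$P)); ys <- sort(unique(g$C))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(g$P, xs), match(g$C, ys))] <- g$z
  graphics::image(xs, ys, z, col = grDevices::hcl.colors(64, "Spectral",
                                                         rev = TRUE),
                  xlab = paste0(x$p_var, " (% energy)"),
                  ylab = paste0(x$c_var, " (% energy)"), ...)
  graphics::contour(xs, ys, z, add = TRUE)
  graphics::points(x$max_composition[["P"]], x$max_composition[["C"]],
                   pch = 8, cex = 1.4)
  invisible(x)
}

#' Lack-of-fit test of a fitted response surface
#'
#' Decomposes the residual sum of squares into pure error (variation of
#' replicate colonies within each distinct diet composition) and lack of
#' fit (deviation of the composition means from the fitted surface), and
#' tests `F = (SS_lof / df_lof) / (SS_pe / df_pe)`. A non-significant p
#' indicates the second-degree surface adequately describes the
#' composition means.
#'
#' @param fit An `rsm_fit` object.
#' @return A list with `F`, `p`, `df_lof`, `df_pure`, `ss_lof`, `ss_pure`.
#' @export
lack_of_fit <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  mf <- fit$lm$model
  y <- mf[[1]]
  key <- interaction(fit$data[[fit$p_var]], fit$data[[fit$c_var]], drop = TRUE)
  m <- nlevels(key)
  N <- length(y)
  df_pe <- N - m
  if (df_pe <= 0)
    stop("no pure error: no diet composition has replicate colonies",
         call. = FALSE)
  gm <- tapply(y, key, mean)
  ss_pe <- sum((y - gm[key])^2)
  ss_res <- sum(stats::residuals(fit$lm)^2)
  p_par <- length(stats::coef(fit$lm))
  df_lof <- m - p_par
  if (df_lof <= 0)
    stop("no lack-of-fit degrees of freedom: as many parameters as design points",
         call. = FALSE)
  ss_lof <- max(0, ss_res - ss_pe)
  Fval <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(F = Fval, p = stats::pf(Fval, df_lof, df_pe, lower.tail = FALSE),
       df_lof = df_lof, df_pure = df_pe, ss_lof = ss_lof, ss_pure = ss_pe)
}

#' Maximize a quadratic surface over the composition simplex
#'
#' Finds the protein:carbohydrate:lipid composition maximizing a fitted (or
#' explicitly given) second-degree surface over the closed simplex
#' `{P >= 0, C >= 0, P + C <= 100}` by exact enumeration: the interior
#' stationary point (when it exists and is feasible), the three edges
#' (one-dimensional quadratics solved in closed form) and the three
#' vertices. With `constrain = "hull"` the search region is shrunk to the
#' triangle spanned by the standard seven-diet design
#' (`P >= 10, C >= 10, P + C <= 90`).
#'
#' @param fit An `rsm_fit` object, or a named numeric vector with elements
#'   `b0, bP, bC, bPP, bCC, bPC` (missing elements are taken as 0).
#' @param constrain `"simplex"` (default) or `"hull"`.
#' @return Named numeric `(P, C, L, value)`: the maximizing composition in
#'   percent and the surface value there.
#' @examples
#' ## a surface rising in C only, curving down: maximum on the P = 0 edge
#' maximize_surface(c(bC = 7.12, bCC = -0.058))
#' @export
maximize_surface <- function(fit, constrain = c("simplex", "hull")) {
  constrain <- match.arg(constrain)
  b <- if (inherits(fit, "rsm_fit")) fit$coefficients else {
    full <- c(b0 = 0, bP = 0, bC = 0, bPP = 0, bCC = 0, bPC = 0)
    full[names(fit)] <- fit
    full
  }
  lo <- if (constrain == "hull") 10 else 0
  hi <- if (constrain == "hull") 90 else 100
  cand <- list()
  add <- function(P, C) cand[[length(cand) + 1]] <<- c(P, C)
  ## vertices
  add(lo, lo); add(hi - lo, lo); add(lo, hi - lo)
  ## 1-D quadratic a2 t^2 + a1 t + a0 on [t0, t1]: interior stationary point
  edge_opt <- function(a2, a1, t0, t1) {
    if (a2 != 0) {
      t <- -a1 / (2 * a2)
      if (t > t0 && t < t1) return(t)
    }
    numeric(0)
  }
  ## edge C = lo
  for (t in edge_opt(b[["bPP"]], b[["bP"]] + b[["bPC"]] * lo, lo, hi - lo))
    add(t, lo)
  ## edge P = lo
  for (t in edge_opt(b[["bCC"]], b[["bC"]] + b[["bPC"]] * lo, lo, hi - lo))
    add(lo, t)
  ## edge P + C = hi: substitute C = hi - P
  a2 <- b[["bPP"]] + b[["bCC"]] - b[["bPC"]]
  a1 <- b[["bP"]] - b[["bC"]] - 2 * b[["bCC"]] * hi + b[["bPC"]] * hi
  for (t in edge_opt(a2, a1, lo, hi - lo)) add(t, hi - t)
  ## interior stationary point: solve the gradient system
  H <- matrix(c(2 * b[["bPP"]], b[["bPC"]], b[["bPC"]], 2 * b[["bCC"]]), 2)
  if (abs(det(H)) > 1e-12) {
    st <- solve(H, -c(b[["bP"]], b[["bC"]]))
    if (st[1] > lo && st[2] > lo && sum(st) < hi) add(st[1], st[2])
  }
  vals <- vapply(cand, function(p) eval_quadratic(b, p[1], p[2]), numeric(1))
  best <- cand[[which.max(vals)]]
  c(P = best[1], C = best[2], L = 100 - best[1] - best[2],
    value = max(vals))
}

#' Thin-plate-spline nutritional landscape
#'
#' Interpolates/smooths colony responses measured at a handful of diet
#' compositions into a continuous landscape over the right-angled mixture
#' triangle, using a classical thin-plate spline: radial basis
#' `r^2 log(r)` plus an affine part, with roughness penalty `n * lambda`
#' added to the radial system. Replicated design points are collapsed to
#' their means before solving; as `lambda -> 0` the surface interpolates
#' those means.
#'
#' @param p,c_ Design-point protein and carbohydrate percentages.
#' @param values Response values (replicates allowed; averaged per point).
#' @param lambda Smoothing parameter (> 0 for smoothing; default 0.001, the
#'   topological resolution used for the package's worked landscapes).
#' @param resolution Grid step in percent (default 1).
#' @return An object of class `landscape_grid`: grid vectors `x`, `y`, the
#'   predicted matrix `z` (`NA` outside the simplex mask), `lambda` and the
#'   spline coefficients. Has `print` and `plot` methods and feeds
#'   [fmn_region()].
#' @export
tps_landscape <- function(p, c_, values, lambda = 0.001, resolution = 1) {
  stopifnot(length(p) == length(c_), length(p) == length(values))
  key <- paste(p, c_, sep = "_")
  ux <- as.numeric(tapply(p, key, mean))
  uy <- as.numeric(tapply(c_, key, mean))
  uf <- as.numeric(tapply(values, key, mean))
  n <- length(ux)
  if (n < 3) stop("degenerate spline: need at least 3 design points",
                  call. = FALSE)
  Tm <- cbind(1, ux, uy)
  if (qr(Tm)$rank < 3)
    stop("degenerate spline: design points are collinear", call. = FALSE)
  eta <- function(r) ifelse(r == 0, 0, r^2 * log(r))
  D <- as.matrix(stats::dist(cbind(ux, uy)))
  K <- eta(D)
  A <- K + n * lambda * diag(n)
  qrT <- qr(Tm)
  Q <- qr.Q(qrT, complete = TRUE)
  Q1 <- Q[, 1:3, drop = FALSE]
  R1 <- qr.R(qrT)[1:3, 1:3]
  if (n == 3) {
    cc <- matrix(0, 3, 1)  # exactly affine: no radial part
  } else {
    Q2 <- Q[, 4:n, drop = FALSE]
    gam <- solve(t(Q2) %*% A %*% Q2, t(Q2) %*% uf)
    cc <- Q2 %*% gam
  }
  d <- backsolve(R1, t(Q1) %*% (uf - A %*% cc))
  xs <- seq(0, 100, resolution)
  ys <- seq(0, 100, resolution)
  z <- matrix(NA_real_, length(xs), length(ys))
  pred <- function(px, py) {
    r <- sqrt((px - ux)^2 + (py - uy)^2)
    d[1] + d[2] * px + d[3] * py + sum(cc * eta(r))
  }
  for (i in seq_along(xs)) for (j in seq_along(ys))
    if (xs[i] + ys[j] <= 100) z[i, j] <- pred(xs[i], ys[j])
  structure(list(
    x = xs, y = ys, z = z, lambda = lambda, resolution = resolution,
    points = data.frame(P = as.numeric(ux), C = as.numeric(uy),
                        value = as.numeric(uf)),
    coef = list(c = as.numeric(cc), d = as.numeric(d)),
    predict = pred
  ), class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("thin-plate-spline landscape: %d design points, lambda = %g, %g%% grid\n",
              nrow(x$points), x$lambda, x$resolution))
  rng <- range(x$z, na.rm = TRUE)
  cat(sprintf("  predicted range %.4g to %.4g over the simplex\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.landscape_grid <- function(x, fmn = NULL, ...) {
  graphics::image(x$x, x$y, x$z,
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  xlab = "Protein (% energy)", ylab = "Carbohydrate (% energy)",
                  ...)
  graphics::contour(x$x, x$y, x$z, add = TRUE)
  graphics::points(x$points$P, x$points$C, pch = 16)
  if (!is.null(fmn))
    graphics::contour(x$x, x$y, ifelse(fmn$mask, 1, 0), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, lwd = 2)
  invisible(x)
}

#' Fundamental macronutrient niche region of a landscape
#'
#' Delineates the high-response region of a nutritional landscape — the
#' fundamental macronutrient niche — as the grid cells whose predicted
#' value reaches the empirical `q`-quantile of all in-simplex predictions.
#'
#' @param grid A `landscape_grid` from [tps_landscape()].
#' @param q Quantile in `[0, 1)` (default 0.9; `q = 0` selects the whole
#'   simplex).
#' @return An object of class `fmn_region`: logical `mask` matrix aligned
#'   with the grid, `threshold` and `area_pct` (percent of the simplex).
#' @export
fmn_region <- function(grid, q = 0.9) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)", call. = FALSE)
  inside <- !is.na(grid$z)
  thr <- stats::quantile(grid$z[inside], q, names = FALSE)
  mask <- inside & grid$z >= thr
  structure(list(
    mask = mask, threshold = thr, q = q,
    area_pct = 100 * sum(mask) / sum(inside),
    grid = grid
  ), class = "fmn_region")
}

#' @export
print.fmn_region <- function(x, ...) {
  cat(sprintf("FMN region: values >= %.4g (q = %.2f), covering %.1f%% of the simplex\n",
              x$threshold, x$q, x$area_pct))
  invisible(x)
}
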