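# Order-2 M-spline densities on the augmented knot sequence
# (t1, t1, t2, t3, t3); the I-splines under test must equal their
# numerically integrated cumulatives.
mspline_density <- function(u, knots, k) {
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  if (k == 1) {
    ifelse(u >= t1 & u < t2, 2 * (t2 - u) / (t2 - t1)^2, 0)
  } else if (k == 2) {
    ifelse(u >= t1 & u < t2, 2 * (u - t1) / ((t3 - t1) * (t2 - t1)),
           ifelse(u >= t2 & u <= t3,
                  2 * (t3 - u) / ((t3 - t1) * (t3 - t2)), 0))
  } else {
    ifelse(u >= t2 & u <= t3, 2 * (u - t2) / (t3 - t2)^2, 0)
  }
}

test_that("I-spline basis matches quadrature of its M-spline density", {
  knots <- c(0, 0.5, 1)
  xs <- seq(0, 1, length.out = 41)
  basis <- ispline_basis(xs, knots)
  for (k in 1:3) {
    for (i in seq_along(xs)) {
      ref <- integrate(mspline_density, 0, xs[i], knots = knots, k = k,
                       rel.tol = 1e-10)$value
      expect_equal(basis[i, k], ref, tolerance = 1e-6)
    }
  }
  # asymmetric knots too
  knots2 <- c(-2, 1, 7)
  xs2 <- seq(-2, 7, length.out = 31)
  basis2 <- ispline_basis(xs2, knots2)
  for (k in 1:3) {
    ref <- vapply(xs2, function(x) {
      integrate(mspline_density, -2, x, knots = knots2, k = k,
                rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(basis2[, k], ref, tolerance = 1e-6)
  }
})

test_that("I-spline basis boundary, monotonicity and degeneracy behaviour", {
  knots <- c(1, 3, 10)
  expect_equal(ispline_basis(1, knots)[1, ], c(0, 0, 0))
  expect_equal(ispline_basis(10, knots)[1, ], c(1, 1, 1))
  # clamping outside the training range
  expect_equal(ispline_basis(-5, knots), ispline_basis(1, knots))
  expect_equal(ispline_basis(99, knots), ispline_basis(10, knots))
  # monotone non-decreasing and within [0, 1] on a dense grid
  b <- ispline_basis(seq(1, 10, length.out = 200), knots)
  expect_true(all(diff(b[, 1]) >= -1e-12))
  expect_true(all(diff(b[, 2]) >= -1e-12))
  expect_true(all(diff(b[, 3]) >= -1e-12))
  expect_true(all(b >= 0 & b <= 1))
  # constant predictor: inert all-zero basis
  expect_true(all(ispline_basis(c(2, 2, 2), c(2, 2, 2)) == 0))
})

test_that("the fitter recovers known spline coefficients", {
  pairs <- make_synthetic_pairs(1000L, a0 = 0, b = 1.2, noise_sd = 0.02,
                                seed = 17L)
  m <- fit_gdm(pairs, knots = list(x = c(0, 0.5, 1)))
  expect_lt(abs(sum(m$coefficients[, "x"]) - 1.2) / 1.2, 0.10)
  # fitted values within the link range
  expect_true(all(m$fitted >= 1 - exp(-m$intercept) - 1e-12))
  expect_true(all(m$fitted < 1))
  expect_true(all(m$coefficients >= 0) && m$intercept >= 0)
})

test_that("degenerate tables fall back to an intercept-only model", {
  pairs <- structure(
    data.frame(site_i = "a", site_j = "b", distance = rep(0, 6), weight = 1,
               s1.x = 1, s2.x = 1),
    predictors = "x", class = c("site_pair_table", "data.frame"))
  expect_warning(expect_warning(m <- fit_gdm(pairs), "constant predictor"),
                 "intercept-only")
  expect_equal(m$intercept, 0)
  expect_equal(length(m$predictors), 0L)
  expect_equal(m$deviance$explained_pct, 0)
})

test_that("tiny fits match a brute-force box-constrained oracle", {
  set.seed(23)
  for (rep in 1:3) {
    pairs <- make_synthetic_pairs(18L, a0 = 0.1, b = 0.9, noise_sd = 0.05,
                                  seed = 100 + rep)
    m <- fit_gdm(pairs, knots = list(x = c(0, 0.5, 1)))
    X1 <- cbind(1, abs(ispline_basis(pairs$s1.x, c(0, 0.5, 1)) -
                         ispline_basis(pairs$s2.x, c(0, 0.5, 1))))
    obj <- function(th) {
      mu <- 1 - exp(-as.numeric(X1 %*% th))
      sum(pairs$weight * (pairs$distance - mu)^2)
    }
    # independent multi-start L-BFGS-B oracle over the same box
    best <- Inf
    for (s in list(rep(0, 4), rep(0.5, 4), c(0.1, 1, 0, 0), runif(4))) {
      o <- optim(s, obj, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = 500, factr = 1e3))
      best <- min(best, o$value)
    }
    expect_lt(m$objective_value, best + 1e-6)
  }
})

test_that("transform maps cells into bounded monotone bioclimate space", {
  fx <- fixture_model()
  tg <- gdm_transform(fx$model, fx$env)
  ok <- tg$valid
  expect_true(all(tg$values[ok, ] >= -1e-12))
  for (p in fx$model$predictors) {
    expect_true(all(tg$values[ok, p] <= tg$f_max[[p]] + 1e-12))
  }
  # cells at the knot extremes hit the exact bounds
  env2 <- fx$env
  env2$values[1, ] <- vapply(colnames(env2$values),
                             function(p) fx$model$knots[[p]][1], numeric(1))
  env2$values[2, ] <- vapply(colnames(env2$values),
                             function(p) fx$model$knots[[p]][3], numeric(1))
  tg2 <- gdm_transform(fx$model, env2)
  expect_equal(unname(tg2$values[1, ]), rep(0, length(fx$model$predictors)))
  expect_equal(tg2$values[2, ], tg2$f_max)
  # elementwise monotonicity of the transform
  set.seed(31)
  for (rep in 1:20) {
    a <- runif(length(fx$model$predictors))
    lo <- vapply(fx$model$knots, function(k) k[1], numeric(1))
    hi <- vapply(fx$model$knots, function(k) k[3], numeric(1))
    xa <- lo + a * (hi - lo)
    xb <- xa + runif(length(xa)) * (hi - xa)
    fa <- vapply(seq_along(xa), function(i) {
      sum(ispline_basis(xa[i], fx$model$knots[[i]]) *
            fx$model$coefficients[, i])
    }, numeric(1))
    fb <- vapply(seq_along(xb), function(i) {
      sum(ispline_basis(xb[i], fx$model$knots[[i]]) *
            fx$model$coefficients[, i])
    }, numeric(1))
    expect_true(all(fb - fa >= -1e-12))
  }
  # missing predictor is a hard error
  env3 <- fx$env; env3$values <- env3$values[, -1]
  env3$var_types <- env3$var_types[-1]
  expect_error(gdm_transform(fx$model, env3), "lacks model predictor")
})

test_that("pairwise prediction follows the negative exponential link", {
  fx <- fixture_model()
  m <- fx$model
  f <- rep(0.2, length(m$predictors))
  expect_equal(predict_dissimilarity(m, f, f), 0)
  # closed form with intercept included
  m2 <- m; m2$intercept <- 0.1
  fa <- c(0.5, rep(0, length(m$predictors) - 1))
  fb <- c(0, rep(0, length(m$predictors) - 1))
  expect_equal(predict_dissimilarity(m2, fa, fb, include_intercept = TRUE),
               1 - exp(-0.6))
  expect_equal(predict_dissimilarity(m, fa, fb),
               predict_dissimilarity(m, fb, fa))
  # asymptote: approaches but stays below 1
  expect_lt(predict_dissimilarity(m, c(30, fb[-1]), fb), 1)
  expect_gt(predict_dissimilarity(m, c(30, fb[-1]), fb), 1 - 1e-12)
  expect_error(predict_dissimilarity(m, c(1, 2), c(1, 2, 3)), "length")
})

test_that("explained deviance is 100% for perfect fits and nested-monotone", {
  pairs <- make_synthetic_pairs(200L, a0 = 0.05, b = 1, noise_sd = 0.02,
                                seed = 53L)
  m <- fit_gdm(pairs, knots = list(x = c(0, 0.5, 1)))
  perfect <- pairs
  perfect$distance <- predict_pairs(m, pairs)
  expect_equal(explained_deviance(m, perfect, type = "binomial"), 100,
               tolerance = 1e-6)

  # adding a predictor never reduces training explained deviance
  set.seed(59)
  pairs2 <- pairs
  pairs2$s1.z <- runif(nrow(pairs)); pairs2$s2.z <- runif(nrow(pairs))
  attr(pairs2, "predictors") <- c("x", "z")
  m1 <- fit_gdm(pairs, objective = "sse")
  m2 <- fit_gdm(pairs2, objective = "sse")
  expect_gte(explained_deviance(m2, pairs2, type = "sse"),
             explained_deviance(m1, pairs, type = "sse") - 0.05)
})

test_that("model serialisation round-trips bit-exactly", {
  fx <- fixture_model()
  f <- tempfile(fileext = ".txt")
  write_gdm(fx$model, f)
  back <- read_gdm(f)
  expect_identical(back$intercept, fx$model$intercept)
  expect_identical(back$coefficients, fx$model$coefficients)
  expect_identical(back$knots, fx$model$knots)
  expect_identical(back$deviance$explained_pct,
                   fx$model$deviance$explained_pct)
})
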