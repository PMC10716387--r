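# A hand-made cc_fit carrying a chosen cross-basis coefficient block, for
# deterministic reduction tests.
fake_fit <- function(theta, V, spec) {
  nm <- tempburden:::crossbasis_colnames(spec)
  names(theta) <- nm
  dimnames(V) <- list(nm, nm)
  structure(list(coef = theta, vcov = V, loglik = 0, converged = TRUE,
                 n_strata = 1L, n_dropped = 0L, iterations = 1L,
                 non_identified = character(), spec = spec),
            class = "cc_fit")
}

demo_spec <- function() {
  crossbasis_spec(
    spline_spec(c(5, 15, 22), c(-10, 32)),
    spline_spec(lag_knots_log(14, 3), c(0, 14), with_intercept = TRUE))
}

test_that("a zero surface reduces to the unit relative-risk curve", {
  spec <- demo_spec()
  fit <- fake_fit(rep(0, 20), diag(1e-4, 20), spec)
  curve <- reduce_overall(fit, spec)
  expect_equal(curve$eta, rep(0, 4))
  curve <- find_mmt(curve, seq(-5, 30, length.out = 500))
  rr <- rr_at(curve, c(-3, 10, 25))
  expect_equal(rr$rr, rep(1, 3))
  expect_true(all(rr$ci_low <= 1 & rr$ci_high >= 1))
})

test_that("reduced prediction equals the explicit sum over lags 0..14", {
  spec <- demo_spec()
  set.seed(44)
  theta <- rnorm(20, sd = 0.2)
  fit <- fake_fit(theta, diag(1e-4, 20), spec)
  curve <- reduce_overall(fit, spec)
  Blag <- ns_basis(0:14, spec$lag_spec)
  for (temp in c(-8, 0, 12, 20, 28)) {
    ref <- 17
    dB <- ns_basis(temp, spec$exposure_spec) -
      ns_basis(ref, spec$exposure_spec)
    brute <- 0
    for (l in 0:14) {
      contrast <- as.numeric(t(outer(drop(dB), Blag[l + 1, ])))
      brute <- brute + sum(contrast * theta)
    }
    expect_equal(cumulative_log_rr(curve, temp, ref = ref), brute,
                 tolerance = 1e-10)
  }
})

test_that("reduced vcov matches the sampling covariance of reduced draws", {
  spec <- demo_spec()
  set.seed(10)
  Araw <- matrix(rnorm(400), 20)
  V <- crossprod(Araw) / 40
  theta <- rnorm(20, sd = 0.3)
  fit <- fake_fit(theta, V, spec)
  curve <- reduce_overall(fit, spec)
  draws <- MASS::mvrnorm(100000, mu = theta, Sigma = V)
  A <- tempburden:::reduction_map(spec)
  eta_draws <- draws %*% t(A)
  expect_equal(cov(eta_draws), curve$vcov, tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(colMeans(eta_draws), curve$eta, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("the minimum of a symmetric U-shaped curve is found exactly", {
  temps <- seq(0, 40, length.out = 2000)
  curve <- curve_from_function(function(x) 0.004 * (x - 20)^2, temps)
  curve <- find_mmt(curve, temps)
  expect_equal(curve$mmt, 20, tolerance = 0.2)
  expect_false(attr(curve, "mmt_boundary"))
  rr <- rr_at(curve, curve$mmt)
  expect_equal(c(rr$rr, rr$ci_low, rr$ci_high), rep(1, 3))
})

test_that("a monotone curve puts the minimum at the bound and flags it", {
  temps <- seq(0, 40, length.out = 2000)
  curve <- curve_from_function(function(x) -0.05 * x, temps)
  curve <- find_mmt(curve, temps)
  expect_true(attr(curve, "mmt_boundary"))
  expect_equal(curve$mmt, unname(quantile(temps, 0.99, type = 7)),
               tolerance = 0.11)
})

test_that("lag-specific RRs multiply to the overall cumulative RR", {
  spec <- demo_spec()
  set.seed(7)
  theta <- rnorm(20, sd = 0.15)
  fit <- fake_fit(theta, diag(1e-4, 20), spec)
  curve <- find_mmt(reduce_overall(fit, spec), seq(-5, 30, length.out = 300))
  for (temp in c(-2, 27)) {
    lr <- lag_response_at(fit, temp, curve$mmt, spec)
    overall <- rr_at(curve, temp)$rr
    expect_equal(prod(lr$rr), overall, tolerance = 1e-10)
  }
  # null model: every lag RR is 1
  fit0 <- fake_fit(rep(0, 20), diag(1e-6, 20), spec)
  lr0 <- lag_response_at(fit0, 25, 17, spec)
  expect_equal(lr0$rr, rep(1, 15))
})

test_that("temperatures beyond the basis boundary are flagged as extrapolated", {
  temps <- seq(0, 30, length.out = 500)
  curve <- curve_from_function(function(x) 0.002 * (x - 18)^2, temps)
  curve <- find_mmt(curve, temps)
  expect_warning(rr <- rr_at(curve, 45), "boundary")
  expect_true(rr$extrapolated)
  expect_true(is.finite(rr$rr))
})

test_that("confidence bands shrink roughly as 1/sqrt(n) with death count", {
  wx <- small_weather()
  s <- default_true_surface(wx$temp_c)
  design <- build_design(wx)
  widths <- sapply(c(2, 8, 32), function(rate) {
    d <- simulate_deaths(wx, s, rate, seed = 17)
    fit <- suppressWarnings(fit_clogit(build_strata(d), design))
    curve <- find_mmt(reduce_overall(fit), wx$temp_c)
    rr <- rr_at(curve, pctl(wx$temp_c, 0.025))
    log(rr$ci_high) - log(rr$ci_low)
  })
  expect_true(all(diff(widths) < 0))
  # quadrupling deaths should about halve the width
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.5)
})
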