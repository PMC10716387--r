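# Toy problems: strata and designs built by hand so the partial likelihood
# can be enumerated directly.

toy_problem <- function(n_strata = 4, n_per = 4, k = 2, seed = 21) {
  set.seed(seed)
  dates <- seq(as.Date("2015-01-01"), by = "day",
               length.out = n_strata * n_per)
  design <- toy_design(data.frame(
    date = dates,
    matrix(rnorm(length(dates) * k), ncol = k,
           dimnames = list(NULL, paste0("x", seq_len(k))))))
  strata <- tibble::tibble(
    stratum = rep(seq_len(n_strata), each = n_per),
    date = dates,
    is_case = rep(c(TRUE, rep(FALSE, n_per - 1)), n_strata))
  list(strata = strata, design = design)
}

test_that("log-likelihood and gradient match brute-force softmax enumeration", {
  tp <- toy_problem(n_strata = 5, n_per = 4, k = 2)
  for (theta in list(c(0, 0), c(0.5, -1.2), c(-2, 3), c(10, -4))) {
    got <- clogit_objective(tp$strata, tp$design, theta)
    want <- brute_clogit(tp$strata, tp$design, theta)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
    expect_equal(unname(got$gradient), unname(want$gradient),
                 tolerance = 1e-10)
  }
})

test_that("the Newton MLE matches an independent optimiser to 1e-6", {
  tp <- toy_problem(n_strata = 5, n_per = 4, k = 2, seed = 33)
  fit <- fit_clogit(tp$strata, tp$design)
  expect_true(fit$converged)
  oracle <- optim(c(0, 0),
                  fn = function(th) -brute_clogit(tp$strata, tp$design, th)$loglik,
                  gr = function(th) -brute_clogit(tp$strata, tp$design, th)$gradient,
                  method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(fit$coef), oracle$par, tolerance = 1e-6)
  expect_equal(fit$loglik, -oracle$value, tolerance = 1e-10)
})

test_that("the MLE agrees with survival::clogit on a moderate problem", {
  skip_if_not_installed("survival")
  wx <- small_weather()
  s <- default_true_surface(wx$temp_c)
  d <- simulate_deaths(wx, s, 2, seed = 14)
  design <- build_design(wx)
  strata <- build_strata(d)
  fit <- fit_clogit(strata, design)
  dat <- dplyr::inner_join(strata, dplyr::filter(design, usable), by = "date")
  covars <- setdiff(names(design), c("date", "usable"))
  X <- as.matrix(dat[covars])
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(dat)), dat$is_case) ~ X +
      survival::strata(dat$stratum),
    method = "exact")
  ok <- !is.na(coef(ref)) & abs(coef(ref)) < 10
  expect_equal(unname(fit$coef[ok]), unname(coef(ref)[ok]), tolerance = 1e-4)
})

test_that("two opposing strata of equal contrast give a zero coefficient", {
  dates <- seq(as.Date("2015-02-02"), by = "day", length.out = 4)
  design <- toy_design(data.frame(date = dates, x1 = c(1, 0, 0, 1)))
  strata <- tibble::tibble(stratum = c(1L, 1L, 2L, 2L),
                           date = dates,
                           is_case = c(TRUE, FALSE, TRUE, FALSE))
  fit <- fit_clogit(strata, design)
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), 0, tolerance = 1e-8)
})

test_that("a single informative stratum is reported as non-identified", {
  dates <- as.Date(c("2015-02-02", "2015-02-03"))
  design <- toy_design(data.frame(date = dates, x1 = c(1, 0)))
  strata <- tibble::tibble(stratum = c(1L, 1L), date = dates,
                           is_case = c(TRUE, FALSE))
  expect_warning(fit <- fit_clogit(strata, design), "non-identified")
  expect_true("x1" %in% fit$non_identified)
})

test_that("a covariate constant within all strata is dropped as non-identified", {
  tp <- toy_problem(n_strata = 3, n_per = 4, k = 1, seed = 5)
  tp$design$x2 <- rep(c(2, 7, -1), each = 4)[seq_len(nrow(tp$design))]
  fit <- fit_clogit(tp$strata, tp$design)
  expect_true("x2" %in% fit$non_identified)
  expect_true(is.na(fit$coef["x2"]))
  expect_false(is.na(fit$coef["x1"]))
})

test_that("the likelihood is invariant to stratum-wise constant shifts", {
  tp <- toy_problem(n_strata = 4, n_per = 4, k = 2, seed = 12)
  theta <- c(0.7, -0.4)
  base <- clogit_objective(tp$strata, tp$design, theta)
  shifted <- tp$design
  shifts <- rep(c(5, -3, 11, 0.5), each = 4)
  shifted$x1 <- shifted$x1 + shifts[seq_len(nrow(shifted))]
  after <- clogit_objective(tp$strata, toy_design(shifted), theta)
  expect_equal(after$loglik, base$loglik, tolerance = 1e-10)
})

test_that("the reported vcov matches a finite-difference Hessian", {
  tp <- toy_problem(n_strata = 6, n_per = 4, k = 3, seed = 77)
  fit <- fit_clogit(tp$strata, tp$design)
  k <- length(fit$coef)
  h <- 1e-5
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    e <- numeric(k); e[j] <- h
    gp <- clogit_objective(tp$strata, tp$design, fit$coef + e)$gradient
    gm <- clogit_objective(tp$strata, tp$design, fit$coef - e)$gradient
    H[, j] <- (gp - gm) / (2 * h)
  }
  V_fd <- solve(-(H + t(H)) / 2)
  expect_equal(fit$vcov, V_fd, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("tidy and glance expose the fit in broom shape", {
  tp <- toy_problem(seed = 3)
  fit <- fit_clogit(tp$strata, tp$design)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 2L)
  gl <- glance(fit)
  expect_equal(gl$n_strata, 4L)
  expect_true(gl$converged)
})

test_that("the null-effect Wald test rejects at close to the nominal rate", {
  wx <- simulate_weather(weather_params(end_date = "2013-12-31", seed = 61))
  design <- build_design(wx)
  flat <- true_surface(function(temp) rep(0, length(temp)),
                       lag_weight_profile("uniform"), 15)
  n_rep <- 150
  reject <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    d <- simulate_deaths(wx, flat, 2, seed = 5000 + r)
    fit <- suppressWarnings(fit_clogit(build_strata(d), design))
    reject[r] <- fit$converged &&
      wald_test(fit, "^cb_")$p.value < 0.05
  }
  rate <- mean(reject)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
})
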