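# Shared fixtures, built lazily and cached for the session so expensive
# simulations run once.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Two years of weather: enough for small association fits.
small_weather <- function() {
  cached("small_weather",
         simulate_weather(weather_params(end_date = "2014-12-31", seed = 42)))
}

# Full-scale recovery world: the package's default run configuration
# (master seed 1: weather sub-seed 2, deaths sub-seed 3), seven years,
# ~12 baseline deaths/day against the default inverted-J truth.
recovery_fixture <- function() {
  cached("recovery", {
    weather <- simulate_weather(weather_params(seed = 2))
    surface <- default_true_surface(weather$temp_c)
    deaths <- simulate_deaths(weather, surface, baseline_rate = 12, seed = 3)
    spec <- default_crossbasis_spec(weather$temp_c)
    design <- build_design(weather, spec)
    fit <- fit_clogit(build_strata(deaths), design)
    curve <- find_mmt(reduce_overall(fit, spec), weather$temp_c)
    list(weather = weather, surface = surface, deaths = deaths,
         spec = spec, fit = fit, curve = curve)
  })
}

# A hand-made design table that satisfies the `cc_design` contract, for toy
# conditional-logistic problems.
toy_design <- function(df) {
  stopifnot("date" %in% names(df))
  if (!"usable" %in% names(df)) df$usable <- TRUE
  out <- tibble::as_tibble(df)
  class(out) <- c("cc_design", class(out))
  out
}

# Brute-force conditional-logistic log-likelihood and gradient by direct
# softmax enumeration over each stratum's days.
brute_clogit <- function(strata, design, theta) {
  covars <- setdiff(names(design), c("date", "usable"))
  ll <- 0
  grad <- numeric(length(theta))
  for (s in unique(strata$stratum)) {
    rows <- strata[strata$stratum == s, ]
    X <- as.matrix(design[match(rows$date, design$date), covars])
    lp <- as.numeric(X %*% theta)
    w <- exp(lp) / sum(exp(lp))
    ll <- ll + lp[rows$is_case] - log(sum(exp(lp)))
    grad <- grad + X[rows$is_case, ] - colSums(w * X)
  }
  list(loglik = ll, gradient = grad)
}

# Least-squares projection of an arbitrary log-RR function onto an exposure
# spline basis, returning a reduced_curve with a chosen coefficient
# covariance. Used to build synthetic "true" curves for the attribution
# machinery.
curve_from_function <- function(f, temps, vcov_scale = 1e-6,
                                probs = c(0.10, 0.75, 0.90)) {
  spec <- spline_spec(pctl(temps, probs), range(temps))
  grid <- seq(min(temps), max(temps), length.out = 400)
  B <- ns_basis(grid, spec)
  # free intercept absorbs the arbitrary level; only contrasts matter
  coefs <- qr.solve(cbind(1, B), f(grid))
  reduced_curve(coefs[-1], diag(vcov_scale, ncol(B)), spec)
}
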