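# Conditional logistic (partial) likelihood for case-crossover strata.
# Each stratum contributes log softmax: x_case.theta - log sum_j exp(x_j.theta).

# Join strata with design rows and drop strata that cannot contribute:
# unusable/missing case day, or no usable control left. Returns the stacked
# numeric problem.
assemble_cc_data <- function(strata, design) {
  assert_that(inherits(design, "cc_design"),
              "`design` must come from `build_design()`.")
  assert_that(is.data.frame(strata) &&
                all(c("stratum", "date", "is_case") %in% names(strata)),
              "`strata` must come from `build_strata()`.")
  covars <- design_covariate_names(design)

  d <- dplyr::inner_join(strata,
                         dplyr::filter(design, .data$usable),
                         by = "date")
  keep <- d |>
    dplyr::summarise(has_case = any(.data$is_case),
                     n_ctrl = sum(!.data$is_case), .by = "stratum") |>
    dplyr::filter(.data$has_case, .data$n_ctrl >= 1L)
  n_total <- length(unique(strata$stratum))
  d <- d[d$stratum %in% keep$stratum, , drop = FALSE]
  d <- d[order(d$stratum, d$date), , drop = FALSE]

  g <- match(d$stratum, sort(unique(d$stratum)))
  list(X = as.matrix(d[covars]),
       is_case = d$is_case,
       g = g,
       n_strata = length(unique(g)),
       n_dropped = n_total - length(unique(g)),
       covars = covars,
       spec = attr(design, "spec"))
}

# Log-likelihood, gradient and expected x-bar per stratum at theta.
cc_objective_internal <- function(X, is_case, g, theta) {
  lp <- drop(X %*% theta)
  mg <- as.numeric(tapply(lp, g, max))
  e <- exp(lp - mg[g])
  denom <- as.numeric(rowsum(e, g))
  lse <- log(denom) + mg
  p <- e / denom[g]
  ll <- sum(lp[is_case]) - sum(lse)
  xbar <- rowsum(p * X, g)                       # n_strata x k
  grad <- colSums(X[is_case, , drop = FALSE]) - colSums(xbar)
  list(loglik = ll, gradient = grad, p = p, xbar = xbar)
}

#' Conditional-logistic log-likelihood and gradient at a given coefficient
#'
#' Exposes the exact partial-likelihood objective maximised by
#' [fit_clogit()], useful for diagnostics and verification.
#'
#' @param strata Stratum table from [build_strata()].
#' @param design Day-level design from [build_design()].
#' @param theta Coefficient vector (length = number of covariate columns).
#' @return A list with `loglik` and `gradient`.
#' @export
clogit_objective <- function(strata, design, theta) {
  dat <- assemble_cc_data(strata, design)
  assert_that(length(theta) == ncol(dat$X),
              sprintf("`theta` must have length %d.", ncol(dat$X)))
  obj <- cc_objective_internal(dat$X, dat$is_case, dat$g, as.numeric(theta))
  list(loglik = obj$loglik, gradient = setNames(obj$gradient, dat$covars))
}

#' Fit the time-stratified case-crossover model
#'
#' Maximises the conditional-logistic partial likelihood over the strata by
#' Newton-Raphson with step-halving, starting at zero. The variance is the
#' inverse observed information at the maximum. Covariate directions that
#' do not vary within any stratum are non-identified: they are excluded
#' from the optimisation and reported as `NA` coefficients. Directions
#' along which the converged likelihood is flat (separation or
#' near-collinearity, recognisable by huge coefficients) keep their
#' estimates, as `survival::clogit` does, but are listed in
#' `non_identified` with a warning.
#'
#' @param strata Stratum table from [build_strata()].
#' @param design Day-level design from [build_design()].
#' @param tol_loglik Relative log-likelihood convergence tolerance.
#' @param tol_gradient Maximum absolute gradient at convergence.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cc_fit` with elements `coef`, `vcov`,
#'   `loglik`, `converged`, `n_strata`, `n_dropped`, `iterations`,
#'   `non_identified`, `spec`.
#' @export
fit_clogit <- function(strata, design, tol_loglik = 1e-9,
                       tol_gradient = 1e-6, max_iter = 50L) {
  dat <- assemble_cc_data(strata, design)
  assert_that(dat$n_strata >= 1L, "No usable stratum remains after joining with the design.")
  X <- dat$X; g <- dat$g; is_case <- dat$is_case
  k <- ncol(X)

  # identifiability: a column with no within-stratum variation cannot move
  # the conditional likelihood
  strat_mean <- rowsum(X, g) / as.numeric(table(g))
  Xc <- X - strat_mean[g, , drop = FALSE]
  scale_ref <- pmax(1, apply(abs(X), 2, max))
  identified <- apply(abs(Xc), 2, max) > 1e-10 * scale_ref
  Xi <- X[, identified, drop = FALSE]
  ki <- ncol(Xi)

  theta <- numeric(ki)
  obj <- cc_objective_internal(Xi, is_case, g, theta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter && ki > 0L) {
    iter <- iter + 1L
    info <- crossprod(Xi, obj$p * Xi) - crossprod(obj$xbar)
    step <- tryCatch(solve(info, obj$gradient), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving keeps the ascent monotone up to floating-point noise in
    # the accumulated log-likelihood
    plateau <- 1e-10 * (1 + abs(obj$loglik))
    new_obj <- NULL
    for (h in 0:20) {
      cand <- theta + step / 2^h
      cand_obj <- cc_objective_internal(Xi, is_case, g, cand)
      if (is.finite(cand_obj$loglik) && cand_obj$loglik >= obj$loglik - plateau) {
        new_obj <- cand_obj; theta <- cand; break
      }
    }
    if (is.null(new_obj)) break
    rel <- abs(new_obj$loglik - obj$loglik) /
      (abs(obj$loglik) + tol_loglik)
    obj <- new_obj
    if (rel < tol_loglik && max(abs(obj$gradient)) < tol_gradient) {
      converged <- TRUE
      break
    }
  }
  if (ki == 0L) converged <- TRUE
  # huge coefficients with a converged gradient mean the likelihood is flat
  # in that direction (separation / near-collinearity): keep the estimates,
  # as survival::clogit does, but flag the terms
  flat <- character()
  if (converged && ki > 0L && any(abs(theta) > 10)) {
    flat <- dat$covars[identified][abs(theta) > 10]
    warn(paste0("Effectively non-identified (flat likelihood) directions: ",
                paste(flat, collapse = ", ")))
  }
  if (!converged && iter >= 1L) {
    warn(sprintf("Newton-Raphson did not converge in %d iterations.", iter))
  }

  coef <- rep(NA_real_, k)
  vcov <- matrix(NA_real_, k, k)
  if (ki > 0L && converged) {
    info <- crossprod(Xi, obj$p * Xi) - crossprod(obj$xbar)
    vi <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ki, ki))
    coef[identified] <- theta
    vcov[identified, identified] <- (vi + t(vi)) / 2
  } else if (ki > 0L) {
    coef[identified] <- theta
  }
  names(coef) <- dat$covars
  dimnames(vcov) <- list(dat$covars, dat$covars)

  structure(list(coef = coef, vcov = vcov,
                 loglik = obj$loglik, converged = converged,
                 n_strata = dat$n_strata, n_dropped = dat$n_dropped,
                 iterations = iter,
                 non_identified = union(dat$covars[!identified], flat),
                 spec = dat$spec),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat("Time-stratified case-crossover conditional logistic fit\n")
  cat(sprintf("  strata used: %d (dropped: %d)\n", x$n_strata, x$n_dropped))
  cat(sprintf("  log-likelihood: %.4f (converged: %s, %d iterations)\n",
              x$loglik, x$converged, x$iterations))
  if (length(x$non_identified)) {
    cat("  non-identified terms:", paste(x$non_identified, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a case-crossover fit
#'
#' @param x A `cc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy cc_fit
#' @export
tidy.cc_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coef / se
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(2 * stats::pnorm(-abs(z))))
}

#' @rdname tidy.cc_fit
#' @return `glance()` returns a one-row tibble of fit-level summaries.
#' @method glance cc_fit
#' @export
glance.cc_fit <- function(x, ...) {
  tibble::tibble(n_strata = x$n_strata, n_dropped = x$n_dropped,
                 logLik = x$loglik, converged = x$converged,
                 iterations = x$iterations,
                 n_non_identified = length(x$non_identified))
}

#' Wald test of a block of coefficients
#'
#' Chi-squared Wald test that all coefficients whose names match `pattern`
#' are zero; by default the full cross-basis block, i.e. a global test of
#' any temperature effect.
#'
#' @param fit A `cc_fit`.
#' @param pattern Regular expression selecting coefficient names.
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @export
wald_test <- function(fit, pattern = "^cb_") {
  assert_that(inherits(fit, "cc_fit"), "`fit` must be a `cc_fit`.")
  idx <- grep(pattern, names(fit$coef))
  idx <- idx[!is.na(fit$coef[idx])]
  assert_that(length(idx) > 0, "No identified coefficient matches `pattern`.")
  b <- fit$coef[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  tibble::tibble(statistic = stat, df = length(idx),
                 p.value = stats::pchisq(stat, df = length(idx),
                                         lower.tail = FALSE))
}
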