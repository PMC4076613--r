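fixture_params <- function(fx) {
  list(beta0 = 0.4, beta1 = -0.2, sigma2 = 1.1, gamma0 = -1.5,
       gamma1 = 0.3, gamma2 = 0.6,
       px = c(0.45, 0.4, 0.15))
}

# independent oracle: per-subject summation with the prevalence integral done
# by adaptive 1-d quadrature (stats::integrate), no shared code
naive_retro_loglik <- function(par, ds) {
  v <- ds$level_values[ds$x + 1]
  rho <- sum(vapply(seq_along(ds$level_values), function(a) {
    val <- ds$level_values[a]
    par$px[a] * stats::integrate(function(y) {
      plogis(par$gamma0 + par$gamma1 * val + par$gamma2 * y) *
        dnorm(y, par$beta0 + par$beta1 * val, sqrt(par$sigma2))
    }, -Inf, Inf, rel.tol = 1e-13)$value
  }, numeric(1)))
  total <- 0
  for (i in seq_len(ds$n)) {
    eta <- par$gamma0 + par$gamma1 * v[i] + par$gamma2 * ds$y[i]
    pd <- plogis(eta)
    total <- total +
      ds$d[i] * log(pd) + (1 - ds$d[i]) * log(1 - pd) +
      dnorm(ds$y[i], par$beta0 + par$beta1 * v[i], sqrt(par$sigma2),
            log = TRUE) +
      log(par$px[ds$x[i] + 1]) -
      (if (ds$d[i] == 1) log(rho) else log(1 - rho))
  }
  as.numeric(total)
}

test_that("retrospective_loglik matches the independent oracle and is stable
           in quadrature order", {
  fx <- fixture_n12()
  par <- fixture_params(fx)
  ours <- retrospective_loglik(par, fx)
  expect_equal(ours, naive_retro_loglik(par, fx), tolerance = 1e-8)
  l32 <- retrospective_loglik(par, fx, gh_order = 32)
  l64 <- retrospective_loglik(par, fx, gh_order = 64)
  l128 <- retrospective_loglik(par, fx, gh_order = 128)
  expect_lt(abs(l64 - l32), 1e-10)
  expect_lt(abs(l128 - l64), 1e-10)
})

test_that("ascertainment terms cancel exactly when D is independent of (X,Y)", {
  # gamma1 = gamma2 = 0: P(D|X,Y) = P(D), so the retrospective loglik equals
  # prospective normal loglik + multinomial loglik (constants cancel)
  fx <- fixture_n12()
  par <- fixture_params(fx)
  par$gamma1 <- 0
  par$gamma2 <- 0
  v <- fx$level_values[fx$x + 1]
  prospective <- sum(dnorm(fx$y, par$beta0 + par$beta1 * v,
                           sqrt(par$sigma2), log = TRUE)) +
    sum(log(par$px[fx$x + 1]))
  expect_equal(retrospective_loglik(par, fx), prospective,
               tolerance = 1e-10)
})

test_that("fit_retrospective reduces to OLS + empirical frequencies without
           ascertainment dependence", {
  # with gamma1 = gamma2 = 0 the ascertainment terms cancel identically, so
  # the remaining likelihood is prospective; the gammas are held at their
  # true zeros because gamma0 is unidentified on that slice (its
  # contribution cancels for every value) and leaving the gammas free puts
  # the optimum on a ridge rather than at the OLS point
  for (seed in c(101, 102, 103)) {
    params <- simulation_params(beta0 = 1, beta1 = -0.12, sigma2 = 1,
                                gamma1 = 0, gamma2 = 0, maf = 0.3,
                                n_cases = 300L, n_controls = 300L,
                                target_rate = 0.3, seed = seed)
    ds <- simulate_case_control(params)
    fit <- fit_retrospective(ds, fixed = list(gamma0 = 0, gamma1 = 0,
                                              gamma2 = 0))
    expect_true(fit$converged)
    v <- ds$level_values[ds$x + 1]
    ols <- lm(ds$y ~ v)
    expect_equal(fit$beta0, unname(coef(ols)[1]), tolerance = 1e-5)
    expect_equal(fit$beta1, unname(coef(ols)[2]), tolerance = 1e-5)
    expect_equal(fit$sigma2, mean(residuals(ols)^2), tolerance = 1e-5)
    expect_equal(fit$px, tabulate(ds$x + 1, 3) / ds$n, tolerance = 1e-5)
  }
})

test_that("fitted maximum dominates the independent oracle at nearby points", {
  ds <- simulate_case_control(paper_params(beta1 = -0.12, gamma1 = log(1.3),
                                           seed = 120, n_cases = 200L,
                                           n_controls = 200L))
  fit <- fit_retrospective(ds, n_starts = 2)
  expect_true(fit$converged)
  at <- list(beta0 = fit$beta0, beta1 = fit$beta1, sigma2 = fit$sigma2,
             gamma0 = fit$gamma0, gamma1 = fit$gamma1, gamma2 = fit$gamma2,
             px = fit$px)
  expect_equal(fit$loglik, naive_retro_loglik(at, ds), tolerance = 1e-6)
  for (eps in list(c(0.05, 0), c(-0.05, 0), c(0, 0.05), c(0, -0.05))) {
    pert <- at
    pert$beta0 <- pert$beta0 + eps[1]
    pert$beta1 <- pert$beta1 + eps[2]
    expect_gte(fit$loglik + 1e-8, retrospective_loglik(pert, ds))
  }
})

test_that("Wald and LRT genotype tests behave and agree structurally", {
  ds <- simulate_case_control(paper_params(beta1 = -0.12, gamma1 = log(1.3),
                                           seed = 130, n_cases = 300L,
                                           n_controls = 300L))
  fit <- fit_retrospective(ds, n_starts = 2)
  w <- wald_test_beta1(fit)
  expect_true(w$converged)
  expect_equal(w$statistic,
               fit$beta1^2 / fit$vcov["beta1", "beta1"],
               tolerance = 1e-12)
  expect_equal(w$p_value, pchisq(w$statistic, 1, lower.tail = FALSE))

  lr <- lrt_beta1(ds, n_starts = 2)
  expect_true(lr$converged)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 1L)

  # vcov unavailable -> explicit unavailable result
  fit_nc <- fit
  fit_nc$vcov <- NULL
  nc <- wald_test_beta1(fit_nc)
  expect_false(nc$converged)
  expect_true(is.na(nc$p_value))
})

test_that("fixed disease rate profiles gamma0 to hit the constraint", {
  ds <- simulate_case_control(paper_params(beta1 = -0.12, gamma1 = log(1.3),
                                           seed = 140, n_cases = 200L,
                                           n_controls = 200L))
  fit <- fit_retrospective(ds, fixed_rate = 0.05, n_starts = 2)
  expect_true(fit$converged)
  at <- list(beta0 = fit$beta0, beta1 = fit$beta1, sigma2 = fit$sigma2,
             gamma0 = fit$gamma0, gamma1 = fit$gamma1, gamma2 = fit$gamma2,
             px = fit$px)
  prev <- secophen:::retro_prevalence(
    list(beta0 = fit$beta0, beta1 = fit$beta1, lsigma2 = log(fit$sigma2),
         gamma0 = fit$gamma0, gamma1 = fit$gamma1, gamma2 = fit$gamma2,
         px = fit$px), ds$level_values, secophen:::gauss_hermite(64))
  expect_equal(prev$rho, 0.05, tolerance = 1e-8)
  expect_identical(fit$constraint, 0.05)
})

test_that("loglik_surface evaluates grids and flags flat directions", {
  fx <- fixture_n12()
  par <- fixture_params(fx)
  surf1 <- loglik_surface(fx, c("beta0", "beta1"),
                          grid = list(beta0 = 0.4, beta1 = -0.2), at = par)
  expect_equal(dim(surf1$loglik), c(1L, 1L))
  expect_equal(surf1$loglik[1, 1], retrospective_loglik(par, fx),
               tolerance = 1e-12)
  expect_error(loglik_surface(fx, c("beta0", "nope"),
                              grid = list(beta0 = 1, nope = 1), at = par),
               "param_pair")

  # TSV round trip
  surf2 <- loglik_surface(fx, c("beta0", "beta1"),
                          grid = list(beta0 = c(0.2, 0.4),
                                      beta1 = c(-0.3, -0.2, -0.1)),
                          at = par)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_surface_table(surf2, path)
  expect_equal(nrow(tab), 6L)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$loglik, as.vector(surf2$loglik), tolerance = 1e-9)
})
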