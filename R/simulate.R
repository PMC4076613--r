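#' Simulation parameters for the ascertained case-control generative model
#'
#' The generative model is: genotype X drawn from Hardy-Weinberg frequencies
#' at a given minor-allele frequency; secondary phenotype
#' Y | X ~ N(beta0 + beta1 * X, sigma2); disease
#' P(D = 1 | X, Y) = expit(gamma0 + gamma1 * X + gamma2 * Y). Sampling is
#' retrospective: individuals are drawn from the population until the case and
#' control quotas are both filled.
#'
#' Exactly one of `gamma0` and `target_rate` must be supplied; when
#' `target_rate` is given the disease-model intercept is calibrated with
#' [calibrate_gamma0()].
#'
#' @param beta0,beta1 intercept and genotype effect of the trait model
#' @param sigma2 trait residual variance (> 0)
#' @param gamma0 disease-model intercept (or `NULL` to calibrate)
#' @param gamma1 genotype log-odds on disease
#' @param gamma2 trait log-odds on disease
#' @param maf minor-allele frequency in (0, 0.5]
#' @param n_cases,n_controls sampling quotas
#' @param target_rate population disease probability in (0,1), or `NULL`
#' @param seed PRNG seed (base R Mersenne-Twister via `set.seed`)
#' @return an object of class `simulation_params`
#' @export
simulation_params <- function(beta0 = 1, beta1 = 0, sigma2 = 1,
                              gamma0 = NULL, gamma1 = 0, gamma2 = log(2),
                              maf = 0.3, n_cases = 500L, n_controls = 500L,
                              target_rate = NULL, seed = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]", call. = FALSE)
  if (is.null(gamma0) == is.null(target_rate)) {
    stop("exactly one of gamma0 and target_rate must be given",
         call. = FALSE)
  }
  if (!is.null(target_rate) && (target_rate <= 0 || target_rate >= 1)) {
    stop("target_rate must lie in (0,1)", call. = FALSE)
  }
  if (n_cases < 1 || n_controls < 1) stop("quotas must be positive",
                                          call. = FALSE)
  structure(list(beta0 = beta0, beta1 = beta1, sigma2 = sigma2,
                 gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
                 maf = maf, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 target_rate = target_rate, seed = seed),
            class = "simulation_params")
}

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf minor-allele frequency in (0, 0.5]
#' @return probability triple over allele counts 0/1/2
#' @export
genotype_probs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5) {
    stop("maf must lie in (0, 0.5]", call. = FALSE)
  }
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

# P(D=1) = sum_x p_x * E[expit(gamma0 + gamma1 x + gamma2 Y) | X = x]
# with Y | X normal; the inner expectation by Gauss-Hermite quadrature.
# `values` are the genotype values, `px` their probabilities.
prevalence_quadrature <- function(beta0, beta1, sigma2, gamma0, gamma1,
                                  gamma2, values, px, gh) {
  sd <- sqrt(sigma2)
  w <- gh$weights / sqrt(pi)
  total <- 0
  for (a in seq_along(values)) {
    v <- values[a]
    y <- beta0 + beta1 * v + sqrt(2) * sd * gh$nodes
    total <- total + px[a] * sum(w * expit(gamma0 + gamma1 * v + gamma2 * y))
  }
  total
}

#' Population disease prevalence under the generative model
#'
#' Evaluates P(D = 1) = sum_x P(x) E[expit(gamma0 + gamma1 x + gamma2 Y) | x]
#' by fixed-order Gauss-Hermite quadrature. Strictly increasing in `gamma0`.
#'
#' @param params a [simulation_params()] object with `gamma0` set explicitly
#' @param gh_order quadrature order (default 64)
#' @return probability in (0, 1)
#' @export
population_prevalence <- function(params, gh_order = 64L) {
  if (is.null(params$gamma0)) {
    stop("population_prevalence requires an explicit gamma0", call. = FALSE)
  }
  gh <- gauss_hermite(gh_order)
  prevalence_quadrature(params$beta0, params$beta1, params$sigma2,
                        params$gamma0, params$gamma1, params$gamma2,
                        values = 0:2, px = genotype_probs(params$maf),
                        gh = gh)
}

#' Calibrate the disease-model intercept to a target prevalence
#'
#' Solves P(D = 1) = `target_rate` for `gamma0` by bracketing root search;
#' prevalence is strictly increasing in `gamma0`, so the root is unique.
#'
#' @param params a [simulation_params()] object (its `gamma0`, if any, is
#'   ignored)
#' @param target_rate population disease probability in (0, 1); defaults to
#'   `params$target_rate`
#' @param gh_order quadrature order
#' @param tol absolute prevalence tolerance at the returned root
#' @return the calibrated `gamma0`
#' @export
calibrate_gamma0 <- function(params, target_rate = params$target_rate,
                             gh_order = 64L, tol = 1e-8) {
  if (is.null(target_rate) || target_rate <= 0 || target_rate >= 1) {
    stop("target_rate must lie in (0,1)", call. = FALSE)
  }
  gh <- gauss_hermite(gh_order)
  px <- genotype_probs(params$maf)
  f <- function(g0) {
    prevalence_quadrature(params$beta0, params$beta1, params$sigma2, g0,
                          params$gamma1, params$gamma2, 0:2, px, gh) -
      target_rate
  }
  lo <- stats::qlogis(target_rate) - 1
  hi <- stats::qlogis(target_rate) + 1
  while (f(lo) > 0) {
    lo <- lo - 2
    if (lo < -50) stop("gamma0 calibration failed: bracket exceeded -50",
                       call. = FALSE)
  }
  while (f(hi) < 0) {
    hi <- hi + 2
    if (hi > 50) stop("gamma0 calibration failed: bracket exceeded +50",
                      call. = FALSE)
  }
  r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  # polish until the prevalence error (not the interval width) meets tol
  if (abs(f(r$root)) >= tol) {
    r <- stats::uniroot(f, c(r$root - 1e-6, r$root + 1e-6), tol = 1e-14,
                        extendInt = "upX")
  }
  r$root
}

# Draw `n` unascertained individuals from the population model.
draw_population <- function(n, beta0, beta1, sigma2, gamma0, gamma1, gamma2,
                            px) {
  x <- sample.int(3L, n, replace = TRUE, prob = px) - 1L
  y <- stats::rnorm(n, beta0 + beta1 * x, sqrt(sigma2))
  d <- stats::rbinom(n, 1L, expit(gamma0 + gamma1 * x + gamma2 * y))
  list(x = x, y = y, d = d)
}

#' Simulate an ascertained case-control dataset
#'
#' Draws population individuals in vectorized blocks (genotype, then trait,
#' then disease status, from a single seeded Mersenne-Twister stream) and
#' retains them in draw order until both the case and the control quota are
#' filled; overflow of an already-filled class is discarded, matching
#' retrospective sampling of independent cases and controls.
#'
#' @param params a [simulation_params()] object; if `gamma0` is `NULL` it is
#'   calibrated to `target_rate` first
#' @param block population draws per block (default 1e5)
#' @param max_draws feasibility cap on total population draws (default 1e8)
#' @param gh_order quadrature order used for calibration if needed
#' @return a [case_control_dataset()] with exactly the requested quotas;
#'   attribute `gamma0` records the intercept used
#' @export
simulate_case_control <- function(params, block = 1e5, max_draws = 1e8,
                                  gh_order = 64L) {
  gamma0 <- params$gamma0
  if (is.null(gamma0)) gamma0 <- calibrate_gamma0(params,
                                                  gh_order = gh_order)
  if (!is.null(params$seed)) set.seed(params$seed)
  px <- genotype_probs(params$maf)
  need_ca <- params$n_cases
  need_co <- params$n_controls
  acc_x <- integer(0); acc_y <- numeric(0); acc_d <- integer(0)
  drawn <- 0
  while (need_ca > 0L || need_co > 0L) {
    if (drawn >= max_draws) {
      stop("feasibility cap reached filling case/control quotas; ",
           "revise gamma0 or target_rate", call. = FALSE)
    }
    b <- draw_population(as.integer(block), params$beta0, params$beta1,
                         params$sigma2, gamma0, params$gamma1, params$gamma2,
                         px)
    drawn <- drawn + block
    ca <- which(b$d == 1L)[seq_len(min(need_ca, sum(b$d)))]
    co <- which(b$d == 0L)[seq_len(min(need_co, sum(1L - b$d)))]
    keep <- sort(c(ca, co))
    acc_x <- c(acc_x, b$x[keep])
    acc_y <- c(acc_y, b$y[keep])
    acc_d <- c(acc_d, b$d[keep])
    need_ca <- need_ca - length(ca)
    need_co <- need_co - length(co)
  }
  values <- sort(unique(acc_x))
  ds <- case_control_dataset(d = acc_d, y = acc_y,
                             x = match(acc_x, values) - 1L,
                             level_values = values)
  attr(ds, "gamma0") <- gamma0
  ds
}
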