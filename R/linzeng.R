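# ---------------------------------------------------------------------------
# Retrospective likelihood for a normally distributed secondary phenotype
# under case-control ascertainment:
#   L = prod_i P(D_i | X_i, Y_i) * phi(Y_i; beta0 + beta1 X_i, sigma2)
#              * p_{X_i} / P(D_i)
# with P(D=1) = sum_x p_x * Integral expit(gamma0 + gamma1 x + gamma2 y)
#                           phi(y; beta0 + beta1 x, sigma2) dy
# evaluated by Gauss-Hermite quadrature. The genotype distribution p_x over
# the finite level set is a free simplex, parameterized by softmax logits
# (first level as the zero reference). Maximization is quasi-Newton (BFGS)
# with analytic gradients; the disease rate can optionally be held fixed, in
# which case gamma0 is profiled out at each iterate by root finding and its
# implicit dependence enters the gradient by the implicit-function theorem.
# ---------------------------------------------------------------------------

LOG_FLOOR <- -1e10   # log-domain floor returned for impossible configurations

retro_scalar_names <- c("beta0", "beta1", "lsigma2", "gamma0", "gamma1",
                        "gamma2")

# prevalence and its partial derivatives at the current parameter point
retro_prevalence <- function(par, values, gh, want_grad = FALSE) {
  sd <- sqrt(exp(par[["lsigma2"]]))
  w <- gh$weights / sqrt(pi)
  K <- length(values)
  A <- numeric(K)
  if (want_grad) {
    Bg0 <- Bg2 <- Bls <- numeric(K)   # per-level pieces for the derivatives
  }
  for (a in seq_len(K)) {
    v <- values[a]
    mu <- par[["beta0"]] + par[["beta1"]] * v
    yk <- mu + sqrt(2) * sd * gh$nodes
    q <- expit(par[["gamma0"]] + par[["gamma1"]] * v + par[["gamma2"]] * yk)
    A[a] <- sum(w * q)
    if (want_grad) {
      qq <- w * q * (1 - q)
      Bg0[a] <- sum(qq)
      Bg2[a] <- sum(qq * yk)
      Bls[a] <- sum(qq * (yk - mu) / 2)
    }
  }
  px <- par$px
  rho <- sum(px * A)
  if (!want_grad) return(list(rho = rho, A = A))
  g2 <- par[["gamma2"]]
  drho <- c(
    beta0  = g2 * sum(px * Bg0),
    beta1  = g2 * sum(px * values * Bg0),
    lsigma2 = g2 * sum(px * Bls),
    gamma0 = sum(px * Bg0),
    gamma1 = sum(px * values * Bg0),
    gamma2 = sum(px * Bg2)
  )
  # softmax logits theta_k, k = 2..K (level 1 is the reference)
  drho_theta <- px * (A - rho)
  list(rho = rho, A = A, drho = drho, drho_theta = drho_theta[-1L])
}

# log-likelihood and gradient given a full parameter list
# par: beta0, beta1, lsigma2, gamma0, gamma1, gamma2, px (prob vector)
# pre-extracted data: d, y, v (genotype values), lev (1-based level index),
# n_lev (counts per level)
retro_core <- function(par, dat, gh, want_grad = FALSE, fixed_rate = NULL) {
  sigma2 <- exp(par[["lsigma2"]])
  mu <- par[["beta0"]] + par[["beta1"]] * dat$v
  eta <- par[["gamma0"]] + par[["gamma1"]] * dat$v + par[["gamma2"]] * dat$y
  p_i <- expit(eta)
  if (any(par$px[unique(dat$lev)] <= 0)) {
    return(list(ll = LOG_FLOOR, note = "zero genotype mass on observed level"))
  }
  prev <- retro_prevalence(par, dat$values, gh, want_grad = want_grad)
  rho <- min(max(prev$rho, 1e-300), 1 - 1e-15)
  n1 <- dat$n1
  n0 <- dat$n0
  resid <- dat$y - mu
  ll <- sum(dat$d * log(p_i) + (1 - dat$d) * log1p(-p_i)) +
    sum(stats::dnorm(dat$y, mu, sqrt(sigma2), log = TRUE)) +
    sum(dat$n_lev * log(par$px)) -
    n1 * log(rho) - n0 * log1p(-rho)
  if (!is.finite(ll)) return(list(ll = LOG_FLOOR, note = "non-finite loglik"))
  if (!want_grad) return(list(ll = ll))
  r <- dat$d - p_i
  e <- resid / sigma2
  gdata <- c(
    beta0  = sum(e),
    beta1  = sum(dat$v * e),
    lsigma2 = sum(-0.5 + resid^2 / (2 * sigma2)),
    gamma0 = sum(r),
    gamma1 = sum(dat$v * r),
    gamma2 = sum(dat$y * r)
  )
  gdata_theta <- (dat$n_lev - dat$n * par$px)[-1L]
  if (is.null(fixed_rate)) {
    C <- n1 / rho - n0 / (1 - rho)
    grad_sc <- gdata - C * prev$drho
    grad_th <- gdata_theta - C * prev$drho_theta
  } else {
    # gamma0 profiled: rho is pinned, so the -log P(D) term is constant and
    # gamma0 moves implicitly: dgamma0/dtheta = -drho/dtheta / drho/dgamma0
    dg0 <- gdata[["gamma0"]]
    s <- prev$drho[["gamma0"]]
    grad_sc <- gdata - dg0 * prev$drho / s
    grad_sc[["gamma0"]] <- 0
    grad_th <- gdata_theta - dg0 * prev$drho_theta / s
  }
  list(ll = ll, grad_scalars = grad_sc, grad_theta = grad_th)
}

prep_retro_data <- function(dataset) {
  lev <- dataset$x + 1L
  list(d = dataset$d, y = dataset$y, lev = lev,
       v = dataset$level_values[lev],
       values = dataset$level_values,
       n_lev = tabulate(lev, length(dataset$level_values)),
       n = dataset$n, n1 = sum(dataset$d),
       n0 = dataset$n - sum(dataset$d))
}

#' Retrospective log-likelihood of a case-control dataset
#'
#' Evaluates the case-control (retrospective) log-likelihood of the joint
#' model: logistic disease risk in genotype and trait, normal trait given
#' genotype, free genotype-frequency simplex, each subject's contribution
#' divided by the marginal probability of their disease class.
#'
#' @param params named list with `beta0`, `beta1`, `sigma2`, `gamma0`,
#'   `gamma1`, `gamma2`, and `px` (probability vector over the dataset's
#'   genotype levels)
#' @param dataset a [case_control_dataset()]
#' @param gh_order Gauss-Hermite order for the prevalence integral
#' @return the log-likelihood; a large negative floor (with attribute `note`)
#'   if an observed genotype level has zero probability
#' @export
retrospective_loglik <- function(params, dataset, gh_order = 64L) {
  if (abs(sum(params$px) - 1) > 1e-8 || any(params$px < 0)) {
    stop("px must be a probability vector over the genotype levels",
         call. = FALSE)
  }
  if (params$sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  par <- list(beta0 = params$beta0, beta1 = params$beta1,
              lsigma2 = log(params$sigma2), gamma0 = params$gamma0,
              gamma1 = params$gamma1, gamma2 = params$gamma2,
              px = params$px)
  res <- retro_core(par, prep_retro_data(dataset), gauss_hermite(gh_order))
  out <- res$ll
  if (!is.null(res$note)) attr(out, "note") <- res$note
  out
}

# pack/unpack between the optimizer vector and the parameter list.
# free scalars: retro_scalar_names minus names(fixed) (gamma0 dropped when
# fixed_rate is used); then K-1 softmax logits.
retro_pack <- function(fixed, fixed_rate, K) {
  free <- setdiff(retro_scalar_names, names(fixed))
  if (!is.null(fixed_rate)) free <- setdiff(free, "gamma0")
  list(free = free, n_par = length(free) + K - 1L)
}

retro_unpack <- function(th, map, fixed, K) {
  par <- as.list(fixed)
  par[map$free] <- th[seq_along(map$free)]
  theta <- c(0, th[length(map$free) + seq_len(K - 1L)])
  ex <- exp(theta - max(theta))
  par$px <- ex / sum(ex)
  par
}

retro_objective <- function(th, map, fixed, fixed_rate, dat, gh) {
  K <- length(dat$values)
  par <- retro_unpack(th, map, fixed, K)
  if (!is.null(fixed_rate)) {
    par[["gamma0"]] <- retro_solve_gamma0(par, dat$values, gh, fixed_rate)
    if (is.na(par[["gamma0"]])) return(list(ll = LOG_FLOOR))
  }
  res <- retro_core(par, dat, gh, want_grad = TRUE, fixed_rate = fixed_rate)
  if (res$ll <= LOG_FLOOR) return(list(ll = LOG_FLOOR))
  grad <- c(res$grad_scalars[map$free], res$grad_theta)
  list(ll = res$ll, grad = grad, par = par)
}

# solve P(D=1) = rate for gamma0 at the other current parameter values
retro_solve_gamma0 <- function(par, values, gh, rate) {
  f <- function(g0) {
    p2 <- par; p2[["gamma0"]] <- g0
    retro_prevalence(p2, values, gh)$rho - rate
  }
  lo <- stats::qlogis(rate) - 1; hi <- stats::qlogis(rate) + 1
  for (i in 1:30) { if (f(lo) <= 0) break; lo <- lo - 2 }
  for (i in 1:30) { if (f(hi) >= 0) break; hi <- hi + 2 }
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# deterministic jitter pattern for multi-start (no RNG: reproducible whatever
# the caller's seed state); rows = starts beyond the warm start
START_JITTER <- rbind(
  c( 0.3, -0.2,  0.2,  0.5, -0.4,  0.3),
  c(-0.3,  0.2, -0.2, -0.5,  0.4, -0.3),
  c( 0.6,  0.4, -0.4,  1.0,  0.8, -0.6),
  c(-0.6, -0.4,  0.4, -1.0, -0.8,  0.6)
)

#' Fit the retrospective likelihood by maximum likelihood
#'
#' Maximizes the retrospective log-likelihood over (beta0, beta1, log sigma2,
#' gamma0, gamma1, gamma2) and the softmax-parameterized genotype simplex by
#' BFGS with analytic gradients, from a warm start (OLS of Y on genotype for
#' the trait model, logistic regression of D on genotype and Y for the
#' disease model, empirical genotype frequencies) plus deterministically
#' jittered extra starts. The likelihood surface is known to be nearly flat
#' in the disease-model parameters under the null, so multi-start agreement
#' is checked and a `flat_surface` flag raised when two starts reach the same
#' likelihood (within 1e-4) at clearly different parameters (max abs
#' difference > 1e-2).
#'
#' @param dataset a [case_control_dataset()]
#' @param fixed_rate optional known population disease rate; when given,
#'   `gamma0` is profiled out by solving P(D=1) = `fixed_rate` at each
#'   iterate
#' @param init optional named list of starting values (`beta0`, `beta1`,
#'   `sigma2`, `gamma0`, `gamma1`, `gamma2`, `px`)
#' @param n_starts number of starts including the warm start (default 5)
#' @param gh_order Gauss-Hermite order
#' @param fix_beta1 hold the genotype effect at 0 (the constrained fit of the
#'   likelihood-ratio test)
#' @param fixed named list of further scalar parameters to hold fixed, e.g.
#'   `list(gamma1 = 0, gamma2 = 0)`; names among `beta0`, `beta1`, `sigma2`,
#'   `gamma0`, `gamma1`, `gamma2`. When disease is modeled as independent of
#'   genotype and trait (`gamma1 = gamma2 = 0`), `gamma0` drops out of the
#'   retrospective likelihood entirely, so it should be fixed too to keep the
#'   information matrix nonsingular.
#' @param max_iter BFGS iteration cap per start
#' @param grad_tol stationarity tolerance on the gradient max-norm
#' @return an object of class `retrospective_fit`
#' @export
fit_retrospective <- function(dataset, fixed_rate = NULL, init = NULL,
                              n_starts = 5L, gh_order = 64L,
                              fix_beta1 = FALSE, fixed = list(),
                              max_iter = 500L, grad_tol = 1e-5) {
  if (length(unique(dataset$d)) < 2L) {
    stop("both cases and controls must be present", call. = FALSE)
  }
  dat <- prep_retro_data(dataset)
  K <- length(dat$values)
  gh <- gauss_hermite(gh_order)
  if (fix_beta1) fixed$beta1 <- 0
  bad <- setdiff(names(fixed), c("beta0", "beta1", "sigma2", "gamma0",
                                 "gamma1", "gamma2"))
  if (length(bad)) stop("unknown fixed parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if ("sigma2" %in% names(fixed)) {
    fixed$lsigma2 <- log(fixed$sigma2)
    fixed$sigma2 <- NULL
  }
  map <- retro_pack(fixed, fixed_rate, K)

  # warm start
  if (is.null(init)) {
    ols <- stats::lm(dat$y ~ dat$v)
    glmfit <- suppressWarnings(
      stats::glm(dat$d ~ dat$v + dat$y, family = stats::binomial()))
    init <- list(beta0 = unname(stats::coef(ols)[1]),
                 beta1 = unname(stats::coef(ols)[2]),
                 sigma2 = mean(stats::residuals(ols)^2),
                 gamma0 = unname(stats::coef(glmfit)[1]),
                 gamma1 = unname(stats::coef(glmfit)[2]),
                 gamma2 = unname(stats::coef(glmfit)[3]),
                 px = dat$n_lev / dat$n)
  }
  base_sc <- c(beta0 = init$beta0, beta1 = init$beta1,
               lsigma2 = log(init$sigma2), gamma0 = init$gamma0,
               gamma1 = init$gamma1, gamma2 = init$gamma2)
  base_th <- log(pmax(init$px, 1e-6) / max(init$px[1], 1e-6))[-1L]
  starts <- list(c(base_sc[map$free], base_th))
  jit_sc <- START_JITTER
  for (s in seq_len(min(n_starts, nrow(jit_sc) + 1L) - 1L)) {
    sc <- base_sc + stats::setNames(jit_sc[s, ], retro_scalar_names)
    starts[[s + 1L]] <- c(sc[map$free], base_th)
  }

  negll <- function(th) -retro_objective(th, map, fixed, fixed_rate, dat,
                                         gh)$ll
  neggr <- function(th) {
    res <- retro_objective(th, map, fixed, fixed_rate, dat, gh)
    if (is.null(res$grad)) return(rep(0, length(th)))
    -res$grad
  }
  runs <- lapply(starts, function(th0) {
    opt <- tryCatch(
      stats::optim(th0, negll, neggr, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    res <- retro_objective(opt$par, map, fixed, fixed_rate, dat, gh)
    if (is.null(res$grad)) return(NULL)
    list(th = opt$par, ll = res$ll, gnorm = max(abs(res$grad)),
         par = res$par)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) {
    stop("all optimizer starts failed", call. = FALSE)
  }
  # Newton-polish each run (BFGS's relative-change stop often leaves the
  # gradient just above tolerance on this nearly flat surface)
  grad_at <- function(th) retro_objective(th, map, fixed, fixed_rate, dat,
                                          gh)$grad
  runs <- lapply(runs, function(run) {
    np <- length(run$th)
    for (it in seq_len(8L)) {
      if (run$gnorm < grad_tol / 10) break
      H <- matrix(NA_real_, np, np)
      h <- 1e-5
      for (j in seq_len(np)) {
        tp <- run$th; tp[j] <- tp[j] + h
        tm <- run$th; tm[j] <- tm[j] - h
        H[, j] <- (grad_at(tp) - grad_at(tm)) / (2 * h)
      }
      res <- retro_objective(run$th, map, fixed, fixed_rate, dat, gh)
      step <- tryCatch(solve((H + t(H)) / 2, res$grad),
                       error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      cand <- run$th - step
      cres <- retro_objective(cand, map, fixed, fixed_rate, dat, gh)
      if (is.null(cres$grad) || cres$ll < run$ll - 1e-6) break
      run <- list(th = cand, ll = cres$ll, gnorm = max(abs(cres$grad)),
                  par = cres$par)
    }
    run
  })
  lls <- vapply(runs, `[[`, numeric(1), "ll")
  gnorms <- vapply(runs, `[[`, numeric(1), "gnorm")
  best <- which.max(ifelse(gnorms < grad_tol, lls, lls - 1e6))
  converged <- gnorms[best] < grad_tol
  fit <- runs[[best]]

  flat <- FALSE
  if (length(runs) > 1L) {
    ord <- order(lls, decreasing = TRUE)
    a <- runs[[ord[1]]]; b <- runs[[ord[2]]]
    if (abs(a$ll - b$ll) < 1e-4 && max(abs(a$th - b$th)) > 1e-2) flat <- TRUE
  }

  # observed information on the free parameters by central differences of the
  # analytic gradient
  vcov <- NULL
  vnote <- ""
  if (converged) {
    np <- length(fit$th)
    H <- matrix(NA_real_, np, np)
    h <- 1e-5
    for (j in seq_len(np)) {
      tp <- fit$th; tp[j] <- tp[j] + h
      tm <- fit$th; tm[j] <- tm[j] - h
      gp <- retro_objective(tp, map, fixed, fixed_rate, dat, gh)$grad
      gm <- retro_objective(tm, map, fixed, fixed_rate, dat, gh)$grad
      H[, j] <- (gp - gm) / (2 * h)
    }
    H <- -(H + t(H)) / 2
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(vcov)) {
      vnote <- "singular observed information; vcov unavailable"
    } else {
      nm <- c(map$free, paste0("logit_px", 2:K))
      dimnames(vcov) <- list(nm, nm)
      if (any(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values <
              -1e-8)) {
        vnote <- "observed information not positive definite"
        vcov <- NULL
      }
    }
  }

  par <- fit$par
  structure(list(beta0 = par[["beta0"]], beta1 = par[["beta1"]],
                 sigma2 = exp(par[["lsigma2"]]), gamma0 = par[["gamma0"]],
                 gamma1 = par[["gamma1"]], gamma2 = par[["gamma2"]],
                 px = unname(par$px), level_values = dat$values,
                 loglik = fit$ll, vcov = vcov, converged = converged,
                 flat_surface = flat, gradient_norm = fit$gnorm,
                 constraint = if (is.null(fixed_rate)) "none" else fixed_rate,
                 fix_beta1 = fix_beta1, n_starts = length(runs),
                 notes = vnote),
            class = "retrospective_fit")
}

#' @export
print.retrospective_fit <- function(x, ...) {
  cat("retrospective-likelihood fit",
      if (x$converged) "(converged)" else "(NOT converged)",
      if (x$flat_surface) "[flat surface flagged]" else "", "\n")
  est <- c(beta0 = x$beta0, beta1 = x$beta1, sigma2 = x$sigma2,
           gamma0 = x$gamma0, gamma1 = x$gamma1, gamma2 = x$gamma2)
  print(signif(est, 5))
  cat("  px:", paste(signif(x$px, 4), collapse = ", "),
      " loglik:", format(x$loglik, digits = 9), "\n")
  invisible(x)
}

#' Wald test of the genotype effect from a retrospective fit
#'
#' @param fit a converged [fit_retrospective()] result with `vcov`
#' @return a [test_result()] with statistic beta1^2 / var(beta1), 1 df
#' @export
wald_test_beta1 <- function(fit) {
  if (!fit$converged || is.null(fit$vcov) ||
      !("beta1" %in% rownames(fit$vcov))) {
    return(test_result("linzeng_wald", NA_real_, 1L, NA_real_, 0L,
                       converged = FALSE,
                       notes = "fit not converged or vcov unavailable"))
  }
  v <- fit$vcov["beta1", "beta1"]
  stat <- fit$beta1^2 / v
  test_result("linzeng_wald", stat, 1L,
              stats::pchisq(stat, 1, lower.tail = FALSE),
              n_used = NA_integer_, converged = TRUE)
}

#' Likelihood-ratio test of the genotype effect under the retrospective model
#'
#' Twice the log-likelihood difference between the unconstrained fit and the
#' fit with `beta1 = 0`, chi-squared 1 df. Both fits share the quadrature
#' order and the multi-start protocol.
#'
#' @inheritParams fit_retrospective
#' @return a [test_result()]
#' @export
lrt_beta1 <- function(dataset, fixed_rate = NULL, n_starts = 5L,
                      gh_order = 64L) {
  fit1 <- fit_retrospective(dataset, fixed_rate = fixed_rate,
                            n_starts = n_starts, gh_order = gh_order)
  fit0 <- fit_retrospective(dataset, fixed_rate = fixed_rate,
                            n_starts = n_starts, gh_order = gh_order,
                            fix_beta1 = TRUE)
  if (!fit1$converged || !fit0$converged) {
    return(test_result("linzeng_lrt", NA_real_, 1L, NA_real_, dataset$n,
                       converged = FALSE,
                       notes = "constrained or unconstrained fit failed"))
  }
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  test_result("linzeng_lrt", stat, 1L,
              stats::pchisq(stat, 1, lower.tail = FALSE), dataset$n)
}

#' Retrospective log-likelihood surface over a parameter grid
#'
#' Evaluates the retrospective log-likelihood over the Cartesian grid of two
#' scalar parameters with the remaining parameters fixed at supplied values
#' (default, the design used to visualize surface flatness) or profiled by
#' constrained maximization.
#'
#' @param dataset a [case_control_dataset()]
#' @param param_pair two names among `beta0`, `beta1`, `sigma2`, `gamma0`,
#'   `gamma1`, `gamma2`
#' @param grid list of two numeric grids, named as `param_pair`
#' @param at named list giving the fixed values of all other parameters
#'   (including `px`)
#' @param profile_others maximize over the remaining parameters at each grid
#'   point instead of fixing them
#' @param gh_order Gauss-Hermite order
#' @return object of class `loglik_surface`: list with `grid1`, `grid2`,
#'   `pair`, and matrix `loglik` (rows = first grid)
#' @export
loglik_surface <- function(dataset, param_pair, grid, at,
                           profile_others = FALSE, gh_order = 64L) {
  ok <- c("beta0", "beta1", "sigma2", "gamma0", "gamma1", "gamma2")
  if (length(param_pair) != 2L || !all(param_pair %in% ok)) {
    stop("param_pair must be two of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  g1 <- grid[[param_pair[1]]]
  g2 <- grid[[param_pair[2]]]
  if (is.null(g1) || is.null(g2)) {
    stop("grid must contain entries named as param_pair", call. = FALSE)
  }
  M <- matrix(NA_real_, length(g1), length(g2))
  for (i in seq_along(g1)) {
    for (j in seq_along(g2)) {
      pars <- at
      pars[[param_pair[1]]] <- g1[i]
      pars[[param_pair[2]]] <- g2[j]
      if (profile_others) {
        fixed <- stats::setNames(
          lapply(param_pair, function(p) {
            if (p == "sigma2") log(pars[[p]]) else pars[[p]]
          }),
          ifelse(param_pair == "sigma2", "lsigma2", param_pair))
        fit <- suppressWarnings(
          fit_retrospective_fixed(dataset, fixed, pars, gh_order))
        M[i, j] <- fit
      } else {
        M[i, j] <- retrospective_loglik(pars, dataset, gh_order)
      }
    }
  }
  structure(list(pair = param_pair, grid1 = g1, grid2 = g2, loglik = M),
            class = "loglik_surface")
}

# profile helper: maximize over everything except the named fixed scalars
fit_retrospective_fixed <- function(dataset, fixed, init, gh_order) {
  dat <- prep_retro_data(dataset)
  K <- length(dat$values)
  gh <- gauss_hermite(gh_order)
  map <- retro_pack(fixed, NULL, K)
  base_sc <- c(beta0 = init$beta0, beta1 = init$beta1,
               lsigma2 = log(init$sigma2), gamma0 = init$gamma0,
               gamma1 = init$gamma1, gamma2 = init$gamma2)
  th0 <- c(base_sc[map$free], log(pmax(init$px, 1e-6) / init$px[1])[-1L])
  negll <- function(th) -retro_objective(th, map, fixed, NULL, dat, gh)$ll
  neggr <- function(th) {
    res <- retro_objective(th, map, fixed, NULL, dat, gh)
    if (is.null(res$grad)) return(rep(0, length(th)))
    -res$grad
  }
  opt <- stats::optim(th0, negll, neggr, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12))
  -opt$value
}

#' Write a log-likelihood surface as a long-format TSV
#' @param surface a [loglik_surface()] result
#' @param path output path
#' @export
write_surface_table <- function(surface, path) {
  tab <- expand.grid(p1 = surface$grid1, p2 = surface$grid2)
  names(tab) <- surface$pair
  tab$loglik <- as.vector(surface$loglik)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
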