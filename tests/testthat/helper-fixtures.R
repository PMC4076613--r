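# Shared fixtures and independent oracles for the test suite.

# fixed 12-subject dataset: both disease classes, all three genotype levels
fixture_n12 <- function() {
  case_control_dataset(
    d = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
    y = c(0.5, -1.2, 0.3, 1.8, -0.7, 1.1, 0.4, -0.3, 2.1, -1.5, 0.8, 0.2),
    x = c(0, 1, 2, 1, 0, 2, 1, 0, 0, 2, 1, 1)
  )
}

# independent per-subject cumulative-logit log-likelihood (naive loop, no
# shared code with the package implementation)
naive_clm_loglik <- function(alphas, deltas, x, Z = NULL) {
  total <- 0
  for (i in seq_along(x)) {
    eta <- if (is.null(Z)) 0 else sum(Z[i, ] * deltas)
    up <- if (x[i] == length(alphas)) 1 else plogis(alphas[x[i] + 1] + eta)
    lo <- if (x[i] == 0) 0 else plogis(alphas[x[i]] + eta)
    total <- total + log(up - lo)
  }
  total
}

# iteratively refined dense grid search maximizer: returns max f over box
grid_refine_max <- function(f, lower, upper, npts = 9, iters = 10) {
  best_val <- -Inf
  best_at <- (lower + upper) / 2
  for (it in seq_len(iters)) {
    grids <- Map(function(l, u) seq(l, u, length.out = npts), lower, upper)
    pts <- as.matrix(do.call(expand.grid, grids))
    vals <- apply(pts, 1, f)
    k <- which.max(vals)
    if (vals[k] > best_val) {
      best_val <- vals[k]
      best_at <- pts[k, ]
    }
    span <- (upper - lower) / (npts - 1)
    lower <- best_at - span
    upper <- best_at + span
  }
  list(value = best_val, at = best_at)
}

# grid-search maximum of the cumulative-logit likelihood for 3 categories,
# parameterized as (alpha1, log gap, deltas...) like nothing in the package:
# plain box search over natural parameters with the monotone gap explicit
clm_grid_oracle <- function(x, Z, delta_box = 3) {
  p <- if (is.null(Z)) 0 else ncol(Z)
  f <- function(par) {
    alphas <- c(par[1], par[1] + exp(par[2]))
    naive_clm_loglik(alphas, if (p) par[2 + seq_len(p)] else numeric(0),
                     x, Z)
  }
  grid_refine_max(f, lower = c(-4, -3, rep(-delta_box, p)),
                  upper = c(4, 2, rep(delta_box, p)))
}

paper_params <- function(beta1 = 0, gamma1 = 0, rate = 0.05, seed = NULL,
                         n_cases = 500L, n_controls = 500L) {
  simulation_params(beta0 = 1, beta1 = beta1, sigma2 = 1,
                    gamma1 = gamma1, gamma2 = log(2), maf = 0.3,
                    n_cases = n_cases, n_controls = n_controls,
                    target_rate = rate, seed = seed)
}

vcf_fixture <- function() {
  system.file("extdata", "synthetic_sites.vcf", package = "secophen")
}
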