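#' Cumulative-logit (proportional-odds) log-likelihood
#'
#' For ordinal codes `x` in `0..J` and predictor matrix `Z`, the model is
#' `logit P(X <= j | z) = alpha_j + delta' z` for thresholds `j = 0..J-1`
#' (note the PLUS sign on the covariate term; many standard implementations
#' subtract, so their slopes are the negatives of ours). Category
#' probabilities are differences of adjacent cumulative logistic terms with
#' `alpha_{-1} = -Inf`, `alpha_J = +Inf`.
#'
#' @param alphas strictly increasing thresholds, length `J`
#' @param deltas slope vector, one per column of `Z` (may be empty)
#' @param x integer codes `0..J`
#' @param Z numeric predictor matrix (subjects x p) or `NULL`
#' @return the log-likelihood (a non-positive number)
#' @export
cumulative_logit_loglik <- function(alphas, deltas, x, Z = NULL) {
  if (length(alphas) > 1L && any(diff(alphas) <= 0)) {
    stop("alphas must be strictly increasing", call. = FALSE)
  }
  eta <- if (is.null(Z) || length(deltas) == 0L) {
    rep(0, length(x))
  } else {
    drop(as.matrix(Z) %*% deltas)
  }
  a_full <- c(-Inf, alphas, Inf)
  upper <- a_full[x + 2L] + eta
  lower <- a_full[x + 1L] + eta
  sum(log(expit(upper) - expit(lower)))
}

# loglik and analytic gradient on the unconstrained scale
# theta = (alpha_1, log-gaps g_2..g_K, deltas); alphas = alpha_1 + cumsum gaps
polr_obj <- function(theta, x, Z, K, p) {
  a1 <- theta[1L]
  gaps <- if (K > 1L) exp(theta[2:K]) else numeric(0)
  alphas <- a1 + c(0, cumsum(gaps))
  deltas <- if (p > 0L) theta[K + seq_len(p)] else numeric(0)
  eta <- if (p > 0L) drop(Z %*% deltas) else rep(0, length(x))
  a_full <- c(-Inf, alphas, Inf)
  Fu <- expit(a_full[x + 2L] + eta)
  Fl <- expit(a_full[x + 1L] + eta)
  P <- pmax(Fu - Fl, 1e-300)
  ll <- sum(log(P))
  fu <- Fu * (1 - Fu)          # 0 automatically where Fu = 1 (upper = +Inf)
  fl <- Fl * (1 - Fl)
  gu <- fu / P
  gl <- fl / P
  # d ll / d alpha_k (1-based threshold k separates categories k-1 | k)
  ga <- vapply(seq_len(K), function(k) {
    sum(gu[x == k - 1L]) - sum(gl[x == k])
  }, numeric(1))
  grad <- numeric(K + p)
  grad[1L] <- sum(ga)
  if (K > 1L) {
    tail_sums <- rev(cumsum(rev(ga)))       # sum_{j >= m} ga_j
    grad[2:K] <- gaps * tail_sums[2:K]
  }
  if (p > 0L) grad[K + seq_len(p)] <- drop(crossprod(Z, gu - gl))
  list(ll = ll, grad = grad, alphas = alphas, deltas = deltas)
}

#' Fit a cumulative-logit proportional-odds model by maximum likelihood
#'
#' Maximizes [cumulative_logit_loglik()] by BFGS with analytic gradients on an
#' unconstrained reparameterization (first threshold free, log-gaps between
#' consecutive thresholds), which enforces strictly increasing thresholds by
#' construction. Thresholds are initialized at the pooled empirical cumulative
#' logits, slopes at zero.
#'
#' @param x integer codes `0..J`, every level occupied
#' @param Z predictor matrix (subjects x p) with column names, or `NULL`
#' @param tol convergence tolerance on the gradient max-norm (default 1e-6)
#' @param max_iter iteration cap (default 200); hitting it returns the best
#'   point found with `converged = FALSE`
#' @return an object of class `cumulative_logit_fit` with fields `alphas`,
#'   `deltas`, `loglik`, `n_iter`, `converged`, `gradient_norm`, `notes`
#' @export
fit_cumulative_logit <- function(x, Z = NULL, tol = 1e-6, max_iter = 200L) {
  x <- as.integer(x)
  K <- max(x)                      # number of thresholds = J
  if (K < 1L || !all(0:K %in% x)) {
    stop("need >= 2 occupied, contiguously coded categories", call. = FALSE)
  }
  p <- 0L
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
    p <- ncol(Z)
    if (p > 0L) {
      if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(p))
      qrz <- qr(cbind(`(icpt)` = 1, Z))
      if (qrz$rank < p + 1L) {
        kept <- qrz$pivot[seq_len(qrz$rank)]
        bad <- setdiff(seq_len(p) + 1L, kept) - 1L
        stop("design matrix is rank deficient (collinear column(s): ",
             paste(colnames(Z)[bad], collapse = ", "), ")", call. = FALSE)
      }
    } else {
      Z <- NULL
    }
  }
  # start: pooled empirical cumulative logits, clipped away from 0/1
  cp <- cumsum(tabulate(x + 1L, K + 1L))[seq_len(K)] / length(x)
  cp <- pmin(pmax(cp, 1e-6), 1 - 1e-6)
  a0 <- stats::qlogis(cp)
  theta0 <- c(a0[1L], if (K > 1L) log(pmax(diff(a0), 1e-6)),
              rep(0, p))
  negll <- function(th) -polr_obj(th, x, Z, K, p)$ll
  neggr <- function(th) -polr_obj(th, x, Z, K, p)$grad
  opt <- stats::optim(theta0, negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  res <- polr_obj(opt$par, x, Z, K, p)
  gnorm <- max(abs(res$grad))
  n_iter <- opt$counts[["function"]]
  # Newton polish: BFGS's relative-change stop can leave the gradient a hair
  # above tolerance; a few Newton steps on the analytic gradient finish it.
  theta <- opt$par
  np <- K + p
  for (it in seq_len(10L)) {
    if (gnorm < tol / 10 || !is.finite(gnorm)) break
    H <- matrix(NA_real_, np, np)
    h <- 1e-6
    for (j in seq_len(np)) {
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      H[, j] <- (polr_obj(tp, x, Z, K, p)$grad -
                   polr_obj(tm, x, Z, K, p)$grad) / (2 * h)
    }
    step <- tryCatch(solve((H + t(H)) / 2, res$grad),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- theta - step
    cres <- polr_obj(cand, x, Z, K, p)
    n_iter <- n_iter + 1L
    if (!is.finite(cres$ll) || cres$ll < res$ll - 1e-8) break
    theta <- cand
    res <- cres
    gnorm <- max(abs(res$grad))
  }
  notes <- ""
  converged <- gnorm < tol
  if (p > 0L && any(abs(res$deltas) > 50)) {
    converged <- FALSE
    notes <- "possible complete separation: |delta| exceeded 50"
  } else if (!converged) {
    notes <- sprintf("gradient max-norm %.3g above tolerance %.1g",
                     gnorm, tol)
  }
  if (p > 0L) names(res$deltas) <- colnames(Z)
  structure(list(alphas = res$alphas, deltas = res$deltas,
                 loglik = res$ll, n_iter = as.integer(n_iter),
                 converged = converged, gradient_norm = gnorm,
                 notes = notes),
            class = "cumulative_logit_fit")
}

#' @export
print.cumulative_logit_fit <- function(x, ...) {
  cat("cumulative-logit fit: loglik =", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  alphas:", paste(signif(x$alphas, 6), collapse = ", "), "\n")
  if (length(x$deltas)) {
    cat("  deltas:", paste(signif(x$deltas, 6), collapse = ", "), "\n")
  }
  invisible(x)
}
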