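#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int_{-\infty}^{\infty} f(t) e^{-t^2} dt \approx
#' \sum_k w_k f(t_k)}, computed by the Golub-Welsch eigenvalue method on the
#' Jacobi matrix of the Hermite recurrence. Used throughout the package to
#' integrate logistic-normal prevalence integrals; the integrand (logistic
#' sigmoid times Gaussian) is smooth, so modest orders are extremely accurate.
#'
#' @param order number of nodes (integer >= 2)
#' @return list with `nodes` and `weights`, both length `order`
#' @keywords internal
gauss_hermite <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 2 ||
      order != round(order)) {
    stop("quadrature order must be an integer >= 2", call. = FALSE)
  }
  order <- as.integer(order)
  # symmetric tridiagonal Jacobi matrix: zero diagonal, off-diagonal sqrt(i/2)
  off <- sqrt(seq_len(order - 1L) / 2)
  J <- matrix(0, order, order)
  J[cbind(seq_len(order - 1L), seq_len(order - 1L) + 1L)] <- off
  J[cbind(seq_len(order - 1L) + 1L, seq_len(order - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  nodes <- e$values[idx]
  weights <- sqrt(pi) * e$vectors[1L, idx]^2
  list(nodes = nodes, weights = weights)
}

#' Integrate a function against a normal density by Gauss-Hermite quadrature
#'
#' Computes \eqn{\int f(y) \phi(y; mean, sd^2) dy} via the change of variable
#' \eqn{y = mean + \sqrt{2} sd \cdot t}.
#'
#' @param f vectorized integrand
#' @param mean,sd normal location and scale (may be vectors; broadcast over
#'   nodes)
#' @param gh quadrature rule from [gauss_hermite()]
#' @keywords internal
gh_normal_expect <- function(f, mean, sd, gh) {
  w <- gh$weights / sqrt(pi)
  y <- outer(mean, sqrt(2) * sd * gh$nodes, `+`)  # only valid for scalar sd
  drop(f(y) %*% w)
}

expit <- stats::plogis
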