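#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,trials counts with `0 <= successes <= trials`
#' @param level confidence level (default 0.95)
#' @return numeric vector `c(lower, upper)`, contained in `[0, 1]` and
#'   containing the point estimate
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials, trials >= 1", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Simulation-study grid
#'
#' Defines the factorial type-I-error / power experiment: trait effect
#' `beta1` (0 = null), disease-model genotype effect `gamma1`, population
#' disease rate, replicates per cell, significance threshold, and the methods
#' to compare.
#'
#' @param gamma1_values numeric grid of disease-model genotype log-odds;
#'   default six points from 0 to log(1.5)
#' @param disease_rates population disease rates (default 0.01 and 0.05)
#' @param beta1_values trait-model genotype effects (default 0 and -0.12)
#' @param n_reps replicates per cell (default 1000)
#' @param alpha significance threshold (default 0.01)
#' @param methods subset of `c("proposed", "case_only", "control_only",
#'   "combined", "combined_adj", "linzeng_wald", "linzeng_lrt")`
#' @param base_params [simulation_params()] template supplying `beta0`,
#'   `sigma2`, `gamma2`, `maf` and the sampling quotas
#' @param seed master seed; per-replicate seeds are derived as
#'   `seed + cell_index * 1e6 + replicate`, so cells are disjoint for any
#'   `n_reps < 1e6`
#' @return an object of class `study_grid`
#' @export
study_grid <- function(gamma1_values = log(seq(1, 1.5, by = 0.1)),
                       disease_rates = c(0.01, 0.05),
                       beta1_values = c(0, -0.12),
                       n_reps = 1000L, alpha = 0.01,
                       methods = c("proposed", "case_only", "control_only",
                                   "combined"),
                       base_params = simulation_params(target_rate = 0.05),
                       seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)",
                                     call. = FALSE)
  if (!length(gamma1_values) || !length(disease_rates) ||
      !length(beta1_values)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  known <- c("proposed", "case_only", "control_only", "combined",
             "combined_adj", "linzeng_wald", "linzeng_lrt")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(gamma1_values = gamma1_values,
                 disease_rates = disease_rates,
                 beta1_values = beta1_values,
                 n_reps = as.integer(n_reps), alpha = alpha,
                 methods = methods, base_params = base_params,
                 seed = as.integer(seed)),
            class = "study_grid")
}

replicate_seed <- function(master, cell_index, rep) {
  s <- master + cell_index * 1e6 + rep
  if (s >= 2^31) stop("derived seed exceeds 2^31; use a smaller master seed",
                      call. = FALSE)
  as.integer(s)
}

study_method_runner <- function(method, alpha) {
  switch(method,
    proposed = function(ds) proposed_lrt(ds),
    case_only = function(ds) case_only_test(ds),
    control_only = function(ds) control_only_test(ds),
    combined = function(ds) combined_test(ds, condition_on_d = FALSE),
    combined_adj = function(ds) combined_test(ds, condition_on_d = TRUE),
    linzeng_wald = function(ds) wald_test_beta1(fit_retrospective(ds)),
    linzeng_lrt = function(ds) lrt_beta1(ds)
  )
}

#' Run the simulation study
#'
#' For every cell of the grid: calibrate `gamma0` once to the cell's disease
#' rate, simulate `n_reps` case-control datasets with deterministically
#' derived per-replicate seeds, apply each requested method, and record the
#' rejection rate at `alpha` among converged replicates with a Wilson 95%
#' interval.
#'
#' @param grid a [study_grid()]
#' @param gh_order quadrature order for calibration
#' @param progress print per-cell progress lines to standard error
#' @return an object of class `study_result` with a long-format `table`
#'   (one row per cell x method)
#' @export
run_study <- function(grid, gh_order = 64L, progress = FALSE) {
  cells <- expand.grid(beta1 = grid$beta1_values,
                       gamma1 = grid$gamma1_values,
                       rate = grid$disease_rates,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    bp <- grid$base_params
    params <- simulation_params(beta0 = bp$beta0, beta1 = cell$beta1,
                                sigma2 = bp$sigma2, gamma1 = cell$gamma1,
                                gamma2 = bp$gamma2, maf = bp$maf,
                                n_cases = bp$n_cases,
                                n_controls = bp$n_controls,
                                target_rate = cell$rate)
    g0 <- tryCatch(calibrate_gamma0(params, gh_order = gh_order),
                   error = function(e) NA_real_)
    if (is.na(g0)) {
      for (m in grid$methods) {
        rows[[length(rows) + 1L]] <- data.frame(
          beta1 = cell$beta1, gamma1 = cell$gamma1, rate = cell$rate,
          gamma0 = NA_real_, method = m, n_reps = grid$n_reps,
          n_converged = 0L, rejections = NA_integer_,
          rejection_rate = NA_real_, ci_lower = NA_real_,
          ci_upper = NA_real_, mean_statistic = NA_real_,
          failed = TRUE)
      }
      next
    }
    params$gamma0 <- g0
    params$target_rate <- NULL
    runners <- lapply(grid$methods, study_method_runner, alpha = grid$alpha)
    names(runners) <- grid$methods
    rej <- conv <- stat_sum <- stats::setNames(numeric(length(runners)),
                                               grid$methods)
    for (r in seq_len(grid$n_reps)) {
      params$seed <- replicate_seed(grid$seed, ci, r)
      ds <- simulate_case_control(params)
      for (m in grid$methods) {
        tr <- tryCatch(runners[[m]](ds), error = function(e) NULL)
        if (is.null(tr) || !tr$converged || is.na(tr$p_value)) next
        conv[m] <- conv[m] + 1
        stat_sum[m] <- stat_sum[m] + tr$statistic
        if (tr$p_value < grid$alpha) rej[m] <- rej[m] + 1
      }
    }
    for (m in grid$methods) {
      ci95 <- if (conv[m] > 0) binomial_ci(rej[m], conv[m]) else
        c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        beta1 = cell$beta1, gamma1 = cell$gamma1, rate = cell$rate,
        gamma0 = g0, method = m, n_reps = grid$n_reps,
        n_converged = as.integer(conv[m]),
        rejections = as.integer(rej[m]),
        rejection_rate = if (conv[m] > 0) rej[m] / conv[m] else NA_real_,
        ci_lower = ci95[1], ci_upper = ci95[2],
        mean_statistic = if (conv[m] > 0) stat_sum[m] / conv[m] else
          NA_real_,
        failed = FALSE)
    }
    if (progress) {
      message(sprintf("cell %d/%d done (beta1=%g gamma1=%g rate=%g)",
                      ci, nrow(cells), cell$beta1, cell$gamma1, cell$rate))
    }
  }
  structure(list(table = do.call(rbind, rows), grid = grid),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("simulation study:", nrow(x$table), "cell x method rows,",
      x$grid$n_reps, "replicates per cell, alpha =", x$grid$alpha, "\n")
  print(utils::head(x$table, 12))
  invisible(x)
}

#' Write the power/type-I-error comparison table
#'
#' One row per cell x method, floating-point values at 6 significant digits.
#' Optionally draws rejection-rate-vs-gamma1 line plots (one panel per
#' disease rate) to a PDF.
#'
#' @param result a [run_study()] result
#' @param path output TSV path
#' @param plot_path optional PDF path for the line plots
#' @export
power_comparison_report <- function(result, path, plot_path = NULL) {
  tab <- result$table
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("study result is empty", call. = FALSE)
  }
  out <- tab
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("n_reps", "n_converged", "rejections"))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(plot_path)) {
    grDevices::pdf(plot_path, width = 10, height = 5)
    on.exit(grDevices::dev.off())
    rates <- sort(unique(tab$rate))
    graphics::par(mfrow = c(1, length(rates)))
    for (r in rates) {
      sub <- tab[tab$rate == r & !tab$failed, ]
      methods <- unique(sub$method)
      graphics::plot(range(sub$gamma1), c(0, max(sub$rejection_rate,
                                                 na.rm = TRUE)),
                     type = "n", xlab = expression(gamma[1]),
                     ylab = "rejection rate",
                     main = sprintf("disease rate %g%%", 100 * r))
      for (k in seq_along(methods)) {
        mm <- sub[sub$method == methods[k], ]
        mm <- mm[order(mm$gamma1), ]
        graphics::lines(mm$gamma1, mm$rejection_rate, col = k, lty = k)
        graphics::points(mm$gamma1, mm$rejection_rate, col = k, pch = k)
      }
      graphics::abline(h = result$grid$alpha, lty = 3, col = "grey40")
      graphics::legend("topleft", legend = methods, col = seq_along(methods),
                       lty = seq_along(methods), pch = seq_along(methods),
                       bty = "n", cex = 0.8)
    }
  }
  invisible(out)
}
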