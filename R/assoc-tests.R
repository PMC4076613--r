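# Build the predictor matrix for the cumulative-logit fits: requested
# covariates are looked up by name in the dataset's covariate matrix.
covariate_matrix <- function(dataset, adjust) {
  if (length(adjust) == 0L) return(NULL)
  if (is.null(dataset$covariates)) {
    stop("dataset has no covariates but adjustment was requested",
         call. = FALSE)
  }
  missing_cov <- setdiff(adjust, colnames(dataset$covariates))
  if (length(missing_cov)) {
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  dataset$covariates[, adjust, drop = FALSE]
}

#' Proportional-odds likelihood-ratio test for secondary-phenotype association
#'
#' Tests genotype association with a quantitative secondary phenotype while
#' conditioning on case-control status, avoiding ascertainment bias. Both
#' hypotheses model the ordinal genotype X by cumulative-logit regression:
#' the null has predictors (D, covariates), the alternative adds Y. The
#' statistic is twice the log-likelihood difference, referred to chi-squared
#' with 1 df (only the Y coefficient is tested, whatever the covariate
#' count). Because only conditional models of X given (Y, D) are fitted, no
#' flat retrospective likelihood needs to be maximized, which is what makes
#' this test cheap enough for genome-wide scans.
#'
#' @param dataset a [case_control_dataset()]
#' @param adjust character vector of covariate names to include in BOTH
#'   models (confounder adjustment)
#' @return a [test_result()]; `p_value` is `NA` if either fit fails
#' @export
proposed_lrt <- function(dataset, adjust = character(0)) {
  d <- dataset$d
  if (length(unique(d)) < 2L) {
    stop("both cases and controls must be present", call. = FALSE)
  }
  cov <- covariate_matrix(dataset, adjust)
  Z0 <- cbind(d = d, cov)
  Z1 <- cbind(y = dataset$y, d = d, cov)
  fit0 <- fit_cumulative_logit(dataset$x, Z0)
  fit1 <- fit_cumulative_logit(dataset$x, Z1)
  notes <- ""
  if (!fit0$converged || !fit1$converged) {
    notes <- trimws(paste(fit0$notes, fit1$notes))
    return(test_result("proposed_lrt", NA_real_, 1L, NA_real_, dataset$n,
                       converged = FALSE, notes = notes))
  }
  stat <- 2 * (fit1$loglik - fit0$loglik)
  if (stat < 0) {
    notes <- sprintf("negative LRT %.3g clamped to 0 (optimizer tolerance)",
                     stat)
    stat <- 0
  }
  test_result("proposed_lrt", stat, 1L,
              stats::pchisq(stat, df = 1, lower.tail = FALSE),
              dataset$n, converged = TRUE, notes = notes)
}

# Shared OLS machinery for the three standard comparators: regress Y on the
# genotype value (additive coding via level_values) plus covariates, report
# the squared t of the genotype slope with its t reference.
ols_y_on_x <- function(dataset, rows, adjust, method,
                       include_d = FALSE) {
  v <- dataset$level_values[dataset$x + 1L][rows]
  y <- dataset$y[rows]
  if (length(unique(v)) < 2L) {
    stop("genotype is constant in the analyzed stratum", call. = FALSE)
  }
  df_frame <- data.frame(y = y, x = v)
  if (include_d) df_frame$d <- dataset$d[rows]
  cov <- covariate_matrix(dataset, adjust)
  if (!is.null(cov)) df_frame <- cbind(df_frame, cov[rows, , drop = FALSE])
  fit <- stats::lm(y ~ ., data = df_frame)
  sm <- summary(fit)$coefficients
  tval <- sm["x", "t value"]
  rdf <- fit$df.residual
  notes <- ""
  rss <- sum(stats::residuals(fit)^2)
  if (!is.finite(tval) || rss <= 1e-24 * max(sum(y^2), 1)) {
    # residuals numerically zero: the t statistic diverges
    stat <- .Machine$double.xmax
    p <- 0
    notes <- "perfect fit; p below machine floor"
  } else {
    stat <- tval^2
    p <- 2 * stats::pt(abs(tval), df = rdf, lower.tail = FALSE)
  }
  test_result(method, stat, 1L, p, length(rows), converged = TRUE,
              notes = notes)
}

#' Standard case-only regression test
#'
#' Ordinary least squares of Y on the additive genotype value (plus
#' covariates) among cases only; squared t of the genotype slope with its
#' residual-df t reference. Biased under ascertainment when the trait affects
#' disease risk; included as the standard comparator.
#'
#' @inheritParams proposed_lrt
#' @export
case_only_test <- function(dataset, adjust = character(0)) {
  ols_y_on_x(dataset, which(dataset$d == 1L), adjust, "case_only")
}

#' Standard control-only regression test
#' @inheritParams proposed_lrt
#' @export
control_only_test <- function(dataset, adjust = character(0)) {
  ols_y_on_x(dataset, which(dataset$d == 0L), adjust, "control_only")
}

#' Standard combined case-and-control regression test
#'
#' OLS of Y on the additive genotype value over all subjects. With
#' `condition_on_d = TRUE`, disease status enters as a covariate; the default
#' (`FALSE`) is the naive pooled analysis whose type-I inflation under
#' ascertainment motivates the proportional-odds test.
#'
#' @inheritParams proposed_lrt
#' @param condition_on_d add D as a covariate?
#' @export
combined_test <- function(dataset, adjust = character(0),
                          condition_on_d = FALSE) {
  if (length(unique(dataset$d)) < 2L) {
    stop("both cases and controls must be present", call. = FALSE)
  }
  ols_y_on_x(dataset, seq_len(dataset$n), adjust,
             if (condition_on_d) "combined_adj" else "combined",
             include_d = condition_on_d)
}

#' Run association tests for every SNP in a genotype matrix
#'
#' Batch driver for the two-step workflow's first step: applies the requested
#' methods to each SNP column, with per-SNP complete-case handling via
#' [attach_genotypes()].
#'
#' @param pheno a `cc_phenotypes` object from [read_phenotype_table()]
#' @param geno numeric matrix, subjects x SNPs, with SNP column names
#' @param methods subset of `c("proposed", "case_only", "control_only",
#'   "combined", "combined_adj")`
#' @param adjust covariate names passed to every test
#' @param mode genotype coding mode for [attach_genotypes()]
#' @return named list (per SNP) of lists of [test_result()]s, suitable for
#'   [write_results_table()]
#' @export
test_all_snps <- function(pheno, geno, methods = "proposed",
                          adjust = character(0), mode = "counts") {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("snp", seq_len(ncol(geno)))
  }
  runners <- list(
    proposed = function(ds) proposed_lrt(ds, adjust),
    case_only = function(ds) case_only_test(ds, adjust),
    control_only = function(ds) control_only_test(ds, adjust),
    combined = function(ds) combined_test(ds, adjust, FALSE),
    combined_adj = function(ds) combined_test(ds, adjust, TRUE)
  )
  unknown <- setdiff(methods, names(runners))
  if (length(unknown)) stop("unknown method(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  out <- lapply(seq_len(ncol(geno)), function(j) {
    ds <- tryCatch(attach_genotypes(pheno, geno[, j], mode = mode),
                   error = function(e) e)
    lapply(methods, function(m) {
      if (inherits(ds, "error")) {
        return(test_result(m, NA_real_, 1L, NA_real_, 0L, FALSE,
                           notes = conditionMessage(ds)))
      }
      tryCatch(runners[[m]](ds),
               error = function(e) test_result(m, NA_real_, 1L, NA_real_,
                                               ds$n, FALSE,
                                               notes = conditionMessage(e)))
    })
  })
  names(out) <- colnames(geno)
  out
}
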