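#' Case-control dataset with a quantitative secondary phenotype
#'
#' The central data container: per-subject disease status `d` (1 = case,
#' 0 = control), quantitative secondary phenotype `y`, ordinal genotype code
#' `x` (integers `0..J`), and an optional covariate matrix. `level_values`
#' records the raw genotype values that the codes `0..J` stand for (allele
#' counts `0,1,2`, or dosage grid points); model terms that treat the genotype
#' additively use these values, not the codes, so that e.g. a sample with no
#' heterozygotes still contrasts 0 vs 2 copies correctly.
#'
#' @param d binary disease indicator (each entry 0 or 1)
#' @param y numeric secondary phenotype
#' @param x integer ordinal genotype codes in `0..J`, all levels occupied
#' @param level_values strictly increasing raw values, one per level
#' @param covariates optional numeric matrix (subjects x p) with column names
#' @return an object of class `case_control_dataset`
#' @export
case_control_dataset <- function(d, y, x, level_values = sort(unique(x)),
                                 covariates = NULL) {
  n <- length(d)
  if (length(y) != n || length(x) != n) {
    stop("d, y, x must have equal length", call. = FALSE)
  }
  if (anyNA(d) || anyNA(y) || anyNA(x)) {
    stop("missing values are not allowed after construction", call. = FALSE)
  }
  if (!all(d %in% c(0, 1))) {
    stop("d must contain only 0/1", call. = FALSE)
  }
  if (any(x != round(x)) || any(x < 0)) {
    stop("x must be non-negative integer codes", call. = FALSE)
  }
  x <- as.integer(x)
  J <- max(x)
  if (J < 1L) stop("genotype is monomorphic: fewer than 2 occupied levels",
                   call. = FALSE)
  if (!all(0:J %in% x)) {
    stop("genotype codes must occupy every level 0..J contiguously",
         call. = FALSE)
  }
  if (length(level_values) != J + 1L || any(diff(level_values) <= 0)) {
    stop("level_values must be strictly increasing with one entry per level",
         call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have n rows",
                                    call. = FALSE)
    if (anyNA(covariates)) stop("covariates must be complete", call. = FALSE)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
    }
  }
  structure(
    list(d = as.integer(d), y = as.numeric(y), x = x,
         level_values = as.numeric(level_values), covariates = covariates,
         n = n),
    class = "case_control_dataset"
  )
}

#' @export
print.case_control_dataset <- function(x, ...) {
  cat(sprintf(
    "case_control_dataset: %d subjects (%d cases, %d controls), %d genotype levels\n",
    x$n, sum(x$d), x$n - sum(x$d), length(x$level_values)))
  cat("  level values:", paste(signif(x$level_values, 4), collapse = ", "),
      "\n")
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a delimited phenotype table
#'
#' Parses a delimited text file with a header row into the phenotype part of a
#' case-control dataset (disease status, secondary phenotype, optional
#' covariates). Rows with a missing value in any mapped column are dropped
#' (complete-case) and counted.
#'
#' @param path file path
#' @param column_map list with elements `d`, `y` (column names) and optionally
#'   `covariates` (character vector of column names)
#' @param delimiter field separator, default tab
#' @return a `cc_phenotypes` list with `d`, `y`, `covariates`, `n`,
#'   `n_dropped`, ready for [attach_genotypes()]
#' @export
read_phenotype_table <- function(path, column_map = list(d = "d", y = "y"),
                                 delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  need <- c(column_map$d, column_map$y, column_map$covariates)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d_raw <- tab[[column_map$d]]
  bad <- which(!is.na(d_raw) & !(d_raw %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("non-binary disease status value '%s' at data row %d",
                 d_raw[bad[1]], bad[1]), call. = FALSE)
  }
  sub <- tab[, need, drop = FALSE]
  keep <- stats::complete.cases(sub)
  n_dropped <- sum(!keep)
  sub <- sub[keep, , drop = FALSE]
  covariates <- NULL
  if (length(column_map$covariates)) {
    covariates <- as.matrix(sub[, column_map$covariates, drop = FALSE])
    storage.mode(covariates) <- "double"
    rownames(covariates) <- NULL
  }
  structure(
    list(d = as.integer(sub[[column_map$d]]),
         y = as.numeric(sub[[column_map$y]]),
         covariates = covariates,
         n = nrow(sub), n_dropped = n_dropped),
    class = "cc_phenotypes"
  )
}

#' Attach a genotype vector to phenotype data
#'
#' Converts raw genotype values into contiguous ordinal codes and builds the
#' full [case_control_dataset()]. In `"counts"` mode values must be allele
#' counts 0/1/2. In `"dosage"` mode distinct observed values become ordered
#' levels; if there are more than `max_levels` distinct values they are first
#' quantized to `max_levels` equally spaced grid points on the observed range
#' (nearest point, ties resolved to the lower level). Levels with no subjects
#' are removed and codes re-indexed; subjects with missing genotype are
#' dropped (complete-case per SNP) and counted.
#'
#' @param pheno a `cc_phenotypes` object or an existing `case_control_dataset`
#'   (from which `d`, `y`, covariates are taken)
#' @param genotypes numeric vector of raw values, one per subject; may contain
#'   `NA`
#' @param mode `"counts"` or `"dosage"`
#' @param max_levels cap on dosage levels before quantization (default 21,
#'   i.e. a 0.1 grid on dosages spanning 0..2)
#' @return a `case_control_dataset`; attribute `n_dropped_genotype` records
#'   subjects dropped for missing genotype
#' @export
attach_genotypes <- function(pheno, genotypes, mode = c("counts", "dosage"),
                             max_levels = 21L) {
  mode <- match.arg(mode)
  if (length(genotypes) != pheno$n) {
    stop("genotype vector length must match subject count", call. = FALSE)
  }
  keep <- !is.na(genotypes)
  n_dropped <- sum(!keep)
  g <- as.numeric(genotypes[keep])
  if (mode == "counts") {
    if (!all(g %in% c(0, 1, 2))) {
      stop("counts mode requires genotype values in {0,1,2}", call. = FALSE)
    }
  } else if (length(unique(g)) > max_levels) {
    lo <- min(g); hi <- max(g)
    step <- (hi - lo) / (max_levels - 1L)
    idx <- ceiling((g - lo) / step - 0.5)   # nearest grid point, ties lower
    idx <- pmin(pmax(idx, 0L), max_levels - 1L)
    g <- lo + step * idx
  }
  values <- sort(unique(g))
  if (length(values) < 2L) {
    stop("degenerate genotype: fewer than 2 occupied levels (monomorphic)",
         call. = FALSE)
  }
  codes <- match(g, values) - 1L
  cov <- pheno$covariates
  if (!is.null(cov)) cov <- cov[keep, , drop = FALSE]
  out <- case_control_dataset(d = pheno$d[keep], y = pheno$y[keep], x = codes,
                              level_values = values, covariates = cov)
  attr(out, "n_dropped_genotype") <- n_dropped
  out
}

#' Extract genotypes for one site from a VCF file
#'
#' Reads a VCF 4.x file (via the VariantAnnotation package) and returns, for a
#' single selected site, either alternate-allele counts (GT field; phased and
#' unphased separators both accepted; any missing allele makes the genotype
#' missing) or imputed dosages (DS field), ordered by `sample_order`.
#'
#' @param path VCF file path (plain or bgzipped)
#' @param site_selector list with either `id` (variant ID) or `chrom` and
#'   `pos`
#' @param field `"GT"` or `"DS"`
#' @param sample_order character vector of sample IDs defining output order
#' @return numeric vector, one value per sample, `NA` where missing
#' @export
read_vcf_genotypes <- function(path, site_selector, field = c("GT", "DS"),
                               sample_order) {
  field <- match.arg(field)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("the VariantAnnotation package is required for VCF input",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (!is.null(site_selector$id)) {
    hit <- which(names(rr) == site_selector$id)
    what <- paste0("ID ", site_selector$id)
  } else {
    hit <- which(as.character(GenomicRanges::seqnames(rr)) ==
                   as.character(site_selector$chrom) &
                 GenomicRanges::start(rr) == site_selector$pos)
    what <- paste0(site_selector$chrom, ":", site_selector$pos)
  }
  if (length(hit) == 0L) stop("site not found in VCF: ", what, call. = FALSE)
  hit <- hit[1L]
  samples <- colnames(vcf)
  absent <- setdiff(sample_order, samples)
  if (length(absent)) {
    stop("sample(s) missing from VCF header: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (field == "GT") {
    if (length(rr$ALT[[hit]]) > 1L) {
      stop("multiallelic site unsupported in GT mode: ", what, call. = FALSE)
    }
    gt <- VariantAnnotation::geno(vcf)$GT[hit, sample_order]
    alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
    out <- vapply(alleles, function(a) {
      if (any(a == ".") || length(a) == 0L) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  } else {
    ds <- VariantAnnotation::geno(vcf)$DS
    if (is.null(ds)) stop("VCF has no DS FORMAT field", call. = FALSE)
    out <- as.numeric(ds[hit, sample_order])
  }
  unname(out)
}

#' One association test result
#'
#' @param method label string
#' @param statistic test statistic (finite when converged)
#' @param df degrees of freedom
#' @param p_value p-value in `[0, 1]`, or `NA` when unavailable
#' @param n_used subjects entering the test
#' @param converged logical convergence flag
#' @param notes free-text diagnostics
#' @return an object of class `secophen_test`
#' @export
test_result <- function(method, statistic, df, p_value, n_used,
                        converged = TRUE, notes = "") {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value must lie in [0,1]", call. = FALSE)
  }
  if (isTRUE(converged) && !is.finite(statistic)) {
    stop("statistic must be finite when converged", call. = FALSE)
  }
  structure(list(method = method, statistic = statistic, df = as.integer(df),
                 p_value = p_value, n_used = as.integer(n_used),
                 converged = isTRUE(converged), notes = notes),
            class = "secophen_test")
}

#' @export
print.secophen_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g on %d df, p = %.4g (n = %d%s)\n",
              x$method, x$statistic, x$df, x$p_value, x$n_used,
              if (x$converged) "" else ", NOT converged"))
  if (nzchar(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

results_to_table <- function(results) {
  rows <- lapply(seq_along(results), function(i) {
    entry <- results[[i]]
    snp <- names(results)[i]
    if (inherits(entry, "secophen_test")) entry <- list(entry)
    do.call(rbind, lapply(entry, function(r) {
      data.frame(snp_id = snp, method = r$method,
                 statistic = signif(r$statistic, 6), df = r$df,
                 p_value = signif(r$p_value, 6), n_used = r$n_used,
                 converged = r$converged, notes = r$notes,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Write association results to a tab-delimited file
#'
#' @param results a named list (names = SNP identifiers) whose elements are
#'   [test_result()] objects or lists of them, or an already-built data frame
#'   with the standard columns
#' @param path output path
#' @return the written data frame, invisibly
#' @export
write_results_table <- function(results, path) {
  if (is.data.frame(results)) {
    tab <- results
  } else {
    if (length(results) == 0L) stop("results must be non-empty",
                                    call. = FALSE)
    tab <- results_to_table(results)
  }
  if (nrow(tab) == 0L) stop("results must be non-empty", call. = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read back a results table written by [write_results_table()]
#' @param path file path
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
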