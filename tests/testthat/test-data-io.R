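write_tsv_tmp <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("read_phenotype_table parses, drops incomplete rows, validates d", {
  path <- write_tsv_tmp(data.frame(d = c(1, 1, 0, 0),
                                   y = c(0.2, -1.1, 0.4, 0.9)))
  ph <- read_phenotype_table(path)
  expect_equal(ph$n, 4L)
  expect_equal(sum(ph$d), 2L)
  expect_equal(ph$y, c(0.2, -1.1, 0.4, 0.9))
  expect_equal(ph$n_dropped, 0L)

  path2 <- write_tsv_tmp(data.frame(d = c(1, 1, 0, 0),
                                    y = c(0.2, NA, 0.4, 0.9)))
  ph2 <- read_phenotype_table(path2)
  expect_equal(ph2$n, 3L)
  expect_equal(ph2$n_dropped, 1L)

  path3 <- write_tsv_tmp(data.frame(d = c(1, 2, 0), y = c(0.1, 0.2, 0.3)))
  expect_error(read_phenotype_table(path3), "row 2")

  path4 <- write_tsv_tmp(data.frame(status = c(1, 0), y = c(0.1, 0.2)))
  expect_error(read_phenotype_table(path4), "not present.*d")

  # named column map and covariates
  path5 <- write_tsv_tmp(data.frame(dis = c(1, 0, 0), trait = c(1, 2, 3),
                                    age = c(40, 50, 60)))
  ph5 <- read_phenotype_table(path5, column_map = list(
    d = "dis", y = "trait", covariates = "age"))
  expect_equal(colnames(ph5$covariates), "age")
  expect_equal(ph5$covariates[, "age"], c(40, 50, 60))
})

test_that("attach_genotypes codes counts and dosages, handles degeneracy", {
  ph <- list(d = c(1L, 1L, 0L, 0L, 0L), y = rnorm(5), covariates = NULL,
             n = 5L)
  ds <- attach_genotypes(ph, c(0, 1, 2, 1, 0), mode = "counts")
  expect_equal(ds$x, c(0L, 1L, 2L, 1L, 0L))
  expect_equal(ds$level_values, c(0, 1, 2))

  # idempotent on already-coded count data
  ds2 <- attach_genotypes(list(d = ds$d, y = ds$y, covariates = NULL,
                               n = ds$n),
                          ds$level_values[ds$x + 1], mode = "counts")
  expect_equal(ds2$x, ds$x)
  expect_equal(ds2$level_values, ds$level_values)

  # dosage distinct-value rule
  ph4 <- list(d = c(1L, 0L, 1L, 0L), y = rnorm(4), covariates = NULL, n = 4L)
  ds3 <- attach_genotypes(ph4, c(0.0, 0.0, 1.0, 2.0), mode = "dosage")
  expect_equal(max(ds3$x), 2L)
  expect_equal(ds3$level_values, c(0, 1, 2))

  expect_error(attach_genotypes(ph4, c(1, 1, 1, 1), mode = "counts"),
               "monomorphic")

  # counts mode rejects out-of-range values
  expect_error(attach_genotypes(ph4, c(0, 1, 2, 1.5), mode = "counts"),
               "0,1,2")

  # missing genotypes dropped and counted
  ds4 <- attach_genotypes(ph4, c(0, NA, 1, 2), mode = "counts")
  expect_equal(ds4$n, 3L)
  expect_equal(attr(ds4, "n_dropped_genotype"), 1L)
})

test_that("dosage quantization maps to nearest grid point, ties to lower", {
  n <- 60L
  ph <- list(d = rep(c(1L, 0L), n / 2), y = rnorm(n), covariates = NULL,
             n = n)
  doses <- seq(0, 2, length.out = n)   # 60 distinct values
  ds <- attach_genotypes(ph, doses, mode = "dosage", max_levels = 5L)
  expect_lte(length(ds$level_values), 5L)
  expect_true(all(ds$level_values %in% seq(0, 2, by = 0.5)))
  # an exact midpoint goes to the lower level
  ph2 <- list(d = c(1L, 0L, 1L, 0L), y = rnorm(4), covariates = NULL, n = 4L)
  ds2 <- attach_genotypes(ph2, c(0, 0.5, 1, 2), mode = "dosage",
                          max_levels = 3L)  # grid 0,1,2; 0.5 ties lower -> 0
  expect_equal(ds2$level_values[ds2$x + 1], c(0, 0, 1, 2))
})

test_that("VCF extraction honors GT/DS conventions and errors", {
  skip_if_not_installed("VariantAnnotation")
  path <- vcf_fixture()
  gt <- read_vcf_genotypes(path, list(id = "rs1"), "GT",
                           sample_order = c("S1", "S2", "S3", "S4"))
  expect_equal(gt, c(1, 2, 0, NA))
  # order follows sample_order
  gt_r <- read_vcf_genotypes(path, list(id = "rs1"), "GT",
                             sample_order = c("S3", "S1"))
  expect_equal(gt_r, c(0, 1))
  ds <- read_vcf_genotypes(path, list(chrom = "1", pos = 200), "DS",
                           sample_order = c("S1", "S2", "S3", "S4"))
  expect_equal(ds, c(0.0, 0.9, 2.0, 1.46))
  expect_error(read_vcf_genotypes(path, list(id = "rs999"), "GT",
                                  c("S1")), "not found")
  expect_error(read_vcf_genotypes(path, list(id = "rs1"), "GT",
                                  c("S1", "S9")), "S9")
  expect_error(read_vcf_genotypes(path, list(id = "rs3"), "GT",
                                  c("S1")), "multiallelic")
})

test_that("results tables round-trip at 6 significant digits", {
  res <- list(
    snpA = test_result("proposed_lrt", 5.4321987, 1L, 0.019876543, 1000L),
    snpB = list(test_result("proposed_lrt", 0.1234567, 1L, 0.72543219, 900L),
                test_result("case_only", 2.3456789, 1L, 0.12654321, 450L))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(res, path)
  lines <- readLines(path)
  expect_length(lines, 4L)   # header + 3 rows
  back <- read_results_table(path)
  expect_equal(back$statistic,
               signif(c(5.4321987, 0.1234567, 2.3456789), 6))
  expect_equal(back$p_value,
               signif(c(0.019876543, 0.72543219, 0.12654321), 6))
  expect_error(write_results_table(list(), withr::local_tempfile()),
               "non-empty")
})

test_that("subject order does not affect downstream statistics", {
  ds <- simulate_case_control(paper_params(beta1 = -0.12, gamma1 = log(1.2),
                                           seed = 42,
                                           n_cases = 150L,
                                           n_controls = 150L))
  perm <- sample(ds$n)
  ds_shuffled <- case_control_dataset(ds$d[perm], ds$y[perm], ds$x[perm],
                                      ds$level_values)
  t1 <- proposed_lrt(ds)
  t2 <- proposed_lrt(ds_shuffled)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-8)
  expect_equal(combined_test(ds)$statistic,
               combined_test(ds_shuffled)$statistic, tolerance = 1e-10)
})
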