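test_that("allele-list filtering drops off-list and mismatched loci", {
  geno <- matrix(sample(0:2, 12, TRUE), 4, 3,
                 dimnames = list(paste0("S", 1:4), c("L1", "L2", "L3")))
  obs <- data.frame(locus_id = c("L1", "L2", "L3"), ref = "A",
                    alt = c("T", "G", "T"))
  listed <- data.frame(locus_id = c("L1", "L2", "L3"), ref = "A", alt = "T")
  res <- filter_allowed_alleles(geno, obs, listed)
  expect_identical(colnames(res$genotypes), c("L1", "L3"))
  expect_identical(res$report$removed$alt_mismatch, 1L)

  # all matching: unchanged, zero removals
  ok <- filter_allowed_alleles(geno, listed, listed)
  expect_identical(ok$genotypes, geno)
  expect_identical(ok$report$removed$off_list, 0L)
  expect_identical(ok$report$removed$alt_mismatch, 0L)

  expect_error(filter_allowed_alleles(geno, obs,
                                      data.frame(locus_id = "LX", ref = "A",
                                                 alt = "T")),
               "no loci survive")
})

test_that("a VCF fixture with off-list alternative alleles is screened", {
  geno <- matrix(rep(0:2, length.out = 20), 4, 5,
                 dimnames = list(paste0("S", 1:4), paste0("L", 1:5)))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(geno, path, ref = "A",
                      alt = c("T", "G", "T", "C", "T"))
  vcf <- read_genotypes_vcf(path)
  expect_equal(vcf$genotypes, geno)
  snp_list <- data.frame(locus_id = paste0("L", 1:5), ref = "A", alt = "T")
  res <- filter_allowed_alleles(vcf$genotypes, vcf$alleles, snp_list)
  expect_identical(res$report$removed$alt_mismatch, 2L)
  expect_identical(ncol(res$genotypes), 3L)
})

test_that("two-stage missingness filter matches the worked example", {
  res <- missingness_filter(missingness_fixture())
  # sample C (75% missing) is excluded from the locus denominators; locus 3
  # is then 50% missing among A and B and is dropped; C keeps 2/3 < 90%
  expect_identical(dim(res$genotypes), c(3L, 3L))
  expect_identical(colnames(res$genotypes), c("L1", "L2", "L4"))
  expect_identical(rownames(res$genotypes), c("A", "B", "C"))
  expect_identical(res$report$removed$high_missing_loci, 1L)
  expect_identical(res$report$removed$high_missing_samples, 0L)
})

test_that("missingness thresholds are strict: exactly 25% is retained", {
  geno <- rbind(A = c(0, NA), B = c(1, 1), C = c(2, 0), D = c(1, 2))
  colnames(geno) <- c("L1", "L2")
  res <- missingness_filter(geno)  # L1 exactly 25% missing
  expect_identical(ncol(res$genotypes), 2L)
})

test_that("missingness filter is idempotent and clean input passes through", {
  pop <- make_population(n = 50, m = 40, seed = 51)
  clean <- missingness_filter(pop$geno)
  expect_identical(clean$genotypes, pop$geno)

  masked <- inject_missingness(pop$geno, 0.3, seed = 52)
  once <- missingness_filter(masked)$genotypes
  twice <- missingness_filter(once)$genotypes
  expect_identical(twice, once)

  allmiss <- matrix(NA_real_, 3, 3)
  expect_error(missingness_filter(allmiss), "informative")
})

test_that("MAF filter uses min(p, 1-p) over non-missing entries", {
  geno <- cbind(mono = c(0, 0, 0), rare = c(0, 0, 1), common = c(1, 2, 1))
  rownames(geno) <- paste0("S", 1:3)
  res <- maf_filter(geno, min_maf = 0.05)
  # rare: p = 1/6 ~ 0.167, retained; monomorphic removed
  expect_identical(colnames(res$genotypes), c("rare", "common"))
  expect_identical(res$report$removed$low_maf, 1L)
  # high-frequency alt allele folds to the minor side: p = 7/8, MAF = 0.125
  hi <- cbind(alt_heavy = c(2, 2, 2, 1))
  expect_identical(ncol(maf_filter(hi, 0.1)$genotypes), 1L)
  expect_identical(ncol(maf_filter(hi, 0.2)$genotypes), 0L)
  # threshold zero removes nothing
  expect_identical(ncol(maf_filter(geno, 0)$genotypes), 3L)
})

test_that("QC report counts reconcile at every stage", {
  pop <- make_population(n = 60, m = 50, seed = 53)
  masked <- inject_missingness(pop$geno, 0.3, seed = 54)
  res <- missingness_filter(masked)
  expect_identical(res$report$n_loci_out,
                   res$report$n_loci_in - res$report$removed$high_missing_loci)
  expect_identical(res$report$n_samples_out,
                   res$report$n_samples_in -
                     res$report$removed$high_missing_samples)
  res2 <- maf_filter(res$genotypes)
  expect_identical(res2$report$n_loci_out,
                   res2$report$n_loci_in - res2$report$removed$low_maf)
})

test_that("LD-kNN imputation leaves complete matrices and observed calls alone", {
  pop <- make_population(n = 40, m = 30, seed = 55)
  expect_identical(unclass(ld_knn_impute(pop$geno))[seq_along(pop$geno)],
                   unclass(pop$geno)[seq_along(pop$geno)])
  masked <- inject_missingness(pop$geno, 0.15, seed = 56)
  imputed <- ld_knn_impute(masked)
  expect_false(anyNA(imputed))
  obs <- !is.na(masked)
  expect_equal(as.numeric(imputed[obs]), as.numeric(masked[obs]))
  expect_true(all(imputed %in% 0:2))
})

test_that("a perfectly duplicated locus drives imputation exactly", {
  pop <- make_population(n = 20, m = 10, seed = 57)
  geno <- cbind(pop$geno, dup = pop$geno[, 1])
  colnames(geno) <- c(colnames(pop$geno), "dup")
  geno[3, 1] <- NA
  # with a single LD-informative locus the duplicate dominates the distance
  imputed <- ld_knn_impute(geno, n_ld_snps = 1, n_neighbors = 5)
  expect_equal(unname(imputed[3, 1]), as.numeric(geno[3, "dup"]))
})

test_that("loci with too few observed calls fall back to the mean dosage", {
  pop <- make_population(n = 20, m = 8, seed = 59)
  geno <- pop$geno
  geno[1:17, 3] <- NA  # 3 observed < 5 neighbours
  imputed <- ld_knn_impute(geno)
  expect_false(anyNA(imputed))
  fb <- floor(mean(geno[18:20, 3]) + 0.5)
  expect_true(all(imputed[1:17, 3] == fb))
  expect_match(attr(imputed, "report")$notes, colnames(geno)[3])
})

test_that("LD-kNN beats per-locus mean imputation on LD-structured data", {
  cfg <- sim_config(n_individuals = 300, n_loci = 200, n_qtl = 10,
                    ld_block_size = 20, seed = 61)
  geno <- simulate_genotypes(cfg)
  acc_ld <- imputation_accuracy(geno, 0.2, seed = 62, imputer = ld_knn_impute)
  acc_mean <- imputation_accuracy(geno, 0.2, seed = 62, imputer = mean_impute)
  expect_gt(acc_ld, acc_mean)
  expect_gt(acc_ld, 0.8)
})

test_that("imputation accuracy scores masked entries correctly", {
  pop <- make_population(n = 30, m = 20, seed = 63)
  oracle <- function(g, ...) pop$geno  # returns the original, unmasked matrix
  expect_equal(imputation_accuracy(pop$geno, 0.3, seed = 64,
                                   imputer = oracle), 1.0)
  all2 <- matrix(2, 20, 10, dimnames = list(NULL, paste0("L", 1:10)))
  zero_imputer <- function(g, ...) { g[is.na(g)] <- 0; g }
  expect_equal(imputation_accuracy(all2, 0.3, seed = 65,
                                   imputer = zero_imputer), 0.0)
  expect_error(imputation_accuracy(pop$geno, 0), "positive")
})
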