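#' @title Genotype quality-control cascade
#' @description Filters mirroring the standard QC applied to
#'   sequencing-derived SNP matrices in forage-grass genomic selection:
#'   allele-list screening, the two-stage missingness filter, minor-allele
#'   -frequency filtering, and LD-kNN imputation of the survivors. The
#'   cascade is order-dependent and each step returns a [qc_report()].
#' @name genotype_qc
NULL

#' Construct a QC report
#'
#' @param n_samples_in,n_samples_out,n_loci_in,n_loci_out dimension counts
#'   before and after the step.
#' @param removed named list of per-stage removal counts.
#' @param missing_before,missing_after missing-call fraction before/after.
#' @param notes optional character notes (e.g. fallback loci).
#' @return an object of class `qc_report`.
#' @export
qc_report <- function(n_samples_in, n_samples_out, n_loci_in, n_loci_out,
                      removed = list(), missing_before = NA_real_,
                      missing_after = NA_real_, notes = character()) {
  stopifnot(n_samples_out <= n_samples_in, n_loci_out <= n_loci_in)
  structure(list(n_samples_in = n_samples_in, n_samples_out = n_samples_out,
                 n_loci_in = n_loci_in, n_loci_out = n_loci_out,
                 removed = removed, missing_before = missing_before,
                 missing_after = missing_after, notes = notes),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  samples: %d -> %d\n", x$n_samples_in, x$n_samples_out))
  cat(sprintf("  loci:    %d -> %d\n", x$n_loci_in, x$n_loci_out))
  for (nm in names(x$removed)) {
    cat(sprintf("  removed (%s): %d\n", nm, x$removed[[nm]]))
  }
  if (!is.na(x$missing_before)) {
    cat(sprintf("  missing rate: %.3f -> %.3f\n",
                x$missing_before, x$missing_after))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

missing_fraction <- function(x) mean(is.na(x))

#' Drop loci whose alternative allele is off the designed SNP list
#'
#' Genotyping against a pre-defined SNP list can call alternative alleles
#' other than the designed one (e.g. a tri-allelic site); such loci, and loci
#' absent from the list altogether, are removed.
#'
#' @param genotypes dosage matrix, loci in columns named to match
#'   `observed_alleles$locus_id`.
#' @param observed_alleles data frame with columns `locus_id`, `ref`, `alt`:
#'   the alleles actually observed per locus.
#' @param snp_list data frame with columns `locus_id`, `ref`, `alt`: the
#'   designed alleles.
#' @return list with `genotypes` (filtered) and `report` ([qc_report()]).
#' @examples
#' geno <- matrix(0:1, 2, 3, dimnames = list(c("a", "b"), c("L1", "L2", "L3")))
#' obs <- data.frame(locus_id = c("L1", "L2", "L3"), ref = "A",
#'                   alt = c("T", "G", "T"))
#' listed <- data.frame(locus_id = c("L1", "L2", "L3"), ref = "A", alt = "T")
#' filter_allowed_alleles(geno, obs, listed)$report
#' @export
filter_allowed_alleles <- function(genotypes, observed_alleles, snp_list) {
  check_genotypes(genotypes)
  stopifnot(all(c("locus_id", "ref", "alt") %in% names(observed_alleles)),
            all(c("locus_id", "ref", "alt") %in% names(snp_list)))
  loci <- colnames(genotypes)
  obs <- observed_alleles[match(loci, observed_alleles$locus_id), ]
  idx <- match(loci, snp_list$locus_id)
  listed <- !is.na(idx)
  alt_ok <- listed & !is.na(obs$alt) & obs$alt == snp_list$alt[idx]
  keep <- which(alt_ok)
  if (!length(keep)) {
    stop("no loci survive the allele-list filter (", sum(!listed),
         " off-list, ", sum(listed & !alt_ok), " allele mismatches)",
         call. = FALSE)
  }
  out <- genotypes[, keep, drop = FALSE]
  rep <- qc_report(nrow(genotypes), nrow(out), ncol(genotypes), ncol(out),
                   removed = list(off_list = sum(!listed),
                                  alt_mismatch = sum(listed & !alt_ok)),
                   missing_before = missing_fraction(genotypes),
                   missing_after = missing_fraction(out))
  list(genotypes = out, report = rep)
}

#' Two-stage missing-data filter over loci then samples
#'
#' Stage 1 computes each locus's missing fraction using only informative
#' samples (overall missing fraction below `informative_sample_threshold`)
#' and drops loci strictly above `locus_threshold`. Stage 2 recomputes each
#' sample's missing fraction on the retained loci and drops samples strictly
#' above `sample_threshold`. All comparisons are strict ("more than" /
#' "greater than"), so a locus at exactly the threshold is retained.
#'
#' @param genotypes dosage matrix with `NA` for missing calls.
#' @param locus_threshold per-locus missing fraction above which the locus is
#'   dropped (default 0.25).
#' @param informative_sample_threshold samples at or above this overall
#'   missing fraction are excluded from the stage-1 denominator (default
#'   0.50).
#' @param sample_threshold per-sample missing fraction (on retained loci)
#'   above which the sample is dropped (default 0.90).
#' @return list with `genotypes` and `report`.
#' @examples
#' geno <- rbind(A = c(0, 1, NA, 2), B = c(1, 1, 0, 2), C = c(NA, NA, NA, 0))
#' colnames(geno) <- paste0("L", 1:4)
#' missingness_filter(geno)$report
#' @export
missingness_filter <- function(genotypes, locus_threshold = 0.25,
                               informative_sample_threshold = 0.50,
                               sample_threshold = 0.90) {
  check_genotypes(genotypes)
  if (!nrow(genotypes) || !ncol(genotypes)) stop("empty genotype matrix",
                                                 call. = FALSE)
  sample_miss <- apply(genotypes, 1, missing_fraction)
  informative <- sample_miss < informative_sample_threshold
  if (!any(informative)) {
    stop("no informative samples: every sample has >= ",
         informative_sample_threshold * 100, "% missing data", call. = FALSE)
  }
  locus_miss <- apply(genotypes[informative, , drop = FALSE], 2,
                      missing_fraction)
  keep_loci <- locus_miss <= locus_threshold
  stage1 <- genotypes[, keep_loci, drop = FALSE]
  sample_miss2 <- apply(stage1, 1, missing_fraction)
  keep_samples <- sample_miss2 <= sample_threshold
  out <- stage1[keep_samples, , drop = FALSE]
  rep <- qc_report(nrow(genotypes), nrow(out), ncol(genotypes), ncol(out),
                   removed = list(high_missing_loci = sum(!keep_loci),
                                  high_missing_samples = sum(!keep_samples)),
                   missing_before = missing_fraction(genotypes),
                   missing_after = missing_fraction(out))
  list(genotypes = out, report = rep)
}

#' Minor-allele-frequency filter
#'
#' The alternative-allele frequency of a locus is its mean dosage over
#' non-missing entries divided by 2; the minor-allele frequency is
#' `min(p, 1 - p)`. Loci below `min_maf` are removed. Works on integer
#' dosages and on continuous pooled allele-frequency rows alike.
#'
#' @param genotypes dosage matrix.
#' @param min_maf minimum minor-allele frequency (default 0.05).
#' @return list with `genotypes` and `report`.
#' @export
maf_filter <- function(genotypes, min_maf = 0.05) {
  check_genotypes(genotypes)
  p <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing locus carries no information
  keep <- maf >= min_maf
  out <- genotypes[, keep, drop = FALSE]
  rep <- qc_report(nrow(genotypes), nrow(out), ncol(genotypes), ncol(out),
                   removed = list(low_maf = sum(!keep)),
                   missing_before = missing_fraction(genotypes),
                   missing_after = missing_fraction(out))
  list(genotypes = out, report = rep)
}

#' Impute missing genotypes by LD-informed k nearest neighbours
#'
#' For each missing call at locus `j`, the loci in highest linkage
#' disequilibrium with `j` (squared Pearson correlation of dosages over
#' pairwise-complete samples) are used to measure how close other samples
#' are: the distance between the target sample and every sample with an
#' observed genotype at `j` is the mean absolute dosage difference over the
#' top `n_ld_snps` loci (pairs where either value is missing are skipped and
#' the sum rescaled by the count used), plus a small constant so inverse
#' distances are finite. The missing dosage is the 1/distance-weighted mean
#' of the `n_neighbors` nearest samples' dosages at `j`, rounded to the
#' nearest integer in `{0, 1, 2}`. Observed entries are never altered. Ties
#' in LD ranking and in neighbour distance are broken by column/row order so
#' the result is deterministic.
#'
#' Loci with fewer than `n_neighbors` observed genotypes fall back to the
#' rounded per-locus mean dosage and are flagged in the report attribute.
#'
#' @param genotypes dosage matrix with `NA` for missing calls.
#' @param n_ld_snps number of highest-LD loci used for the distance
#'   (default 30, the published default of the method).
#' @param n_neighbors number of nearest samples averaged (default 5).
#' @param eps small constant added to distances (default 1e-6).
#' @return the completed integer dosage matrix, with a `qc_report` in
#'   attribute `"report"` listing fallback loci.
#' @examples
#' geno <- simulate_genotypes(sim_config(n_individuals = 40, n_loci = 60,
#'                                       n_qtl = 5, ld_block_size = 10,
#'                                       seed = 5))
#' masked <- inject_missingness(geno, 0.1, seed = 6)
#' imputed <- ld_knn_impute(masked)
#' mean(imputed[is.na(masked)] == geno[is.na(masked)])
#' @export
ld_knn_impute <- function(genotypes, n_ld_snps = 30, n_neighbors = 5,
                          eps = 1e-6) {
  check_genotypes(genotypes)
  if (!anyNA(genotypes)) {
    attr(genotypes, "report") <-
      qc_report(nrow(genotypes), nrow(genotypes), ncol(genotypes),
                ncol(genotypes), missing_before = 0, missing_after = 0)
    return(genotypes)
  }
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  miss_before <- missing_fraction(genotypes)
  out <- genotypes
  # composite LD: squared Pearson correlation of dosages, pairwise complete
  suppressWarnings(
    r2 <- stats::cor(genotypes, use = "pairwise.complete.obs")^2)
  fallback <- character()
  for (j in which(colSums(is.na(genotypes)) > 0)) {
    observed_j <- which(!is.na(genotypes[, j]))
    missing_j <- which(is.na(genotypes[, j]))
    if (length(observed_j) < n_neighbors) {
      fb <- if (length(observed_j)) {
        round_clamp(mean(genotypes[observed_j, j]))
      } else 1L
      out[missing_j, j] <- fb
      fallback <- c(fallback, colnames(genotypes)[j])
      next
    }
    ld <- r2[, j]
    ld[j] <- NA
    ld[is.na(ld)] <- -Inf
    top <- order(-ld, seq_len(m))[seq_len(min(n_ld_snps, m - 1L))]
    block <- genotypes[, top, drop = FALSE]
    for (s in missing_j) {
      diff <- abs(sweep(block[observed_j, , drop = FALSE], 2, block[s, ]))
      used <- rowSums(!is.na(diff))
      d <- rowSums(diff, na.rm = TRUE) / pmax(used, 1L) + eps
      d[used == 0] <- Inf
      ord <- order(d, observed_j)
      nn <- ord[seq_len(min(n_neighbors, length(ord)))]
      w <- 1 / d[nn]
      if (!any(is.finite(w))) {
        out[s, j] <- round_clamp(mean(genotypes[observed_j, j]))
      } else {
        w[!is.finite(w)] <- 0
        out[s, j] <- round_clamp(
          sum(w * genotypes[observed_j[nn], j]) / sum(w))
      }
    }
  }
  attr(out, "report") <- qc_report(
    n, n, m, m, missing_before = miss_before,
    missing_after = missing_fraction(out),
    notes = if (length(fallback)) {
      paste0("mean-imputation fallback at loci: ",
             paste(fallback, collapse = ","))
    } else character())
  out
}

#' Baseline imputation by the per-locus mean dosage
#'
#' Fills every missing call with the locus's rounded mean observed dosage;
#' the naive baseline LD-kNN imputation is benchmarked against.
#'
#' @inheritParams ld_knn_impute
#' @return completed integer dosage matrix.
#' @export
mean_impute <- function(genotypes) {
  check_genotypes(genotypes)
  for (j in which(colSums(is.na(genotypes)) > 0)) {
    obs <- genotypes[!is.na(genotypes[, j]), j]
    genotypes[is.na(genotypes[, j]), j] <-
      if (length(obs)) round_clamp(mean(obs)) else 1L
  }
  genotypes
}

#' Estimate imputation accuracy by masking observed genotypes
#'
#' Masks a random fraction of the observed entries, runs the imputer, and
#' reports the fraction of masked entries whose imputed integer dosage
#' matches the original call.
#'
#' @param genotypes dosage matrix (may already contain missing values; only
#'   observed entries are masked).
#' @param mask_rate fraction of observed entries to mask (> 0).
#' @param seed integer seed for the mask.
#' @param imputer function taking and returning a genotype matrix
#'   (default [ld_knn_impute()]).
#' @param ... passed on to `imputer`.
#' @return scalar accuracy in `[0, 1]`.
#' @export
imputation_accuracy <- function(genotypes, mask_rate, seed = 1L,
                                imputer = ld_knn_impute, ...) {
  check_genotypes(genotypes)
  if (mask_rate <= 0) {
    stop("mask_rate must be positive: no entries to score", call. = FALSE)
  }
  observed <- which(!is.na(genotypes))
  if (!length(observed)) stop("no observed entries to mask", call. = FALSE)
  masked_idx <- with_seed(seed, {
    observed[stats::runif(length(observed)) < mask_rate]
  })
  if (!length(masked_idx)) {
    stop("mask_rate too small: no entries were masked", call. = FALSE)
  }
  masked <- genotypes
  masked[masked_idx] <- NA
  imputed <- imputer(masked, ...)
  mean(round(imputed[masked_idx]) == genotypes[masked_idx])
}
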