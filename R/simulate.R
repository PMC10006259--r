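#' Configuration for the synthetic ryegrass-style population generator
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' generator emulates the statistical structure a genomic-selection analysis
#' of an obligate-outbreeding diploid population assumes: biallelic dosage
#' genotypes with tunable allele-frequency spectrum and block-wise linkage
#' disequilibrium, polygenic traits with a set narrow-sense heritability,
#' genetically correlated seasonal occasions, multi-year cohorts with additive
#' year shifts, optional ordinal (1-9 style) scoring, and missing genotype
#' calls.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_loci number of biallelic SNP loci.
#' @param n_qtl number of causal loci underlying the trait; must not exceed
#'   `n_loci`.
#' @param target_h2 narrow-sense heritability aimed for on each occasion;
#'   scalar or one value per occasion, each in `[0, 1]`. Environmental noise
#'   is scaled analytically as `var(g) * (1 - h2) / h2` so the expected
#'   heritability equals the target without post-hoc rescaling.
#' @param occasion_corr genetic correlation matrix across measurement
#'   occasions (symmetric, unit diagonal, positive semi-definite). The
#'   default `diag(1)` gives a single occasion.
#' @param occasions optional character names for the occasions; defaults to
#'   `"OCC1"`, `"OCC2"`, ...
#' @param trait trait label written into the phenotype table.
#' @param maf_range length-2 numeric, the interval in `(0, 0.5]` from which
#'   per-block alternative-allele frequencies are drawn uniformly.
#' @param ld_block_size number of consecutive loci sharing latent gametes
#'   (and hence in mutual LD); 1 means all loci independent.
#' @param ld_decay per-locus probability that a gamete's allele is redrawn
#'   from the block frequency instead of copied from the shared latent
#'   gamete; smaller values give tighter within-block LD. Leaves the marginal
#'   allele frequency unchanged.
#' @param year_shift numeric vector of additive per-cohort offsets (trait
#'   units); its length sets the number of cohorts, to which individuals are
#'   assigned in round-robin order. `NULL` means a single cohort with no
#'   shift.
#' @param ordinal_scale optional length-2 integer range (e.g. `c(1, 9)`);
#'   when given, phenotypes are rounded to the nearest integer in the range
#'   and clamped at the bounds, emulating visual 1-9 scoring.
#' @param missing_rate fraction of genotype calls set missing by
#'   [inject_missingness()] when the caller requests it; `[0, 1)`.
#' @param seed integer seed; every generator is deterministic given the seed.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 50, n_loci = 100, n_qtl = 10, seed = 1)
#' @export
sim_config <- function(n_individuals = 200,
                       n_loci = 500,
                       n_qtl = 50,
                       target_h2 = 0.4,
                       occasion_corr = diag(1),
                       occasions = NULL,
                       trait = "trait1",
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 1,
                       ld_decay = 0.1,
                       year_shift = NULL,
                       ordinal_scale = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  stopifnot(n_individuals >= 2, n_loci >= 1, n_qtl >= 1)
  if (n_qtl > n_loci) {
    stop("invalid configuration: n_qtl (", n_qtl, ") exceeds n_loci (",
         n_loci, ")", call. = FALSE)
  }
  occasion_corr <- as.matrix(occasion_corr)
  n_occ <- nrow(occasion_corr)
  if (ncol(occasion_corr) != n_occ ||
      !isTRUE(all.equal(occasion_corr, t(occasion_corr))) ||
      any(abs(diag(occasion_corr) - 1) > 1e-8)) {
    stop("occasion_corr must be a symmetric matrix with unit diagonal",
         call. = FALSE)
  }
  if (min(eigen(occasion_corr, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("occasion_corr must be positive semi-definite", call. = FALSE)
  }
  if (length(target_h2) == 1) target_h2 <- rep(target_h2, n_occ)
  if (length(target_h2) != n_occ) {
    stop("target_h2 must be scalar or one value per occasion", call. = FALSE)
  }
  if (any(target_h2 < 0 | target_h2 > 1)) {
    stop("target_h2 must lie in [0, 1]", call. = FALSE)
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]", call. = FALSE)
  }
  if (!is.null(ordinal_scale)) {
    stopifnot(length(ordinal_scale) == 2, ordinal_scale[1] < ordinal_scale[2])
  }
  stopifnot(missing_rate >= 0, missing_rate < 1,
            ld_block_size >= 1, ld_decay >= 0, ld_decay <= 1)
  if (is.null(occasions)) occasions <- paste0("OCC", seq_len(n_occ))
  stopifnot(length(occasions) == n_occ)
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_loci = as.integer(n_loci),
         n_qtl = as.integer(n_qtl),
         target_h2 = target_h2,
         occasion_corr = occasion_corr,
         occasions = occasions,
         trait = trait,
         maf_range = maf_range,
         ld_block_size = as.integer(ld_block_size),
         ld_decay = ld_decay,
         year_shift = year_shift,
         ordinal_scale = ordinal_scale,
         missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate dosage genotypes with block-wise linkage disequilibrium
#'
#' Generates a samples x loci matrix of alternative-allele dosages (0/1/2)
#' for a diploid population. Loci are grouped into consecutive blocks of
#' `ld_block_size`; within a block every locus is derived from the same pair
#' of latent gametes per individual, with each allele independently redrawn
#' from the block frequency with probability `ld_decay`. This yields
#' correlated dosages within a block (squared correlation about
#' `(1 - ld_decay)^2`) and independence across blocks, without full
#' coalescent machinery. The block allele frequency is drawn uniformly from
#' `maf_range`, so the marginal frequency of every locus in the block equals
#' it in expectation.
#'
#' @param config a [sim_config()] object.
#' @return integer dosage matrix (`n_individuals` x `n_loci`) with sample and
#'   locus dimnames.
#' @examples
#' geno <- simulate_genotypes(sim_config(n_individuals = 20, n_loci = 40,
#'                                       n_qtl = 5, seed = 3))
#' @seealso [simulate_phenotypes()], [inject_missingness()]
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_loci
  bs <- config$ld_block_size
  with_seed(config$seed, {
    geno <- matrix(0L, n, m)
    start <- 1L
    while (start <= m) {
      end <- min(start + bs - 1L, m)
      width <- end - start + 1L
      p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
      # two shared latent gametes per individual for the whole block
      g1 <- stats::rbinom(n, 1, p)
      g2 <- stats::rbinom(n, 1, p)
      for (j in start:end) {
        flip1 <- stats::rbinom(n, 1, config$ld_decay) == 1
        flip2 <- stats::rbinom(n, 1, config$ld_decay) == 1
        a1 <- ifelse(flip1, stats::rbinom(n, 1, p), g1)
        a2 <- ifelse(flip2, stats::rbinom(n, 1, p), g2)
        geno[, j] <- a1 + a2
      }
      start <- end + 1L
    }
    label_genotypes(geno)
  })
}

#' Simulate polygenic phenotypes with known ground truth
#'
#' Builds phenotypes on top of a complete genotype matrix: `n_qtl` loci are
#' drawn as causal, additive effects across occasions are sampled from a
#' multivariate normal with correlation `occasion_corr`, and environmental
#' noise is added with variance `var(g) * (1 - h2) / h2` so the expected
#' narrow-sense heritability per occasion equals `target_h2`. True breeding
#' values are centred to zero mean per occasion. Optional per-cohort year
#' shifts and rounding onto an ordinal scale are applied last. The returned
#' ground truth supports parameter-recovery tests of the prediction engine.
#'
#' With `target_h2 = 0` the genetic term is omitted from the phenotype (noise
#' variance would otherwise be undefined) while the true breeding values are
#' still reported, so phenotype and breeding value are uncorrelated by
#' construction.
#'
#' @param genotypes complete dosage matrix from [simulate_genotypes()];
#'   missing values are an error (impute first).
#' @param config the [sim_config()] used to generate the genotypes.
#' @return a list with
#'   \describe{
#'     \item{phenotypes}{long-format data frame with columns `sample_id`,
#'       `trait`, `occasion`, `cohort`, `value`.}
#'     \item{truth}{list with `qtl_indices`, `qtl_effects` (loci x occasions),
#'       `true_breeding_values` (samples x occasions, zero column means),
#'       `realized_h2` per occasion, and `cohort` assignment.}
#'   }
#' @examples
#' cfg <- sim_config(n_individuals = 50, n_loci = 100, n_qtl = 10, seed = 2)
#' sim <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' head(sim$phenotypes)
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  check_genotypes(genotypes, allow_missing = FALSE)
  n <- nrow(genotypes)
  n_occ <- length(config$occasions)
  with_seed(config$seed + 1L, {
    qtl <- sort(sample.int(ncol(genotypes), config$n_qtl))
    # effects correlated across occasions via the Cholesky factor
    L <- chol(config$occasion_corr + diag(1e-10, n_occ))
    z <- matrix(stats::rnorm(config$n_qtl * n_occ), config$n_qtl, n_occ)
    effects <- z %*% L
    g <- genotypes[, qtl, drop = FALSE] %*% effects
    g <- scale(g, center = TRUE, scale = FALSE)  # zero-mean TBV per occasion
    cohorts <- if (is.null(config$year_shift)) {
      rep(1L, n)
    } else {
      rep_len(seq_along(config$year_shift), n)
    }
    shift <- if (is.null(config$year_shift)) 0 else config$year_shift[cohorts]
    pheno <- matrix(NA_real_, n, n_occ)
    realized_h2 <- numeric(n_occ)
    for (k in seq_len(n_occ)) {
      h2 <- config$target_h2[k]
      var_g <- stats::var(g[, k])
      if (h2 == 0 || var_g == 0) {
        e <- stats::rnorm(n, 0, sqrt(max(var_g, 1)))
        pheno[, k] <- shift + e
        realized_h2[k] <- 0
      } else {
        var_e <- var_g * (1 - h2) / h2
        e <- stats::rnorm(n, 0, sqrt(var_e))
        pheno[, k] <- shift + g[, k] + e
        realized_h2[k] <- var_g / (var_g + stats::var(e))
      }
    }
    if (!is.null(config$ordinal_scale)) {
      pheno <- round_clamp(pheno, config$ordinal_scale[1],
                           config$ordinal_scale[2])
    }
    tbl <- data.frame(
      sample_id = rep(rownames(genotypes), times = n_occ),
      trait = config$trait,
      occasion = rep(config$occasions, each = n),
      cohort = rep(cohorts, times = n_occ),
      value = as.vector(pheno),
      stringsAsFactors = FALSE)
    truth <- list(
      qtl_indices = qtl,
      qtl_effects = effects,
      true_breeding_values = structure(unclass(g),
                                       dimnames = list(rownames(genotypes),
                                                       config$occasions)),
      realized_h2 = stats::setNames(realized_h2, config$occasions),
      cohort = stats::setNames(cohorts, rownames(genotypes)))
    list(phenotypes = tbl, truth = truth)
  })
}

#' Pool individuals into synthetic-variety allele-frequency genotypes
#'
#' Emulates a reference population of synthetic varieties, each generated by
#' poly-crossing a small group of parents. Each pool's genotype row is the
#' per-locus arithmetic mean dosage of its parents (continuous in `[0, 2]`,
#' i.e. twice the pool allele frequency), the representation used when whole
#' varieties rather than individuals are genotyped.
#'
#' @param genotypes parent dosage matrix (samples x loci, no missing values).
#' @param parents_per_pool parents per synthetic variety (>= 1; 4 is the
#'   classic poly-cross size, 1 degenerates to the individual itself).
#' @param n_pools number of pools to draw.
#' @param seed integer seed for parent sampling.
#' @param phenotype optional numeric vector aligned with `genotypes` rows;
#'   when supplied, pool phenotypes (parent means) are returned too.
#' @return list with `genotypes` (pools x loci matrix), `members` (list of
#'   parent ids per pool) and, if requested, `phenotype`.
#' @examples
#' geno <- simulate_genotypes(sim_config(n_individuals = 30, n_loci = 50,
#'                                       n_qtl = 5, seed = 4))
#' pools <- simulate_variety_pools(geno, parents_per_pool = 4, n_pools = 10,
#'                                 seed = 9)
#' range(pools$genotypes)
#' @export
simulate_variety_pools <- function(genotypes, parents_per_pool, n_pools,
                                   seed = 1L, phenotype = NULL) {
  check_genotypes(genotypes, allow_missing = FALSE)
  if (parents_per_pool < 1) {
    stop("parents_per_pool must be at least 1", call. = FALSE)
  }
  if (parents_per_pool > nrow(genotypes)) {
    stop("parents_per_pool (", parents_per_pool,
         ") exceeds the number of individuals (", nrow(genotypes), ")",
         call. = FALSE)
  }
  if (!is.null(phenotype)) stopifnot(length(phenotype) == nrow(genotypes))
  with_seed(seed, {
    members <- replicate(n_pools,
                         sample.int(nrow(genotypes), parents_per_pool),
                         simplify = FALSE)
    pooled <- t(vapply(members, function(idx) {
      colMeans(genotypes[idx, , drop = FALSE])
    }, numeric(ncol(genotypes))))
    rownames(pooled) <- sprintf("POOL%03d", seq_len(n_pools))
    colnames(pooled) <- colnames(genotypes)
    out <- list(genotypes = pooled,
                members = lapply(members, function(i) rownames(genotypes)[i]))
    if (!is.null(phenotype)) {
      out$phenotype <- vapply(members, function(idx) mean(phenotype[idx]),
                              numeric(1))
      names(out$phenotype) <- rownames(pooled)
    }
    out
  })
}

#' Set genotype calls missing completely at random
#'
#' Masks entries of a dosage matrix uniformly at random at the given expected
#' rate, emulating the missing-call rates of low-coverage sequencing-based
#' genotyping. The caller keeps the original matrix to score imputation
#' accuracy against.
#'
#' @param genotypes dosage matrix.
#' @param rate expected missing fraction in `[0, 1)`.
#' @param seed integer seed; the mask is deterministic given the seed.
#' @return the matrix with masked entries set to `NA`.
#' @examples
#' geno <- matrix(rep(0:2, 4), 3, 4)
#' inject_missingness(geno, rate = 0.25, seed = 1)
#' @export
inject_missingness <- function(genotypes, rate, seed = 1L) {
  check_genotypes(genotypes)
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(genotypes)
  with_seed(seed, {
    mask <- stats::runif(length(genotypes)) < rate
    genotypes[mask] <- NA
    genotypes
  })
}
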