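#' @title Prediction-accuracy evaluation schemes
#' @description Three evaluation designs for genomic prediction accuracy:
#'   within-population k-fold cross-validation, forward prediction across
#'   years, and prediction of individuals from a pooled allele-frequency
#'   (synthetic-variety) reference population. Accuracy is predictive
#'   ability throughout — the Pearson correlation between GEBVs and observed
#'   phenotypes in the validation set — not divided by the square root of
#'   heritability.
#' @name prediction_eval
NULL

eval_result <- function(scheme, accuracy_mean, n_train, n_test, ...) {
  structure(c(list(scheme = scheme, accuracy_mean = accuracy_mean,
                   n_train = n_train, n_test = n_test), list(...)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Genomic prediction accuracy [%s]: %.3f", x$scheme,
              x$accuracy_mean))
  if (!is.null(x$accuracy_sd)) cat(sprintf(" (sd %.3f)", x$accuracy_sd))
  if (!is.null(x$slope)) cat(sprintf(", inflation slope %.3f", x$slope))
  cat(sprintf("  [n_train %d, n_test %d]\n", x$n_train, x$n_test))
  invisible(x)
}

# MAF-filter loci on the given (training) subset; returns kept locus names
training_loci <- function(K, rows, min_maf) {
  if (min_maf <= 0) return(colnames(K))
  kept <- maf_filter(K[rows, , drop = FALSE], min_maf = min_maf)$genotypes
  colnames(kept)
}

#' Within-population k-fold prediction accuracy
#'
#' Partitions the phenotyped samples into disjoint folds of about
#' `mask_fraction` each, fits the model on the unmasked remainder, and
#' scores the Pearson correlation between predicted GEBVs and observed
#' phenotypes on the masked fold. The minor-allele-frequency filter is
#' re-applied within every training subset before fitting. Returns the mean
#' and standard deviation over rounds.
#'
#' A disjoint random partition (every sample tested exactly once) is the
#' default; `disjoint = FALSE` instead draws `n_rounds` independent random
#' masks of size `mask_fraction`.
#'
#' @param y phenotype vector (no missing values; subset beforehand).
#' @param K genotype matrix aligned with `y` (complete, integer dosages).
#' @param mask_fraction fraction of samples masked per round (default 0.2).
#' @param n_rounds number of rounds (default 5).
#' @param config a [bayesa_config()]; its seed is re-derived per round so
#'   rounds use distinct chains.
#' @param seed seed controlling the fold assignment.
#' @param h2_prior `"auto"` for a per-training-set heritability pre-pass, or
#'   a number in (0, 1) used for every round (cheaper; pass e.g. a
#'   previously estimated heritability).
#' @param min_maf minor-allele-frequency threshold re-applied per training
#'   subset (default 0.05).
#' @param disjoint use one disjoint partition (default) rather than
#'   independent masks.
#' @return an `eval_result` with `accuracy_mean`, `accuracy_sd`, per-round
#'   accuracies in `rounds`, and fold sizes. Rounds whose test fold has zero
#'   phenotype variance are reported `NA` with a warning and excluded from
#'   the mean.
#' @examples
#' \donttest{
#' cfg <- sim_config(n_individuals = 120, n_loci = 150, n_qtl = 15,
#'                   target_h2 = 0.6, seed = 21)
#' geno <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(geno, cfg)
#' kfold_accuracy(sim$phenotypes$value, geno, seed = 1,
#'                config = bayesa_config(n_iter = 500, burn_in = 100),
#'                h2_prior = 0.5)
#' }
#' @export
kfold_accuracy <- function(y, K, mask_fraction = 0.2, n_rounds = 5,
                           config = bayesa_config(), seed = 1L,
                           h2_prior = "auto", min_maf = 0.05,
                           disjoint = TRUE) {
  y <- as.numeric(y)
  K <- as.matrix(K)
  stopifnot(length(y) == nrow(K), mask_fraction > 0, mask_fraction < 1)
  n <- length(y)
  if (n < 10) stop("need at least 10 phenotyped samples", call. = FALSE)
  folds <- with_seed(seed, {
    if (disjoint) {
      k <- max(2L, round(1 / mask_fraction))
      split(sample.int(n), rep_len(seq_len(k), n))[seq_len(min(n_rounds,
                                                               round(1 / mask_fraction)))]
    } else {
      lapply(seq_len(n_rounds), function(i) {
        sample.int(n, max(1L, round(mask_fraction * n)))
      })
    }
  })
  acc <- rep(NA_real_, length(folds))
  for (r in seq_along(folds)) {
    test <- folds[[r]]
    train <- setdiff(seq_len(n), test)
    loci <- training_loci(K, train, min_maf)
    cfg <- config
    cfg$seed <- config$seed + r
    fit <- genomic_prediction(y[train], K[train, loci, drop = FALSE],
                              config = cfg, h2_prior = h2_prior)
    pred <- predict_gebv(fit, K[test, loci, drop = FALSE])
    if (stats::var(y[test]) == 0 || stats::var(pred) == 0) {
      warning("round ", r, ": zero variance in test fold; accuracy undefined")
    } else {
      acc[r] <- stats::cor(pred, y[test])
    }
  }
  eval_result("kfold",
              accuracy_mean = mean(acc, na.rm = TRUE),
              n_train = n - length(folds[[1]]),
              n_test = length(folds[[1]]),
              accuracy_sd = stats::sd(acc, na.rm = TRUE),
              rounds = acc)
}

#' Forward prediction into the next year
#'
#' Fits the model on pooled earlier-year cohorts and predicts the next
#' year's samples. Besides the accuracy, reports the inflation slope — the
#' least-squares coefficient of observed phenotype regressed on GEBV. A
#' slope below 1 means the spread of GEBVs overstates the spread of
#' realised phenotypes (inflated predictions).
#'
#' @param y_train,K_train phenotypes and genotypes of the training years.
#' @param y_test,K_test phenotypes and genotypes of the target year; loci
#'   are aligned to the training loci by name.
#' @param config a [bayesa_config()].
#' @param h2_prior as in [kfold_accuracy()].
#' @param min_maf MAF threshold applied to the training genotypes.
#' @return an `eval_result` with `accuracy_mean` and `slope`.
#' @export
forward_prediction <- function(y_train, K_train, y_test, K_test,
                               config = bayesa_config(), h2_prior = "auto",
                               min_maf = 0.05) {
  K_train <- as.matrix(K_train)
  K_test <- as.matrix(K_test)
  stopifnot(length(y_train) == nrow(K_train), length(y_test) == nrow(K_test))
  loci <- training_loci(K_train, seq_len(nrow(K_train)), min_maf)
  fit <- genomic_prediction(y_train, K_train[, loci, drop = FALSE],
                            config = config, h2_prior = h2_prior)
  pred <- predict_gebv(fit, K_test)
  if (stats::var(pred) == 0) {
    stop("zero GEBV variance in the test set: slope undefined", call. = FALSE)
  }
  eval_result("forward",
              accuracy_mean = stats::cor(pred, y_test),
              n_train = length(y_train), n_test = length(y_test),
              slope = unname(stats::coef(stats::lm(y_test ~ pred))[2]))
}

#' Predict individuals from a pooled allele-frequency reference population
#'
#' Trains on synthetic-variety pools — rows are per-locus mean parent
#' dosages (continuous in `[0, 2]`) with pool-mean phenotypes — and predicts
#' GEBVs of individual plants, scoring them against the individuals'
#' observed phenotypes. With pools of size 1 this reduces to ordinary
#' individual-reference prediction.
#'
#' @param y_pool pool phenotypes.
#' @param K_pool pooled genotype rows (pools x loci).
#' @param K_targets individual genotype matrix to predict.
#' @param y_obs observed phenotypes of the target individuals.
#' @param config a [bayesa_config()]; for heading date from a
#'   synthetic-variety reference a fixed prior heritability of 0.85 is the
#'   protocol (`h2_prior = 0.85`).
#' @param h2_prior as in [kfold_accuracy()].
#' @param min_maf MAF threshold applied to the pooled training rows.
#' @return an `eval_result`.
#' @export
pooled_reference_prediction <- function(y_pool, K_pool, K_targets, y_obs,
                                        config = bayesa_config(),
                                        h2_prior = 0.85, min_maf = 0.05) {
  K_pool <- as.matrix(K_pool)
  K_targets <- as.matrix(K_targets)
  stopifnot(length(y_pool) == nrow(K_pool),
            length(y_obs) == nrow(K_targets))
  loci <- training_loci(K_pool, seq_len(nrow(K_pool)), min_maf)
  fit <- genomic_prediction(y_pool, K_pool[, loci, drop = FALSE],
                            config = config, h2_prior = h2_prior)
  pred <- predict_gebv(fit, K_targets)
  eval_result("pooled_reference",
              accuracy_mean = stats::cor(pred, y_obs),
              n_train = length(y_pool), n_test = length(y_obs))
}

#' Correlation between heritability and prediction accuracy
#'
#' Pearson correlation over matched trait-occasion cells of a heritability
#' table and an accuracy table. Cells missing in either table are dropped
#' pairwise. Inputs are numeric vectors; when both are named, matching is by
#' name, otherwise by position.
#'
#' @param h2 heritabilities (optionally named by trait-occasion).
#' @param accuracy accuracies (same keys).
#' @return Pearson correlation (scalar).
#' @examples
#' heritability_accuracy_correlation(c(a = 0.4, b = 0.3, c = 0.2),
#'                                   c(a = 0.45, b = 0.28, c = 0.19))
#' @export
heritability_accuracy_correlation <- function(h2, accuracy) {
  if (!is.null(names(h2)) && !is.null(names(accuracy))) {
    keys <- intersect(names(h2), names(accuracy))
    h2 <- h2[keys]
    accuracy <- accuracy[keys]
  } else if (length(h2) != length(accuracy)) {
    stop("unnamed inputs of different length cannot be matched", call. = FALSE)
  }
  ok <- !is.na(h2) & !is.na(accuracy)
  if (sum(ok) < 3) {
    stop("need at least 3 matched non-missing pairs", call. = FALSE)
  }
  stats::cor(h2[ok], accuracy[ok])
}
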