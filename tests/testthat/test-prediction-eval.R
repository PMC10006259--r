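tiny_chain <- function(seed = 1, ...) {
  bayesa_config(n_iter = 1200, burn_in = 300, seed = seed, ...)
}

test_that("k-fold folds are disjoint, exhaustive and seed-deterministic", {
  pop <- make_population(n = 60, m = 50, seed = 91)
  r1 <- kfold_accuracy(pop$y, pop$geno, config = tiny_chain(), seed = 5,
                       h2_prior = 0.5)
  r2 <- kfold_accuracy(pop$y, pop$geno, config = tiny_chain(), seed = 5,
                       h2_prior = 0.5)
  expect_identical(r1$rounds, r2$rounds)
  expect_identical(r1$accuracy_mean, r2$accuracy_mean)
  expect_identical(length(r1$rounds), 5L)
  expect_true(abs(r1$accuracy_mean) <= 1)
  expect_gte(r1$accuracy_sd, 0)
})

test_that("a noiseless marker-determined trait is predicted almost perfectly", {
  cfg <- sim_config(n_individuals = 300, n_loci = 50, n_qtl = 5,
                    maf_range = c(0.2, 0.5), seed = 93)
  geno <- simulate_genotypes(cfg)
  set.seed(94)
  causal <- sample(ncol(geno), 5)
  y <- drop(geno[, causal] %*% c(2, -1.5, 1, 0.8, -1.2))
  res <- kfold_accuracy(y, geno, config = tiny_chain(), seed = 6,
                        h2_prior = 0.9)
  expect_gt(res$accuracy_mean, 0.9)
})

test_that("accuracy cannot exceed the heritability ceiling by much", {
  pop <- make_population(n = 200, m = 150, n_qtl = 20, h2 = 0.4, seed = 95)
  res <- kfold_accuracy(pop$y, pop$geno, config = tiny_chain(), seed = 7,
                        h2_prior = 0.4)
  expect_lte(res$accuracy_mean, sqrt(pop$truth$realized_h2[1]) + 0.1)
})

test_that("forward prediction recovers identity and linear rescale exactly", {
  pop <- make_population(n = 80, m = 60, n_qtl = 10, h2 = 0.6, seed = 97)
  train <- 1:50; test <- 51:80
  fit <- genomic_prediction(pop$y[train], pop$geno[train, ], tiny_chain(8),
                            h2_prior = 0.5)
  pred <- predict_gebv(fit, pop$geno[test, ])
  # observed equal to predicted: accuracy 1, slope 1
  res <- forward_prediction(pop$y[train], pop$geno[train, ], pred,
                            pop$geno[test, ], config = tiny_chain(8),
                            h2_prior = 0.5, min_maf = 0)
  expect_equal(res$accuracy_mean, 1)
  expect_equal(res$slope, 1)
  # observed = 2 x predicted: accuracy 1, slope 2
  res2 <- forward_prediction(pop$y[train], pop$geno[train, ], 2 * pred,
                             pop$geno[test, ], config = tiny_chain(8),
                             h2_prior = 0.5, min_maf = 0)
  expect_equal(res2$accuracy_mean, 1)
  expect_equal(res2$slope, 2)
})

test_that("forward prediction across shared-architecture years is informative", {
  # three cohorts sharing QTL: train on the first two, predict the third
  cfg <- sim_config(n_individuals = 300, n_loci = 200, n_qtl = 20,
                    target_h2 = 0.6, ld_block_size = 10,
                    year_shift = c(0, 1, 2), seed = 99)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  cohort <- sim$truth$cohort
  train <- cohort %in% c(1, 2)
  res <- forward_prediction(sim$phenotypes$value[train], geno[train, ],
                            sim$phenotypes$value[!train], geno[!train, ],
                            config = tiny_chain(9), h2_prior = 0.6)
  expect_gt(res$accuracy_mean, 0.3)
  expect_lt(res$accuracy_mean, sqrt(0.6) + 0.1)
})

test_that("single-parent pools reduce to individual-reference prediction", {
  pop <- make_population(n = 60, m = 50, n_qtl = 10, h2 = 0.7, seed = 103)
  train <- 1:40; test <- 41:60
  # "pools" of one parent each: the training individuals themselves
  res_pool <- pooled_reference_prediction(pop$y[train], pop$geno[train, ],
                                          pop$geno[test, ], pop$y[test],
                                          config = tiny_chain(10),
                                          h2_prior = 0.5)
  res_ind <- forward_prediction(pop$y[train], pop$geno[train, ],
                                pop$y[test], pop$geno[test, ],
                                config = tiny_chain(10), h2_prior = 0.5)
  expect_equal(res_pool$accuracy_mean, res_ind$accuracy_mean)
  expect_equal(res_pool$n_train, 40L)
  # locus permutation of the target matrix changes nothing
  perm <- sample(ncol(pop$geno))
  res_perm <- pooled_reference_prediction(pop$y[train], pop$geno[train, ],
                                          pop$geno[test, perm], pop$y[test],
                                          config = tiny_chain(10),
                                          h2_prior = 0.5)
  expect_equal(res_perm$accuracy_mean, res_pool$accuracy_mean)
})

test_that("pooled-reference accuracy is positive but below within-population", {
  pop <- make_population(n = 260, m = 150, n_qtl = 20, h2 = 0.8, block = 10,
                         seed = 105)
  test <- 201:260
  pools <- simulate_variety_pools(pop$geno[1:200, ], 4, n_pools = 80,
                                  seed = 4, phenotype = pop$y[1:200])
  res <- pooled_reference_prediction(pools$phenotype, pools$genotypes,
                                     pop$geno[test, ], pop$y[test],
                                     config = tiny_chain(11), h2_prior = 0.8)
  expect_gt(res$accuracy_mean, 0.3)
  within <- kfold_accuracy(pop$y[test], pop$geno[test, ],
                           config = tiny_chain(11), seed = 12,
                           h2_prior = 0.8)
  expect_lt(res$accuracy_mean, within$accuracy_mean + 0.15)
})

test_that("heritability-accuracy correlation matches by key and drops NAs", {
  h2 <- c(a = 0.4, b = 0.3, c = 0.2, d = NA)
  acc <- c(d = 0.5, c = 0.19, b = 0.28, a = 0.45)
  expect_equal(heritability_accuracy_correlation(h2, acc),
               stats::cor(c(0.4, 0.3, 0.2), c(0.45, 0.28, 0.19)))
  expect_equal(heritability_accuracy_correlation(h2[1:3], h2[1:3]), 1.0)
  expect_error(heritability_accuracy_correlation(c(1, 2), c(1, 2)),
               "3 matched")
  expect_error(heritability_accuracy_correlation(c(1, 2, 3), c(1, 2)),
               "length")
})
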