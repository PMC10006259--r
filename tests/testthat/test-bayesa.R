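short_chain <- function(seed = 1, ...) {
  bayesa_config(n_iter = 1200, burn_in = 300, seed = seed, ...)
}

test_that("chains are deterministic given the seed and reject bad input", {
  pop <- make_population(n = 40, m = 30, seed = 71)
  f1 <- fit_bayesa(pop$y, pop$geno, short_chain(5))
  f2 <- fit_bayesa(pop$y, pop$geno, short_chain(5))
  expect_identical(f1$v_mean, f2$v_mean)
  expect_identical(f1$h2_samples, f2$h2_samples)
  f3 <- fit_bayesa(pop$y, pop$geno, short_chain(6))
  expect_false(identical(f1$v_mean, f3$v_mean))

  expect_error(fit_bayesa(rep(1, 40), pop$geno, short_chain()), "Var\\(y\\)")
  yna <- pop$y; yna[1] <- NA
  expect_error(fit_bayesa(yna, pop$geno, short_chain()), "missing")
  expect_error(bayesa_config(burn_in = 500, n_iter = 400))
})

test_that("an all-zero genotype matrix carries no genetic signal", {
  set.seed(1)
  y <- rnorm(50)
  K <- matrix(0, 50, 20, dimnames = list(NULL, paste0("L", 1:20)))
  fit <- fit_bayesa(y, K, short_chain(2))
  expect_true(all(fit$gebv == 0))
  expect_lt(fit$h2_mean, 0.05)
})

test_that("marker full conditional matches the analytic conjugate posterior", {
  # n = 6, m = 2 instance; oracle: joint MVN posterior of (v1, v2) with fixed
  # variances, conditioned on v2 by standard MVN conditioning
  set.seed(42)
  K <- matrix(sample(0:2, 12, TRUE), 6, 2)
  y <- c(1.2, -0.4, 2.1, 0.3, 1.8, -1.0)
  u <- 0.25; v2 <- 0.4; s2v <- c(0.7, 0.7); s2e <- 1.3

  Sigma <- solve(crossprod(K) / s2e + diag(1 / s2v))
  mu <- Sigma %*% crossprod(K, y - u) / s2e
  cond_var <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
  cond_mean <- mu[1] + Sigma[1, 2] / Sigma[2, 2] * (v2 - mu[2])

  fc <- marker_full_conditional(y, K, j = 1, u = u, v = c(0, v2),
                                sigma2_vj = s2v[1], sigma2_e = s2e)
  expect_equal(fc$mean, as.numeric(cond_mean), tolerance = 1e-6)
  expect_equal(fc$var, as.numeric(cond_var), tolerance = 1e-6)
})

test_that("per-state heritability arithmetic and limits are exact", {
  K <- cbind(c(0, 1, 2, 1), c(2, 0, 1, 1))
  expect_identical(heritability_from_state(K, c(0, 0), 1.5), 0)
  # construct g = K v with Var(g) = 3 exactly
  g0 <- c(-1, 0, 1, 2)                     # var = 5/3... scale to var 3
  g <- g0 * sqrt(3 / stats::var(g0))
  K <- matrix(g, ncol = 1)
  expect_equal(heritability_from_state(K, 1, 1.0), 0.75)
  # vanishing residual variance drives h2 to 1
  expect_gt(heritability_from_state(K, 1, 1e-12), 1 - 1e-9)
  expect_error(heritability_from_state(K[1, , drop = FALSE], 1, 1), "2 individuals")
})

test_that("residual bookkeeping holds at the end of the chain", {
  pop <- make_population(n = 50, m = 40, seed = 73)
  fit <- fit_bayesa(pop$y, pop$geno, short_chain(3))
  st <- fit$state
  recomputed <- pop$y - st$u - drop(pop$geno %*% st$v)
  expect_lt(max(abs(recomputed - st$e)), 1e-8)
  expect_true(all(fit$h2_samples >= 0 & fit$h2_samples <= 1))
  expect_true(all(fit$sigma2_e_samples > 0))
  expect_true(all(st$sigma2_v > 0))
})

test_that("traces have the expected length and thinning works", {
  pop <- make_population(n = 30, m = 20, seed = 79)
  fit <- fit_bayesa(pop$y, pop$geno,
                    bayesa_config(n_iter = 1000, burn_in = 200, thin = 4,
                                  seed = 1))
  expect_identical(nrow(fit$traces), (1000L - 200L) %/% 4L)
  expect_named(fit$traces, c("iteration", "intercept", "sigma2_e", "h2"))
})

test_that("adding a constant to y only moves the intercept", {
  pop <- make_population(n = 40, m = 30, seed = 81)
  f0 <- fit_bayesa(pop$y, pop$geno, short_chain(4))
  f1 <- fit_bayesa(pop$y + 100, pop$geno, short_chain(4))
  expect_equal(f1$gebv, f0$gebv)
  expect_equal(f1$u_mean - f0$u_mean, 100)
})

test_that("with a fixed common marker variance the fit approaches BLUP", {
  pop <- make_population(n = 30, m = 10, n_qtl = 5, h2 = 0.6, seed = 83)
  s2v <- 0.05
  fit <- fit_bayesa(pop$y, pop$geno,
                    bayesa_config(n_iter = 50000, burn_in = 5000, seed = 9,
                                  fixed_marker_variance = s2v))
  s2e <- mean(fit$sigma2_e_samples)
  # closed-form ridge/BLUP with an unpenalised intercept column
  X <- cbind(1, pop$geno)
  D <- diag(c(0, rep(1 / s2v, ncol(pop$geno))))
  beta <- solve(crossprod(X) / s2e + D, crossprod(X, pop$y) / s2e)
  expect_lt(max(abs(fit$v_mean - beta[-1])), 0.05)
})

test_that("heritability is recovered on simulated data", {
  pop <- make_population(n = 250, m = 300, n_qtl = 30, h2 = 0.5, block = 10,
                         seed = 85)
  fit <- genomic_prediction(pop$y, pop$geno,
                            bayesa_config(n_iter = 3000, burn_in = 500,
                                          seed = 10))
  expect_lt(abs(fit$h2_mean - pop$truth$realized_h2[1]), 0.15)
  expect_gt(stats::cor(fit$gebv, pop$truth$true_breeding_values[, 1]), 0.5)
})

test_that("GEBV prediction aligns loci and is linear", {
  pop <- make_population(n = 40, m = 30, seed = 87)
  fit <- fit_bayesa(pop$y, pop$geno, short_chain(7))
  # training matrix reproduces training GEBVs
  expect_equal(unname(predict_gebv(fit, pop$geno)), unname(fit$gebv))
  # a pooled row equal to the mean of four rows maps to the mean GEBV
  pool <- t(colMeans(pop$geno[1:4, , drop = FALSE]))
  rownames(pool) <- "pool"
  expect_equal(unname(predict_gebv(fit, pool)), mean(fit$gebv[1:4]))
  # locus order does not matter
  perm <- sample(ncol(pop$geno))
  expect_equal(predict_gebv(fit, pop$geno[, perm]), predict_gebv(fit, pop$geno))
  # zero overlap is an error
  none <- pop$geno
  colnames(none) <- paste0("X", seq_len(ncol(none)))
  expect_error(predict_gebv(fit, none), "overlap")
  # intercept shifts predictions onto the phenotype scale
  expect_equal(predict_gebv(fit, pop$geno, include_intercept = TRUE),
               predict_gebv(fit, pop$geno) + fit$u_mean)
})
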