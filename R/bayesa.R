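#' Configuration for the BayesA Gibbs sampler
#'
#' @param n_iter total Gibbs iterations (default 12000).
#' @param burn_in iterations discarded before summarising (default 2000).
#' @param h2_prior prior expectation of narrow-sense heritability in (0, 1);
#'   sets the hyper-scales of the variance priors (see Details).
#' @param df_marker prior degrees of freedom of the per-marker variance
#'   (default 5; the marginal prior on each effect is then a scaled-t with
#'   `df_marker` degrees of freedom).
#' @param df_residual prior degrees of freedom of the residual variance
#'   (default 5).
#' @param seed integer seed; chains are fully deterministic given the seed.
#' @param thin keep every `thin`-th post-burn-in sample (default 1).
#' @param center subtract genotype column means before fitting (default
#'   `FALSE`: dosages enter the model as coded, 0/1/2).
#' @param fixed_marker_variance optional positive scalar: hold every marker
#'   variance fixed at this value instead of sampling it, which reduces the
#'   model to ridge regression / SNP-BLUP. Used for validation.
#' @param update_scale treat the common scale of the marker-variance prior
#'   as unknown with a Gamma prior (mode at the `h2_prior`-derived value)
#'   and sample it each iteration (default `TRUE`, the standard default of
#'   the reference software). `FALSE` keeps the scale fixed; with many
#'   effect-free markers a fixed scale props up their sampled effects and
#'   inflates the heritability estimate.
#' @param shape0 shape of the Gamma prior on the marker-variance scale when
#'   `update_scale = TRUE` (default 1.1, weakly informative).
#'
#' @details The prior scales follow the default calibration rule of standard
#' Bayesian whole-genome regression software: with `V = var(y)`,
#' `S_e = V * (1 - h2_prior) * (df_residual + 2)` and
#' `S_v = V * h2_prior * (df_marker + 2) / MSx`, where `MSx` is the sum of
#' the genotype columns' sample variances. Scaled-inverse-chi-squared(nu, S)
#' is parameterised so that a draw is `S' / rchisq(nu)` with `S'` the updated
#' (sum-of-squares) scale — i.e. the prior scale enters full conditionals
#' additively, `S + v_j^2`, not multiplied by nu.
#'
#' @return an object of class `bayesa_config`.
#' @export
bayesa_config <- function(n_iter = 12000, burn_in = 2000, h2_prior = 0.5,
                          df_marker = 5, df_residual = 5, seed = 1L,
                          thin = 1, center = FALSE,
                          fixed_marker_variance = NULL,
                          update_scale = TRUE, shape0 = 1.1) {
  stopifnot(n_iter >= 1, burn_in >= 0, burn_in < n_iter,
            h2_prior > 0, h2_prior < 1, df_marker > 0, df_residual > 0,
            thin >= 1, shape0 > 1)
  if (!is.null(fixed_marker_variance)) stopifnot(fixed_marker_variance > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 h2_prior = h2_prior, df_marker = df_marker,
                 df_residual = df_residual, seed = as.integer(seed),
                 thin = as.integer(thin), center = center,
                 fixed_marker_variance = fixed_marker_variance,
                 update_scale = isTRUE(update_scale), shape0 = shape0),
            class = "bayesa_config")
}

#' Fit BayesA whole-genome regression by Gibbs sampling
#'
#' Fits `y = u 1 + K v + e` where every marker effect `v_j` has its own
#' variance with a scaled-inverse-chi-squared prior (marginally, a scaled-t
#' prior on effects). Updates are single-site: the intercept from its normal
#' full conditional, each effect from its normal full conditional, each
#' marker variance from scaled-inv-chisq(`df_marker + 1`, `S_v + v_j^2`),
#' and the residual variance from scaled-inv-chisq(`df_residual + n`,
#' `S_e + e'e`). Narrow-sense heritability is tracked per iteration as the
#' sample variance of the genomic values `g = K v` over individuals divided
#' by that variance plus the residual variance.
#'
#' @param y numeric phenotype vector, no missing values, non-zero variance.
#' @param K genotype matrix (samples x loci), integer dosages 0/1/2 or
#'   continuous pooled rows in `[0, 2]`; no missing values.
#' @param config a [bayesa_config()].
#' @return object of class `bayesa_fit` with elements `u_mean`, `v_mean`
#'   (named by locus), `gebv` (named by sample, `K %*% v_mean`), `h2_mean`,
#'   `h2_samples`, `sigma2_e_samples`, `traces` (data frame of kept
#'   iterations: intercept, residual variance, heritability — for
#'   convergence inspection), `state` (final sampler state) and the scales
#'   used.
#' @examples
#' cfg <- sim_config(n_individuals = 80, n_loci = 100, n_qtl = 10,
#'                   target_h2 = 0.5, seed = 11)
#' geno <- simulate_genotypes(cfg)
#' sim <- simulate_phenotypes(geno, cfg)
#' y <- sim$phenotypes$value
#' fit <- fit_bayesa(y, geno, bayesa_config(n_iter = 600, burn_in = 100))
#' fit$h2_mean
#' @export
fit_bayesa <- function(y, K, config = bayesa_config()) {
  stopifnot(inherits(config, "bayesa_config"))
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(K)) {
    stop("missing values in y or K; subset to phenotyped samples and impute ",
         "genotypes first", call. = FALSE)
  }
  K <- as.matrix(K)
  if (nrow(K) != length(y)) stop("nrow(K) must equal length(y)", call. = FALSE)
  if (ncol(K) < 1) stop("K must have at least one locus", call. = FALSE)
  vy <- stats::var(y)
  if (vy == 0) {
    stop("Var(y) is zero: hyper-scales undefined", call. = FALSE)
  }
  centers <- NULL
  if (config$center) {
    centers <- colMeans(K)
    K <- sweep(K, 2, centers)
  }
  msx <- sum(apply(K, 2, stats::var))
  S_e <- vy * (1 - config$h2_prior) * (config$df_residual + 2)
  S_v <- if (msx > 0) {
    vy * config$h2_prior * (config$df_marker + 2) / msx
  } else {
    vy * config$h2_prior * (config$df_marker + 2)  # degenerate constant K
  }
  fixed <- if (is.null(config$fixed_marker_variance)) NA_real_ else
    config$fixed_marker_variance
  res <- with_seed(config$seed, {
    .bayesa_gibbs(y, K, config$n_iter, config$burn_in, config$thin,
                  config$df_marker, config$df_residual, S_v, S_e, fixed,
                  config$update_scale, config$shape0)
  })
  v_mean <- stats::setNames(res$v_mean, colnames(K))
  gebv <- drop(K %*% v_mean)
  names(gebv) <- rownames(K)
  structure(
    list(u_mean = res$u_mean,
         v_mean = v_mean,
         gebv = gebv,
         h2_mean = mean(res$h2_samples),
         h2_samples = res$h2_samples,
         sigma2_e_samples = res$sigma2_e_samples,
         traces = data.frame(iteration = seq_along(res$u_samples),
                             intercept = res$u_samples,
                             sigma2_e = res$sigma2_e_samples,
                             h2 = res$h2_samples),
         state = res$state,
         scales = c(S_v = S_v, S_e = S_e, MSx = msx, var_y = vy),
         centers = centers,
         loci = colnames(K),
         config = config),
    class = "bayesa_fit")
}

#' @export
print.bayesa_fit <- function(x, ...) {
  cat("BayesA fit:", length(x$gebv), "samples x", length(x$v_mean), "loci\n")
  cat(sprintf("  chain: %d iterations, burn-in %d, thin %d\n",
              x$config$n_iter, x$config$burn_in, x$config$thin))
  cat(sprintf("  intercept %.4f, posterior mean h2 %.3f, residual var %.4f\n",
              x$u_mean, x$h2_mean, mean(x$sigma2_e_samples)))
  invisible(x)
}

#' Narrow-sense heritability from one sampler state
#'
#' Given marker effects and a residual variance, computes
#' `h2 = Var(g) / (Var(g) + sigma2_e)` with `g = K v` and `Var` the sample
#' variance over individuals — the per-iteration heritability the sampler
#' tracks.
#'
#' @param K genotype matrix (samples x loci).
#' @param v marker-effect vector.
#' @param sigma2_e residual variance (> 0).
#' @return heritability in `[0, 1]`.
#' @export
heritability_from_state <- function(K, v, sigma2_e) {
  K <- as.matrix(K)
  if (nrow(K) < 2) stop("need at least 2 individuals", call. = FALSE)
  stopifnot(sigma2_e > 0, length(v) == ncol(K))
  var_g <- stats::var(drop(K %*% v))
  var_g / (var_g + sigma2_e)
}

#' Normal full conditional of a single marker effect
#'
#' Mean and variance of the Gibbs full conditional of `v[j]` given the
#' intercept, all other effects, its marker variance and the residual
#' variance: precision `C = K_j'K_j / sigma2_e + 1 / sigma2_vj`, mean
#' `K_j'(y - u - K_{-j} v_{-j}) / (sigma2_e * C)`. Exposed for validation
#' against the closed-form conjugate posterior.
#'
#' @param y phenotype vector.
#' @param K genotype matrix.
#' @param j column index of the effect.
#' @param u current intercept.
#' @param v current effect vector (the value at `j` is ignored).
#' @param sigma2_vj current variance of effect `j`.
#' @param sigma2_e current residual variance.
#' @return list with `mean` and `var`.
#' @export
marker_full_conditional <- function(y, K, j, u, v, sigma2_vj, sigma2_e) {
  K <- as.matrix(K)
  stopifnot(j >= 1, j <= ncol(K), length(v) == ncol(K),
            sigma2_vj > 0, sigma2_e > 0)
  r <- y - u - drop(K[, -j, drop = FALSE] %*% v[-j])
  xtx <- sum(K[, j]^2)
  C <- xtx / sigma2_e + 1 / sigma2_vj
  list(mean = sum(K[, j] * r) / sigma2_e / C, var = 1 / C)
}

#' Estimate narrow-sense heritability with a neutral prior
#'
#' Pre-pass of the same sampler with `h2_prior = 0.5`: its posterior mean
#' heritability is then used as the prior for the prediction run (see
#' [genomic_prediction()]).
#'
#' @inheritParams fit_bayesa
#' @param config chain settings; its `h2_prior` is overridden to 0.5.
#' @return posterior mean heritability (scalar), with the full fit in
#'   attribute `"fit"`.
#' @export
estimate_heritability <- function(y, K, config = bayesa_config()) {
  config$h2_prior <- 0.5
  fit <- fit_bayesa(y, K, config)
  structure(fit$h2_mean, fit = fit)
}

#' Heritability pre-pass plus BayesA prediction run
#'
#' The two-stage protocol used throughout: heritability is first estimated
#' with a neutral prior (0.5), and the resulting posterior mean seeds the
#' `h2_prior` of the prediction chain. Pass a numeric `h2_prior` to skip the
#' pre-pass (e.g. 0.85 for heading date predicted from a synthetic-variety
#' reference population).
#'
#' @inheritParams fit_bayesa
#' @param h2_prior `"auto"` (default) runs the pre-pass; a number in (0, 1)
#'   is used directly.
#' @return a `bayesa_fit`; the pre-pass estimate, when run, is stored in
#'   element `h2_prepass`.
#' @export
genomic_prediction <- function(y, K, config = bayesa_config(),
                               h2_prior = "auto") {
  prepass <- NULL
  if (identical(h2_prior, "auto")) {
    prepass <- as.numeric(estimate_heritability(y, K, config))
    # guard against boundary estimates breaking the scale rule
    config$h2_prior <- min(max(prepass, 0.01), 0.99)
  } else {
    stopifnot(is.numeric(h2_prior), h2_prior > 0, h2_prior < 1)
    config$h2_prior <- h2_prior
  }
  fit <- fit_bayesa(y, K, config)
  fit$h2_prepass <- prepass
  fit
}

#' Predict genomic estimated breeding values for new genotypes
#'
#' Computes `K_new %*% v_mean` after aligning the new matrix's loci to the
#' training loci by name (intersection, training order). Accepts integer
#' dosages and continuous allele-frequency-coded pooled rows alike.
#'
#' @param fit a [fit_bayesa()] result.
#' @param K_new genotype matrix with locus column names.
#' @param include_intercept add `u_mean` for phenotype-scale predictions
#'   (default `FALSE`: breeding-value scale).
#' @return named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, K_new, include_intercept = FALSE) {
  stopifnot(inherits(fit, "bayesa_fit"))
  K_new <- as.matrix(K_new)
  if (is.null(colnames(K_new)) || is.null(fit$loci)) {
    if (ncol(K_new) != length(fit$v_mean)) {
      stop("unnamed loci and column count differs from training", call. = FALSE)
    }
    common <- seq_along(fit$v_mean)
    Kn <- K_new
    v <- fit$v_mean
  } else {
    common <- intersect(fit$loci, colnames(K_new))
    if (!length(common)) {
      stop("no overlapping loci between training and prediction matrices",
           call. = FALSE)
    }
    if (length(common) < length(fit$loci)) {
      warning(length(fit$loci) - length(common),
              " training loci absent from prediction matrix; using ",
              length(common), " shared loci")
    }
    Kn <- K_new[, common, drop = FALSE]
    v <- fit$v_mean[common]
  }
  if (!is.null(fit$centers)) {
    Kn <- sweep(Kn, 2, fit$centers[common])
  }
  out <- drop(Kn %*% v)
  if (include_intercept) out <- out + fit$u_mean
  names(out) <- rownames(K_new)
  out
}
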