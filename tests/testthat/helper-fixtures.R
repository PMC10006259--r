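# shared fixture builders; everything generated in code, nothing on disk

# small population with LD blocks plus a phenotyped trait
make_population <- function(n = 100, m = 120, n_qtl = 12, h2 = 0.5,
                            block = 10, seed = 101, ...) {
  n_qtl <- max(2L, min(n_qtl, m %/% 2L))
  cfg <- sim_config(n_individuals = n, n_loci = m, n_qtl = n_qtl,
                    target_h2 = h2, ld_block_size = block, seed = seed, ...)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(geno, cfg)
  list(cfg = cfg, geno = geno, y = sim$phenotypes$value, truth = sim$truth,
       phenotypes = sim$phenotypes)
}

# the worked 3-sample x 4-locus missingness fixture
missingness_fixture <- function() {
  geno <- rbind(A = c(0, 1, NA, 2),
                B = c(1, 1, 0, 2),
                C = c(NA, NA, NA, 0))
  colnames(geno) <- paste0("L", 1:4)
  geno
}

# exact expectation of the windowed parental-group mean phenotype range by
# enumerating every ordered selection path with its probability
enumerate_group_expectation <- function(gebv, phenotype, window,
                                        group_size = 4) {
  n <- length(gebv)
  succ_prob <- 0
  succ_exp <- 0
  fail_prob <- 0
  recurse <- function(chosen, prob) {
    if (length(chosen) == group_size) {
      succ_prob <<- succ_prob + prob
      succ_exp <<- succ_exp + prob * diff(range(phenotype[chosen]))
      return(invisible())
    }
    ok <- vapply(seq_len(n), function(i) {
      !(i %in% chosen) && all(abs(gebv[i] - gebv[chosen]) <= window)
    }, logical(1))
    cand <- which(ok)
    if (!length(cand)) {
      fail_prob <<- fail_prob + prob
      return(invisible())
    }
    for (i in cand) recurse(c(chosen, i), prob / length(cand))
  }
  for (first in seq_len(n)) recurse(first, 1 / n)
  list(mean_range = succ_exp / succ_prob,
       success_prob = succ_prob, fail_prob = fail_prob)
}
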