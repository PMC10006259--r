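# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit, so generators are deterministic
#' without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# round to nearest integer, half away from zero, clamped to [lo, hi];
# dosages must land in {0, 1, 2} deterministically (round() is half-to-even)
round_clamp <- function(x, lo = 0L, hi = 2L) {
  pmin(pmax(floor(x + 0.5), lo), hi)
}

# checks a samples x loci dosage matrix
check_genotypes <- function(geno, allow_missing = TRUE, allow_continuous = TRUE) {
  if (!is.matrix(geno) || !is.numeric(geno)) {
    stop("genotypes must be a numeric matrix (samples in rows, loci in columns)",
         call. = FALSE)
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (!allow_missing && anyNA(geno)) {
    stop("genotype matrix contains missing values; impute first ",
         "(see ld_knn_impute())", call. = FALSE)
  }
  if (!allow_continuous && length(vals) && any(vals != round(vals))) {
    stop("genotype matrix must contain integer dosages 0/1/2", call. = FALSE)
  }
  invisible(geno)
}

# default dimnames for generated matrices
label_genotypes <- function(geno, sample_prefix = "S", locus_prefix = "L") {
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("%s%03d", sample_prefix, seq_len(nrow(geno)))
  }
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("%s%05d", locus_prefix, seq_len(ncol(geno)))
  }
  geno
}
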