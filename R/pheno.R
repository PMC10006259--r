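#' @title Phenotype preprocessing and descriptive statistics
#' @description Long-format phenotype tables carry one record per sample x
#'   trait x occasion (with a cohort/year column). Preprocessing removes
#'   boxplot-rule outliers per trait x occasion; descriptives cover
#'   trait-occasion correlation matrices with significance stars and
#'   boxplot-style distribution summaries.
#' @name pheno_stats
NULL

check_phenotypes <- function(table) {
  need <- c("sample_id", "trait", "occasion", "value")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("phenotype table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  invisible(table)
}

#' Remove outliers by the Tukey boxplot rule
#'
#' Drops values falling outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with
#' quartiles taken as Tukey hinges — exactly the points
#' `grDevices::boxplot.stats()` flags, which is the function used for the
#' rule. With fewer than 4 values hinges are unstable, so nothing is removed
#' and a warning is raised. Applied once, not iterated.
#'
#' @param values numeric vector.
#' @return list with `kept` and `removed`.
#' @examples
#' remove_outliers(c(1:10, 100))
#' @export
remove_outliers <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (!length(values)) return(list(kept = numeric(), removed = numeric()))
  if (length(values) < 4) {
    warning("fewer than 4 values: outlier rule skipped")
    return(list(kept = values, removed = numeric()))
  }
  out <- grDevices::boxplot.stats(values)$out
  list(kept = values[!values %in% out], removed = values[values %in% out])
}

#' Apply the boxplot outlier rule per trait and occasion
#'
#' @param table long-format phenotype table (`sample_id`, `trait`,
#'   `occasion`, optional `cohort`, `value`).
#' @return the table with outlier records dropped; removal counts per group
#'   in attribute `"removed"`.
#' @export
clean_phenotypes <- function(table) {
  check_phenotypes(table)
  key <- interaction(table$trait, table$occasion, drop = TRUE)
  drop_idx <- unlist(lapply(split(seq_len(nrow(table)), key), function(idx) {
    vals <- table$value[idx]
    if (sum(!is.na(vals)) < 4) return(integer())
    out <- grDevices::boxplot.stats(vals[!is.na(vals)])$out
    idx[!is.na(vals) & vals %in% out]
  }), use.names = FALSE)
  removed <- table(key[drop_idx])
  out <- if (length(drop_idx)) table[-drop_idx, , drop = FALSE] else table
  attr(out, "removed") <- removed
  out
}

#' Trait-occasion correlation matrix with significance stars
#'
#' Pearson correlations between every pair of trait-occasion series, matched
#' by `sample_id` with pairwise-complete deletion, with two-sided t-test
#' p-values and the conventional star flags (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001; no multiple-testing correction). Cells with fewer than 3
#' complete pairs or a constant series are `NA`.
#'
#' @param table long-format phenotype table.
#' @param traits traits to include (default: all present).
#' @param occasions occasions to include (default: all present).
#' @return object of class `trait_correlation`: list with matrices `r`, `p`,
#'   `n`, and character `stars`, rows/columns labelled `trait.occasion`.
#' @export
correlation_matrix <- function(table, traits = NULL, occasions = NULL) {
  check_phenotypes(table)
  if (is.null(traits)) traits <- unique(table$trait)
  if (is.null(occasions)) occasions <- unique(table$occasion)
  table <- table[table$trait %in% traits & table$occasion %in% occasions, ]
  samples <- unique(table$sample_id)
  cells <- expand.grid(trait = traits, occasion = occasions,
                       stringsAsFactors = FALSE)
  labels <- paste(cells$trait, cells$occasion, sep = ".")
  wide <- matrix(NA_real_, length(samples), nrow(cells),
                 dimnames = list(samples, labels))
  for (i in seq_len(nrow(cells))) {
    sub <- table[table$trait == cells$trait[i] &
                   table$occasion == cells$occasion[i], ]
    wide[match(sub$sample_id, samples), i] <- sub$value
  }
  keep <- colSums(!is.na(wide)) > 0
  wide <- wide[, keep, drop = FALSE]
  q <- ncol(wide)
  r <- p <- matrix(NA_real_, q, q, dimnames = list(colnames(wide),
                                                   colnames(wide)))
  npair <- matrix(0L, q, q, dimnames = dimnames(r))
  for (i in seq_len(q)) {
    for (j in i:q) {
      ok <- !is.na(wide[, i]) & !is.na(wide[, j])
      npair[i, j] <- npair[j, i] <- sum(ok)
      if (sum(ok) >= 3 && stats::sd(wide[ok, i]) > 0 &&
          stats::sd(wide[ok, j]) > 0) {
        if (i == j) {
          r[i, j] <- 1
          p[i, j] <- 0
        } else {
          ct <- stats::cor.test(wide[ok, i], wide[ok, j])
          r[i, j] <- r[j, i] <- unname(ct$estimate)
          p[i, j] <- p[j, i] <- ct$p.value
        }
      }
    }
  }
  stars <- matrix("", q, q, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  structure(list(r = r, p = p, n = npair, stars = stars),
            class = "trait_correlation")
}

#' @export
print.trait_correlation <- function(x, digits = 3, ...) {
  shown <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                         x$stars),
                  nrow(x$r), dimnames = dimnames(x$r))
  shown[is.na(x$r)] <- "NA"
  print(noquote(shown))
  invisible(x)
}

#' Distribution summary per trait and occasion
#'
#' Boxplot-ready summary statistics — count, mean, minimum, Tukey lower
#' hinge, median, Tukey upper hinge, maximum — for every trait x occasion
#' group present in the table.
#'
#' @param table long-format phenotype table.
#' @return data frame with one row per trait x occasion.
#' @export
distribution_summary <- function(table) {
  check_phenotypes(table)
  if (!nrow(table)) stop("empty phenotype table", call. = FALSE)
  key <- interaction(table$trait, table$occasion, drop = TRUE, sep = "\r")
  rows <- lapply(split(table, key), function(sub) {
    v <- sub$value[!is.na(sub$value)]
    fn <- stats::fivenum(v)
    data.frame(trait = sub$trait[1], occasion = sub$occasion[1],
               n = length(v), mean = mean(v), min = fn[1], q1 = fn[2],
               median = fn[3], q3 = fn[4], max = fn[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
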