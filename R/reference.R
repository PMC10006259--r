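#' Published reference results for perennial ryegrass genomic selection
#'
#' Per-trait summary results reported by a published genomic-selection study
#' of perennial ryegrass, shipped as plain CSV under `inst/extdata` so the
#' package's summary statistics (e.g.
#' [heritability_accuracy_correlation()]) can be exercised against real
#' reported values without access to the underlying breeding-program data,
#' which is not publicly deposited.
#'
#' * `nv_reference()` — nutritive-value traits (crude protein CP,
#'   water-soluble carbohydrates WSC, in vitro dry matter digestibility
#'   IVVDMD) across four seasonal timepoints: narrow-sense heritability and
#'   k-fold prediction accuracy (mean, sd).
#' * `pbr_reference()` — plant breeder's rights traits (heading date HD,
#'   leaf width LW, height H, leaf curvature LC, growth habit GH) across
#'   three years: heritability, k-fold accuracy (mean, sd), forward
#'   prediction (mean, inflation slope), and synthetic-variety
#'   pooled-reference accuracy for HD. `NA` marks trait-year cells that were
#'   not phenotyped or evaluated.
#' * `selection_window_reference()` — mean observed-phenotype range of
#'   10,000 simulated 4-parent groupings per GEBV selection window.
#'
#' @return a data frame.
#' @examples
#' nv <- nv_reference()
#' heritability_accuracy_correlation(nv$h2, nv$kfold_mean)
#' @export
nv_reference <- function() {
  utils::read.csv(system.file("extdata", "nv_reference.csv",
                              package = "forageGS"),
                  stringsAsFactors = FALSE)
}

#' @rdname nv_reference
#' @export
pbr_reference <- function() {
  utils::read.csv(system.file("extdata", "pbr_reference.csv",
                              package = "forageGS"),
                  stringsAsFactors = FALSE)
}

#' @rdname nv_reference
#' @export
selection_window_reference <- function() {
  utils::read.csv(system.file("extdata", "selection_window_reference.csv",
                              package = "forageGS"),
                  stringsAsFactors = FALSE)
}
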