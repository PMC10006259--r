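#' @title Reading and writing genotype and phenotype files
#' @description Plain-text interchange: genotype TSV (rows = samples,
#'   columns = loci, `NA` for missing), minimal unphased VCF with a GT field
#'   only, long-format phenotype CSV, and JSON for QC reports.
#' @name file_io
NULL

#' Write a genotype matrix to TSV
#'
#' @param genotypes dosage matrix (samples x loci).
#' @param path output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  check_genotypes(genotypes)
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' @param path file written by [write_genotypes_tsv()] (first column
#'   `sample_id`, remaining columns loci, `NA` for missing).
#' @return numeric dosage matrix with dimnames.
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(geno) <- "double"
  rownames(geno) <- df[[1]]
  check_genotypes(geno)
  geno
}

#' Write a minimal VCF with genotype (GT) calls only
#'
#' Integer dosages are written as unphased biallelic GT fields (`0/0`,
#' `0/1`, `1/1`, `./.` for missing) with one record per locus on a
#' placeholder chromosome. Continuous pooled rows cannot be represented and
#' are an error.
#'
#' @param genotypes integer dosage matrix.
#' @param path output file.
#' @param chrom,ref,alt recycled per-locus CHROM/REF/ALT fields.
#' @export
write_genotypes_vcf <- function(genotypes, path, chrom = "1", ref = "A",
                                alt = "T") {
  check_genotypes(genotypes, allow_continuous = FALSE)
  genotypes <- label_genotypes(genotypes)
  m <- ncol(genotypes)
  chrom <- rep_len(chrom, m)
  ref <- rep_len(ref, m)
  alt <- rep_len(alt, m)
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    gt <- ifelse(is.na(genotypes[, j]), "./.", gt_code[genotypes[, j] + 1L])
    paste(c(chrom[j], j, colnames(genotypes)[j], ref[j], alt[j], ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Parses GT fields (phased or unphased) into alternative-allele dosages via
#' the vcfR package; any call containing a missing allele becomes `NA`.
#'
#' @param path VCF file.
#' @return list with `genotypes` (samples x loci dosage matrix) and
#'   `alleles` (data frame `locus_id`, `ref`, `alt`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x),
           NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1,
                                       dimnames = list(rownames(gt),
                                                       colnames(gt)))
  geno <- t(dos)
  ids <- rownames(gt)
  if (is.null(ids)) ids <- paste0("L", seq_len(ncol(geno)))
  colnames(geno) <- ids
  list(genotypes = geno,
       alleles = data.frame(locus_id = ids,
                            ref = vcfR::getREF(vcf),
                            alt = vcfR::getALT(vcf),
                            stringsAsFactors = FALSE))
}

#' Write / read long-format phenotype tables
#'
#' CSV with header `sample_id,trait,occasion,cohort,value`.
#'
#' @param table phenotype data frame.
#' @param path file path.
#' @export
write_phenotypes_csv <- function(table, path) {
  check_phenotypes(table)
  if (is.null(table$cohort)) table$cohort <- 1L
  utils::write.csv(table[, c("sample_id", "trait", "occasion", "cohort",
                             "value")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_phenotypes(tbl)
  tbl
}

#' Serialise a QC report to JSON
#'
#' @param report a [qc_report()].
#' @param path output file.
#' @export
write_qc_report_json <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
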