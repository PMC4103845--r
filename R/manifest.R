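#' Bundled gene-to-SNP manifest
#'
#' The packaged manifest lists 61 tagSNPs in the seven nicotinic
#' acetylcholine receptor genes (CHRNA3--CHRNA6, CHRNB2--CHRNB4) used
#' throughout the examples and as the default layout of the synthetic-study
#' generator. SNP identifiers and gene assignments follow the candidate-gene
#' panel of the worked example; chromosome, position, minor-allele frequency
#' and allele labels are synthetic (invented, plausible) values fixed at
#' package build time.
#'
#' @param path optional path to a tab-separated manifest. When `NULL` the
#'   packaged default is returned. A manifest needs at least columns `snp`
#'   and `gene`; the packaged one adds `chrom`, `pos`, `maf`, `minor_allele`
#'   and `major_allele`.
#' @return a data.frame with one row per SNP.
#' @examples
#' m <- gene_manifest()
#' table(m$gene)
#' @export
gene_manifest <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_manifest.tsv",
                                package = "famtpm", mustWork = TRUE)
  read_gene_manifest(path)
}

#' Read a gene-to-SNP manifest file
#'
#' @param path tab-separated file with a header; columns `snp` and `gene`
#'   are required, extra columns are kept.
#' @return a data.frame, one row per SNP.
#' @export
read_gene_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  if (!all(c("snp", "gene") %in% names(m)))
    stop("manifest must have columns 'snp' and 'gene'")
  if (anyDuplicated(m$snp))
    stop("manifest assigns a SNP to more than one gene: ",
         paste(unique(m$snp[duplicated(m$snp)]), collapse = ", "))
  m
}

#' Bundled example p-value tables
#'
#' Two small tables of p-values from a published candidate-gene analysis of
#' nicotinic-receptor variants and four obesity traits (body-mass index,
#' waist circumference, waist-to-hip ratio, percent body fat), bundled as
#' worked-example input for the combination stage: one row per SNP
#' (`example_snp_pvalues()`) or per gene plus a `gene_family` row
#' (`example_gene_pvalues()`).
#'
#' @return a data.frame with columns `snp` and/or `gene` and one p-value
#'   column per trait (`bmi`, `wc`, `whr`, `pbf`).
#' @examples
#' g <- example_gene_pvalues()
#' tpm_statistic(g$wc[g$gene != "gene_family"], tau = 0.05)
#' @export
example_snp_pvalues <- function() {
  utils::read.table(system.file("extdata", "snp_pvalues_example.tsv",
                                package = "famtpm", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname example_snp_pvalues
#' @export
example_gene_pvalues <- function() {
  utils::read.table(system.file("extdata", "gene_pvalues_example.tsv",
                                package = "famtpm", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
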