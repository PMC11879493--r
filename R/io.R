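# Writers for the package's plain-text exchange dialects. Readers for the
# standard formats (VCF, GFF3, BED) live in gasm.R and go through
# vcfR / rtracklayer.

as_snp_data <- function(x) {
  if (inherits(x, "ril_genotypes"))
    return(list(sites = x$sites, geno = x$geno, line_ids = x$line_ids))
  if (inherits(x, "snp_table"))
    return(list(sites = x$sites, geno = x$geno, line_ids = x$line_ids))
  stop_config("expected a ril_genotypes or snp_table object")
}

#' Write genotypes as a coded TSV
#'
#' One row per SNP site with columns `chrom`, `pos`, `id`, then one column
#' per line holding allele codes 0 / 1 / NA.
#'
#' @param x A `ril_genotypes` or `snp_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(x, path) {
  d <- as_snp_data(x)
  out <- cbind(d$sites[, c("chrom", "pos", "id")],
               as.data.frame(t(d$geno)))
  colnames(out) <- c("chrom", "pos", "id", d$line_ids)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (v4.2, GT only)
#'
#' Homozygous allele codes become `0/0` / `1/1`; missing becomes `./.`.
#' REF/ALT are written as A/T placeholders (the simulation tracks allele
#' codes, not nucleotides).
#'
#' @inheritParams write_genotypes_tsv
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  d <- as_snp_data(x)
  gt <- matrix("./.", nrow(d$sites), length(d$line_ids))
  g <- t(d$geno)
  gt[g == 0L] <- "0/0"
  gt[g == 1L] <- "1/1"
  body <- cbind(d$sites$chrom, d$sites$pos, d$sites$id, "A", "T", ".",
                "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", d$line_ids), collapse = "\t")
  ), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write gene annotation as BED (0-based half-open) or GFF3 (1-based closed)
#'
#' @param map A [make_map()] `genetic_map`.
#' @param path Output file path.
#' @param format `"bed"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(map, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  loci <- map$loci
  if (format == "bed") {
    out <- data.frame(loci$chrom_id, loci$bp_start - 1L, loci$bp_end,
                      loci$gene_id)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    writeLines(sprintf("%s\tshadenet\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       loci$chrom_id, loci$bp_start, loci$bp_end,
                       loci$gene_id), con)
  }
  invisible(path)
}

#' Write plot-level phenotype records as long-format CSV
#'
#' Columns: `line`, `env`, `rep`, `condition`, `PH`, `NN`.
#'
#' @param plots Data frame of raw plot records (from
#'   [simulate_phenotypes()] raw mode).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_csv <- function(plots, path) {
  stopifnot(all(c("line", "env", "rep", "condition", "PH", "NN") %in%
                  names(plots)))
  utils::write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write micrograph cell-length records as CSV
#'
#' @param cells Data frame from [simulate_cells()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  stopifnot(all(c("line", "condition", "image_id", "length") %in% names(cells)))
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an expression count matrix and gene lengths as TSV
#'
#' @param expr A [simulate_expression()] object.
#' @param counts_path,lengths_path Output paths for the counts table
#'   (gene_id + one column per sample) and the gene-length table.
#' @return A list with both paths, invisibly.
#' @export
write_counts_tsv <- function(expr, counts_path, lengths_path) {
  counts <- data.frame(gene_id = rownames(expr$counts),
                       expr$counts, check.names = FALSE)
  write.table(counts, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  lens <- data.frame(gene_id = names(expr$lengths), length = expr$lengths)
  write.table(lens, lengths_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(counts = counts_path, lengths = lengths_path))
}

#' Write simulation ground truth as JSON
#'
#' Records QTL effects and planted DE flags so downstream recovery can be
#' scored without re-running the generators.
#'
#' @param arch A [trait_architecture()], or `NULL`.
#' @param expr A [simulate_expression()] object, or `NULL`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(path, arch = NULL, expr = NULL) {
  truth <- list()
  if (!is.null(arch)) {
    truth$qtl <- arch$qtl
    truth$h2_main <- arch$h2_main
    truth$h2_gei <- arch$h2_gei
  }
  if (!is.null(expr)) truth$de <- expr$truth
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
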