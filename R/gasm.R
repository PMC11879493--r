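#' Read a biallelic SNP genotype table from VCF or coded TSV
#'
#' VCF input (v4.2, GT field) is parsed with vcfR; only biallelic sites are
#' kept (multi-allelic sites are skipped and counted). Homozygous genotypes
#' become allele codes 0/1; heterozygous or missing genotypes become `NA`
#' (residual heterozygosity in inbred lines is treated as missing). The TSV
#' dialect is the one written by [write_genotypes_tsv()]: columns `chrom`,
#' `pos`, `id`, then one column per line.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return Object of class `snp_table`: list with `sites` (data frame
#'   `chrom`, `pos`, `id`), `geno` (lines x sites matrix, 0/1/NA),
#'   `line_ids`, and `n_skipped` (multi-allelic site count).
#' @export
read_genotypes <- function(path, format = NULL) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  format <- format %||% if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    code <- matrix(NA_integer_, nrow(gt), ncol(gt))
    code[gt %in% c("0/0", "0|0")] <- 0L
    code[gt %in% c("1/1", "1|1")] <- 1L
    sites <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        id = fix[, "ID"], stringsAsFactors = FALSE)
    geno <- t(code)
    line_ids <- colnames(gt)
    n_skipped <- sum(multi)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "id")
    if (!all(need %in% names(tab)))
      stop_config("TSV must have columns chrom, pos, id + line columns")
    sites <- tab[, need]
    geno <- t(as.matrix(tab[, setdiff(names(tab), need), drop = FALSE]))
    storage.mode(geno) <- "integer"
    bad <- stats::na.omit(unique(as.vector(geno)))
    if (!all(bad %in% c(0L, 1L)))
      stop_config("TSV allele codes must be 0, 1, or NA")
    line_ids <- rownames(geno)
    n_skipped <- 0L
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  geno <- geno[, ord, drop = FALSE]
  if (any(duplicated(paste(sites$chrom, sites$pos))))
    stop_config("duplicate site positions within a chromosome")
  dimnames(geno) <- list(line_ids, sites$id)
  structure(list(sites = sites, geno = geno, line_ids = line_ids,
                 n_skipped = n_skipped),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d lines x %d biallelic sites (%d multi-allelic skipped)\n",
              length(x$line_ids), nrow(x$sites), x$n_skipped))
  invisible(x)
}

#' Read gene annotation intervals from GFF3 or BED
#'
#' Parsed with rtracklayer; coordinates are returned 1-based closed
#' (the GRanges convention; rtracklayer handles the BED offset).
#'
#' @param path Input file.
#' @param format `"gff3"` or `"bed"` (default guessed from the extension).
#' @return Data frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  format <- format %||% if (grepl("\\.bed$", path)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  ids <- if (format == "bed") gr$name else {
    if (!is.null(gr$ID)) gr$ID else gr$Name
  }
  if (is.null(ids) || anyNA(ids))
    stop_config("annotation records lack gene identifiers")
  out <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) stop_config("duplicate gene_id in annotation")
  if (any(out$start > out$end)) stop_config("annotation has start > end")
  out
}

# genetic_map loci as an annotation data frame (convenience for in-memory
# pipelines that skip the GFF3/BED round trip)
map_annotation <- function(map) {
  data.frame(gene_id = map$loci$gene_id, chrom = map$loci$chrom_id,
             start = map$loci$bp_start, end = map$loci$bp_end,
             strand = "+", stringsAsFactors = FALSE)
}

#' Assemble within-gene SNP haplotypes into multi-allelic GASMs
#'
#' For each annotated gene, the alleles of all SNPs inside the gene interval
#' are concatenated per line into a haplotype string; the distinct complete
#' haplotypes observed in the population are the marker's alleles. Genes
#' containing no SNPs are dropped, as are monomorphic markers. A haplotype
#' with missing sites is resolved by the `"match_or_missing"` policy: it is
#' assigned to an allele only when exactly one observed complete haplotype is
#' compatible with its non-missing sites, otherwise the line is missing at
#' that marker. Markers whose call rate falls below `min_call_rate` are
#' dropped.
#'
#' @param snps A `snp_table` (or `ril_genotypes`).
#' @param genes Gene annotation data frame from [read_gene_annotation()]
#'   (1-based closed intervals); strand is ignored (haplotypes read in
#'   ascending position).
#' @param missing_policy Currently `"match_or_missing"`.
#' @param min_call_rate Minimum fraction of non-missing lines (default 0.8:
#'   markers with more than 20% missing lines are dropped).
#' @return Object of class `gasm_set`: list with `gasms` (per marker:
#'   `gene_id`, `chrom`, `site_ids`, `alleles` — haplotype strings ordered
#'   by descending frequency —, `assign` — per-line allele index or `NA` —,
#'   `n_alleles`), `line_ids`, and drop counters (`n_no_snp`,
#'   `n_monomorphic`, `n_low_call`).
#' @export
assemble_gasms <- function(snps, genes, missing_policy = "match_or_missing",
                           min_call_rate = 0.8) {
  if (missing_policy != "match_or_missing")
    stop_config("unknown missing_policy: %s", missing_policy)
  d <- as_snp_data(snps)
  n_lines <- length(d$line_ids)
  gasms <- list()
  n_no_snp <- n_mono <- n_low <- 0L
  for (i in seq_len(nrow(genes))) {
    in_gene <- d$sites$chrom == genes$chrom[i] &
      d$sites$pos >= genes$start[i] & d$sites$pos <= genes$end[i]
    if (!any(in_gene)) { n_no_snp <- n_no_snp + 1L; next }
    sub <- d$geno[, in_gene, drop = FALSE]
    hap_chr <- matrix(as.character(sub), nrow = n_lines)
    hap_chr[is.na(sub)] <- "."
    haps <- apply(hap_chr, 1, paste, collapse = "")
    complete <- !grepl(".", haps, fixed = TRUE)
    tab <- sort(table(haps[complete]), decreasing = TRUE)
    alleles <- names(tab)
    assign <- rep(NA_integer_, n_lines)
    assign[complete] <- match(haps[complete], alleles)
    if (any(!complete) && length(alleles) > 0) {
      amat <- do.call(rbind, strsplit(alleles, ""))
      for (j in which(!complete)) {
        h <- strsplit(haps[j], "")[[1]]
        known <- h != "."
        if (!any(known)) next
        compat <- which(colSums(t(amat[, known, drop = FALSE]) != h[known]) == 0)
        if (length(compat) == 1L) assign[j] <- compat
      }
    }
    if (length(alleles) < 2L) { n_mono <- n_mono + 1L; next }
    if (mean(!is.na(assign)) < min_call_rate) { n_low <- n_low + 1L; next }
    gasms[[length(gasms) + 1L]] <- list(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      site_ids = d$sites$id[in_gene],
      alleles = alleles,
      assign = setNames(assign, d$line_ids),
      n_alleles = length(alleles)
    )
  }
  if (length(gasms) == 0L)
    warning("no polymorphic GASMs assembled (empty SNP/gene overlap?)")
  structure(
    list(gasms = gasms, line_ids = d$line_ids, n_no_snp = n_no_snp,
         n_monomorphic = n_mono, n_low_call = n_low),
    class = "gasm_set"
  )
}

#' @export
print.gasm_set <- function(x, ...) {
  cat(sprintf(
    "gasm_set: %d markers x %d lines (dropped: %d no-SNP, %d monomorphic, %d low call rate)\n",
    length(x$gasms), length(x$line_ids), x$n_no_snp, x$n_monomorphic,
    x$n_low_call
  ))
  invisible(x)
}

#' Summary counts for an assembled GASM set
#'
#' @param gasms A [assemble_gasms()] `gasm_set`.
#' @return List with `total`, `per_chromosome` (named counts), and
#'   `allele_histogram` (markers per allele count).
#' @export
gasm_summary <- function(gasms) {
  stopifnot(inherits(gasms, "gasm_set"))
  if (length(gasms$gasms) == 0) {
    warning("empty GASM set")
    return(list(total = 0L, per_chromosome = integer(0),
                allele_histogram = integer(0)))
  }
  chrom <- vapply(gasms$gasms, `[[`, "", "chrom")
  n_all <- vapply(gasms$gasms, `[[`, 0L, "n_alleles")
  list(total = length(gasms$gasms),
       per_chromosome = table(chrom),
       allele_histogram = table(n_all))
}

#' Write / read GASM allele assignments as TSV
#'
#' One row per marker: `gene_id`, `chrom`, `alleles` (haplotype strings
#' joined by `;`), then one column per line with the allele index (1-based,
#' `NA` for missing).
#'
#' @param gasms A `gasm_set`.
#' @param path File path.
#' @return `path` (writer) or a `gasm_set` without `site_ids` (reader).
#' @export
write_gasms_tsv <- function(gasms, path) {
  stopifnot(inherits(gasms, "gasm_set"))
  rows <- lapply(gasms$gasms, function(g) {
    c(gene_id = g$gene_id, chrom = g$chrom,
      alleles = paste(g$alleles, collapse = ";"),
      setNames(as.character(g$assign), names(g$assign)))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gasms_tsv
#' @export
read_gasms_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  line_ids <- setdiff(names(tab), c("gene_id", "chrom", "alleles"))
  gasms <- lapply(seq_len(nrow(tab)), function(i) {
    alleles <- strsplit(tab$alleles[i], ";", fixed = TRUE)[[1]]
    list(gene_id = tab$gene_id[i], chrom = tab$chrom[i],
         site_ids = NULL, alleles = alleles,
         assign = setNames(as.integer(tab[i, line_ids]), line_ids),
         n_alleles = length(alleles))
  })
  structure(list(gasms = gasms, line_ids = line_ids, n_no_snp = NA_integer_,
                 n_monomorphic = NA_integer_, n_low_call = NA_integer_),
            class = "gasm_set")
}
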