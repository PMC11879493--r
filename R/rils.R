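# Meiosis engine shared by the RIL simulator and the linkage-model
# recombination-potential predictor.
#
# Haplotypes are 0/1 matrices (individuals x loci) coding parental origin.
# A gamete follows a Markov chain along the ordered loci: the starting
# haplotype is chosen at random per chromosome and switches between the two
# parental haplotypes at each interval with the Haldane recombination
# fraction for that interval (r = 0.5 across chromosome boundaries).
make_gametes <- function(h1, h2, r) {
  n <- nrow(h1)
  L <- ncol(h1)
  use2 <- matrix(FALSE, n, L)
  use2[, 1] <- runif(n) < 0.5
  if (L > 1) {
    for (l in 2:L) {
      sw <- runif(n) < r[l]
      use2[, l] <- xor(use2[, l - 1], sw)
    }
  }
  out <- h1
  out[use2] <- h2[use2]
  out
}

#' Simulate a biparental RIL population by single-seed descent
#'
#' Starting from the F1 of two fully inbred parents (P1 carries allele 0 at
#' every SNP, P2 allele 1), each line is advanced by `n_selfing_gens` rounds
#' of self-fertilisation with one offspring kept per generation (single-seed
#' descent). Meiosis uses the Haldane map function with no interference. All
#' SNPs within a gene locus inherit that locus's parental origin (gene bp
#' spans are negligible on the cM scale, so intra-gene crossovers are not
#' simulated).
#'
#' @param map A [make_map()] `genetic_map`.
#' @param n_lines Number of RILs (>= 2).
#' @param n_selfing_gens Number of selfing generations after the F1 (>= 1);
#'   6 corresponds to F7 lines, with residual per-locus heterozygosity
#'   about 2^-6.
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `ril_genotypes`: list with `line_ids`,
#'   `source` (lines x loci character matrix with values `"P1"`, `"P2"`,
#'   `"HET"`), `geno` (lines x SNP-sites integer matrix, 0 = P1 allele,
#'   1 = P2 allele, `NA` at residually heterozygous loci), `sites`
#'   (data frame `chrom`, `pos`, `id`, `gene_id`), `generation` (e.g.
#'   `"F7"`), and the `map`.
#' @examples
#' map <- make_map(2, 5, 100, 2, seed = 1)
#' rils <- simulate_rils(map, 20, 6, seed = 2)
#' table(rils$source)
#' @export
simulate_rils <- function(map, n_lines, n_selfing_gens = 6, seed = NULL) {
  if (!inherits(map, "genetic_map") || nrow(map$loci) == 0)
    stop_config("`map` must be a non-empty genetic_map")
  check_number(n_lines, "n_lines", min = 2, integer = TRUE)
  check_number(n_selfing_gens, "n_selfing_gens", min = 1, integer = TRUE)
  L <- nrow(map$loci)
  r <- interval_recomb(map)

  with_seed(seed, {
    h1 <- matrix(0L, n_lines, L) # F1: one chromosome set from each parent
    h2 <- matrix(1L, n_lines, L)
    for (g in seq_len(n_selfing_gens)) {
      g1 <- make_gametes(h1, h2, r)
      g2 <- make_gametes(h1, h2, r)
      h1 <- g1
      h2 <- g2
    }
    src <- matrix("HET", n_lines, L)
    src[h1 == 0L & h2 == 0L] <- "P1"
    src[h1 == 1L & h2 == 1L] <- "P2"
    colnames(src) <- map$loci$gene_id
    line_ids <- sprintf("RIL%03d", seq_len(n_lines))
    rownames(src) <- line_ids

    # expand locus origin to per-SNP alleles
    n_snps <- map$loci$n_snps
    locus_of_site <- rep(seq_len(L), n_snps)
    geno <- matrix(NA_integer_, n_lines, sum(n_snps))
    fixed1 <- h1 == h2
    allele <- matrix(NA_integer_, n_lines, L)
    allele[fixed1] <- h1[fixed1]
    geno[] <- allele[, locus_of_site]
    snp_in_gene <- sequence(n_snps)
    sites <- data.frame(
      chrom = map$loci$chrom_id[locus_of_site],
      pos = map$loci$bp_start[locus_of_site] +
        (snp_in_gene - 1) * pmax(1, floor(1999 / pmax(n_snps[locus_of_site], 1))),
      id = sprintf("%s_snp%d", map$loci$gene_id[locus_of_site], snp_in_gene),
      gene_id = map$loci$gene_id[locus_of_site],
      stringsAsFactors = FALSE
    )
    colnames(geno) <- sites$id
    rownames(geno) <- line_ids
    structure(
      list(
        line_ids = line_ids, source = src, geno = geno, sites = sites,
        generation = sprintf("F%d", n_selfing_gens + 1), map = map
      ),
      class = "ril_genotypes"
    )
  })
}

#' @export
print.ril_genotypes <- function(x, ...) {
  het <- mean(x$source == "HET")
  cat(sprintf(
    "ril_genotypes: %d %s lines x %d loci (%d SNPs), %.2f%% residual het\n",
    length(x$line_ids), x$generation, ncol(x$source), ncol(x$geno), 100 * het
  ))
  invisible(x)
}
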