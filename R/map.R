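#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction under
#' the Haldane mapping function (independent crossovers, no interference):
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM Numeric vector of map distances in centimorgans (>= 0).
#' @return Recombination fractions in [0, 0.5).
#' @examples
#' haldane(c(0, 10, 50, Inf))
#' @export
haldane <- function(d_cM) {
  if (any(d_cM < 0)) stop_config("map distances must be non-negative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Expected recombinant-line fraction between two loci in selfed RILs
#'
#' For recombinant inbred lines derived by repeated selfing to fixation, the
#' expected fraction of lines recombinant between two loci with single-meiosis
#' recombination fraction `r` is R = 2r / (1 + 2r).
#'
#' @param r Single-meiosis recombination fraction(s) in [0, 0.5].
#' @return Expected recombinant-line fraction(s).
#' @examples
#' ril_recomb_fraction(haldane(10))
#' @export
ril_recomb_fraction <- function(r) {
  if (any(r < 0 | r > 0.5)) stop_config("r must be in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Build a synthetic genetic map of gene loci
#'
#' Lays out `genes_per_chrom` gene loci per chromosome, approximately
#' uniformly spaced with random jitter, each carrying a stated number of SNPs
#' and a base-pair interval (non-overlapping within a chromosome).
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param genes_per_chrom Gene loci per chromosome (>= 1).
#' @param chrom_length_cM Chromosome length in centimorgans (> 0); recycled
#'   across chromosomes.
#' @param snps_per_gene Either a single SNP count per gene or a length-2 range
#'   `c(min, max)` from which counts are drawn uniformly.
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return An object of class `genetic_map`: a list with data frames
#'   `chromosomes` (`chrom_id`, `length_cM`) and `loci` (`gene_id`,
#'   `chrom_id`, `pos_cM`, `bp_start`, `bp_end`, `n_snps`), loci sorted by
#'   chromosome then position.
#' @examples
#' map <- make_map(2, 10, 120, c(1, 4), seed = 1)
#' head(map$loci)
#' @export
make_map <- function(n_chrom, genes_per_chrom, chrom_length_cM,
                     snps_per_gene = c(1, 5), seed = NULL) {
  check_number(n_chrom, "n_chrom", min = 1, integer = TRUE)
  check_number(genes_per_chrom, "genes_per_chrom", min = 1, integer = TRUE)
  if (any(chrom_length_cM <= 0)) stop_config("chrom_length_cM must be > 0")
  if (length(snps_per_gene) == 1L) snps_per_gene <- rep(snps_per_gene, 2L)
  if (snps_per_gene[1] < 1) stop_config("snps_per_gene must be >= 1")
  lens <- rep_len(chrom_length_cM, n_chrom)

  with_seed(seed, {
    loci <- vector("list", n_chrom)
    for (ch in seq_len(n_chrom)) {
      g <- genes_per_chrom
      # uniform grid with jitter, kept strictly increasing inside (0, L)
      grid <- (seq_len(g) - 0.5) / g * lens[ch]
      jit <- runif(g, -0.3, 0.3) * lens[ch] / g
      pos <- sort(pmin(pmax(grid + jit, 0), lens[ch]))
      # enforce strict increase in degenerate jitter cases
      pos <- pos + seq_len(g) * 1e-9
      pos <- pmin(pos, lens[ch])
      n_snps <- if (snps_per_gene[1] == snps_per_gene[2]) {
        rep(snps_per_gene[1], g)
      } else {
        sample(seq(snps_per_gene[1], snps_per_gene[2]), g, replace = TRUE)
      }
      # bp positions: 1 cM ~ 4e5 bp; gene span 2 kb, grid spacing guarantees
      # non-overlap for the simulated densities
      bp_start <- round(pos * 4e5) + 1
      bp_end <- bp_start + 1999
      loci[[ch]] <- data.frame(
        gene_id = sprintf("g%02d_%03d", ch, seq_len(g)),
        chrom_id = sprintf("chr%02d", ch),
        pos_cM = pos, bp_start = bp_start, bp_end = bp_end,
        n_snps = n_snps, stringsAsFactors = FALSE
      )
    }
    loci <- do.call(rbind, loci)
    rownames(loci) <- NULL
    structure(
      list(
        chromosomes = data.frame(
          chrom_id = sprintf("chr%02d", seq_len(n_chrom)),
          length_cM = lens, stringsAsFactors = FALSE
        ),
        loci = loci
      ),
      class = "genetic_map"
    )
  })
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "genetic_map: %d chromosomes, %d gene loci, %d SNPs total\n",
    nrow(x$chromosomes), nrow(x$loci), sum(x$loci$n_snps)
  ))
  invisible(x)
}

# adjacent-interval recombination fractions per chromosome; first locus of
# each chromosome gets r = 0.5 (new chromosome => free assortment)
interval_recomb <- function(map) {
  loci <- map$loci
  r <- numeric(nrow(loci))
  r[1] <- 0.5
  if (nrow(loci) > 1) {
    same <- loci$chrom_id[-1] == loci$chrom_id[-nrow(loci)]
    d <- diff(loci$pos_cM)
    r[-1] <- ifelse(same, haldane(pmax(d, 0)), 0.5)
  }
  r
}
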