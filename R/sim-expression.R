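#' Simulate a negative-binomial RNA-seq count matrix with planted DE genes
#'
#' Emulates a 2-genotype x 2-condition x `n_rep` expression experiment.
#' Baseline gene means are drawn log-uniformly from `mean_range`; for each
#' genotype a fraction `de_fraction` of genes is planted as differentially
#' expressed between shade and control with |log2 fold change| drawn
#' uniformly from `lfc_range` and random sign. Counts are negative binomial
#' with common gene-wise `dispersion` (0 gives Poisson).
#'
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes planted DE per contrast, in [0, 1].
#' @param lfc_range Length-2 non-negative range of |log2FC| for planted DE.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2), >= 0.
#' @param mean_range Length-2 range of baseline means (counts).
#' @param n_rep Replicates per genotype x condition cell.
#' @param seed Integer seed, or `NULL`.
#' @return Object of class `sim_expression`: list with `counts` (genes x
#'   samples integer matrix), `lengths` (gene lengths, bp), `samples`
#'   (data frame `sample`, `genotype` in G/Z, `condition` in S/CK, `rep`),
#'   and `truth` (per gene: `is_de_G`, `lfc_G`, `is_de_Z`, `lfc_Z`).
#' @examples
#' ex <- simulate_expression(500, 0.1, c(1, 3), 0.05, seed = 1)
#' table(ex$truth$is_de_G)
#' @export
simulate_expression <- function(n_genes, de_fraction = 0.1,
                                lfc_range = c(1, 3), dispersion = 0.05,
                                mean_range = c(20, 2000), n_rep = 3,
                                seed = NULL) {
  check_number(n_genes, "n_genes", min = 1, integer = TRUE)
  check_number(de_fraction, "de_fraction", min = 0, max = 1)
  if (length(lfc_range) != 2 || any(lfc_range < 0) || lfc_range[1] > lfc_range[2])
    stop_config("lfc_range must be an increasing non-negative pair")
  if (dispersion < 0) stop_config("dispersion must be >= 0")
  check_number(n_rep, "n_rep", min = 2, integer = TRUE)

  samples <- expand.grid(rep = seq_len(n_rep), condition = c("S", "CK"),
                         genotype = c("G", "Z"), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = sprintf("%s_%s_r%d", samples$genotype, samples$condition,
                     samples$rep),
    genotype = samples$genotype, condition = samples$condition,
    rep = samples$rep, stringsAsFactors = FALSE
  )

  with_seed(seed, {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    base_mu <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
    lengths <- sample(500:5000, n_genes, replace = TRUE)
    plant <- function() {
      is_de <- runif(n_genes) < de_fraction
      lfc <- numeric(n_genes)
      lfc[is_de] <- sample(c(-1, 1), sum(is_de), replace = TRUE) *
        runif(sum(is_de), lfc_range[1], lfc_range[2])
      list(is_de = is_de, lfc = lfc)
    }
    pg <- plant()
    pz <- plant()
    # shade mean = baseline * 2^lfc for the planted genotype contrast
    mu <- matrix(rep(base_mu, nrow(samples)), n_genes, nrow(samples))
    sh_g <- samples$genotype == "G" & samples$condition == "S"
    sh_z <- samples$genotype == "Z" & samples$condition == "S"
    mu[, sh_g] <- mu[, sh_g] * 2^pg$lfc
    mu[, sh_z] <- mu[, sh_z] * 2^pz$lfc
    counts <- matrix(0L, n_genes, nrow(samples),
                     dimnames = list(gene_id, samples$sample))
    for (j in seq_len(nrow(samples))) {
      counts[, j] <- if (dispersion > 0) {
        rnbinom(n_genes, mu = mu[, j], size = 1 / dispersion)
      } else {
        stats::rpois(n_genes, mu[, j])
      }
    }
    structure(
      list(
        counts = counts, lengths = setNames(lengths, gene_id),
        samples = samples,
        truth = data.frame(gene_id = gene_id,
                           is_de_G = pg$is_de, lfc_G = pg$lfc,
                           is_de_Z = pz$is_de, lfc_Z = pz$lfc,
                           stringsAsFactors = FALSE)
      ),
      class = "sim_expression"
    )
  })
}

#' @export
print.sim_expression <- function(x, ...) {
  cat(sprintf(
    "sim_expression: %d genes x %d samples, %d/%d planted DE (G/Z contrasts)\n",
    nrow(x$counts), ncol(x$counts), sum(x$truth$is_de_G), sum(x$truth$is_de_Z)
  ))
  invisible(x)
}
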