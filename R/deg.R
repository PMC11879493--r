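#' FPKM from a count matrix
#'
#' FPKM_gs = counts_gs * 1e9 / (length_g * libsize_s), with library size
#' the column sum of counts.
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @param lengths Gene lengths in bp (> 0), recycled along rows.
#' @return FPKM matrix with the same dimnames.
#' @examples
#' fpkm(matrix(100), 1000) * 1 # libsize 100 here
#' @export
fpkm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop_config("gene lengths must be > 0")
  if (length(lengths) != nrow(counts))
    stop_config("lengths must match the number of genes")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_config("zero library size in sample(s): %s",
                                 paste(which(lib <= 0), collapse = ", "))
  sweep(counts / lengths, 2, lib, "/") * 1e9
}

# vectorised Welch two-sample t-test on rows; returns two-sided P
welch_rows <- function(A, B) {
  nA <- ncol(A)
  nB <- ncol(B)
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[se2 == 0 & mA == mB] <- 1 # identical constant groups: no evidence
  data.frame(t = t, df = df, p = p)
}

#' Threshold-based differential-expression calls
#'
#' For each gene, log2FC = log2((mean FPKM_shade + c) / (mean FPKM_control
#' + c)) with pseudocount `c`, and P from a two-sample Welch t-test on
#' log2(FPKM + c) across replicates. A gene is called when `P <= p_max` AND
#' `|log2FC| >= lfc_min` (both thresholds inclusive); direction is the sign
#' of log2FC. Optionally P values are BH-adjusted before thresholding.
#'
#' @param expr A [simulate_expression()] object, or a list with `counts`,
#'   `lengths`, `samples` (`sample`, `genotype`, `condition`, `rep`).
#' @param genotype Which genotype's shade-vs-control contrast to test.
#' @param p_max P-value threshold (default 0.05).
#' @param lfc_min Absolute log2 fold-change threshold (default 0.807).
#' @param pseudocount Pseudocount `c` added to mean FPKM and to FPKM before
#'   the log for the t-test (default 1).
#' @param fdr Apply Benjamini-Hochberg adjustment before thresholding?
#'   Off by default (raw per-gene P rule).
#' @return Object of class `deg_calls`: data frame `gene_id`, `log2fc`,
#'   `p`, `direction` (`"up"` / `"down"`), one row per called gene;
#'   attributes `contrast`, `n_tested`.
#' @export
call_degs <- function(expr, genotype = "G", p_max = 0.05, lfc_min = 0.807,
                      pseudocount = 1, fdr = FALSE) {
  stopifnot(!is.null(expr$counts), !is.null(expr$lengths),
            !is.null(expr$samples))
  sm <- expr$samples
  sel_s <- sm$genotype == genotype & sm$condition == "S"
  sel_c <- sm$genotype == genotype & sm$condition == "CK"
  if (sum(sel_s) < 2 || sum(sel_c) < 2)
    stop_config("need >= 2 replicates per group for contrast %s", genotype)
  f <- fpkm(expr$counts, expr$lengths)
  lfc <- log2((rowMeans(f[, sel_s, drop = FALSE]) + pseudocount) /
                (rowMeans(f[, sel_c, drop = FALSE]) + pseudocount))
  wt <- welch_rows(log2(f[, sel_s, drop = FALSE] + pseudocount),
                   log2(f[, sel_c, drop = FALSE] + pseudocount))
  p <- if (fdr) stats::p.adjust(wt$p, "BH") else wt$p
  hit <- !is.na(p) & p <= p_max & abs(lfc) >= lfc_min
  out <- data.frame(
    gene_id = rownames(expr$counts)[hit],
    log2fc = lfc[hit], p = p[hit],
    direction = ifelse(lfc[hit] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "contrast") <- sprintf("%s_S_vs_CK", genotype)
  attr(out, "n_tested") <- nrow(expr$counts)
  class(out) <- c("deg_calls", class(out))
  out
}

#' Venn partition of two DEG call lists with trend classification
#'
#' Exact set arithmetic on gene ids, with shared genes split by whether the
#' two contrasts agree in direction (same trend: up-up or down-down) or
#' disagree (opposite trend).
#'
#' @param calls_a,calls_b [call_degs()] results (data frames with
#'   `gene_id`, `direction`).
#' @return List with `unique_a` / `unique_b` (each `n`, `up`, `down`),
#'   `shared` (`n`, `same_trend`, `opposite_trend`, and the same/opposite
#'   up/down splits), `total_a`, `total_b`, `union_total`.
#' @export
venn_partition <- function(calls_a, calls_b) {
  for (d in list(calls_a, calls_b)) {
    if (anyDuplicated(d$gene_id))
      stop_config("duplicate gene ids in a call list")
  }
  ga <- calls_a$gene_id
  gb <- calls_b$gene_id
  shared <- intersect(ga, gb)
  ua <- setdiff(ga, gb)
  ub <- setdiff(gb, ga)
  dira <- setNames(calls_a$direction, ga)
  dirb <- setNames(calls_b$direction, gb)
  same <- shared[dira[shared] == dirb[shared]]
  opp <- setdiff(shared, same)
  res <- list(
    unique_a = list(n = length(ua), up = sum(dira[ua] == "up"),
                    down = sum(dira[ua] == "down")),
    unique_b = list(n = length(ub), up = sum(dirb[ub] == "up"),
                    down = sum(dirb[ub] == "down")),
    shared = list(
      n = length(shared), same_trend = length(same),
      opposite_trend = length(opp),
      same_up = sum(dira[same] == "up"),
      same_down = sum(dira[same] == "down"),
      opposite_a_up = sum(dira[opp] == "up"),
      opposite_a_down = sum(dira[opp] == "down")
    ),
    total_a = length(ga), total_b = length(gb),
    union_total = length(ua) + length(ub) + length(shared)
  )
  stopifnot(res$union_total == length(union(ga, gb))) # identity check
  res
}

#' Intersect DEG calls with GWAS gene lists
#'
#' Gene ids are normalised (trimmed, upper-cased) before matching; output
#' carries provenance columns.
#'
#' @param calls A `deg_calls` data frame.
#' @param gwas_genes Data frame with `gene_id` and optionally `trait` and
#'   `class` (LC/SC) columns, or a character vector of ids.
#' @return Data frame of shared genes: `gene_id`, `direction`, `log2fc`,
#'   plus any GWAS provenance columns.
#' @export
intersect_gwas <- function(calls, gwas_genes) {
  norm <- function(x) toupper(trimws(x))
  if (is.character(gwas_genes))
    gwas_genes <- data.frame(gene_id = gwas_genes, stringsAsFactors = FALSE)
  key_deg <- norm(calls$gene_id)
  key_gwas <- norm(gwas_genes$gene_id)
  m <- match(key_deg, key_gwas)
  hit <- !is.na(m)
  out <- data.frame(gene_id = calls$gene_id[hit],
                    direction = calls$direction[hit],
                    log2fc = calls$log2fc[hit], stringsAsFactors = FALSE)
  extra <- setdiff(names(gwas_genes), "gene_id")
  for (cn in extra) out[[cn]] <- gwas_genes[[cn]][m[hit]]
  rownames(out) <- NULL
  out
}
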