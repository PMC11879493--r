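#' Build the gene-allele matrix of main-effect values
#'
#' Rows are lines, columns the selected loci in genetic-map order; entries
#' are the deviation-coded main-effect values of the allele each line
#' carries. Lines missing at a locus get `NA` (treated as a 0 /
#' population-mean contribution by the potential predictors, and flagged).
#'
#' @param fit A [stage2_stepwise()] `multilocus_fit` with at least one
#'   main-effect locus.
#' @param genotypes A `gasm_set` supplying allele assignments (defaults to
#'   the one stored in the fit).
#' @param direction `"smaller_better"` (shade-tolerance semantics: lower
#'   indicator = more tolerant) or `"larger_better"`.
#' @return Object of class `gene_allele_matrix`: list with `effects`
#'   (lines x loci), `loci` (data frame `gene_id`, `chrom`), `mu`,
#'   `direction`, `line_ids`.
#' @export
build_matrix <- function(fit, genotypes = NULL,
                         direction = c("smaller_better", "larger_better")) {
  stopifnot(inherits(fit, "multilocus_fit"))
  direction <- match.arg(direction)
  genotypes <- genotypes %||% fit$gasms
  eff <- allele_effects(fit)
  loci_ids <- unique(eff$gene_id)
  if (length(loci_ids) == 0) stop_config("fit has no main-effect loci")
  gene_ids_all <- vapply(genotypes$gasms, `[[`, "", "gene_id")
  idx <- match(loci_ids, gene_ids_all)
  if (anyNA(idx))
    stop_config("loci missing from genotypes: %s",
                paste(loci_ids[is.na(idx)], collapse = ", "))
  n <- length(genotypes$line_ids)
  E <- matrix(NA_real_, n, length(loci_ids),
              dimnames = list(genotypes$line_ids, loci_ids))
  for (k in seq_along(loci_ids)) {
    g <- genotypes$gasms[[idx[k]]]
    e <- eff$effect[eff$gene_id == loci_ids[k]]
    # effects are ordered as g$alleles in allele_effects()
    E[, k] <- e[g$assign]
  }
  structure(
    list(effects = E,
         loci = data.frame(gene_id = loci_ids,
                           chrom = vapply(genotypes$gasms[idx], `[[`, "", "chrom"),
                           stringsAsFactors = FALSE),
         mu = fit$mu, direction = direction,
         line_ids = genotypes$line_ids),
    class = "gene_allele_matrix"
  )
}

#' @export
print.gene_allele_matrix <- function(x, ...) {
  cat(sprintf("gene_allele_matrix: %d lines x %d loci (mu = %.4g, %s)\n",
              nrow(x$effects), ncol(x$effects), x$mu, x$direction))
  invisible(x)
}

#' Predicted genotypic values of the lines themselves
#'
#' mu + row sum of allele-effect values (missing loci contribute 0).
#'
#' @param matrix A [build_matrix()] `gene_allele_matrix`.
#' @return Named numeric vector.
#' @export
genotypic_values <- function(matrix) {
  stopifnot(inherits(matrix, "gene_allele_matrix"))
  E <- matrix$effects
  E[is.na(E)] <- 0
  setNames(matrix$mu + rowSums(E), matrix$line_ids)
}

resolve_pair <- function(matrix, i, j) {
  ids <- matrix$line_ids
  ii <- if (is.character(i)) match(i, ids) else as.integer(i)
  jj <- if (is.character(j)) match(j, ids) else as.integer(j)
  if (is.na(ii) || is.na(jj) || ii < 1 || jj < 1 || ii > length(ids) ||
      jj > length(ids))
    stop_config("unknown line in pair (%s, %s)", i, j)
  c(ii, jj)
}

#' Recombination potential of a cross under independent assortment
#'
#' The genotypic value of the optimal transgressive progeny under free
#' assortment: mu + the per-locus favorable extreme of the two parents'
#' allele-effect values (minimum for `smaller_better`). Missing effects
#' contribute 0 (population mean).
#'
#' @param matrix A `gene_allele_matrix`.
#' @param i,j Line indices or ids (`i == j` returns the line's own
#'   predicted genotypic value).
#' @return List of class `pair_potential`: `i`, `j`, `model`
#'   (`"independent"`), `value`, `n_missing` (loci with a missing effect in
#'   either parent).
#' @export
potential_independent <- function(matrix, i, j) {
  stopifnot(inherits(matrix, "gene_allele_matrix"))
  p <- resolve_pair(matrix, i, j)
  ei <- matrix$effects[p[1], ]
  ej <- matrix$effects[p[2], ]
  n_missing <- sum(is.na(ei) | is.na(ej))
  ei[is.na(ei)] <- 0
  ej[is.na(ej)] <- 0
  best <- if (matrix$direction == "smaller_better") pmin(ei, ej) else pmax(ei, ej)
  structure(
    list(i = matrix$line_ids[p[1]], j = matrix$line_ids[p[2]],
         model = "independent", value = matrix$mu + sum(best),
         n_missing = n_missing),
    class = "pair_potential"
  )
}

#' @export
print.pair_potential <- function(x, ...) {
  cat(sprintf("pair_potential[%s]: %s x %s -> %.4f\n",
              x$model, x$i, x$j, x$value))
  invisible(x)
}

#' Recombination potential of a cross under the linkage model
#'
#' Monte-Carlo definition: simulate `n_progeny` inbred progeny of the cross
#' i x j by map-based meiosis (Haldane, single-seed descent for
#' `generations` selfing rounds), score each progeny as mu + the sum of its
#' inherited allele-effect values (residually heterozygous loci contribute
#' the parental mean), and return the favorable extreme (or the stated
#' favorable-tail quantile). Linkage between loci restricts which allele
#' combinations are reachable, so this value is never better than the
#' free-assortment potential (up to Monte-Carlo noise).
#'
#' @inheritParams potential_independent
#' @param map A `genetic_map` covering every matrix locus.
#' @param n_progeny Number of simulated progeny (>= 1).
#' @param generations Selfing generations (default 5, i.e. F6 progeny).
#' @param quantile Favorable-tail quantile in [0, 1); 0 returns the extreme.
#' @param seed Integer seed, or `NULL`.
#' @return A `pair_potential` with `model = "linkage"` plus the Monte-Carlo
#'   parameters.
#' @export
potential_linkage <- function(matrix, map, i, j, n_progeny = 1000,
                              generations = 5, quantile = 0, seed = NULL) {
  stopifnot(inherits(matrix, "gene_allele_matrix"),
            inherits(map, "genetic_map"))
  check_number(n_progeny, "n_progeny", min = 1, integer = TRUE)
  check_number(generations, "generations", min = 1, integer = TRUE)
  check_number(quantile, "quantile", min = 0, max = 1)
  p <- resolve_pair(matrix, i, j)
  idx <- match(matrix$loci$gene_id, map$loci$gene_id)
  if (anyNA(idx))
    stop_config("matrix loci absent from map: %s",
                paste(matrix$loci$gene_id[is.na(idx)], collapse = ", "))
  ord <- order(idx)
  sub <- map$loci[idx[ord], , drop = FALSE]
  submap <- structure(list(chromosomes = map$chromosomes, loci = sub),
                      class = "genetic_map")
  r <- interval_recomb(submap)
  ei <- matrix$effects[p[1], ord]
  ej <- matrix$effects[p[2], ord]
  ei[is.na(ei)] <- 0
  ej[is.na(ej)] <- 0
  L <- length(ei)
  vals <- with_seed(seed, {
    h1 <- matrix(0L, n_progeny, L) # 0 = allele from parent i, 1 = from j
    h2 <- matrix(1L, n_progeny, L)
    for (g in seq_len(generations)) {
      g1 <- make_gametes(h1, h2, r)
      g2 <- make_gametes(h1, h2, r)
      h1 <- g1
      h2 <- g2
    }
    Em <- matrix(rep(ei, each = n_progeny), n_progeny, L)
    Em[h1 == 1L] <- rep(ej, each = n_progeny)[h1 == 1L]
    Em2 <- matrix(rep(ei, each = n_progeny), n_progeny, L)
    Em2[h2 == 1L] <- rep(ej, each = n_progeny)[h2 == 1L]
    matrix$mu + rowSums((Em + Em2) / 2)
  })
  value <- if (matrix$direction == "smaller_better") {
    if (quantile == 0) min(vals) else quantile(vals, quantile, names = FALSE)
  } else {
    if (quantile == 0) max(vals) else quantile(vals, 1 - quantile, names = FALSE)
  }
  structure(
    list(i = matrix$line_ids[p[1]], j = matrix$line_ids[p[2]],
         model = "linkage", value = value, n_progeny = n_progeny,
         generations = generations, quantile = quantile, seed = seed),
    class = "pair_potential"
  )
}

#' Recombination potentials of all line pairs with percentile summary
#'
#' Evaluates every unordered pair (n(n-1)/2 crosses). Under the independent
#' model the per-pair value has the closed form used by
#' [potential_independent()] and is computed for all pairs via the L1
#' distance identity min(a,b) = (a + b - |a - b|)/2. Under the linkage
#' model each pair is scored by [potential_linkage()] (Monte-Carlo; intended
#' for moderate n). The summary reports deciles plus the favorable-tail
#' 10th percentile (linear interpolation between order statistics).
#'
#' @param matrix A `gene_allele_matrix`.
#' @param model `"independent"` or `"linkage"`.
#' @param map Required for the linkage model.
#' @param n_progeny,generations,quantile,seed Linkage-model parameters.
#' @param keep_pairs Return the per-pair table?
#' @return Object of class `potential_summary`: list with `n_lines`,
#'   `n_pairs`, `model`, `percentiles` (0-100% deciles), `p10_favorable`,
#'   `best`, and optionally `pairs` (data frame `i`, `j`, `value`).
#' @export
summarize_pairs <- function(matrix, model = c("independent", "linkage"),
                            map = NULL, n_progeny = 1000, generations = 5,
                            quantile = 0, seed = NULL, keep_pairs = FALSE) {
  stopifnot(inherits(matrix, "gene_allele_matrix"))
  model <- match.arg(model)
  n <- length(matrix$line_ids)
  if (n < 2) stop_config("need >= 2 lines")
  smaller <- matrix$direction == "smaller_better"
  if (model == "independent") {
    E <- matrix$effects
    E[is.na(E)] <- 0
    s <- rowSums(E)
    M <- as.matrix(stats::dist(E, method = "manhattan"))
    P <- if (smaller) {
      matrix$mu + (outer(s, s, "+") - M) / 2
    } else {
      matrix$mu + (outer(s, s, "+") + M) / 2
    }
    ut <- upper.tri(P)
    vals <- P[ut]
    pairs <- if (keep_pairs) {
      w <- which(ut, arr.ind = TRUE)
      data.frame(i = matrix$line_ids[w[, 1]], j = matrix$line_ids[w[, 2]],
                 value = vals, stringsAsFactors = FALSE)
    } else NULL
  } else {
    if (is.null(map)) stop_config("linkage model requires `map`")
    combs <- utils::combn(n, 2)
    seeds <- if (is.null(seed)) rep(list(NULL), ncol(combs)) else
      as.list(seed + seq_len(ncol(combs)))
    vals <- vapply(seq_len(ncol(combs)), function(k) {
      potential_linkage(matrix, map, combs[1, k], combs[2, k],
                        n_progeny = n_progeny, generations = generations,
                        quantile = quantile, seed = seeds[[k]])$value
    }, 0)
    pairs <- if (keep_pairs) {
      data.frame(i = matrix$line_ids[combs[1, ]],
                 j = matrix$line_ids[combs[2, ]], value = vals,
                 stringsAsFactors = FALSE)
    } else NULL
  }
  pct <- quantile(vals, seq(0, 1, 0.1))
  structure(
    list(n_lines = n, n_pairs = n * (n - 1) / 2, model = model,
         percentiles = pct,
         p10_favorable = unname(quantile(vals, if (smaller) 0.1 else 0.9)),
         best = if (smaller) min(vals) else max(vals),
         pairs = pairs),
    class = "potential_summary"
  )
}

#' @export
print.potential_summary <- function(x, ...) {
  cat(sprintf(
    "potential_summary[%s]: %d lines, %d pairs; favorable 10th percentile = %.4f\n",
    x$model, x$n_lines, x$n_pairs, x$p10_favorable
  ))
  invisible(x)
}
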