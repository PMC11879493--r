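# Shared fixture builders and independent oracles.

# Build a gasm_set directly from an allele-index matrix (lines x loci).
# Used to plant exact genotype configurations in assoc/crossplan tests.
gasm_set_from_matrix <- function(M, chrom = NULL, gene_ids = NULL) {
  n <- nrow(M)
  L <- ncol(M)
  line_ids <- rownames(M) %||% sprintf("L%03d", seq_len(n))
  gene_ids <- gene_ids %||% (colnames(M) %||% sprintf("gene%03d", seq_len(L)))
  chrom <- chrom %||% rep("chr01", L)
  gasms <- lapply(seq_len(L), function(l) {
    a <- M[, l]
    K <- max(a, na.rm = TRUE)
    list(gene_id = gene_ids[l], chrom = chrom[l], site_ids = NULL,
         alleles = as.character(seq_len(K)),
         assign = stats::setNames(as.integer(a), line_ids),
         n_alleles = as.integer(K))
  })
  structure(list(gasms = gasms, line_ids = line_ids, n_no_snp = 0L,
                 n_monomorphic = 0L, n_low_call = 0L),
            class = "gasm_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent connected-components oracle: plain union-find on an edge
# data frame (node_a, node_b) over a node universe.
union_find_components <- function(edges, nodes) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    ri <- find(match(edges$node_a[k], nodes))
    rj <- find(match(edges$node_b[k], nodes))
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  stats::setNames(match(roots, unique(roots)), nodes)
}

# Random edge fixture on n nodes
random_edges <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%03d", seq_len(n_nodes))
    data.frame(
      node_a = sample(nodes, n_edges, replace = TRUE),
      node_b = sample(nodes, n_edges, replace = TRUE),
      score = stats::runif(n_edges, 0.2, 1),
      stringsAsFactors = FALSE
    )
  })
}

# A tiny snp_table built by hand (3 SNPs in one gene, planted haplotypes)
make_tiny_snp_table <- function(haps, chrom = "chr01", pos = c(100, 200, 300)) {
  geno <- do.call(rbind, lapply(strsplit(haps, ""), function(h) {
    suppressWarnings(as.integer(ifelse(h == ".", NA, h)))
  }))
  line_ids <- sprintf("L%02d", seq_along(haps))
  sites <- data.frame(chrom = chrom, pos = pos[seq_len(ncol(geno))],
                      id = sprintf("s%d", seq_len(ncol(geno))),
                      stringsAsFactors = FALSE)
  dimnames(geno) <- list(line_ids, sites$id)
  structure(list(sites = sites, geno = geno, line_ids = line_ids,
                 n_skipped = 0L), class = "snp_table")
}
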