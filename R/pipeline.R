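# Stage seeds are derived from the single global seed so any stage can be
# re-run in isolation: stage i uses seed + 1000 * i.
stage_seed <- function(seed, i) if (is.null(seed)) NULL else seed + 1000L * i

#' Default pipeline configuration
#'
#' Returns the nested parameter list consumed by [run_pipeline()], holding
#' every stage's thresholds at the package defaults (alpha1 = alpha2 =
#' 0.05, LC = 1.5%, DEG P <= 0.05 and |log2FC| >= 0.807, PPI score >=
#' 0.18, hub degree > 10, chunk cap 2000) and a demonstration-scale
#' synthetic design (250 lines, 10 chromosomes x 20 genes, 10 STI QTL with
#' GEI, 8 RCL QTL, 2000-gene expression matrix).
#'
#' @param seed Global seed fanned out to per-stage seeds.
#' @return A named list of per-stage parameter blocks.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    map = list(n_chrom = 10, genes_per_chrom = 20, chrom_length_cM = 120,
               snps_per_gene = c(1, 4)),
    rils = list(n_lines = 250, n_selfing_gens = 6),
    sti = list(n_qtl = 10, effect_sd = 0.06, gei_sd = 0.03,
               h2_main = 0.67, h2_gei = 0.18, n_env = 3, n_rep = 3,
               mu = 1.6),
    rcl = list(n_qtl = 8, effect_sd = 0.15, h2_main = 0.9, n_rep = 5,
               mu = 1.2),
    gasm = list(min_call_rate = 0.8),
    assoc = list(alpha1 = 0.05, alpha2 = 0.05, lc_threshold = 1.5,
                 eigen_k = 0, gei = TRUE),
    crossplan = list(model = "independent", linkage_lines = 0,
                     n_progeny = 500, generations = 5),
    expression = list(n_genes = 2000, de_fraction = 0.15,
                      lfc_range = c(1, 3), dispersion = 0.05, n_rep = 3),
    deg = list(p_max = 0.05, lfc_min = 0.807, pseudocount = 1),
    netstats = list(min_score = 0.18, hub_threshold = 10, chunk_max = 2000,
                    top_k = 5, edge_prob = 0.01)
  )
}

# merge user overrides into the defaults, rejecting unknown keys
merge_config <- function(config) {
  def <- default_config(config$seed %||% 1)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop_config("unknown config blocks: %s", paste(unknown, collapse = ", "))
  for (blk in names(config)) {
    if (blk == "seed") { def$seed <- config$seed; next }
    bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(bad))
      stop_config("unknown keys in config$%s: %s", blk,
                  paste(bad, collapse = ", "))
    def[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  def
}

#' Run the full synthetic shade-tolerance analysis pipeline
#'
#' Orchestrates simulate -> indicators/heritability -> GASM assembly ->
#' two-stage multilocus GWAS (STI with GEI, RCL single-environment) ->
#' cross recombination potential -> DEG calling with Venn partition and
#' GWAS intersection -> PPI statistics on a synthetic edge list among the
#' DEGs, and verifies the accounting identities (gene union, Venn union,
#' pair count, polygene remainder) before returning the report. The run is
#' deterministic for a fixed config.
#'
#' @param config A configuration list; unspecified values fall back to
#'   [default_config()].
#' @return A `run_report` list with per-stage summaries and an
#'   `identities_ok` flag.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  seed <- cfg$seed

  # --- simulate -------------------------------------------------------------
  map <- do.call(make_map, c(cfg$map, list(seed = stage_seed(seed, 1))))
  rils <- do.call(simulate_rils,
                  c(list(map = map), cfg$rils,
                    list(seed = stage_seed(seed, 2))))
  arch_sti <- assign_architecture(
    map, cfg$sti$n_qtl, cfg$sti$effect_sd, cfg$sti$gei_sd,
    cfg$sti$h2_main, cfg$sti$h2_gei, cfg$sti$n_env, cfg$sti$n_rep,
    seed = stage_seed(seed, 3), mu = cfg$sti$mu
  )
  ph_sti <- simulate_phenotypes(rils, arch_sti, mode = "raw",
                                seed = stage_seed(seed, 4))
  arch_rcl <- assign_architecture(
    map, cfg$rcl$n_qtl, cfg$rcl$effect_sd, 0, cfg$rcl$h2_main, 0,
    n_env = 1, n_rep = cfg$rcl$n_rep, seed = stage_seed(seed, 5),
    mu = cfg$rcl$mu
  )
  ph_rcl <- simulate_phenotypes(rils, arch_rcl, seed = stage_seed(seed, 6))

  # --- pheno ----------------------------------------------------------------
  sti <- sti_table(ph_sti$plots)
  vc_sti <- anova_components(sti)
  h2_sti <- heritability(vc_sti)
  rcl_latent <- ph_rcl$indicator
  cells <- simulate_cells(
    data.frame(line = rcl_latent$line, value = rcl_latent$value),
    seed = stage_seed(seed, 7)
  )
  rcl <- rcl_table(cells, n_keep = cfg$rcl$n_rep, seed = stage_seed(seed, 8))
  vc_rcl <- anova_components(rcl)
  h2_rcl <- heritability(vc_rcl)

  # --- gasm -----------------------------------------------------------------
  gasms <- assemble_gasms(rils, map_annotation(map),
                          min_call_rate = cfg$gasm$min_call_rate)

  # --- assoc ----------------------------------------------------------------
  covs <- if (cfg$assoc$eigen_k > 0) eigen_covariates(gasms, cfg$assoc$eigen_k)
          else NULL
  fit_trait <- function(ind, h2, gei) {
    if (gei) {
      y <- aggregate(value ~ line + env, ind, mean)
    } else {
      y <- aggregate(value ~ line, ind, mean)
    }
    pre <- stage1_preselect(gasms, y, covariates = covs,
                            alpha1 = cfg$assoc$alpha1)
    cap <- if (gei) min(1, h2$h2_total) else min(1, h2$h2_main)
    stage2_stepwise(gasms, y, pre, covariates = covs,
                    alpha2 = cfg$assoc$alpha2, h2_cap = cap, gei = gei)
  }
  fit_sti <- fit_trait(sti, h2_sti, cfg$assoc$gei)
  fit_rcl <- fit_trait(rcl, h2_rcl, FALSE)
  tab_sti <- r2_table(fit_sti, cfg$assoc$lc_threshold)
  tab_rcl <- r2_table(fit_rcl, cfg$assoc$lc_threshold)
  acct_sti <- contribution_summary(tab_sti, 100 * h2_sti$h2_main,
                                   100 * h2_sti$h2_gei)
  acct_rcl <- contribution_summary(tab_rcl, 100 * h2_rcl$h2_main)
  union_acct <- gene_union(tab_sti$gene_id, tab_rcl$gene_id)

  # --- crossplan ------------------------------------------------------------
  cross <- NULL
  if (nrow(tab_sti) > 0) {
    gam <- build_matrix(fit_sti)
    cross <- summarize_pairs(gam, model = "independent")
    if (cfg$crossplan$linkage_lines >= 2) {
      sub <- gam
      keep <- seq_len(min(cfg$crossplan$linkage_lines, length(gam$line_ids)))
      sub$effects <- gam$effects[keep, , drop = FALSE]
      sub$line_ids <- gam$line_ids[keep]
      cross$linkage <- summarize_pairs(
        sub, model = "linkage", map = map,
        n_progeny = cfg$crossplan$n_progeny,
        generations = cfg$crossplan$generations,
        seed = stage_seed(seed, 9)
      )
    }
  } else {
    warning("no STI loci selected; crossplan stage skipped")
  }

  # --- deg ------------------------------------------------------------------
  expr <- do.call(simulate_expression,
                  c(cfg$expression, list(seed = stage_seed(seed, 10))))
  # expression matrix covers the annotated genes first, then unannotated ones
  n_named <- min(nrow(map$loci), nrow(expr$counts))
  new_ids <- c(map$loci$gene_id[seq_len(n_named)],
               rownames(expr$counts)[-seq_len(n_named)])
  rownames(expr$counts) <- names(expr$lengths) <- expr$truth$gene_id <- new_ids
  degs_g <- call_degs(expr, "G", cfg$deg$p_max, cfg$deg$lfc_min,
                      cfg$deg$pseudocount)
  degs_z <- call_degs(expr, "Z", cfg$deg$p_max, cfg$deg$lfc_min,
                      cfg$deg$pseudocount)
  venn <- venn_partition(degs_g, degs_z)
  gwas_genes <- rbind(
    data.frame(gene_id = tab_sti$gene_id,
               trait = rep("STI", nrow(tab_sti)),
               class = tab_sti$class, stringsAsFactors = FALSE),
    data.frame(gene_id = tab_rcl$gene_id,
               trait = rep("RCL", nrow(tab_rcl)),
               class = tab_rcl$class, stringsAsFactors = FALSE)
  )
  deg_gwas <- intersect_gwas(degs_g, gwas_genes)

  # --- netstats (synthetic interaction map among the DEG union) ------------
  deg_union <- union(degs_g$gene_id, degs_z$gene_id)
  net <- NULL
  if (length(deg_union) >= 2) {
    edges <- with_seed(stage_seed(seed, 11), {
      n_e <- max(1, round(cfg$netstats$edge_prob *
                            length(deg_union)^2 / 2))
      ii <- sample(deg_union, n_e, replace = TRUE)
      jj <- sample(deg_union, n_e, replace = TRUE)
      data.frame(node_a = ii, node_b = jj,
                 score = runif(n_e), stringsAsFactors = FALSE)
    })
    el <- filter_edges(edges, cfg$netstats$min_score)
    graph <- build_ppi_graph(el, nodes = deg_union)
    comp <- ppi_components(graph)
    hub_tab <- hubs(graph, cfg$netstats$hub_threshold)
    grp <- chunk_nodes(deg_union, cfg$netstats$chunk_max,
                       seed = stage_seed(seed, 12))
    group_hubs <- lapply(sort(unique(grp)), function(gi) {
      sub_nodes <- names(grp)[grp == gi]
      sub_edges <- el[el$node_a %in% sub_nodes & el$node_b %in% sub_nodes, ]
      hubs(build_ppi_graph(sub_edges, nodes = sub_nodes),
           cfg$netstats$hub_threshold)
    })
    meta <- top_hubs_meta(group_hubs, el, cfg$netstats$top_k)
    net <- list(
      n_nodes = igraph::vcount(graph), n_edges = igraph::ecount(graph),
      components = comp$sizes, n_isolated = comp$n_isolated,
      n_key_hubs = sum(hub_tab$is_key_hub),
      chunk_sizes = as.integer(table(grp)),
      n_meta_hubs = nrow(meta$hubs), n_meta_edges = meta$n_meta_edges
    )
  }

  # --- report with accounting identities ------------------------------------
  identities_ok <- all(
    union_acct$n_union == union_acct$n_a + union_acct$n_b - union_acct$n_shared,
    venn$union_total == venn$unique_a$n + venn$unique_b$n + venn$shared$n,
    venn$shared$n == venn$shared$same_trend + venn$shared$opposite_trend,
    is.null(cross) ||
      cross$n_pairs == cross$n_lines * (cross$n_lines - 1) / 2,
    acct_sti$polygene_main_pct >= -1e-6,
    acct_rcl$polygene_main_pct >= -1e-6,
    is.null(net) || sum(net$chunk_sizes) == length(deg_union)
  )
  structure(
    list(
      config = cfg,
      map = list(n_loci = nrow(map$loci), n_snps = sum(map$loci$n_snps)),
      rils = list(n_lines = length(rils$line_ids),
                  het_fraction = mean(rils$source == "HET")),
      pheno = list(h2_sti = h2_sti, h2_rcl = h2_rcl, vc_sti = vc_sti,
                   vc_rcl = vc_rcl,
                   gcv_sti = gcv(sqrt(vc_sti$sigma2_g), vc_sti$mu)),
      gasm = gasm_summary(gasms),
      assoc = list(sti = acct_sti, rcl = acct_rcl, union = union_acct,
                   fit_sti = fit_sti, fit_rcl = fit_rcl,
                   table_sti = tab_sti, table_rcl = tab_rcl),
      crossplan = cross,
      deg = list(venn = venn, n_g = nrow(degs_g), n_z = nrow(degs_z),
                 gwas_overlap = deg_gwas,
                 truth = expr$truth),
      netstats = net,
      identities_ok = identities_ok
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("shadenet run report\n")
  cat(sprintf("  lines: %d, GASMs: %d\n", x$rils$n_lines, x$gasm$total))
  cat(sprintf("  STI: h2 = %.1f%% + %.1f%% GEI; %d loci mapped (%.2f%% PV), polygene %.2f%%\n",
              100 * x$pheno$h2_sti$h2_main, 100 * x$pheno$h2_sti$h2_gei,
              x$assoc$sti$n_genes, x$assoc$sti$sum_r2_main_pct,
              x$assoc$sti$polygene_main_pct))
  cat(sprintf("  RCL: h2 = %.1f%%; %d loci mapped (%.2f%% PV), polygene %.2f%%\n",
              100 * x$pheno$h2_rcl$h2_main, x$assoc$rcl$n_genes,
              x$assoc$rcl$sum_r2_main_pct, x$assoc$rcl$polygene_main_pct))
  cat(sprintf("  gene union: %d + %d - %d = %d\n", x$assoc$union$n_a,
              x$assoc$union$n_b, x$assoc$union$n_shared, x$assoc$union$n_union))
  if (!is.null(x$crossplan))
    cat(sprintf("  crosses: %d pairs, favorable 10th percentile %.3f\n",
                x$crossplan$n_pairs, x$crossplan$p10_favorable))
  cat(sprintf("  DEGs: %d (G) / %d (Z), union %d\n", x$deg$n_g, x$deg$n_z,
              x$deg$venn$union_total))
  if (!is.null(x$netstats))
    cat(sprintf("  PPI: %d nodes, %d edges, %d key hubs\n",
                x$netstats$n_nodes, x$netstats$n_edges, x$netstats$n_key_hubs))
  cat(sprintf("  accounting identities: %s\n",
              if (x$identities_ok) "OK" else "FAILED"))
  invisible(x)
}
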