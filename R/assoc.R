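# Design-matrix blocks ------------------------------------------------------
#
# Loci enter models as deviation-coded (sum-to-zero) column blocks: a marker
# with K alleles contributes K-1 columns; lines missing at the marker get 0
# on every column (population-mean imputation, consistent with the
# gene-allele-matrix missing rule). Environment factors are deviation-coded
# too, so the intercept stays the grand mean and allele/GEI effects sum to
# zero within locus (and within locus x environment).

contr_sum_rows <- function(assign, K) {
  C <- stats::contr.sum(K)
  X <- matrix(0, length(assign), K - 1L)
  ok <- !is.na(assign)
  X[ok, ] <- C[assign[ok], , drop = FALSE]
  X
}

# completion matrix mapping K-1 deviation coefficients to K level effects
dev_completion <- function(K) rbind(diag(K - 1L), -1)

interaction_block <- function(Zl, Ze) {
  # all pairwise products of locus columns and env columns
  out <- matrix(0, nrow(Zl), ncol(Zl) * ncol(Ze))
  k <- 0
  for (b in seq_len(ncol(Ze))) {
    for (a in seq_len(ncol(Zl))) {
      k <- k + 1
      out[, k] <- Zl[, a] * Ze[, b]
    }
  }
  out
}

# align a phenotype data frame (line, value[, env]) to a gasm_set; returns
# observation-level index structures
align_pheno <- function(y, gasms) {
  stopifnot(is.data.frame(y), all(c("line", "value") %in% names(y)))
  idx <- match(y$line, gasms$line_ids)
  if (anyNA(idx))
    stop_config("phenotype lines absent from genotypes: %s",
                paste(unique(y$line[is.na(idx)]), collapse = ", "))
  env <- if ("env" %in% names(y)) factor(y$env) else NULL
  list(value = y$value, line_idx = idx,
       env = if (!is.null(env) && nlevels(env) > 1) env else NULL)
}

base_design <- function(al, covariates = NULL) {
  n_obs <- length(al$value)
  X <- matrix(1, n_obs, 1)
  colnames(X) <- "(Intercept)"
  if (!is.null(al$env)) {
    Ze <- stats::contr.sum(nlevels(al$env))[al$env, , drop = FALSE]
    colnames(Ze) <- paste0("env", seq_len(ncol(Ze)))
    X <- cbind(X, Ze)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates[al$line_idx, , drop = FALSE])
  }
  X
}

#' Population-structure eigenvector covariates from allele sharing
#'
#' Computes the line x line similarity matrix (fraction of GASMs at which
#' two lines carry the same allele, over markers where both are called) and
#' returns its top `k` eigenvectors for use as covariates. `k = 0` returns
#' `NULL` (a biparental RIL population has no structure to correct).
#'
#' @param gasms A [assemble_gasms()] `gasm_set`.
#' @param k Number of eigenvectors (0 to n_lines - 1).
#' @return An n_lines x k matrix (rows named by line), or `NULL` when
#'   `k = 0`.
#' @export
eigen_covariates <- function(gasms, k = 10) {
  stopifnot(inherits(gasms, "gasm_set"))
  n <- length(gasms$line_ids)
  check_number(k, "k", min = 0, integer = TRUE)
  if (k == 0) return(NULL)
  if (k >= n) stop_config("k must be < number of lines (%d)", n)
  G <- length(gasms$gasms)
  if (G == 0) stop_config("empty GASM set")
  ncols <- vapply(gasms$gasms, `[[`, 0L, "n_alleles")
  B <- matrix(0, n, sum(ncols))
  Bmiss <- matrix(0, n, G)
  off <- 0L
  for (g in seq_len(G)) {
    a <- gasms$gasms[[g]]$assign
    ok <- !is.na(a)
    B[cbind(which(ok), off + a[ok])] <- 1
    Bmiss[ok, g] <- 1
    off <- off + ncols[g]
  }
  matches <- tcrossprod(B)
  joint <- tcrossprod(Bmiss)
  S <- matches / pmax(joint, 1)
  ev <- eigen(S, symmetric = TRUE)
  out <- ev$vectors[, seq_len(k), drop = FALSE]
  dimnames(out) <- list(gasms$line_ids, paste0("EV", seq_len(k)))
  out
}

#' Stage 1: single-locus preselection of GASMs
#'
#' Fits each marker one at a time as `y ~ (env) + (covariates) + locus`
#' (environment as a deviation-coded blocking factor; GEI is not screened)
#' and keeps markers whose locus F-test has `P <= alpha1`. Markers with
#' fewer than two observed alleles among the phenotyped lines, aliased
#' blocks, or fewer than 3 residual df are skipped.
#'
#' @param gasms A `gasm_set`.
#' @param y Phenotype data frame with columns `line`, `value`, optionally
#'   `env` (per line x environment values; omit `env` for line means).
#' @param covariates Optional n_lines x k matrix (e.g.
#'   [eigen_covariates()]), rows aligned to `gasms$line_ids`.
#' @param alpha1 Preselection significance threshold (default 0.05).
#' @return Object of class `preselection`: data frame `gene_id`, `F`, `P`,
#'   `kept`, `skipped`.
#' @export
stage1_preselect <- function(gasms, y, covariates = NULL, alpha1 = 0.05) {
  stopifnot(inherits(gasms, "gasm_set"))
  check_number(alpha1, "alpha1", min = 0, max = 1)
  al <- align_pheno(y, gasms)
  X0 <- base_design(al, covariates)
  fit0 <- rss_rank(X0, al$value)
  n_obs <- length(al$value)
  out <- data.frame(
    gene_id = vapply(gasms$gasms, `[[`, "", "gene_id"),
    F = NA_real_, P = NA_real_, kept = FALSE, skipped = FALSE,
    stringsAsFactors = FALSE
  )
  for (g in seq_along(gasms$gasms)) {
    a <- gasms$gasms[[g]]$assign[al$line_idx]
    if (length(unique(a[!is.na(a)])) < 2L) {
      out$skipped[g] <- TRUE
      next
    }
    Z <- contr_sum_rows(a, gasms$gasms[[g]]$n_alleles)
    fit1 <- rss_rank(cbind(X0, Z), al$value)
    q <- fit1$rank - fit0$rank
    df_res <- n_obs - fit1$rank
    if (q < 1 || df_res < 3) {
      out$skipped[g] <- TRUE
      next
    }
    Fstat <- ((fit0$rss - fit1$rss) / q) / (fit1$rss / df_res)
    out$F[g] <- Fstat
    out$P[g] <- pf(Fstat, q, df_res, lower.tail = FALSE)
  }
  out$kept <- !out$skipped & !is.na(out$P) & out$P <= alpha1
  class(out) <- c("preselection", class(out))
  out
}

#' Stage 2: stepwise multilocus model with heritability cap
#'
#' Forward selection over preselected markers with backward elimination
#' after each entry. A candidate term (locus main effect, or locus x
#' environment interaction once its main term is in the model) enters when
#' its partial-F P passes the experiment-wise threshold AND the model's
#' summed genetic contribution stays `<= h2_cap`; among qualifying
#' candidates the smallest P wins (ties: largest incremental SS, then
#' genome order). The backward scan removes any term whose partial F given
#' the rest exceeds the same threshold, except main terms shielded by an
#' active interaction term. Contributions are measured against the residual
#' sum of squares of the base model (intercept + environment + covariates),
#' the same line-mean scale as the heritability denominator.
#'
#' The multilocus model carries its own experiment-wise error control: with
#' `experimentwise = TRUE` (default) the per-term threshold is `alpha2 / m`
#' with m the number of candidate markers — the Bonferroni-equivalent rule.
#' Without it (plain per-test `alpha2`), every marginally significant
#' marker re-qualifies inside the model and the selection degenerates to
#' the single-locus screen.
#'
#' @param gasms A `gasm_set`.
#' @param y Phenotype data frame (`line`, `value`[, `env`]).
#' @param preselection A [stage1_preselect()] result, or `NULL` to consider
#'   every marker.
#' @param covariates Optional covariate matrix as in [stage1_preselect()].
#' @param alpha2 Experiment-wise significance level (default 0.05).
#' @param h2_cap Cap on the summed genetic R^2, in (0, 1]; use the trait's
#'   estimated heritability.
#' @param gei Allow locus x environment interaction terms (requires `env`
#'   in `y`)?
#' @param experimentwise Divide `alpha2` by the number of candidate markers
#'   (default `TRUE`)?
#' @return Object of class `multilocus_fit`; see [allele_effects()] and
#'   [r2_table()] for downstream summaries. Key fields: `terms` (entry-
#'   ordered data frame with sequential SS, R^2 % and final partial P),
#'   `coef` (named coefficient vector of the final model), `mu`
#'   (intercept), `r2_total_pct`, `ss_corrected`, `df_resid`,
#'   `sigma2_resid`.
#' @export
stage2_stepwise <- function(gasms, y, preselection = NULL, covariates = NULL,
                            alpha2 = 0.05, h2_cap = 1, gei = FALSE,
                            experimentwise = TRUE) {
  stopifnot(inherits(gasms, "gasm_set"))
  check_number(alpha2, "alpha2", min = 0, max = 1)
  check_number(h2_cap, "h2_cap", min = 0, max = 1)
  al <- align_pheno(y, gasms)
  if (gei && is.null(al$env))
    stop_config("gei = TRUE requires an `env` column with >= 2 environments")
  X0 <- base_design(al, covariates)
  fit0 <- rss_rank(X0, al$value)
  ss_corr <- fit0$rss
  n_obs <- length(al$value)

  keep_ids <- if (is.null(preselection)) {
    vapply(gasms$gasms, `[[`, "", "gene_id")
  } else {
    preselection$gene_id[preselection$kept]
  }
  cand_idx <- which(vapply(gasms$gasms, `[[`, "", "gene_id") %in% keep_ids)
  p_thresh <- if (experimentwise) alpha2 / max(1, length(cand_idx)) else alpha2

  # precompute line-level locus blocks for candidates
  blocks <- lapply(cand_idx, function(g) {
    a <- gasms$gasms[[g]]$assign[al$line_idx]
    contr_sum_rows(a, gasms$gasms[[g]]$n_alleles)
  })
  names(blocks) <- as.character(cand_idx)
  Ze <- if (!is.null(al$env)) {
    stats::contr.sum(nlevels(al$env))[al$env, , drop = FALSE]
  } else NULL

  # model state: list of terms, each {gene_idx, type, cols}
  terms <- list()
  term_key <- function(t) paste(t$gene_idx, t$type)
  model_X <- function(tl) {
    if (length(tl) == 0) return(X0)
    cbind(X0, do.call(cbind, lapply(tl, `[[`, "cols")))
  }
  cur_fit <- fit0

  repeat {
    in_main <- vapply(terms, function(t) {
      if (t$type == "main") t$gene_idx else NA_integer_
    }, 0L)
    in_gei <- vapply(terms, function(t) {
      if (t$type == "gei") t$gene_idx else NA_integer_
    }, 0L)
    cands <- list()
    for (g in cand_idx) {
      if (!(g %in% in_main)) {
        cands[[length(cands) + 1L]] <- list(gene_idx = g, type = "main",
                                            cols = blocks[[as.character(g)]])
      } else if (gei && !is.null(Ze) && !(g %in% in_gei)) {
        cands[[length(cands) + 1L]] <- list(
          gene_idx = g, type = "gei",
          cols = interaction_block(blocks[[as.character(g)]], Ze)
        )
      }
    }
    if (length(cands) == 0) break

    Xc <- model_X(terms)
    best <- NULL
    for (cn in cands) {
      ft <- rss_rank(cbind(Xc, cn$cols), al$value)
      q <- ft$rank - cur_fit$rank
      df_res <- n_obs - ft$rank
      if (q < 1 || df_res < 3) next # aliased or df-exhausted: skip
      dss <- cur_fit$rss - ft$rss
      Fstat <- (dss / q) / (ft$rss / df_res)
      P <- pf(Fstat, q, df_res, lower.tail = FALSE)
      if (P > p_thresh) next
      if ((ss_corr - ft$rss) / ss_corr > h2_cap) next
      if (is.null(best) || P < best$P - 1e-12 ||
          (abs(P - best$P) <= 1e-12 && dss > best$dss + 1e-12)) {
        best <- list(term = cn, P = P, dss = dss, fit = ft)
      }
    }
    if (is.null(best)) break
    terms[[length(terms) + 1L]] <- best$term
    cur_fit <- best$fit

    # backward scan
    repeat {
      if (length(terms) < 2) break
      gei_genes <- vapply(terms, function(t) {
        if (t$type == "gei") t$gene_idx else NA_integer_
      }, 0L)
      worst <- NULL
      for (ti in seq_along(terms)) {
        t <- terms[[ti]]
        if (t$type == "main" && t$gene_idx %in% gei_genes) next # shielded
        Xwo <- model_X(terms[-ti])
        fwo <- rss_rank(Xwo, al$value)
        q <- cur_fit$rank - fwo$rank
        df_res <- n_obs - cur_fit$rank
        if (q < 1) { # aliased term contributes nothing: drop it
          worst <- list(ti = ti, P = Inf, fit = fwo)
          break
        }
        Fstat <- ((fwo$rss - cur_fit$rss) / q) / (cur_fit$rss / df_res)
        P <- pf(Fstat, q, df_res, lower.tail = FALSE)
        if (P > p_thresh && (is.null(worst) || P > worst$P)) {
          worst <- list(ti = ti, P = P, fit = fwo)
        }
      }
      if (is.null(worst)) break
      terms <- terms[-worst$ti]
      cur_fit <- rss_rank(model_X(terms), al$value)
    }
  }

  # final model summaries ----------------------------------------------------
  Xf <- model_X(terms)
  qr_f <- qr(Xf)
  coefs <- qr.coef(qr_f, al$value)
  df_resid <- n_obs - qr_f$rank
  rss_f <- sum(qr.resid(qr_f, al$value)^2)

  gene_ids_all <- vapply(gasms$gasms, `[[`, "", "gene_id")
  term_info <- data.frame(
    gene_id = vapply(terms, function(t) gene_ids_all[t$gene_idx], ""),
    type = vapply(terms, `[[`, "", "type"),
    entry_order = seq_along(terms),
    q = vapply(terms, function(t) ncol(t$cols), 0L),
    stringsAsFactors = FALSE
  )

  # sequential (entry-order) SS and final partial F per term
  seq_ss <- p_final <- numeric(length(terms))
  prev <- fit0
  for (k in seq_along(terms)) {
    fk <- rss_rank(model_X(terms[seq_len(k)]), al$value)
    seq_ss[k] <- prev$rss - fk$rss
    prev <- fk
  }
  for (k in seq_along(terms)) {
    fwo <- rss_rank(model_X(terms[-k]), al$value)
    q <- prev$rank - fwo$rank
    if (q >= 1 && df_resid > 0) {
      Fst <- ((fwo$rss - rss_f) / q) / (rss_f / df_resid)
      p_final[k] <- pf(Fst, q, df_resid, lower.tail = FALSE)
    } else p_final[k] <- NA_real_
  }
  term_info$seq_ss <- seq_ss
  term_info$r2_pct <- 100 * seq_ss / ss_corr
  term_info$p_partial <- p_final

  # map coefficients back to term blocks
  n_base <- ncol(X0)
  offsets <- cumsum(c(n_base, vapply(terms, function(t) ncol(t$cols), 0L)))
  term_coefs <- lapply(seq_along(terms), function(k) {
    b <- coefs[(offsets[k] + 1):offsets[k + 1]]
    b[is.na(b)] <- 0
    b
  })

  structure(
    list(
      terms = term_info, term_list = terms, term_coefs = term_coefs,
      coef = coefs, mu = unname(coefs[1]),
      env_levels = if (!is.null(al$env)) levels(al$env) else NULL,
      gasm_index = vapply(terms, `[[`, 0L, "gene_idx"),
      gasms = gasms,
      ss_corrected = ss_corr, rss = rss_f, df_resid = df_resid,
      sigma2_resid = if (df_resid > 0) rss_f / df_resid else NA_real_,
      r2_total_pct = 100 * (ss_corr - rss_f) / ss_corr,
      alpha2 = alpha2, h2_cap = h2_cap, n_obs = n_obs
    ),
    class = "multilocus_fit"
  )
}

#' @export
print.multilocus_fit <- function(x, ...) {
  n_main <- sum(x$terms$type == "main")
  n_gei <- sum(x$terms$type == "gei")
  cat(sprintf(
    "multilocus_fit: %d main-effect loci + %d GEI terms, total R2 = %.2f%% (cap %.0f%%)\n",
    n_main, n_gei, x$r2_total_pct, 100 * x$h2_cap
  ))
  invisible(x)
}

#' Deviation-coded allele effects of a fitted multilocus model
#'
#' Expands each selected locus's sum-to-zero coefficients into one effect
#' per allele (effects sum to exactly 0 within a locus; for biparental data
#' the two alleles get +a and -a). Interaction terms are expanded to one
#' effect per (allele, environment), summing to zero over alleles within
#' each environment and over environments within each allele.
#'
#' @param fit A [stage2_stepwise()] `multilocus_fit`.
#' @return Data frame `gene_id`, `allele` (haplotype string), `effect`, and
#'   when GEI terms are present additional `gei_<env>` columns.
#' @export
allele_effects <- function(fit) {
  stopifnot(inherits(fit, "multilocus_fit"))
  mains <- which(fit$terms$type == "main")
  out <- vector("list", length(mains))
  for (i in seq_along(mains)) {
    k <- mains[i]
    g <- fit$gasms$gasms[[fit$gasm_index[k]]]
    K <- g$n_alleles
    eff <- drop(dev_completion(K) %*% fit$term_coefs[[k]])
    d <- data.frame(gene_id = g$gene_id, allele = g$alleles, effect = eff,
                    stringsAsFactors = FALSE)
    gk <- which(fit$terms$type == "gei" &
                  fit$terms$gene_id == fit$terms$gene_id[k])
    if (length(gk) == 1 && !is.null(fit$env_levels)) {
      E <- length(fit$env_levels)
      B <- matrix(fit$term_coefs[[gk]], K - 1L, E - 1L)
      full <- dev_completion(K) %*% B %*% t(dev_completion(E))
      colnames(full) <- paste0("gei_", fit$env_levels)
      d <- cbind(d, as.data.frame(full))
    }
    out[[i]] <- d
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(0), allele = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(out, function(d) {
    d[setdiff(names(out[[which.max(vapply(out, ncol, 0L))]]), names(d))] <- 0
    d
  }))
  rownames(res) <- NULL
  res
}

#' Per-locus contribution table with LC/SC classification
#'
#' Reports each selected locus's contribution to phenotypic variance as the
#' incremental (entry-order sequential) sum of squares divided by the
#' corrected total SS, in percent; main and GEI contributions are listed
#' separately and loci are classed LC (large contribution) when
#' `R2_main >= lc_threshold` (default 1.5%), else SC.
#'
#' @param fit A `multilocus_fit`.
#' @param lc_threshold LC classification threshold in percent.
#' @return Object of class `contribution_table`: data frame `gene_id`,
#'   `r2_main_pct`, `r2_gei_pct`, `class`.
#' @export
r2_table <- function(fit, lc_threshold = 1.5) {
  stopifnot(inherits(fit, "multilocus_fit"))
  mains <- fit$terms[fit$terms$type == "main", c("gene_id", "r2_pct")]
  geis <- fit$terms[fit$terms$type == "gei", c("gene_id", "r2_pct")]
  out <- data.frame(gene_id = mains$gene_id, r2_main_pct = mains$r2_pct,
                    r2_gei_pct = numeric(nrow(mains)),
                    stringsAsFactors = FALSE)
  m <- match(geis$gene_id, out$gene_id)
  out$r2_gei_pct[m[!is.na(m)]] <- geis$r2_pct[!is.na(m)]
  out$class <- classify_lc(out$r2_main_pct, lc_threshold)
  class(out) <- c("contribution_table", class(out))
  out
}

# LC (large contribution) at r2 >= threshold, inclusive; SC below
classify_lc <- function(r2_pct, lc_threshold = 1.5) {
  ifelse(r2_pct >= lc_threshold, "LC", "SC")
}

#' Contribution accounting: LC/SC subtotals and the polygene remainder
#'
#' The polygene remainder is the trait heritability not accounted for by
#' mapped loci: `h2_main_pct - sum(R2_main)` (and analogously for the GEI
#' row when `h2_gei_pct` is supplied). A remainder below -1e-6 indicates an
#' inconsistent accounting basis and raises an error.
#'
#' @param table A [r2_table()] `contribution_table`.
#' @param h2_main_pct Trait main-effect heritability, percent.
#' @param h2_gei_pct Optional GEI heritability share, percent.
#' @return List with LC/SC gene counts and subtotal percents, the summed
#'   contributions, and polygene remainders.
#' @export
contribution_summary <- function(table, h2_main_pct, h2_gei_pct = NA) {
  stopifnot(inherits(table, "contribution_table"))
  sum_main <- sum(table$r2_main_pct)
  sum_gei <- sum(table$r2_gei_pct)
  lc <- table$class == "LC"
  rem_main <- h2_main_pct - sum_main
  if (rem_main < -1e-6)
    stop_config("mapped main contributions (%.4f%%) exceed h2_main (%.4f%%)",
                sum_main, h2_main_pct)
  rem_gei <- if (is.na(h2_gei_pct)) NA_real_ else h2_gei_pct - sum_gei
  list(
    n_genes = nrow(table),
    lc = list(n = sum(lc), total_pct = sum(table$r2_main_pct[lc])),
    sc = list(n = sum(!lc), total_pct = sum(table$r2_main_pct[!lc])),
    sum_r2_main_pct = sum_main,
    sum_r2_gei_pct = sum_gei,
    polygene_main_pct = rem_main,
    polygene_gei_pct = rem_gei,
    h2_main_pct = h2_main_pct,
    h2_gei_pct = h2_gei_pct
  )
}

#' Union accounting for two traits' gene lists
#'
#' @param genes_a,genes_b Character vectors of gene ids.
#' @return List `n_a`, `n_b`, `n_shared`, `n_union` (= n_a + n_b - shared).
#' @export
gene_union <- function(genes_a, genes_b) {
  genes_a <- unique(genes_a)
  genes_b <- unique(genes_b)
  shared <- intersect(genes_a, genes_b)
  list(n_a = length(genes_a), n_b = length(genes_b),
       n_shared = length(shared),
       n_union = length(genes_a) + length(genes_b) - length(shared),
       shared = shared)
}
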