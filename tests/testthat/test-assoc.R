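# shared simulated dataset: 250-line RIL, one strong planted QTL
sim_qtl_data <- function(seed, n_lines = 250, r2 = 0.2) {
  map <- make_map(4, 10, 120, 1, seed = seed)
  rils <- simulate_rils(map, n_lines, 6, seed = seed + 1)
  qtl <- map$loci$gene_id[15]
  arch <- trait_architecture(qtl, effect = 2 * sqrt(r2),
                             h2_main = r2, n_env = 1, n_rep = 1)
  ph <- simulate_phenotypes(rils, arch, seed = seed + 2)
  y <- aggregate(value ~ line, ph$indicator, mean)
  gasms <- assemble_gasms(rils, shadenet:::map_annotation(map))
  list(map = map, rils = rils, qtl = qtl, y = y, gasms = gasms)
}

test_that("eigen_covariates separates clonal groups and handles k = 0", {
  M <- rbind(matrix(1L, 10, 20), matrix(2L, 10, 20))
  rownames(M) <- sprintf("L%03d", 1:20)
  gs <- gasm_set_from_matrix(M)
  ev <- eigen_covariates(gs, k = 2)
  expect_equal(dim(ev), c(20, 2))
  # identical lines get identical eigenvector rows
  expect_lt(max(abs(sweep(ev[1:10, , drop = FALSE], 2, ev[1, ]))), 1e-8)
  # first eigenvector separates the two clonal blocks
  expect_gt(abs(mean(ev[1:10, 1]) - mean(ev[11:20, 1])), 0.1)
  expect_null(eigen_covariates(gs, k = 0))
  expect_error(eigen_covariates(gs, k = 20), "k must be <")
})

test_that("stage 1 keeps a strong QTL and skips degenerate loci", {
  d <- sim_qtl_data(100)
  # monomorphic locus is skipped
  mono <- d$gasms
  mono$gasms[[1]]$assign[] <- 1L
  pre <- stage1_preselect(mono, d$y)
  expect_true(pre$skipped[1])
  expect_false(pre$kept[1])
  # planted QTL (20% PV, n = 250) always survives the screen
  hits <- vapply(1:20, function(i) {
    di <- sim_qtl_data(200 + 7 * i)
    p <- stage1_preselect(di$gasms, di$y)
    p$kept[p$gene_id == di$qtl] & p$P[p$gene_id == di$qtl] < 1e-4
  }, TRUE)
  expect_true(all(hits))
})

test_that("stage 1 type-I rate matches alpha on null data", {
  withr::with_seed(5, {
    n <- 200
    L <- 1000
    M <- matrix(sample(1:2, n * L, replace = TRUE), n, L)
    rownames(M) <- sprintf("L%03d", 1:n)
    gs <- gasm_set_from_matrix(M)
    y <- data.frame(line = rownames(M), value = rnorm(n))
    pre <- stage1_preselect(gs, y, alpha1 = 0.05)
    frac <- mean(pre$kept)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / L))
  })
})

test_that("stage 2 recovers a single planted QTL", {
  sel <- lapply(1:60, function(i) {
    di <- sim_qtl_data(300 + 11 * i, r2 = 0.5)
    pre <- stage1_preselect(di$gasms, di$y)
    # the cap is an upper bound supplied with slack (as when passing an
    # estimated heritability); at exactly h2 the QTL's sample R2 straddles it
    fit <- stage2_stepwise(di$gasms, di$y, pre, h2_cap = 0.7)
    list(genes = fit$terms$gene_id, qtl = di$qtl,
         kept = pre$gene_id[pre$kept])
  })
  found <- vapply(sel, function(s) s$qtl %in% s$genes, TRUE)
  exact <- vapply(sel, function(s) identical(s$genes, s$qtl), TRUE)
  extras <- vapply(sel, function(s) length(setdiff(s$genes, s$qtl)), 0L)
  expect_equal(mean(found), 1) # the QTL itself is never missed
  expect_gte(mean(exact), 0.85) # occasional lone false entry past alpha2/m
  expect_lte(mean(extras), 0.3)
  # selected set is always a subset of the preselected set
  for (s in sel) expect_true(all(s$genes %in% s$kept))
})

test_that("the heritability cap restricts the model", {
  d <- sim_qtl_data(400, r2 = 0.5)
  pre <- stage1_preselect(d$gasms, d$y)
  fit0 <- stage2_stepwise(d$gasms, d$y, pre, h2_cap = 0)
  expect_equal(nrow(fit0$terms), 0)
  for (cap in c(0.05, 0.3, 0.9)) {
    fit <- stage2_stepwise(d$gasms, d$y, pre, h2_cap = cap)
    expect_lte(sum(fit$terms$r2_pct) / 100, cap + 1e-9)
  }
})

test_that("sequential R2 equals marginal R2 on an orthogonal design", {
  # full 2x2 factorial replicated: the two loci are exactly orthogonal
  M <- as.matrix(expand.grid(a = 1:2, b = 1:2))[rep(1:4, each = 10), ]
  rownames(M) <- sprintf("L%03d", 1:40)
  gs <- gasm_set_from_matrix(M, gene_ids = c("gA", "gB"))
  withr::with_seed(9, {
    x1 <- ifelse(M[, 1] == 1, 0.5, -0.5)
    x2 <- ifelse(M[, 2] == 1, 0.3, -0.3)
    y <- data.frame(line = rownames(M), value = 1 + x1 + x2 + rnorm(40, 0, 0.4))
  })
  fit <- stage2_stepwise(gs, y, h2_cap = 1)
  expect_setequal(fit$terms$gene_id, c("gA", "gB"))
  # marginal R2 from single-locus fits
  for (g in c("gA", "gB")) {
    single <- gasm_set_from_matrix(M[, (g == "gB") + 1, drop = FALSE],
                                   gene_ids = g)
    f1 <- stage2_stepwise(single, y, h2_cap = 1)
    expect_equal(fit$terms$r2_pct[fit$terms$gene_id == g],
                 f1$terms$r2_pct, tolerance = 1e-9)
  }
  # order independence of the selected set: reverse the marker order
  gs_rev <- gasm_set_from_matrix(M[, 2:1], gene_ids = c("gB", "gA"))
  fit_rev <- stage2_stepwise(gs_rev, y, h2_cap = 1)
  expect_setequal(fit_rev$terms$gene_id, fit$terms$gene_id)
})

test_that("R2 decomposition sums to the total model R2", {
  d <- sim_qtl_data(500, r2 = 0.4)
  pre <- stage1_preselect(d$gasms, d$y)
  fit <- stage2_stepwise(d$gasms, d$y, pre, h2_cap = 0.9)
  expect_gt(nrow(fit$terms), 0)
  expect_equal(sum(fit$terms$r2_pct), fit$r2_total_pct, tolerance = 1e-9)
  expect_equal(fit$r2_total_pct + 100 * fit$rss / fit$ss_corrected, 100,
               tolerance = 1e-9)
})

test_that("allele effects are deviation-coded and recover planted contrasts", {
  map <- make_map(4, 10, 120, 1, seed = 600)
  rils <- simulate_rils(map, 400, 6, seed = 601)
  qtl <- map$loci$gene_id[c(5, 25)]
  arch <- trait_architecture(qtl, effect = c(0.1, 0.1),
                             h2_main = 0.6, n_env = 1, n_rep = 1)
  ph <- simulate_phenotypes(rils, arch, seed = 602)
  y <- aggregate(value ~ line, ph$indicator, mean)
  gasms <- assemble_gasms(rils, shadenet:::map_annotation(map))
  pre <- stage1_preselect(gasms, y)
  fit <- stage2_stepwise(gasms, y, pre, h2_cap = 0.7)
  eff <- allele_effects(fit)
  for (g in unique(eff$gene_id)) {
    expect_equal(sum(eff$effect[eff$gene_id == g]), 0, tolerance = 1e-9)
  }
  # planted homozygous contrast 0.1 -> deviation-form effects ~ +/- 0.05
  hit <- intersect(qtl, eff$gene_id)
  expect_gt(length(hit), 0)
  for (g in hit) {
    expect_equal(sort(abs(eff$effect[eff$gene_id == g]))[1], 0.05,
                 tolerance = 0.35) # wide CI at sigma ~ 0.08, n = 400
  }
})

test_that("GEI terms respect hierarchy and sum-to-zero constraints", {
  map <- make_map(4, 10, 120, 1, seed = 700)
  rils <- simulate_rils(map, 250, 6, seed = 701)
  arch <- assign_architecture(map, 6, 0.08, 0.05, 0.5, 0.3, n_env = 3,
                              n_rep = 3, seed = 702)
  ph <- simulate_phenotypes(rils, arch, seed = 703)
  y <- aggregate(value ~ line + env, ph$indicator, mean)
  gasms <- assemble_gasms(rils, shadenet:::map_annotation(map))
  pre <- stage1_preselect(gasms, y)
  fit <- stage2_stepwise(gasms, y, pre, h2_cap = 0.85, gei = TRUE)
  # every GEI term has its main term in the model (hierarchy)
  geis <- fit$terms$gene_id[fit$terms$type == "gei"]
  mains <- fit$terms$gene_id[fit$terms$type == "main"]
  expect_true(all(geis %in% mains))
  eff <- allele_effects(fit)
  gei_cols <- grep("^gei_", names(eff), value = TRUE)
  if (length(gei_cols) > 0) {
    for (g in unique(eff$gene_id)) {
      sub <- eff[eff$gene_id == g, gei_cols, drop = FALSE]
      expect_equal(colSums(sub), setNames(rep(0, ncol(sub)), gei_cols),
                   tolerance = 1e-9) # over alleles within env
      expect_equal(unname(rowSums(sub)), rep(0, nrow(sub)), tolerance = 1e-9)
    }
  }
  expect_error(stage2_stepwise(gasms, aggregate(value ~ line, ph$indicator, mean),
                               pre, h2_cap = 0.85, gei = TRUE),
               "requires an `env`")
})

test_that("LC classification uses the inclusive 1.5% rule", {
  expect_equal(shadenet:::classify_lc(c(1.49, 1.5, 1.51)),
               c("SC", "LC", "LC"))
})

test_that("contribution accounting reproduces printed-identity arithmetic", {
  # LC/SC tables constructed to the published subtotals
  tab <- data.frame(
    gene_id = sprintf("g%03d", 1:73),
    r2_main_pct = c(rep(27.15 / 14, 14), rep(30.29 / 59, 59)),
    r2_gei_pct = 0
  )
  tab$class <- shadenet:::classify_lc(tab$r2_main_pct)
  class(tab) <- c("contribution_table", class(tab))
  acc <- contribution_summary(tab, h2_main_pct = 67.17, h2_gei_pct = 18.02)
  expect_equal(acc$lc$n, 14)
  expect_equal(acc$sc$n, 59)
  expect_equal(acc$lc$total_pct + acc$sc$total_pct, 57.44, tolerance = 1e-9)
  expect_equal(acc$polygene_main_pct, 9.73, tolerance = 1e-9)
  # inconsistent accounting rejected
  expect_error(contribution_summary(tab, h2_main_pct = 50), "exceed")
})

test_that("gene_union applies inclusion-exclusion", {
  a <- sprintf("g%03d", 1:99)
  b <- sprintf("g%03d", 93:211)
  u <- gene_union(a, b)
  expect_equal(u$n_shared, 7)
  expect_equal(u$n_union, 211)
  expect_equal(u$n_union, u$n_a + u$n_b - u$n_shared)
})
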