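test_that("make_map lays out ordered loci with the requested dimensions", {
  map <- make_map(1, 5, 100, 3, seed = 1)
  expect_equal(nrow(map$loci), 5)
  expect_true(all(diff(map$loci$pos_cM) > 0))
  expect_true(all(map$loci$pos_cM >= 0 & map$loci$pos_cM <= 100))
  expect_true(all(map$loci$n_snps == 3))

  big <- make_map(20, 10, 120, 2, seed = 7)
  expect_equal(nrow(big$loci), 200)
  expect_equal(nrow(big$chromosomes), 20)

  expect_identical(make_map(3, 8, 90, c(1, 4), seed = 11),
                   make_map(3, 8, 90, c(1, 4), seed = 11))
  expect_error(make_map(0, 5, 100), "n_chrom")
})

test_that("bp intervals do not overlap within a chromosome and ids are unique", {
  map <- make_map(4, 25, 120, c(1, 5), seed = 3)
  expect_false(anyDuplicated(map$loci$gene_id) > 0)
  for (ch in unique(map$loci$chrom_id)) {
    sub <- map$loci[map$loci$chrom_id == ch, ]
    expect_true(all(sub$bp_start[-1] > sub$bp_end[-nrow(sub)]))
  }
})

test_that("RIL recombinant-line fraction follows R = 2r/(1+2r)", {
  # completely linked loci never recombine
  map0 <- make_map(1, 2, 100, 1, seed = 1)
  map0$loci$pos_cM <- c(50, 50 + 1e-12)
  rils0 <- simulate_rils(map0, 300, 8, seed = 2)
  fixed <- rils0$source[, 1] != "HET" & rils0$source[, 2] != "HET"
  expect_true(all(rils0$source[fixed, 1] == rils0$source[fixed, 2]))

  # 10 cM apart: R = 2r/(1+2r) with r = Haldane(10) ~ 0.0906 -> R ~ 0.1536
  map10 <- make_map(1, 2, 100, 1, seed = 1)
  map10$loci$pos_cM <- c(45, 55)
  rils <- simulate_rils(map10, 2000, 12, seed = 3)
  hom <- rils$source[, 1] != "HET" & rils$source[, 2] != "HET"
  obs <- mean(rils$source[hom, 1] != rils$source[hom, 2])
  R <- ril_recomb_fraction(haldane(10))
  expect_equal(R, 0.1536, tolerance = 1e-3)
  expect_lt(abs(obs - R), 3 * sqrt(R * (1 - R) / sum(hom)))
})

test_that("unselected descent keeps parental frequencies at 1/2", {
  map <- make_map(2, 3, 100, 1, seed = 4)
  rils <- simulate_rils(map, 2000, 10, seed = 5)
  p1 <- colMeans(rils$source == "P1")
  p2 <- colMeans(rils$source == "P2")
  tol <- 3 * sqrt(0.25 / 2000)
  expect_true(all(abs(p1 - 0.5) < tol + 2^-10))
  expect_true(all(abs(p2 - 0.5) < tol + 2^-10))
})

test_that("residual heterozygosity decays as 2^-g with selfing generation", {
  map <- make_map(2, 1, 100, 1, seed = 6) # independent loci
  for (g in c(3, 6)) {
    rils <- simulate_rils(map, 2000, g, seed = 6 + g)
    p <- 2^-g
    obs <- mean(rils$source == "HET")
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / (2000 * 2)))
  }
})

test_that("simulate_rils is deterministic and validates inputs", {
  map <- make_map(2, 4, 80, 2, seed = 1)
  expect_identical(simulate_rils(map, 50, 6, seed = 9),
                   simulate_rils(map, 50, 6, seed = 9))
  expect_error(simulate_rils(list(), 50, 6), "genetic_map")
  expect_error(simulate_rils(map, 1, 6), "n_lines")
})

test_that("SNP alleles are consistent with their locus source", {
  map <- make_map(2, 5, 100, c(2, 4), seed = 2)
  rils <- simulate_rils(map, 80, 6, seed = 3)
  for (l in seq_len(ncol(rils$source))) {
    gid <- colnames(rils$source)[l]
    cols <- which(rils$sites$gene_id == gid)
    for (cc in cols) {
      expect_true(all(rils$geno[rils$source[, l] == "P1", cc] == 0L))
      expect_true(all(rils$geno[rils$source[, l] == "P2", cc] == 1L))
      expect_true(all(is.na(rils$geno[rils$source[, l] == "HET", cc])))
    }
  }
})

test_that("assign_architecture respects zero-GEI and empty-QTL cases", {
  map <- make_map(2, 10, 100, 1, seed = 1)
  arch0 <- assign_architecture(map, 4, 0.1, gei_sd = 0, seed = 2)
  expect_true(all(arch0$gei == 0))
  archn <- assign_architecture(map, 0, 0.1, seed = 3)
  expect_equal(nrow(archn$qtl), 0)
  expect_identical(assign_architecture(map, 5, 0.1, 0.05, seed = 4),
                   assign_architecture(map, 5, 0.1, 0.05, seed = 4))
  expect_error(assign_architecture(map, 21, 0.1), "exceeds")
  # GEI effects are deviation-coded across environments
  arch <- assign_architecture(map, 5, 0.1, 0.05, n_env = 3, seed = 5)
  expect_equal(rowSums(arch$gei), rep(0, 5), tolerance = 1e-12)
})

test_that("noiseless architecture yields heritability ~ 1", {
  map <- make_map(2, 10, 100, 1, seed = 1)
  rils <- simulate_rils(map, 60, 6, seed = 2)
  arch <- assign_architecture(map, 5, 0.2, gei_sd = 0,
                              h2_main = 1 - 1e-9, h2_gei = 0, seed = 3)
  ph <- simulate_phenotypes(rils, arch, seed = 4)
  vc <- anova_components(ph$indicator)
  expect_lt(vc$sigma2_eps, 1e-6 * vc$sigma2_g)
  expect_equal(heritability(vc)$h2_total, 1, tolerance = 1e-6)
})

test_that("generated phenotypes hit the target heritability partition", {
  map <- make_map(10, 10, 120, 1, seed = 1)
  rils <- simulate_rils(map, 246, 6, seed = 2)
  arch <- assign_architecture(map, 30, 0.05, 0.025, h2_main = 0.67,
                              h2_gei = 0.18, n_env = 3, n_rep = 3, seed = 3)
  h2 <- replicate(40, {
    ph <- simulate_phenotypes(rils, arch, seed = NULL)
    unlist(heritability(anova_components(ph$indicator)))
  })
  m <- rowMeans(h2)
  expect_lt(abs(m["h2_main"] - 0.67), 0.03)
  expect_lt(abs(m["h2_gei"] - 0.18), 0.03)
  expect_lt(abs(m["h2_total"] - 0.85), 0.03)
})

test_that("raw-mode back-construction is the identity on latent indicators", {
  map <- make_map(2, 8, 100, 1, seed = 1)
  rils <- simulate_rils(map, 50, 6, seed = 2)
  arch <- assign_architecture(map, 4, 0.05, 0.02, 0.67, 0.18, seed = 3)
  ph <- simulate_phenotypes(rils, arch, mode = "raw", seed = 4)
  sti <- sti_table(ph$plots)
  key <- function(d) paste(d$line, d$env, d$rep)
  m <- match(key(sti), key(ph$indicator))
  expect_lt(max(abs(sti$value - ph$indicator$value[m])), 1e-9)
})

test_that("simulate_cells reproduces latent RCL values through compute_rcl", {
  rcl <- data.frame(line = rep(c("A", "B"), each = 3),
                    value = c(1.1, 1.3, 0.9, 2.0, 1.8, 2.2))
  cells <- simulate_cells(rcl, seed = 5)
  rec <- rcl_table(cells, n_keep = 3, seed = 6)
  expect_equal(sort(rec$value[rec$line == "A"]),
               sort(rcl$value[rcl$line == "A"]), tolerance = 1e-9)
  expect_equal(sort(rec$value[rec$line == "B"]),
               sort(rcl$value[rcl$line == "B"]), tolerance = 1e-9)
})

test_that("simulate_expression plants the stated DE structure", {
  ex0 <- simulate_expression(300, 0, seed = 1)
  expect_equal(sum(ex0$truth$is_de_G) + sum(ex0$truth$is_de_Z), 0)
  ex <- simulate_expression(300, 0.2, c(1, 3), 0.05, seed = 2)
  expect_true(all(ex$counts >= 0))
  expect_true(all(ex$counts == round(ex$counts)))
  expect_equal(nrow(ex$samples), 12)
  expect_true(all(abs(ex$truth$lfc_G[ex$truth$is_de_G]) >= 1))
  expect_identical(simulate_expression(100, 0.1, seed = 3),
                   simulate_expression(100, 0.1, seed = 3))
  expect_error(simulate_expression(100, 0.1, dispersion = -1), "dispersion")
})
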