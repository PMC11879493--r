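test_that("VCF and TSV encodings of the same data read identically", {
  map <- make_map(2, 4, 80, 2, seed = 1)
  rils <- simulate_rils(map, 20, 6, seed = 2)
  vcf <- tempfile(fileext = ".vcf")
  tsv <- tempfile(fileext = ".tsv")
  write_vcf(rils, vcf)
  write_genotypes_tsv(rils, tsv)
  a <- read_genotypes(vcf)
  b <- read_genotypes(tsv)
  expect_equal(a$sites, b$sites)
  expect_equal(unname(a$geno), unname(b$geno))
  expect_equal(a$line_ids, b$line_ids)
  expect_equal(unname(a$geno), unname(rils$geno[, order(rils$sites$chrom, rils$sites$pos)]))
})

test_that("multi-allelic VCF sites are skipped and counted", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "L1", "L2", "L3"), collapse = "\t"),
    "chr1\t100\ts1\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1\t./.",
    "chr1\t200\ts2\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2",
    "chr1\t300\ts3\tA\tT\t.\tPASS\t.\tGT\t1/1\t0/0\t0/0"
  ), vcf)
  st <- read_genotypes(vcf)
  expect_equal(st$n_skipped, 1L)
  expect_equal(nrow(st$sites), 2)
  expect_equal(unname(st$geno[, 1]), c(0L, 1L, NA))
  expect_equal(unname(st$geno[, 2]), c(1L, 0L, 0L))
})

test_that("gene annotation round-trips through GFF3 and BED", {
  map <- make_map(2, 5, 100, 1, seed = 3)
  for (fmt in c("gff3", "bed")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_gene_annotation(map, f, fmt)
    ann <- read_gene_annotation(f)
    expect_equal(ann$gene_id, map$loci$gene_id)
    expect_equal(ann$start, map$loci$bp_start)
    expect_equal(ann$end, map$loci$bp_end)
  }
})

test_that("a single biallelic SNP gene yields exactly two alleles", {
  st <- make_tiny_snp_table(c("0", "0", "1", "1", "0"), pos = 150)
  genes <- data.frame(gene_id = "gA", chrom = "chr01", start = 100,
                      end = 200, strand = "+")
  gs <- assemble_gasms(st, genes)
  expect_equal(length(gs$gasms), 1)
  expect_equal(gs$gasms[[1]]$n_alleles, 2)
  # allele 1 is the more frequent haplotype ("0")
  expect_equal(unname(gs$gasms[[1]]$assign), c(1L, 1L, 2L, 2L, 1L))
})

test_that("a recombinant haplotype creates a third allele", {
  st <- make_tiny_snp_table(c("000", "000", "111", "111", "001"))
  genes <- data.frame(gene_id = "gA", chrom = "chr01", start = 50,
                      end = 350, strand = "+")
  gs <- assemble_gasms(st, genes)
  expect_equal(gs$gasms[[1]]$n_alleles, 3)
  expect_setequal(gs$gasms[[1]]$alleles, c("000", "111", "001"))
})

test_that("monomorphic and SNP-free genes are dropped with counters", {
  st <- make_tiny_snp_table(c("000", "000", "000"))
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr01",
                      start = c(50, 1000), end = c(350, 1200), strand = "+")
  expect_warning(gs <- assemble_gasms(st, genes), "no polymorphic")
  expect_equal(length(gs$gasms), 0)
  expect_equal(gs$n_monomorphic, 1L)
  expect_equal(gs$n_no_snp, 1L)
})

test_that("match-or-missing resolves unambiguous incomplete haplotypes", {
  st <- make_tiny_snp_table(c("000", "111", "0.0", "1.1", "..1", "0..",
                              "000", "111"))
  genes <- data.frame(gene_id = "gA", chrom = "chr01", start = 50,
                      end = 350, strand = "+")
  gs <- assemble_gasms(st, genes, min_call_rate = 0.5)
  a <- unname(gs$gasms[[1]]$assign)
  # "0.0" only compatible with "000"; "1.1" with "111"; same for "..1"/"0.."
  expect_equal(a[3], a[1])
  expect_equal(a[4], a[2])
  expect_equal(a[5], a[2])
  expect_equal(a[6], a[1])
})

test_that("ambiguous incomplete haplotypes and low call rates drop out", {
  # alleles 00 and 01 share the first site: ".0" is ambiguous... "0." is
  st <- make_tiny_snp_table(c("00", "01", "0.", "00", "01"),
                            pos = c(100, 200))
  genes <- data.frame(gene_id = "gA", chrom = "chr01", start = 50,
                      end = 250, strand = "+")
  gs <- assemble_gasms(st, genes)
  expect_true(is.na(gs$gasms[[1]]$assign[3]))
  # >20% missing lines: dropped by default call-rate rule
  st2 <- make_tiny_snp_table(c("0", "1", ".", ".", "0"), pos = 100)
  genes2 <- data.frame(gene_id = "gA", chrom = "chr01", start = 50,
                       end = 150, strand = "+")
  expect_warning(gs2 <- assemble_gasms(st2, genes2), "no polymorphic")
  expect_equal(length(gs2$gasms), 0)
  expect_equal(gs2$n_low_call, 1L)
  expect_equal(length(assemble_gasms(st2, genes2, min_call_rate = 0.5)$gasms), 1)
})

test_that("assembly is invariant to line order", {
  map <- make_map(2, 6, 90, c(2, 3), seed = 5)
  rils <- simulate_rils(map, 40, 6, seed = 6)
  gs1 <- assemble_gasms(rils, shadenet:::map_annotation(map))
  perm <- withr::with_seed(1, sample(40))
  rils2 <- rils
  rils2$geno <- rils$geno[perm, ]
  rils2$line_ids <- rils$line_ids[perm]
  rils2$source <- rils$source[perm, ]
  gs2 <- assemble_gasms(rils2, shadenet:::map_annotation(map))
  expect_equal(length(gs1$gasms), length(gs2$gasms))
  for (k in seq_along(gs1$gasms)) {
    g1 <- gs1$gasms[[k]]
    g2 <- gs2$gasms[[k]]
    # same haplotype string per line regardless of input order
    hap1 <- setNames(g1$alleles[g1$assign], names(g1$assign))
    hap2 <- setNames(g2$alleles[g2$assign], names(g2$assign))
    expect_equal(hap1[sort(names(hap1))], hap2[sort(names(hap2))])
  }
})

test_that("gasm_summary counts markers per chromosome", {
  M <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2), c(2, 2, 1, 1),
             c(1, 2, 2, 1), c(2, 1, 2, 1))
  gs <- gasm_set_from_matrix(M, chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"))
  s <- gasm_summary(gs)
  expect_equal(s$total, 5)
  expect_equal(as.integer(s$per_chromosome[c("chr1", "chr2")]), c(3, 2))
  empty <- gasm_set_from_matrix(M[, 0, drop = FALSE])
  expect_warning(s0 <- gasm_summary(empty), "empty")
  expect_equal(s0$total, 0)
})

test_that("GASM assignments round-trip through TSV", {
  map <- make_map(2, 5, 90, c(1, 3), seed = 7)
  rils <- simulate_rils(map, 30, 6, seed = 8)
  gs <- assemble_gasms(rils, shadenet:::map_annotation(map))
  f <- tempfile(fileext = ".tsv")
  write_gasms_tsv(gs, f)
  gs2 <- read_gasms_tsv(f)
  expect_equal(length(gs2$gasms), length(gs$gasms))
  for (k in seq_along(gs$gasms)) {
    expect_equal(gs2$gasms[[k]]$assign, gs$gasms[[k]]$assign)
    expect_equal(gs2$gasms[[k]]$alleles, gs$gasms[[k]]$alleles)
  }
})

test_that("allele counts are bounded by observed haplotype diversity", {
  map <- make_map(2, 8, 90, c(2, 4), seed = 9)
  rils <- simulate_rils(map, 60, 6, seed = 10)
  gs <- assemble_gasms(rils, shadenet:::map_annotation(map))
  for (g in gs$gasms) {
    n_snps <- length(g$site_ids)
    expect_gte(g$n_alleles, 2)
    expect_lte(g$n_alleles, 2^n_snps)
    # haplotype strings all same length
    expect_true(all(nchar(g$alleles) == n_snps))
  }
})
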