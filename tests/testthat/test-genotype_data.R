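test_that("PLINK text reading follows the additive coding conventions", {
  dir <- withr::local_tempdir()
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(c("1\tsnp1\t0\t1000000",
               "1\tsnp2\t2.5\t2000000"), map)
  writeLines(c("f1 s1 0 0 1 -9 A A C C",
               "f2 s2 0 0 2 -9 0 A C G",
               "f3 s3 0 0 1 -9 G A G G"), ped)
  gt <- read_plink(ped, map)
  # allele_a = first allele observed in file order
  expect_equal(gt$snps$allele_a, c("A", "C"))
  expect_equal(unname(gt$genotypes[, "snp1"]), c(2L, NA_integer_, 1L))
  expect_equal(unname(gt$genotypes[, "snp2"]), c(2L, 1L, 0L))
  # cM column used when non-zero, left for inference when zero
  expect_equal(gt$snps$genetic_pos, c(NA, 2.5))
  expect_equal(gt$subjects$subject_id, c("s1", "s2", "s3"))
})

test_that("malformed PLINK input is rejected with the offending line", {
  dir <- withr::local_tempdir()
  ped <- file.path(dir, "bad.ped")
  map <- file.path(dir, "bad.map")
  writeLines(c("1\tsnp1\t0\t1000"), map)
  writeLines(c("f1 s1 0 0 1 -9 A A",
               "f2 s2 0 0 1 -9 A"), ped)
  expect_error(read_plink(ped, map), "ragged .ped row")
  writeLines(c("f1 s1 0 0 1 -9 A C",
               "f2 s2 0 0 1 -9 G T"), ped)
  expect_error(read_plink(ped, map), "not biallelic")
  writeLines(c("1\tsnp1\t0\t1000", "1\tsnp1\t0\t2000"), map)
  expect_error(read_plink(ped, map), "duplicate SNP ids")
})

test_that("PLINK write-then-read round-trips, and rewriting is bit-identical", {
  set.seed(42)
  gt <- toy_table(matrix(c(2L, 1L, 0L, NA, 1L, 2L), nrow = 3))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.ped"); m1 <- file.path(dir, "a.map")
  write_plink(gt, p1, m1)
  back <- read_plink(p1, m1)
  expect_equal(unname(back$genotypes), unname(gt$genotypes))
  expect_equal(back$snps$snp_id, gt$snps$snp_id)
  # write(read(f)) reproduces a conforming file byte for byte
  p2 <- file.path(dir, "b.ped"); m2 <- file.path(dir, "b.map")
  write_plink(back, p2, m2)
  expect_identical(readLines(p2), readLines(p1))
  expect_identical(readLines(m2), readLines(m1))
})

test_that("VCF genotypes are read as REF-allele counts, phase ignored", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0|1\t./.",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0",
    "1\t300\trs3\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0"), vcf)
  expect_message(gt <- read_vcf(vcf), "1 multi-allelic")
  expect_equal(ncol(gt$genotypes), 2L)  # multi-allelic rs3 skipped
  expect_equal(unname(gt$genotypes[, "rs1"]), c(2L, 1L, NA_integer_))
  expect_equal(unname(gt$genotypes[, "rs2"]), c(0L, 1L, 2L))
  expect_equal(gt$snps$allele_a, c("A", "C"))
})

test_that("genetic-map inference is linear, idempotent and never overwrites", {
  snps <- data.frame(snp_id = c("a", "b", "c"), chromosome = 1L,
                     physical_pos = c(2e6, 3e6, 5e6),
                     genetic_pos = c(NA, 3.7, NA),
                     allele_a = "A", allele_b = "B")
  out <- infer_genetic_map(snps, rate = 1)
  expect_equal(out$genetic_pos, c(2.0, 3.7, 5.0))
  expect_identical(infer_genetic_map(out, rate = 1), out)
  expect_error(infer_genetic_map(snps, rate = -1), "non-negative")
  # monotone: sorted physical positions give non-decreasing cM
  set.seed(3)
  pos <- sort(sample.int(1e8, 50))
  snps2 <- data.frame(snp_id = paste0("s", 1:50), chromosome = 2L,
                      physical_pos = pos, genetic_pos = NA_real_,
                      allele_a = "A", allele_b = "B")
  expect_true(!is.unsorted(infer_genetic_map(snps2, 1.3)$genetic_pos))
})

test_that("allele counts satisfy X + Y = T and exclude missing genotypes", {
  gt <- toy_table(rbind(c(2L, 2L, 1L), c(1L, 2L, NA), c(0L, NA, NA)))
  expect_equal(allele_counts(gt, 1), list(X = 3L, Y = 3L, T = 6L))
  expect_equal(allele_counts(gt, 2), list(X = 4L, Y = 0L, T = 4L))
  expect_equal(allele_counts(gt, 3), list(X = 1L, Y = 1L, T = 2L))
  gt$genotypes[, 3] <- NA_integer_
  expect_error(allele_counts(gt, 3), "no non-missing")
  # property over a random table
  set.seed(11)
  tab <- hwe_table(40, runif(25, 0.05, 0.95))
  ac <- ibdscreen:::allele_counts_all(tab)
  expect_true(all(ac$X + ac$Y == ac$T))
})

test_that("genotype_table enforces sorting and value invariants", {
  geno <- rbind(c(1L, 2L), c(0L, 1L))
  snps <- data.frame(snp_id = c("b", "a"), chromosome = 1L,
                     physical_pos = c(2e6, 1e6), genetic_pos = NA_real_,
                     allele_a = "A", allele_b = "B")
  subj <- data.frame(subject_id = c("x", "y"), is_reference = TRUE)
  gt <- genotype_table(geno, snps, subj)
  expect_equal(gt$snps$snp_id, c("a", "b"))       # re-sorted by bp
  expect_equal(unname(gt$genotypes[1, ]), c(2L, 1L))
  expect_error(genotype_table(matrix(3L, 2, 2), snps, subj), "0, 1, 2")
  snps$chromosome <- 23L
  expect_error(genotype_table(geno, snps, subj), "autosome")
})
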