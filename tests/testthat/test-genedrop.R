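# genome of a few chromosomes with known map lengths, plus a uniform model
flat_models <- function(chroms, m_per_chr, freq = 0.5) {
  mods <- lapply(chroms, function(ch)
    haplotype_model(ch, sprintf("c%d_s%d", ch, seq_len(m_per_chr)),
                    rep(freq, m_per_chr),
                    if (m_per_chr > 1)
                      matrix(rep(c(freq, 1 - freq, freq, 1 - freq),
                                 each = m_per_chr - 1), ncol = 4)
                    else NULL,
                    "independence"))
  names(mods) <- as.character(chroms)
  mods
}

flat_snps <- function(chroms, m_per_chr, span_cm = 50) {
  do.call(rbind, lapply(chroms, function(ch)
    data.frame(snp_id = sprintf("c%d_s%d", ch, seq_len(m_per_chr)),
               chromosome = ch,
               physical_pos = seq_len(m_per_chr) * 1e6,
               genetic_pos = seq(0, span_cm, length.out = m_per_chr),
               allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)))
}

test_that("built-in pedigrees have the required minimal structure", {
  po <- builtin_pedigree("parent.offspring")
  expect_equal(nrow(po), 3L)
  expect_equal(sum(po$father_id == 0 & po$mother_id == 0), 2L)
  expect_length(validate_pedigree(po), 0L)
  hs <- builtin_pedigree("half.sibs")
  shared <- intersect(c(hs$father_id[1], hs$mother_id[1]),
                      c(hs$father_id[2], hs$mother_id[2]))
  expect_length(shared, 1L)    # exactly one shared parent
  expect_length(validate_pedigree(builtin_pedigree("cousins")), 0L)
  for (r in c("unrelated", "dup.mz", "full.sibs"))
    expect_length(validate_pedigree(builtin_pedigree(r)), 0L)
  expect_error(builtin_pedigree("sibs-in-law"), "unknown relationship")
})

test_that("pedigree validation reports each violated invariant", {
  expect_length(validate_pedigree(inbred_pedigree()), 0L)
  bad_sex <- builtin_pedigree("parent.offspring")
  bad_sex$sex[3] <- 2L         # father female-coded
  expect_match(validate_pedigree(bad_sex), "not male-coded")
  loop <- data.frame(member_id = 1:3, father_id = c(3L, 0L, 1L),
                     mother_id = c(2L, 0L, 2L), sex = c(1L, 2L, 1L))
  expect_match(validate_pedigree(loop), "cycle", all = FALSE)
  orphan <- data.frame(member_id = 1:2, father_id = c(9L, 0L),
                       mother_id = c(2L, 0L), sex = c(1L, 2L))
  expect_match(validate_pedigree(orphan), "father 9 not in pedigree",
               all = FALSE)
})

test_that("gene drop obeys Mendelian transmission and copy semantics", {
  mods <- flat_models(1:2, 20)
  snps <- flat_snps(1:2, 20)
  set.seed(51)
  dup <- drop_genes(builtin_pedigree("dup.mz"), mods, snps)
  expect_identical(dup$g1, dup$g2)
  for (i in 1:20) {
    po <- drop_genes(builtin_pedigree("parent.offspring"), mods, snps)
    # parent and offspring share at least one allele IBS at every locus
    expect_true(all(ibs_state(po$g1, po$g2) >= 1L))
  }
  # missing genetic positions are rejected before simulation
  snps_na <- snps; snps_na$genetic_pos[3] <- NA
  expect_error(drop_genes(builtin_pedigree("unrelated"), mods, snps_na),
               "genetic_pos")
})

test_that("crossover counts follow the Poisson map-length expectation", {
  gpos <- seq(0, 100, length.out = 11)  # 100 cM = 1 Morgan
  set.seed(52)
  nx <- replicate(2000, ibdscreen:::meiosis(rep(1L, 11), rep(2L, 11),
                                            gpos)$n_crossovers)
  expect_lt(abs(mean(nx) - 1), 0.07)
})

test_that("tracked IBD labels give the textbook relationship proportions", {
  mods <- flat_models(1:4, 15)
  snps <- flat_snps(1:4, 15, span_cm = 80)
  set.seed(53)
  fs <- builtin_pedigree("full.sibs")
  z <- replicate(500, {
    d <- drop_genes(fs, mods, snps, return_ibd = TRUE)
    tabulate(d$ibd + 1L, 3L) / length(d$ibd)
  })
  expect_lt(max(abs(rowMeans(z) - c(0.25, 0.5, 0.25))), 0.03)
  # offspring alleles always come from the parents (IBS >= 1 with each)
  po <- builtin_pedigree("parent.offspring")
  d <- drop_genes(po, mods, snps, return_ibd = TRUE)
  expect_true(all(d$ibd == 1L))  # non-inbred parent-offspring: 1 allele IBD
})

test_that("missingness mimicry copies study subjects' missing patterns", {
  geno <- matrix(rbinom(200, 2, 0.5), 10, 20)
  gt_complete <- toy_table(geno)
  pair <- list(g1 = rep(1L, 20), g2 = rep(2L, 20))
  expect_identical(apply_missingness(pair, gt_complete), pair)
  # single donor subject: its mask is forced onto both simulated members
  geno1 <- matrix(rbinom(20, 2, 0.5), 1, 20)
  geno1[1, 1:10] <- NA
  gt1 <- toy_table(geno1)
  out <- apply_missingness(pair, gt1)
  expect_true(all(is.na(out$g1[1:10])) && all(!is.na(out$g1[11:20])))
  expect_true(all(is.na(out$g2[1:10])))
  # marginal missingness rate matches the study rate
  set.seed(54)
  geno_m <- matrix(rbinom(3000, 2, 0.5), 15, 200)
  geno_m[runif(3000) < 0.1] <- NA
  gt_m <- toy_table(geno_m)
  rates <- replicate(500, {
    out <- apply_missingness(list(g1 = rep(1L, 200), g2 = rep(1L, 200)), gt_m)
    mean(is.na(c(out$g1, out$g2)))
  })
  expect_lt(abs(mean(rates) - mean(is.na(geno_m))), 0.02)
})

test_that("simulated reference pairs estimate their relationship and are reproducible", {
  set.seed(55)
  gt <- hwe_table(60, runif(40, 0.2, 0.8), chromosome = rep(1:2, each = 20))
  mods <- ibdscreen:::fit_all_models(gt, fit_ld = FALSE)
  set.seed(56)
  mz <- simulate_reference_pairs("dup.mz", 20, mods, gt,
                                 mimic_missingness = FALSE)
  expect_true(all(mz$k0 == 0 & mz$k1 == 0 & mz$k2 == 1))
  set.seed(57)
  a <- simulate_reference_pairs("full.sibs", 15, mods, gt)
  set.seed(57)
  b <- simulate_reference_pairs("full.sibs", 15, mods, gt)
  expect_identical(a, b)
})
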