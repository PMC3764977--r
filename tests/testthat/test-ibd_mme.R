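test_that("IBS states follow the opposite-homozygote / identity rules", {
  expect_equal(ibs_state(2L, 0L), 0L)
  expect_equal(ibs_state(0L, 2L), 0L)
  expect_equal(ibs_state(1L, 1L), 2L)
  expect_equal(ibs_state(2L, 1L), 1L)
  expect_equal(ibs_state(c(2L, 2L, 0L), c(NA, 2L, 1L)), c(NA, 2L, 1L))
})

test_that("count-form conditional IBS estimators match draw enumeration", {
  # the worked pool {A,A,a,a}: opposite homozygotes in 1/3 of 4-draws
  tab <- cond_ibs_unbiased(2, 2, 4)
  expect_equal(tab$i0z0, 1 / 3)
  oz0 <- oracle_cond_z0(2, 2)
  expect_equal(c(tab$i0z0, tab$i1z0, tab$i2z0), oz0)
  # a second, asymmetric pool against both oracles
  tab2 <- cond_ibs_unbiased(5, 2, 7)
  expect_equal(c(tab2$i0z0, tab2$i1z0, tab2$i2z0), oracle_cond_z0(5, 2))
  expect_equal(c(tab2$i0z1, tab2$i1z1, tab2$i2z1), oracle_cond_z1(5, 2))
})

test_that("monomorphic pools give degenerate conditional probabilities", {
  tab <- cond_ibs_unbiased(6, 0, 6)
  expect_equal(tab$i0z0, 0)
  expect_equal(tab$i2z0, 1)
  expect_equal(tab$i2z1, 1)
  # T < 4 is unusable
  expect_false(cond_ibs_unbiased(2, 1, 3)$usable)
  expect_true(is.na(cond_ibs_unbiased(2, 1, 3)$i0z0))
})

test_that("count form converges to the plug-in form as the pool grows", {
  p <- 0.3
  for (tt in c(1e3, 1e5)) {
    x <- round(p * tt)
    cf <- cond_ibs_unbiased(x, tt - x, tt)
    pl <- cond_ibs_plugin(x, tt - x, tt)
    expect_lt(max(abs(unlist(cf[1, 1:9]) - unlist(pl[1, ]))), 10 / tt)
  }
  # the limiting value itself: P(I=0|Z=0) -> 2 p^2 q^2
  cf <- cond_ibs_unbiased(3e5, 7e5, 1e6)
  expect_equal(cf$i0z0, 2 * 0.3^2 * 0.7^2, tolerance = 1e-4)
})

test_that("count form equals the plug-in-times-correction-factor form", {
  for (tt in c(6L, 37L, 200L)) {
    X <- 1:(tt - 1); Y <- tt - X
    p <- X / tt; q <- Y / tt
    cf <- cond_ibs_unbiased(X, Y, tt)
    corr00 <- 2 * p^2 * q^2 * (X - 1) / X * (Y - 1) / Y *
      tt / (tt - 1) * tt / (tt - 2) * tt / (tt - 3)
    corr11 <- 2 * p^2 * q * (X - 1) / X * tt / (tt - 1) * tt / (tt - 2) +
      2 * p * q^2 * (Y - 1) / Y * tt / (tt - 1) * tt / (tt - 2)
    expect_equal(cf$i0z0, corr00, tolerance = 1e-14)
    expect_equal(cf$i1z1, corr11, tolerance = 1e-14)
  }
})

test_that("conditional rows sum to one exactly for T >= 4", {
  set.seed(31)
  tt <- sample(4:300, 400, replace = TRUE)
  x <- vapply(tt, function(t) sample.int(t + 1L, 1L) - 1L, integer(1))
  tab <- cond_ibs_unbiased(x, tt - x, tt)
  expect_equal(tab$i0z0 + tab$i1z0 + tab$i2z0, rep(1, 400))
  expect_equal(tab$i0z1 + tab$i1z1 + tab$i2z1, rep(1, 400))
  expect_equal(tab$i0z2 + tab$i1z2 + tab$i2z2, rep(1, 400))
})

test_that("pair IBS summary reproduces the hand-worked two-SNP toy", {
  # both SNPs have counts X = 3, Y = 3, T = 6; the pair is (2,0) and (1,1):
  # one opposite-homozygote SNP, one identical SNP.  Hand arithmetic from
  # the count formulas: P(I=0|Z=0) = 72/360, P(I=1|Z=0) = 144/360,
  # P(I=2|Z=0) = 144/360, P(I=1|Z=1) = 72/120, P(I=2|Z=1) = 48/120.
  ref <- toy_table(rbind(c(2L, 2L), c(1L, 1L), c(0L, 0L)))
  tables <- ibdscreen:::cond_ibs_tables(ref)
  s <- pair_ibs_summary(c(2L, 1L), c(0L, 1L), tables)
  expect_equal(s$L, 2L)
  expect_equal(s$N_obs, c(1L, 0L, 1L))
  expect_equal(unname(s$N_cond[, 1]), 2 * c(0.2, 0.4, 0.4))
  expect_equal(unname(s$N_cond[, 2]), 2 * c(0, 0.6, 0.4))
  expect_equal(unname(s$N_cond[, 3]), 2 * c(0, 0, 1))
  # identical vectors: all SNPs at IBS 2
  s2 <- pair_ibs_summary(c(2L, 1L), c(2L, 1L), tables)
  expect_equal(s2$N_obs, c(0L, 0L, 2L))
  # row-sum identity on arbitrary genotypes
  expect_equal(sum(s$N_obs), s$L)
  expect_equal(unname(colSums(s$N_cond)), rep(2, 3))
})

test_that("sequential moment solution is exact for duplicates and sums to 1", {
  ref <- hwe_table(30, rep(0.5, 10)); set.seed(32)
  tables <- ibdscreen:::cond_ibs_tables(ref)
  g <- rbinom(10, 2, 0.5)
  dup <- estimate_pair_ibd(pair_ibs_summary(g, g, tables))
  expect_equal(c(dup$k0, dup$k1, dup$k2), c(0, 0, 1))
  # k0 + k1 + k2 = 1 on random inputs (algebraic identity of the system)
  for (i in 1:50) {
    g1 <- rbinom(10, 2, 0.5); g2 <- rbinom(10, 2, 0.5)
    est <- estimate_pair_ibd(pair_ibs_summary(g1, g2, tables))
    expect_equal(est$k0 + est$k1 + est$k2, 1)
  }
})

test_that("inestimable pairs are reported with a reason", {
  ref <- toy_table(rbind(c(2L, 2L), c(2L, 2L), c(2L, 2L)))  # monomorphic
  tables <- ibdscreen:::cond_ibs_tables(ref)
  est <- estimate_pair_ibd(pair_ibs_summary(c(2L, 2L), c(2L, 2L), tables))
  expect_equal(est$status, "zero_N_I0_Z0")
  expect_true(is.na(est$k0))
  est2 <- estimate_pair_ibd(pair_ibs_summary(c(NA, NA), c(2L, 2L), tables))
  expect_equal(est2$status, "no_shared_snps")
})

test_that("all-pairs estimation is complete, vectorised-consistent and order-invariant", {
  set.seed(33)
  gt <- hwe_table(12, runif(60, 0.1, 0.9))
  gt$genotypes[sample(length(gt$genotypes), 40)] <- NA
  gt$genotypes[3, ] <- gt$genotypes[2, ]   # planted duplicate
  est <- estimate_all_pairs(gt)
  expect_equal(nrow(est), choose(12, 2))
  # the duplicated pair is exactly (0, 0, 1)
  dup <- est[est$subject1 == "t02" & est$subject2 == "t03", ]
  expect_equal(c(dup$k0, dup$k1, dup$k2), c(0, 0, 1))
  # matrix path agrees with the per-pair path
  tables <- ibdscreen:::cond_ibs_tables(gt)
  for (r in c(1, 17, 40)) {
    i <- match(est$subject1[r], gt$subjects$subject_id)
    j <- match(est$subject2[r], gt$subjects$subject_id)
    ref_est <- estimate_pair_ibd(pair_ibs_summary(
      gt$genotypes[i, ], gt$genotypes[j, ], tables))
    expect_equal(est$k0[r], ref_est$k0)
    expect_equal(est$k1[r], ref_est$k1)
    expect_equal(est$L[r], ref_est$L)
  }
  # permuting subjects permutes but does not change the pair estimates
  perm <- sample(12)
  gt2 <- ibdscreen:::subset_gt(gt, subjects = perm)
  est2 <- estimate_all_pairs(gt2)
  expect_equal(est2, est)
  expect_equal(est$k0 + est$k1 + est$k2, rep(1, nrow(est)))
})
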