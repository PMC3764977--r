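# Independent brute-force oracles and small fixture builders shared by the
# test files.  The oracles enumerate allelic draws directly and never call
# the estimator code they are used to check.

# IBS state of two unordered genotype pairs given as allele counts (number
# of "A" alleles per individual computed by the caller)
oracle_ibs <- function(g1, g2) {
  if (g1 == g2) 2L else if (abs(g1 - g2) == 2L) 0L else 1L
}

# Conditional IBS probabilities given Z = 0 by exhaustive enumeration of all
# ordered draws of four distinct alleles from a pool of X 'A's and Y 'a's:
# the first two alleles form individual 1, the last two individual 2.
oracle_cond_z0 <- function(X, Y) {
  pool <- c(rep(1L, X), rep(0L, Y))
  tt <- length(pool)
  counts <- c(0, 0, 0)
  for (i in 1:tt) for (j in 1:tt) for (k in 1:tt) for (l in 1:tt) {
    if (length(unique(c(i, j, k, l))) < 4L) next
    ibs <- oracle_ibs(pool[i] + pool[j], pool[k] + pool[l])
    counts[ibs + 1L] <- counts[ibs + 1L] + 1
  }
  counts / (tt * (tt - 1) * (tt - 2) * (tt - 3))
}

# Conditional IBS probabilities given Z = 1 by enumeration of ordered draws
# of three distinct alleles: the first is shared, the second completes
# individual 1 and the third individual 2.
oracle_cond_z1 <- function(X, Y) {
  pool <- c(rep(1L, X), rep(0L, Y))
  tt <- length(pool)
  counts <- c(0, 0, 0)
  for (i in 1:tt) for (j in 1:tt) for (k in 1:tt) {
    if (length(unique(c(i, j, k))) < 3L) next
    ibs <- oracle_ibs(pool[i] + pool[j], pool[i] + pool[k])
    counts[ibs + 1L] <- counts[ibs + 1L] + 1
  }
  counts / (tt * (tt - 1) * (tt - 2))
}

# small complete-data genotype table with given genotype matrix; SNPs get
# one per 'chromosome 1' position slots and unit-spaced genetic positions
toy_table <- function(geno, is_reference = TRUE, chromosome = 1L) {
  geno <- as.matrix(geno)
  m <- ncol(geno)
  snps <- data.frame(snp_id = paste0("s", seq_len(m)),
                     chromosome = rep_len(chromosome, m),
                     physical_pos = numeric(m), genetic_pos = NA_real_,
                     allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  snps$physical_pos <- stats::ave(seq_len(m), snps$chromosome,
                                  FUN = seq_along) * 1e6
  subjects <- data.frame(subject_id = sprintf("t%02d", seq_len(nrow(geno))),
                         is_reference = rep_len(is_reference, nrow(geno)),
                         stringsAsFactors = FALSE)
  genotype_table(geno, infer_genetic_map(snps), subjects)
}

# genotype table of n subjects drawn under HWE at independent SNPs with the
# given allele-A frequencies
hwe_table <- function(n, freqs, is_reference = TRUE, chromosome = 1L) {
  geno <- vapply(freqs, function(p) stats::rbinom(n, 2L, p),
                 integer(n))
  toy_table(matrix(geno, nrow = n), is_reference, chromosome)
}

# offspring-of-first-cousin-marriage pedigree: the target pair is mother (2)
# and daughter (1); the daughter's parents (2 and 3) are first cousins via
# sibling parents 4 and 6, children of shared grandparents 8 and 9
inbred_pedigree <- function() {
  ped <- data.frame(
    member_id = 1:9,
    father_id = c(3L, 4L, 6L, 8L, 0L, 8L, 0L, 0L, 0L),
    mother_id = c(2L, 5L, 7L, 9L, 0L, 9L, 0L, 0L, 0L),
    sex       = c(2L, 2L, 1L, 1L, 2L, 1L, 2L, 1L, 2L))
  attr(ped, "relationship") <- "user"
  ped
}
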