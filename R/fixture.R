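## feasible two-locus haplotype frequency for target correlation r:
## h11 = p1 p2 + r * sqrt(p1 q1 p2 q2), clamped inside the Frechet bounds
hap_freq_from_r <- function(p1, p2, r) {
  h <- p1 * p2 + r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  lo <- pmax(0, p1 + p2 - 1) + 1e-9
  hi <- pmin(p1, p2) - 1e-9
  pmin(pmax(h, lo), hi)
}

## truth haplotype model for one chromosome of the synthetic study:
## genes are blocks of SNPs with strong within-block adjacent correlation
## and independence between blocks
truth_chrom_model <- function(chromosome, gene_sizes, ld_strength,
                              gene_spacing_mb = 10, snp_spacing_kb = 5) {
  p <- numeric(0); gene_of <- integer(0)
  for (g in seq_along(gene_sizes)) {
    base <- stats::runif(1, 0.1, 0.9)
    pj <- pmin(pmax(base + stats::runif(gene_sizes[g], -0.02, 0.02),
                    0.05), 0.95)
    p <- c(p, pj); gene_of <- c(gene_of, rep(g, gene_sizes[g]))
  }
  m <- length(p)
  snp_ids <- sprintf("snp_c%02d_%04d", as.integer(chromosome), seq_len(m))
  pos <- 1e6 + (gene_of - 1) * gene_spacing_mb * 1e6 +
    (sequence(gene_sizes) - 1) * snp_spacing_kb * 1e3
  trans <- NULL
  if (m > 1L) {
    same_gene <- gene_of[-1L] == gene_of[-m]
    r <- ifelse(same_gene, ld_strength, 0)
    h11 <- hap_freq_from_r(p[-m], p[-1L], r)
    pAA <- h11 / p[-m]
    pAa <- (p[-1L] - h11) / (1 - p[-m])
    pAA <- pmin(pmax(pAA, 0), 1); pAa <- pmin(pmax(pAa, 0), 1)
    trans <- cbind(pAA, 1 - pAA, pAa, 1 - pAa)
  }
  model <- haplotype_model(chromosome, snp_ids, p, trans, "markov_ld")
  attr(model, "physical_pos") <- pos
  model
}

#' Generate a synthetic candidate-gene study with planted relatives
#'
#' Builds a genotype table emulating a candidate-gene case-control panel:
#' SNPs grouped into gene-like clusters spread across autosomes, with
#' adjacent-SNP haplotype correlation `ld_strength` within clusters and
#' independence between clusters.  Unrelated subjects receive two
#' independent haplotypes from the truth model; planted related pairs are
#' generated by gene drop on the corresponding pedigrees with founder
#' haplotypes from the same truth model, and replace subjects in the
#' non-reference (case) block so the reference pool remains a population
#' random sample.  Missingness is independent per genotype.
#'
#' Defaults mirror a typical candidate-gene panel: 200 subjects (the first
#' 52\% flagged as the reference pool, as in a roughly balanced case-control
#' study), 1250 SNPs in clusters of about 6, and two planted
#' parent-offspring plus three full-sibling pairs.
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs.
#' @param n_chromosomes number of autosomes used (1-22).
#' @param planted named integer vector of pair counts per relationship,
#'   e.g. `c(parent.offspring = 2, full.sibs = 3)`; may be `NULL`.
#' @param snps_per_gene SNPs per gene-like cluster.
#' @param ld_strength within-cluster adjacent haplotype correlation in
#'   \[0, 1\] (0 = independent SNPs).
#' @param missing_rate independent per-genotype missingness probability.
#' @param reference_fraction fraction of subjects in the reference pool.
#' @param seed optional integer seed for exact reproducibility.
#' @return list with `data` (a [genotype_table()]), `truth` (data frame of
#'   planted pairs: subject1, subject2, relationship) and `models` (the
#'   synthetic truth haplotype models, one per chromosome).
#' @export
generate_fixture <- function(n_subjects = 200, n_snps = 1250,
                             n_chromosomes = 22,
                             planted = c(parent.offspring = 2, full.sibs = 3),
                             snps_per_gene = 6, ld_strength = 0.6,
                             missing_rate = 0.01, reference_fraction = 0.52,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_chromosomes < 1 || n_chromosomes > 22)
    stop("n_chromosomes must be in 1..22")
  n_planted_subj <- if (length(planted)) 2L * sum(planted) else 0L
  n_ref <- round(reference_fraction * n_subjects)
  if (n_planted_subj > n_subjects - n_ref)
    stop("infeasible planting: ", n_planted_subj,
         " related subjects exceed the non-reference block of ",
         n_subjects - n_ref)

  # distribute genes, then SNPs, across chromosomes
  n_genes <- max(1L, ceiling(n_snps / snps_per_gene))
  gene_chr <- rep_len(seq_len(n_chromosomes), n_genes)
  sizes <- rep(snps_per_gene, n_genes)
  excess <- sum(sizes) - n_snps
  if (excess > 0) sizes[n_genes] <- sizes[n_genes] - excess
  used_chr <- sort(unique(gene_chr))
  models <- lapply(used_chr, function(ch)
    truth_chrom_model(ch, sizes[gene_chr == ch], ld_strength))
  names(models) <- as.character(used_chr)

  snps <- do.call(rbind, lapply(models, function(mod)
    data.frame(snp_id = mod$snp_ids, chromosome = mod$chromosome,
               physical_pos = attr(mod, "physical_pos"),
               genetic_pos = NA_real_, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE)))
  rownames(snps) <- NULL
  snps <- infer_genetic_map(snps)

  # unrelated background: two independent haplotypes per subject
  geno <- matrix(0L, n_subjects, nrow(snps))
  col0 <- 0L
  for (mod in models) {
    h <- sample_haplotypes(mod, 2L * n_subjects)
    mc <- length(mod$snp_ids)
    geno[, col0 + seq_len(mc)] <-
      h[seq_len(n_subjects) * 2L - 1L, , drop = FALSE] +
      h[seq_len(n_subjects) * 2L, , drop = FALSE]
    col0 <- col0 + mc
  }

  subject_id <- sprintf("sub%03d", seq_len(n_subjects))
  subjects <- data.frame(subject_id = subject_id,
                         is_reference = seq_len(n_subjects) <= n_ref,
                         stringsAsFactors = FALSE)

  # plant related pairs at the end of the case block
  truth <- data.frame(subject1 = character(), subject2 = character(),
                      relationship = character(), stringsAsFactors = FALSE)
  slot <- n_subjects
  if (length(planted)) {
    for (rel in names(planted)) {
      for (k in seq_len(planted[[rel]])) {
        pair <- drop_genes(builtin_pedigree(rel), models, snps)
        geno[slot - 1L, ] <- pair$g1
        geno[slot, ] <- pair$g2
        truth <- rbind(truth, data.frame(
          subject1 = subject_id[slot - 1L], subject2 = subject_id[slot],
          relationship = rel, stringsAsFactors = FALSE))
        slot <- slot - 2L
      }
    }
  }

  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_

  list(data = genotype_table(geno, snps, subjects),
       truth = truth[order(truth$subject1), , drop = FALSE],
       models = models)
}
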