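#' Quality-control thresholds
#'
#' Bundles the SNP- and subject-level filtering thresholds.  All are
#' proportions in \[0, 1\].  Defaults are conventional GWAS-QC values; minor
#' allele frequency and Hardy-Weinberg equilibrium are assessed on the
#' reference pool only, to avoid artifacts from case enrichment.
#'
#' @param snp_call_rate minimum SNP call rate (over all subjects).
#' @param subject_call_rate minimum subject call rate (over all SNPs).
#' @param maf_min minimum minor allele frequency (reference pool).
#' @param hwe_p_min minimum exact Hardy-Weinberg p-value (reference pool).
#' @param filter logical; `FALSE` bypasses QC entirely (useful when the data
#'   were already filtered in an earlier run).
#' @return a list of class `filter_thresholds`.
#' @export
filter_control <- function(snp_call_rate = 0.9, subject_call_rate = 0.9,
                           maf_min = 0.01, hwe_p_min = 0.001, filter = TRUE) {
  th <- list(snp_call_rate = snp_call_rate,
             subject_call_rate = subject_call_rate,
             maf_min = maf_min, hwe_p_min = hwe_p_min,
             filter = isTRUE(filter))
  num <- unlist(th[1:4])
  if (any(!is.finite(num)) || any(num < 0 | num > 1))
    stop("all thresholds must lie in [0, 1]")
  class(th) <- "filter_thresholds"
  th
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability, under HWE, of heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype required")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  # attainable heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # P(n_Aa = h | nA, na) = n! / (nAA! nAa! naa!) * 2^h / C(2n, nA) terms;
  # computed on the log scale via lgamma for stability
  logp <- function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (max(nA, na) - h) / 2
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }
  lp <- vapply(hets, logp, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  # tolerance guards ties against floating-point noise
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

## per-SNP QC statistics on a genotype table
snp_qc_stats <- function(data) {
  g <- data$genotypes
  ref <- data$subjects$is_reference
  gr <- g[ref, , drop = FALSE]
  call_rate <- colMeans(!is.na(g))
  n_aa2 <- colSums(gr == 2L, na.rm = TRUE)  # homozygous allele_a
  n_het <- colSums(gr == 1L, na.rm = TRUE)
  n_bb2 <- colSums(gr == 0L, na.rm = TRUE)
  tot <- n_aa2 + n_het + n_bb2
  p <- ifelse(tot > 0, (2 * n_aa2 + n_het) / (2 * tot), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- rep(NA_real_, ncol(g))
  for (j in which(tot > 0))
    hwe_p[j] <- hwe_exact_test(n_aa2[j], n_het[j], n_bb2[j])
  data.frame(snp_id = data$snps$snp_id, call_rate = call_rate, maf = maf,
             hwe_p = hwe_p, stringsAsFactors = FALSE)
}

#' Filter SNPs on call rate, MAF and HWE
#'
#' Removes SNPs whose call rate (all subjects) falls below
#' `th$snp_call_rate`, whose reference-pool minor allele frequency falls
#' below `th$maf_min`, or whose reference-pool exact HWE p-value falls below
#' `th$hwe_p_min`.  The first rule triggered (in that order) is the one
#' reported.
#'
#' @param data a [genotype_table()].
#' @param th a [filter_control()] object.
#' @return list with elements `data` (filtered table) and `report`
#'   (data frame: item, rule, value, threshold).
#' @export
filter_snps <- function(data, th = filter_control()) {
  st <- snp_qc_stats(data)
  bad_call <- st$call_rate < th$snp_call_rate
  bad_maf <- is.na(st$maf) | st$maf < th$maf_min
  bad_hwe <- !is.na(st$hwe_p) & st$hwe_p < th$hwe_p_min
  rule <- rep(NA_character_, nrow(st))
  value <- rep(NA_real_, nrow(st))
  thr <- rep(NA_real_, nrow(st))
  pick <- function(idx, r, v, t) {
    sel <- idx & is.na(rule)
    rule[sel] <<- r; value[sel] <<- v[sel]; thr[sel] <<- t
  }
  pick(bad_call, "snp_call_rate", st$call_rate, th$snp_call_rate)
  pick(bad_maf, "maf_min", st$maf, th$maf_min)
  pick(bad_hwe, "hwe_p_min", st$hwe_p, th$hwe_p_min)
  drop <- !is.na(rule)
  report <- data.frame(item = st$snp_id[drop], rule = rule[drop],
                       value = value[drop], threshold = thr[drop],
                       stringsAsFactors = FALSE)
  if (all(drop)) stop("all SNPs removed by QC")
  out <- if (any(drop)) subset_gt(data, snps = which(!drop)) else data
  list(data = out, report = report)
}

#' Filter subjects on genotype call rate
#'
#' @param data a [genotype_table()].
#' @param th a [filter_control()] object.
#' @return list with elements `data` and `report` (as in [filter_snps()]).
#' @export
filter_subjects <- function(data, th = filter_control()) {
  cr <- rowMeans(!is.na(data$genotypes))
  drop <- cr < th$subject_call_rate
  report <- data.frame(item = data$subjects$subject_id[drop],
                       rule = rep("subject_call_rate", sum(drop)),
                       value = cr[drop],
                       threshold = rep(th$subject_call_rate, sum(drop)),
                       stringsAsFactors = FALSE)
  if (all(drop)) stop("all subjects removed by QC")
  out <- if (any(drop)) subset_gt(data, subjects = which(!drop)) else data
  list(data = out, report = report)
}

#' Apply the full QC stage
#'
#' Subjects are filtered first (on call rate), then SNPs (on call rate, MAF
#' and HWE computed on the remaining subjects).  With `th$filter = FALSE`
#' the data pass through untouched and the report is empty.
#'
#' @param data a [genotype_table()].
#' @param th a [filter_control()] object.
#' @return list with elements `data` and `report`.
#' @export
apply_qc <- function(data, th = filter_control()) {
  empty <- data.frame(item = character(), rule = character(),
                      value = numeric(), threshold = numeric(),
                      stringsAsFactors = FALSE)
  if (!th$filter) return(list(data = data, report = empty))
  s1 <- filter_subjects(data, th)
  s2 <- filter_snps(s1$data, th)
  list(data = s2$data, report = rbind(s1$report, s2$report))
}
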