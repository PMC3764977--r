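#' First-order Markov haplotype-frequency models
#'
#' A haplotype model describes the joint distribution of alleles along one
#' chromosome as an inhomogeneous first-order Markov chain: an initial
#' allele-A frequency at the first SNP and, for each adjacent SNP pair, a
#' 2x2 transition matrix P(allele at m | allele at m-1).  Fitted models
#' capture adjacent-marker linkage disequilibrium and are used to sample
#' founder haplotypes for gene-drop simulation; the `independence` variant
#' sets every transition row to the marginal allele frequency.
#'
#' @name haplotype_model
#' @param chromosome chromosome label.
#' @param snp_ids SNP identifiers in map order.
#' @param freq marginal allele-A frequency per SNP (first entry is the
#'   chain's initial frequency).
#' @param trans (M-1) x 4 matrix of transitions in previous-allele-major
#'   order: P(A|A), P(a|A), P(A|a), P(a|a); `NULL` allowed when M = 1.
#' @param model_kind `"markov_ld"` or `"independence"`.
#' @return an object of class `haplotype_model`.
#' @export
haplotype_model <- function(chromosome, snp_ids, freq, trans,
                            model_kind = c("markov_ld", "independence")) {
  model_kind <- match.arg(model_kind)
  m <- length(snp_ids)
  if (length(freq) != m) stop("freq length must match snp_ids")
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  if (m > 1L) {
    trans <- matrix(as.numeric(trans), nrow = m - 1L, ncol = 4L)
    if (any(trans < 0 | trans > 1)) stop("transition entries must lie in [0, 1]")
    rs <- cbind(trans[, 1] + trans[, 2], trans[, 3] + trans[, 4])
    if (any(abs(rs - 1) > 1e-8)) stop("transition rows must sum to 1")
    colnames(trans) <- c("pAA", "paA", "pAa", "paa")
  } else trans <- NULL
  structure(list(chromosome = chromosome, snp_ids = as.character(snp_ids),
                 freq = as.numeric(freq), trans = trans,
                 model_kind = model_kind),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("haplotype_model (", x$model_kind, "): chromosome ", x$chromosome,
      ", ", length(x$snp_ids), " SNPs\n", sep = "")
  invisible(x)
}

## two-locus haplotype-frequency EM, vectorised across adjacent SNP pairs.
## n?? are vectors of genotype-pair counts (index = copies of allele A at the
## left and right locus); returns haplotype frequencies hAA, hAa, haA, haa
## (left-locus allele first) and the log-likelihood trace when asked.
two_locus_em <- function(counts, tol = 1e-6, max_iter = 500, trace = FALSE) {
  n <- with(counts, n22 + n21 + n20 + n12 + n11 + n10 + n02 + n01 + n00)
  ntot <- 2 * n
  pL <- with(counts, (2 * (n22 + n21 + n20) + n12 + n11 + n10) / ntot)
  pR <- with(counts, (2 * (n22 + n12 + n02) + n21 + n11 + n01) / ntot)
  # linkage-equilibrium start: deterministic fitting
  hAA <- pL * pR; hAa <- pL * (1 - pR); haA <- (1 - pL) * pR
  haa <- (1 - pL) * (1 - pR)
  ll <- NULL
  loglik <- function() {
    with(counts,
         n22 * log(pmax(hAA^2, 1e-300)) +
         n21 * log(pmax(2 * hAA * hAa, 1e-300)) +
         n20 * log(pmax(hAa^2, 1e-300)) +
         n12 * log(pmax(2 * hAA * haA, 1e-300)) +
         n11 * log(pmax(2 * hAA * haa + 2 * hAa * haA, 1e-300)) +
         n10 * log(pmax(2 * hAa * haa, 1e-300)) +
         n02 * log(pmax(haA^2, 1e-300)) +
         n01 * log(pmax(2 * haA * haa, 1e-300)) +
         n00 * log(pmax(haa^2, 1e-300)))
  }
  for (it in seq_len(max_iter)) {
    if (trace) ll <- rbind(ll, loglik())
    # E-step: split double heterozygotes between the two phase resolutions
    denom <- hAA * haa + hAa * haA
    wcis <- ifelse(denom > 0, hAA * haa / denom, 0.5)
    eAA <- with(counts, 2 * n22 + n21 + n12 + n11 * wcis)
    eAa <- with(counts, 2 * n20 + n21 + n10 + n11 * (1 - wcis))
    eaA <- with(counts, 2 * n02 + n12 + n01 + n11 * (1 - wcis))
    eaa <- with(counts, 2 * n00 + n10 + n01 + n11 * wcis)
    nAA <- eAA / ntot; nAa <- eAa / ntot; naA <- eaA / ntot; naa <- eaa / ntot
    delta <- pmax(abs(nAA - hAA), abs(nAa - hAa), abs(naA - haA),
                  abs(naa - haa))
    hAA <- nAA; hAa <- nAa; haA <- naA; haa <- naa
    if (max(delta, 0) < tol) break
  }
  if (trace) ll <- rbind(ll, loglik())
  list(hAA = hAA, hAa = hAa, haA = haA, haa = haa, pL = pL, pR = pR,
       iterations = it, loglik = ll)
}

## genotype-pair counts for every adjacent SNP pair on a chromosome
adjacent_pair_counts <- function(g) {
  m <- ncol(g)
  I2 <- (!is.na(g) & g == 2L) + 0
  I1 <- (!is.na(g) & g == 1L) + 0
  I0 <- (!is.na(g) & g == 0L) + 0
  left <- seq_len(m - 1L); right <- left + 1L
  cnt <- function(A, B) colSums(A[, left, drop = FALSE] * B[, right, drop = FALSE])
  list(n22 = cnt(I2, I2), n21 = cnt(I2, I1), n20 = cnt(I2, I0),
       n12 = cnt(I1, I2), n11 = cnt(I1, I1), n10 = cnt(I1, I0),
       n02 = cnt(I0, I2), n01 = cnt(I0, I1), n00 = cnt(I0, I0))
}

#' Fit a Markov LD model to one chromosome
#'
#' Fits the first-order Markov haplotype model by
#' expectation-maximization over the unobserved phase of adjacent-SNP
#' genotype pairs, using reference-pool subjects only.  Each adjacent pair's
#' two-locus haplotype frequencies are estimated by the classic two-locus EM
#' (only double heterozygotes have ambiguous phase), started from linkage
#' equilibrium and iterated until the largest parameter change is below
#' `tol` (default 1e-6) or `max_iter` (default 500) iterations; transition
#' rows are the fitted conditional allele probabilities.
#'
#' @param data a [genotype_table()].
#' @param chromosome chromosome label to fit.
#' @param tol,max_iter EM convergence controls.
#' @return a [haplotype_model()] with `model_kind = "markov_ld"`.
#' @export
fit_markov_model <- function(data, chromosome, tol = 1e-6, max_iter = 500) {
  sel <- which(data$snps$chromosome == chromosome)
  if (!length(sel)) stop("no SNPs on chromosome ", chromosome)
  g <- data$genotypes[data$subjects$is_reference, sel, drop = FALSE]
  tt <- 2 * colSums(!is.na(g))
  if (any(tt == 0))
    stop("chromosome ", chromosome, ": SNP(s) with no reference genotypes")
  freq <- colSums(g, na.rm = TRUE) / tt
  m <- length(sel)
  if (m == 1L)
    return(haplotype_model(chromosome, data$snps$snp_id[sel], freq, NULL,
                           "markov_ld"))
  counts <- adjacent_pair_counts(g)
  em <- two_locus_em(counts, tol = tol, max_iter = max_iter)
  pL <- em$hAA + em$hAa
  qL <- em$haA + em$haa
  pAA <- ifelse(pL > 0, em$hAA / pL, em$pR)
  pAa <- ifelse(qL > 0, em$haA / qL, em$pR)
  trans <- cbind(pAA, 1 - pAA, pAa, 1 - pAa)
  haplotype_model(chromosome, data$snps$snp_id[sel], freq, trans, "markov_ld")
}

#' Fit an independence (no-LD) model to one chromosome
#'
#' Transition rows equal the marginal allele frequencies, so sampled alleles
#' are independent across SNPs.  Exact; no iteration.
#'
#' @inheritParams fit_markov_model
#' @return a [haplotype_model()] with `model_kind = "independence"`.
#' @export
fit_independence_model <- function(data, chromosome) {
  sel <- which(data$snps$chromosome == chromosome)
  if (!length(sel)) stop("no SNPs on chromosome ", chromosome)
  g <- data$genotypes[data$subjects$is_reference, sel, drop = FALSE]
  tt <- 2 * colSums(!is.na(g))
  if (any(tt == 0))
    stop("chromosome ", chromosome, ": SNP(s) with no reference genotypes")
  freq <- colSums(g, na.rm = TRUE) / tt
  m <- length(sel)
  trans <- if (m > 1L) {
    f <- freq[-1L]
    cbind(f, 1 - f, f, 1 - f)
  } else NULL
  haplotype_model(chromosome, data$snps$snp_id[sel], freq, trans,
                  "independence")
}

## fit models for every chromosome of a table
fit_all_models <- function(data, fit_ld = TRUE, tol = 1e-6, max_iter = 500) {
  chroms <- sort(unique(data$snps$chromosome))
  models <- lapply(chroms, function(ch)
    if (fit_ld) fit_markov_model(data, ch, tol, max_iter)
    else fit_independence_model(data, ch))
  names(models) <- as.character(chroms)
  models
}

#' Sample haplotypes from a fitted model
#'
#' Draws `n` haplotypes (rows) along the model's chromosome: the first
#' allele is Bernoulli(initial frequency), subsequent alleles follow the
#' transition rows.  Alleles are coded 1 = allele A, 0 = allele a.
#' Reproducible under `set.seed()`.
#'
#' @param model a [haplotype_model()].
#' @param n number of haplotypes.
#' @return n x M 0/1 matrix (columns = SNPs in map order).
#' @export
sample_haplotypes <- function(model, n = 1L) {
  m <- length(model$snp_ids)
  h <- matrix(0L, n, m, dimnames = list(NULL, model$snp_ids))
  h[, 1L] <- as.integer(stats::runif(n) < model$freq[1L])
  if (m > 1L) {
    tr <- model$trans
    for (j in 2L:m) {
      pA <- ifelse(h[, j - 1L] == 1L, tr[j - 1L, "pAA"], tr[j - 1L, "pAa"])
      h[, j] <- as.integer(stats::runif(n) < pA)
    }
  }
  h
}

#' @rdname sample_haplotypes
#' @export
sample_haplotype <- function(model) drop(sample_haplotypes(model, 1L))

#' Save haplotype models as plain-text files
#'
#' Writes one TSV per chromosome (`ldmodel_chr<label>.txt`): a header line
#' with the chromosome, SNP count and model kind, then one line per SNP with
#' the SNP id, marginal frequency and the four transition entries from the
#' previous SNP (previous-allele-major order; `NA` on the first SNP).
#' Floating-point values are printed with 17 significant digits so that
#' [load_models()] reproduces every parameter bit-exactly.
#'
#' @param models list of [haplotype_model()] objects.
#' @param dir output directory (created if needed).
#' @return character vector of file paths.
#' @export
save_models <- function(models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  paths <- vapply(models, function(mod) {
    path <- file.path(dir, paste0("ldmodel_chr", mod$chromosome, ".txt"))
    m <- length(mod$snp_ids)
    header <- paste(mod$chromosome, m, mod$model_kind, sep = "\t")
    tr <- rbind(rep(NA_real_, 4),
                if (m > 1L) mod$trans else NULL)
    body <- paste(mod$snp_ids, fmt(mod$freq),
                  fmt(tr[, 1]), fmt(tr[, 2]), fmt(tr[, 3]), fmt(tr[, 4]),
                  sep = "\t")
    writeLines(c(header, body), path)
    path
  }, character(1))
  unname(paths)
}

#' Load haplotype models from plain-text files
#'
#' @param paths files written by [save_models()].
#' @return named list of [haplotype_model()] objects (names = chromosomes).
#' @export
load_models <- function(paths) {
  models <- lapply(paths, function(path) {
    lines <- readLines(path)
    if (!length(lines)) stop(path, ": empty model file (line 1)")
    head <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(head) != 3L)
      stop(path, ": malformed header (line 1): expected ",
           "'chromosome<TAB>n_snps<TAB>model_kind'")
    m <- suppressWarnings(as.integer(head[2L]))
    if (is.na(m) || length(lines) != m + 1L)
      stop(path, ": header declares ", head[2L], " SNPs but file has ",
           length(lines) - 1L, " body line(s) (line 1)")
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    badlen <- which(lengths(fields) != 6L)
    if (length(badlen))
      stop(path, ": malformed SNP record (line ", badlen[1L] + 1L, ")")
    rec <- do.call(rbind, fields)
    freq <- as.numeric(rec[, 2L])
    if (anyNA(freq))
      stop(path, ": non-numeric frequency (line ",
           which(is.na(freq))[1L] + 1L, ")")
    trans <- if (m > 1L) {
      tr <- suppressWarnings(matrix(as.numeric(rec[-1L, 3:6]), ncol = 4L))
      if (anyNA(tr))
        stop(path, ": non-numeric transition entry (line ",
             which(rowSums(is.na(tr)) > 0)[1L] + 2L, ")")
      tr
    } else NULL
    haplotype_model(head[1L], rec[, 1L], freq, trans, head[3L])
  })
  names(models) <- vapply(models, function(x) as.character(x$chromosome),
                          character(1))
  models
}
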