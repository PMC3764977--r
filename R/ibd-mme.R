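#' Identity-by-state of a genotype pair
#'
#' IBS state for additive genotypes: 0 for opposite homozygotes, 2 for
#' identical genotypes, 1 otherwise; `NA` when either genotype is missing.
#' Vectorised over aligned genotype vectors.
#'
#' @param g1,g2 genotype vectors with entries in `{0, 1, 2, NA}`.
#' @return integer vector of IBS states.
#' @export
ibs_state <- function(g1, g2) {
  out <- ifelse(g1 == g2, 2L, ifelse(abs(g1 - g2) == 2L, 0L, 1L))
  out[is.na(g1) | is.na(g2)] <- NA_integer_
  as.integer(out)
}

#' Bias-corrected conditional IBS probabilities for one SNP
#'
#' Given reference-pool allele counts (X copies of allele A, Y of allele a,
#' T = X + Y), returns finite-sample unbiased estimates of P(I = i | Z = z)
#' for IBS states i and IBD states z in `{0, 1, 2}`.  The estimators are the
#' exact proportions of ordered without-replacement draws from the T-allele
#' pool that yield each IBS state: four distinct draws when the pair shares
#' no allele IBD (Z = 0), three draws with one shared when Z = 1.  For
#' example
#' \deqn{\hat P(I=0 \mid Z=0) = \frac{2X(X-1)Y(Y-1)}{T(T-1)(T-2)(T-3)},}
#' which converges to the familiar plug-in value \eqn{2p^2q^2} as the pool
#' grows.  Working with integer count products (rather than the equivalent
#' plug-in-times-correction-factor form) avoids 0/0 when X or Y is 0.
#' Structural entries: P(I=0|Z=1) = P(I=0|Z=2) = P(I=1|Z=2) = 0 and
#' P(I=2|Z=2) = 1.  Each conditional row sums to 1 exactly.
#'
#' @param X,Y,T allele counts (vectors allowed; `T = X + Y >= 4`).
#' @return data frame with columns `i0z0, i1z0, i2z0, i0z1, i1z1, i2z1,
#'   i0z2, i1z2, i2z2` and logical `usable` (`T >= 4`); unusable rows are NA.
#' @export
cond_ibs_unbiased <- function(X, Y, T) {
  if (any(X + Y != T)) stop("X + Y must equal T")
  X <- as.numeric(X); Y <- as.numeric(Y); T <- as.numeric(T)
  usable <- T >= 4
  d4 <- T * (T - 1) * (T - 2) * (T - 3)
  d3 <- T * (T - 1) * (T - 2)
  i0z0 <- 2 * X * (X - 1) * Y * (Y - 1) / d4
  i1z0 <- (4 * X * (X - 1) * (X - 2) * Y + 4 * X * Y * (Y - 1) * (Y - 2)) / d4
  i2z0 <- (X * (X - 1) * (X - 2) * (X - 3) + Y * (Y - 1) * (Y - 2) * (Y - 3) +
             4 * X * (X - 1) * Y * (Y - 1)) / d4
  i1z1 <- (2 * X * (X - 1) * Y + 2 * X * Y * (Y - 1)) / d3
  i2z1 <- (X * (X - 1) * (X - 2) + Y * (Y - 1) * (Y - 2) +
             X * Y * (Y - 1) + Y * X * (X - 1)) / d3
  out <- data.frame(i0z0 = i0z0, i1z0 = i1z0, i2z0 = i2z0,
                    i0z1 = 0, i1z1 = i1z1, i2z1 = i2z1,
                    i0z2 = 0, i1z2 = 0, i2z2 = 1,
                    usable = usable)
  out[!usable, 1:9] <- NA_real_
  out
}

#' Plug-in conditional IBS probabilities
#'
#' The naive estimators obtained by substituting the allele-frequency
#' estimates p = X/T, q = Y/T into the infinite-population conditional IBS
#' probabilities (e.g. 2 p^2 q^2 for P(I=0|Z=0)).  These are biased in
#' finite pools; provided for comparison with [cond_ibs_unbiased()].
#'
#' @inheritParams cond_ibs_unbiased
#' @return data frame with the same probability columns.
#' @export
cond_ibs_plugin <- function(X, Y, T) {
  if (any(X + Y != T)) stop("X + Y must equal T")
  p <- X / T; q <- Y / T
  data.frame(i0z0 = 2 * p^2 * q^2,
             i1z0 = 4 * p^3 * q + 4 * p * q^3,
             i2z0 = p^4 + q^4 + 4 * p^2 * q^2,
             i0z1 = 0,
             i1z1 = 2 * p^2 * q + 2 * p * q^2,
             i2z1 = p^3 + q^3 + p * q,
             i0z2 = 0, i1z2 = 0, i2z2 = 1)
}

## conditional IBS tables for every SNP of a genotype table (reference pool)
cond_ibs_tables <- function(data) {
  ac <- allele_counts_all(data)
  tab <- cond_ibs_unbiased(ac$X, ac$Y, ac$T)
  cbind(ac, tab[, setdiff(names(tab), "usable")], usable = tab$usable)
}

#' Per-pair IBS summary
#'
#' For one pair of aligned genotype vectors, counts the SNPs in each IBS
#' state and accumulates the conditional IBS probabilities over the SNPs
#' contributing to the pair.  A SNP contributes iff both genotypes are
#' non-missing and its reference pool has T >= 4 alleles; L is the number of
#' contributing SNPs, so the observed counts and each conditional row both
#' sum to L.
#'
#' @param g1,g2 genotype vectors aligned to the SNP list of `tables`.
#' @param tables conditional tables from `cond_ibs_tables()` (or any data
#'   frame with the nine probability columns and `usable`).
#' @return list with `N_obs` (length-3: SNPs with IBS 0/1/2), `N_cond`
#'   (3 x 3 matrix, rows IBS state, columns IBD state) and `L`.
#' @export
pair_ibs_summary <- function(g1, g2, tables) {
  use <- tables$usable & !is.na(g1) & !is.na(g2)
  ibs <- ibs_state(g1[use], g2[use])
  N_obs <- tabulate(ibs + 1L, nbins = 3L)
  N_cond <- matrix(0, 3, 3, dimnames = list(ibs = 0:2, ibd = 0:2))
  cols <- c("i0z0", "i1z0", "i2z0", "i0z1", "i1z1", "i2z1",
            "i0z2", "i1z2", "i2z2")
  sums <- colSums(tables[use, cols, drop = FALSE])
  N_cond[] <- sums  # column-major fill matches iXzY ordering above
  list(N_obs = N_obs, N_cond = N_cond, L = sum(use))
}

#' Method-of-moments IBD coefficients for one pair
#'
#' Solves the moment system sequentially for the pair's IBD coefficients
#' (k0, k1, k2) = (P(Z=0), P(Z=1), P(Z=2)):
#' k0 = N(I=0)/N(I=0|Z=0), then k1 and k2 by back-substitution.  The three
#' estimates sum to 1 by construction but are not clamped to \[0, 1\]:
#' values outside the simplex are informative about estimation noise and are
#' plotted as-is.
#'
#' @param summary a [pair_ibs_summary()] result.
#' @return list with `k0`, `k1`, `k2`, `L` and `status` (`"ok"` or a reason
#'   the pair is inestimable, in which case the coefficients are NA).
#' @export
estimate_pair_ibd <- function(summary) {
  bad <- function(reason) list(k0 = NA_real_, k1 = NA_real_, k2 = NA_real_,
                               L = summary$L, status = reason)
  if (summary$L < 1L) return(bad("no_shared_snps"))
  Nc <- summary$N_cond
  if (Nc[1, 1] <= 0) return(bad("zero_N_I0_Z0"))
  if (Nc[2, 2] <= 0) return(bad("zero_N_I1_Z1"))
  k0 <- summary$N_obs[1] / Nc[1, 1]
  k1 <- (summary$N_obs[2] - k0 * Nc[2, 1]) / Nc[2, 2]
  k2 <- (summary$N_obs[3] - k0 * Nc[3, 1] - k1 * Nc[3, 2]) / Nc[3, 3]
  list(k0 = k0, k1 = k1, k2 = k2, L = summary$L, status = "ok")
}

## one-call convenience used by the simulation path
estimate_pair_from_genotypes <- function(g1, g2, tables)
  estimate_pair_ibd(pair_ibs_summary(g1, g2, tables))

#' Estimate IBD coefficients for all pairs of study subjects
#'
#' Computes (k0, k1, k2) for every unordered pair of subjects (reference or
#' not), using conditional IBS tables estimated once from the reference pool
#' and shared by all pairs.  Pairwise IBS counts are accumulated with matrix
#' products over genotype indicator matrices, so the cost is a handful of
#' n x n crossproducts rather than a loop over pairs.
#'
#' @param data a [genotype_table()].
#' @param tables optional precomputed `cond_ibs_tables(data)`.
#' @return data frame with one row per unordered pair, ordered
#'   lexicographically by subject label: `subject1`, `subject2`, `k0`, `k1`,
#'   `k2`, `L`, `status`.
#' @export
estimate_all_pairs <- function(data, tables = NULL) {
  if (is.null(tables)) tables <- cond_ibs_tables(data)
  g <- data$genotypes[, tables$usable, drop = FALSE]
  tab <- tables[tables$usable, , drop = FALSE]
  n <- nrow(g)
  if (n < 2L) stop("need at least two subjects")

  A0 <- (!is.na(g) & g == 0L) + 0
  A1 <- (!is.na(g) & g == 1L) + 0
  A2 <- (!is.na(g) & g == 2L) + 0
  Obs <- (!is.na(g)) + 0

  ibs2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  ibs0 <- tcrossprod(A0, A2); ibs0 <- ibs0 + t(ibs0)
  L <- tcrossprod(Obs)
  ibs1 <- L - ibs0 - ibs2

  wsum <- function(col) tcrossprod(Obs * rep(tab[[col]], each = n), Obs)
  C00 <- wsum("i0z0"); C10 <- wsum("i1z0"); C20 <- wsum("i2z0")
  C11 <- wsum("i1z1"); C21 <- wsum("i2z1")
  # Z = 2 column: P(I=2|Z=2) = 1 at every SNP, so its sum is L

  idx <- which(upper.tri(L), arr.ind = TRUE)
  pick <- function(mat) mat[idx]
  l <- pick(L); n0 <- pick(ibs0); n1 <- pick(ibs1); n2 <- pick(ibs2)
  c00 <- pick(C00); c10 <- pick(C10); c20 <- pick(C20)
  c11 <- pick(C11); c21 <- pick(C21)

  k0 <- n0 / c00
  k1 <- (n1 - k0 * c10) / c11
  k2 <- (n2 - k0 * c20 - k1 * c21) / l
  status <- rep("ok", length(l))
  status[c11 <= 0] <- "zero_N_I1_Z1"
  status[c00 <= 0] <- "zero_N_I0_Z0"
  status[l < 1] <- "no_shared_snps"
  bad <- status != "ok"
  k0[bad] <- k1[bad] <- k2[bad] <- NA_real_

  ids <- data$subjects$subject_id
  id1 <- ids[idx[, 1]]; id2 <- ids[idx[, 2]]
  # canonical pair labelling: subject1 < subject2, rows sorted by labels, so
  # the output is invariant to subject input order up to pair relabelling
  s1 <- pmin(id1, id2); s2 <- pmax(id1, id2)
  out <- data.frame(subject1 = s1, subject2 = s2,
                    k0 = k0, k1 = k1, k2 = k2, L = as.integer(l),
                    status = status, stringsAsFactors = FALSE)
  out <- out[order(out$subject1, out$subject2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write pair estimates to TSV
#'
#' @param estimates data frame from [estimate_all_pairs()].
#' @param path output file.
#' @export
write_ibd_estimates <- function(estimates, path) {
  utils::write.table(estimates, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
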