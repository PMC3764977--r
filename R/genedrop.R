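#' Built-in relationship pedigrees
#'
#' Returns the minimal pedigree capturing a common close relationship, with
#' the target pair as the first two members.  Pedigree columns are
#' `member_id`, `father_id`, `mother_id`, `sex` (1 = male, 2 = female);
#' founders carry father and mother id 0.  Relationships:
#' `unrelated` (two founders), `dup.mz` (duplicate samples / monozygotic
#' twins: one simulated genome copied), `parent.offspring` (mother-daughter
#' plus the second founder parent), `full.sibs`, `half.sibs` (one shared
#' mother, three founders) and `cousins` (first cousins, eight members).
#'
#' @param name one of `"unrelated"`, `"dup.mz"`, `"parent.offspring"`,
#'   `"full.sibs"`, `"half.sibs"`, `"cousins"`.
#' @return a pedigree data frame with attribute `relationship`.
#' @export
builtin_pedigree <- function(name) {
  ped <- switch(name,
    unrelated = data.frame(
      member_id = 1:2, father_id = c(0L, 0L), mother_id = c(0L, 0L),
      sex = c(1L, 2L)),
    dup.mz = data.frame(
      member_id = 1:2, father_id = c(0L, 0L), mother_id = c(0L, 0L),
      sex = c(1L, 1L)),
    parent.offspring = data.frame(
      member_id = 1:3, father_id = c(3L, 0L, 0L), mother_id = c(2L, 0L, 0L),
      sex = c(2L, 2L, 1L)),
    full.sibs = data.frame(
      member_id = 1:4, father_id = c(3L, 3L, 0L, 0L),
      mother_id = c(4L, 4L, 0L, 0L), sex = c(1L, 2L, 1L, 2L)),
    half.sibs = data.frame(
      member_id = 1:5, father_id = c(3L, 5L, 0L, 0L, 0L),
      mother_id = c(4L, 4L, 0L, 0L, 0L), sex = c(1L, 2L, 1L, 2L, 1L)),
    cousins = data.frame(
      member_id = 1:8, father_id = c(3L, 8L, 5L, 0L, 0L, 0L, 5L, 0L),
      mother_id = c(4L, 7L, 6L, 0L, 0L, 0L, 6L, 0L),
      sex = c(1L, 2L, 1L, 2L, 1L, 2L, 2L, 1L)),
    stop("unknown relationship: ", name))
  attr(ped, "relationship") <- name
  ped
}

#' Validate a pedigree
#'
#' Checks the structural invariants: non-founder parent ids reference
#' existing members, fathers are male-coded and mothers female-coded, no
#' member is its own ancestor, and the target pair (first two rows) is
#' well-defined.  Inbred pedigrees (e.g. an offspring of a first-cousin
#' marriage) are valid.
#'
#' @param ped pedigree data frame (columns `member_id`, `father_id`,
#'   `mother_id`, `sex`).
#' @return character vector of problems; empty when the pedigree is valid.
#' @export
validate_pedigree <- function(ped) {
  errs <- character()
  need <- c("member_id", "father_id", "mother_id", "sex")
  if (!all(need %in% names(ped)))
    return(paste("missing column(s):",
                 paste(setdiff(need, names(ped)), collapse = ", ")))
  if (nrow(ped) < 2L)
    errs <- c(errs, "pedigree must have at least two members (the target pair)")
  if (anyDuplicated(ped$member_id))
    errs <- c(errs, "duplicate member ids")
  if (!all(ped$sex %in% c(1L, 2L)))
    errs <- c(errs, "sex must be coded 1 (male) or 2 (female)")
  is_founder <- ped$father_id == 0L & ped$mother_id == 0L
  half <- xor(ped$father_id == 0L, ped$mother_id == 0L)
  if (any(half))
    errs <- c(errs, paste("member(s) with exactly one parent specified:",
                          paste(ped$member_id[half], collapse = ", ")))
  for (i in which(!is_founder & !half)) {
    fa <- match(ped$father_id[i], ped$member_id)
    mo <- match(ped$mother_id[i], ped$member_id)
    if (is.na(fa))
      errs <- c(errs, paste0("member ", ped$member_id[i],
                             ": father ", ped$father_id[i], " not in pedigree"))
    else if (ped$sex[fa] != 1L)
      errs <- c(errs, paste0("member ", ped$member_id[i],
                             ": father ", ped$father_id[i], " is not male-coded"))
    if (is.na(mo))
      errs <- c(errs, paste0("member ", ped$member_id[i],
                             ": mother ", ped$mother_id[i], " not in pedigree"))
    else if (ped$sex[mo] != 2L)
      errs <- c(errs, paste0("member ", ped$member_id[i],
                             ": mother ", ped$mother_id[i], " is not female-coded"))
  }
  if (is.null(pedigree_order(ped)))
    errs <- c(errs, "pedigree contains a cycle (a member is its own ancestor)")
  errs
}

## topological order (parents before children); NULL if cyclic
pedigree_order <- function(ped) {
  placed <- ped$father_id == 0L & ped$mother_id == 0L
  ord <- which(placed)
  while (length(ord) < nrow(ped)) {
    ready <- !placed &
      (ped$father_id %in% c(0L, ped$member_id[placed])) &
      (ped$mother_id %in% c(0L, ped$member_id[placed]))
    if (!any(ready)) return(NULL)
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  ord
}

#' Read a pedigree file
#'
#' Whitespace-delimited columns: member id, father id, mother id, sex
#' (1 = male, 2 = female); founders have father and mother 0; the first two
#' rows are the target pair.
#'
#' @param path file path.
#' @return a validated pedigree data frame with `relationship = "user"`.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names =
                             c("member_id", "father_id", "mother_id", "sex"),
                           colClasses = "integer")
  errs <- validate_pedigree(tab)
  if (length(errs)) stop("invalid pedigree ", path, ":\n  ",
                         paste(errs, collapse = "\n  "))
  attr(tab, "relationship") <- "user"
  tab
}

## one meiosis on a chromosome: recombine the parent's two label vectors.
## Crossovers are a homogeneous Poisson process on the genetic map (Haldane,
## no interference); the starting haplotype is chosen with probability 1/2.
meiosis <- function(lab1, lab2, gpos) {
  len_m <- (max(gpos) - min(gpos)) / 100  # Morgans
  n_x <- stats::rpois(1L, len_m)
  start <- stats::runif(1L) < 0.5
  if (n_x > 0L) {
    xpos <- stats::runif(n_x, min(gpos), max(gpos))
    crossed <- findInterval(gpos, sort(xpos))
    phase <- (start + crossed) %% 2L
  } else phase <- rep(as.integer(start), length(gpos))
  list(gamete = ifelse(phase == 0L, lab1, lab2), n_crossovers = n_x)
}

## per-chromosome geometry shared by the gene-drop routines
drop_layout <- function(ped, models, snps) {
  errs <- validate_pedigree(ped)
  if (length(errs)) stop("invalid pedigree:\n  ", paste(errs, collapse = "\n  "))
  if (anyNA(snps$genetic_pos))
    stop("genetic_pos required for all SNPs before gene drop; ",
         "run infer_genetic_map() or supply a map")
  chroms <- unique(snps$chromosome)
  missing_mod <- setdiff(as.character(chroms), names(models))
  if (length(missing_mod))
    stop("no haplotype model for chromosome(s): ",
         paste(missing_mod, collapse = ", "))
  per_chr <- lapply(chroms, function(ch) {
    idx <- which(snps$chromosome == ch)
    mod <- models[[as.character(ch)]]
    if (!identical(mod$snp_ids, snps$snp_id[idx]))
      stop("model for chromosome ", ch, " does not match the SNP list")
    list(chrom = ch, idx = idx, gpos = snps$genetic_pos[idx], model = mod)
  })
  founders <- which(ped$father_id == 0L & ped$mother_id == 0L)
  list(per_chr = per_chr, ord = pedigree_order(ped), founders = founders,
       n_founders = length(founders))
}

## drop one pedigree realisation given pre-sampled founder haplotypes
## (list over chromosomes of 2*n_founders x Mc allele matrices).  Returns
## target-pair genotypes aligned to the full SNP list and, optionally, the
## realised IBD state per SNP from founder-haplotype labels.
drop_once <- function(ped, layout, founder_alleles, duplicate = FALSE,
                      return_ibd = FALSE) {
  m_total <- sum(lengths(lapply(layout$per_chr, `[[`, "idx")))
  g1 <- integer(m_total); g2 <- integer(m_total)
  ibd <- if (return_ibd) integer(m_total) else NULL
  fid <- ped$member_id[layout$founders]
  for (ci in seq_along(layout$per_chr)) {
    pc <- layout$per_chr[[ci]]
    mc <- length(pc$idx)
    H <- founder_alleles[[ci]]
    # labels: row index into H; each member gets two label vectors
    lab <- vector("list", nrow(ped))
    for (k in seq_along(layout$founders))
      lab[[layout$founders[k]]] <- rbind(rep(2L * k - 1L, mc),
                                         rep(2L * k, mc))
    for (i in layout$ord) {
      if (!is.null(lab[[i]])) next
      fa <- match(ped$father_id[i], ped$member_id)
      mo <- match(ped$mother_id[i], ped$member_id)
      lab[[i]] <- rbind(meiosis(lab[[fa]][1L, ], lab[[fa]][2L, ], pc$gpos)$gamete,
                        meiosis(lab[[mo]][1L, ], lab[[mo]][2L, ], pc$gpos)$gamete)
    }
    if (duplicate) lab[[2L]] <- lab[[1L]]
    pick <- function(labmat) H[cbind(labmat[1L, ], seq_len(mc))] +
      H[cbind(labmat[2L, ], seq_len(mc))]
    g1[pc$idx] <- pick(lab[[1L]])
    g2[pc$idx] <- pick(lab[[2L]])
    if (return_ibd) {
      a <- lab[[1L]]; b <- lab[[2L]]
      m1 <- (a[1L, ] == b[1L, ]) + (a[2L, ] == b[2L, ])
      m2 <- (a[1L, ] == b[2L, ]) + (a[2L, ] == b[1L, ])
      ibd[pc$idx] <- pmax(m1, m2)
    }
  }
  list(g1 = g1, g2 = g2, ibd = ibd)
}

#' Gene-drop a pedigree once
#'
#' Simulates one realisation of the target pair's genotypes: founders
#' receive haplotypes sampled from the per-chromosome haplotype models, and
#' each meiosis transmits a recombinant haplotype with crossovers drawn as a
#' Poisson process on the genetic map (Haldane model, no interference) and
#' the starting parental haplotype chosen with probability 1/2.
#' Chromosomes segregate independently.  For `dup.mz` pedigrees one genome
#' is simulated and copied.
#'
#' @param ped a pedigree (see [builtin_pedigree()]); first two members are
#'   the target pair.
#' @param models named list of [haplotype_model()] objects (one per
#'   chromosome, names = chromosome labels).
#' @param snps SNP metadata with complete `genetic_pos`.
#' @param return_ibd if `TRUE`, also return the realised IBD state (0/1/2)
#'   at every SNP, obtained by tracking founder-haplotype labels.
#' @return list with genotype vectors `g1`, `g2` (and `ibd` if requested),
#'   aligned to `snps`.
#' @export
drop_genes <- function(ped, models, snps, return_ibd = FALSE) {
  layout <- drop_layout(ped, models, snps)
  founder_alleles <- lapply(layout$per_chr, function(pc)
    sample_haplotypes(pc$model, 2L * layout$n_founders))
  out <- drop_once(ped, layout, founder_alleles,
                   duplicate = identical(attr(ped, "relationship"), "dup.mz"),
                   return_ibd = return_ibd)
  out$relationship <- attr(ped, "relationship")
  out
}

#' Mimic study missingness on a simulated pair
#'
#' For each simulated individual independently, one study subject is drawn
#' uniformly at random and its pattern of missing genotypes is copied onto
#' the simulated genotype vector.
#'
#' @param pair list with genotype vectors `g1`, `g2` (from [drop_genes()]).
#' @param study a [genotype_table()] whose SNPs align with the pair.
#' @return the pair with missingness applied.
#' @export
apply_missingness <- function(pair, study) {
  n <- nrow(study$genotypes)
  if (n < 1L) stop("study must have at least one subject")
  for (el in c("g1", "g2")) {
    donor <- sample.int(n, 1L)
    pair[[el]][is.na(study$genotypes[donor, ])] <- NA_integer_
  }
  pair
}

#' Simulate reference pairs of a known relationship
#'
#' Generates `n_pairs` gene-drop realisations of the relationship, applies
#' study missingness to each, and estimates IBD coefficients with the same
#' conditional IBS tables used for study pairs.  Founder haplotypes for all
#' pairs are sampled in one batch per chromosome for speed; results are
#' reproducible under `set.seed()`.
#'
#' @param relationship a built-in relationship name or a pedigree data frame
#'   (e.g. from [read_pedigree()]).
#' @param n_pairs number of simulated pairs (default 200).
#' @param models named per-chromosome list of [haplotype_model()] objects.
#' @param data the study [genotype_table()] (supplies the SNP list and the
#'   missingness patterns).
#' @param tables conditional IBS tables from `cond_ibs_tables()`; computed
#'   from `data` when `NULL`.
#' @param mimic_missingness copy study missingness patterns (default TRUE).
#' @return data frame of estimates: `relationship`, `replicate`, `k0`, `k1`,
#'   `k2`, `L`, `status`.
#' @export
simulate_reference_pairs <- function(relationship, n_pairs = 200, models,
                                     data, tables = NULL,
                                     mimic_missingness = TRUE) {
  ped <- if (is.data.frame(relationship)) relationship
         else builtin_pedigree(relationship)
  rel_name <- attr(ped, "relationship")
  if (is.null(rel_name)) rel_name <- "user"
  if (is.null(tables)) tables <- cond_ibs_tables(data)
  layout <- drop_layout(ped, models, data$snps)
  nf <- layout$n_founders
  # batch founder haplotypes: rows (pair, founder haplotype) per chromosome
  batch <- lapply(layout$per_chr, function(pc)
    sample_haplotypes(pc$model, 2L * nf * n_pairs))
  dup <- identical(rel_name, "dup.mz")
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    rows <- (p - 1L) * 2L * nf + seq_len(2L * nf)
    fa <- lapply(batch, function(H) H[rows, , drop = FALSE])
    pair <- drop_once(ped, layout, fa, duplicate = dup)
    if (mimic_missingness) pair <- apply_missingness(pair, data)
    est <- estimate_pair_from_genotypes(pair$g1, pair$g2, tables)
    out[[p]] <- data.frame(relationship = rel_name, replicate = p,
                           k0 = est$k0, k1 = est$k1, k2 = est$k2,
                           L = est$L, status = est$status,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  n_bad <- sum(res$status != "ok")
  if (n_bad > 0)
    message("simulate_reference_pairs(", rel_name, "): ", n_bad,
            " inestimable pair(s) excluded")
  res
}
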