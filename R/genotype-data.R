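#' Construct a genotype table
#'
#' The central data container: an additive genotype matrix (subjects in rows,
#' SNPs in columns, entries counting copies of `allele_a`, `NA` for missing)
#' together with SNP metadata and subject metadata.  Within each chromosome
#' SNPs must be sorted by ascending physical position; the constructor
#' enforces this and all other structural invariants.
#'
#' @param genotypes integer matrix, subjects x SNPs, entries in `{0, 1, 2, NA}`.
#' @param snps data frame with columns `snp_id`, `chromosome` (autosome 1-22),
#'   `physical_pos` (1-based bp), `genetic_pos` (cM, may be `NA`), `allele_a`,
#'   `allele_b`.
#' @param subjects data frame with columns `subject_id` and `is_reference`,
#'   the latter a logical flag marking subjects used to estimate conditional
#'   IBS probabilities and to fit LD models (e.g. the controls of a
#'   case-control study).
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(genotypes, snps, subjects) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)

  need_snp <- c("snp_id", "chromosome", "physical_pos", "genetic_pos",
                "allele_a", "allele_b")
  missing_cols <- setdiff(need_snp, names(snps))
  if (length(missing_cols))
    stop("snps is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(c("subject_id", "is_reference") %in% names(subjects)))
    stop("subjects must have columns subject_id and is_reference")

  if (nrow(snps) != ncol(genotypes))
    stop("ncol(genotypes) [", ncol(genotypes), "] != nrow(snps) [",
         nrow(snps), "]")
  if (nrow(subjects) != nrow(genotypes))
    stop("nrow(genotypes) [", nrow(genotypes), "] != nrow(subjects) [",
         nrow(subjects), "]")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("genotype entries must be 0, 1, 2 or NA")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP ids: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject ids")
  chrom <- suppressWarnings(as.integer(snps$chromosome))
  if (any(is.na(chrom)) || any(chrom < 1L | chrom > 22L))
    stop("chromosome must be an autosome label 1-22")
  snps$chromosome <- chrom
  if (any(snps$physical_pos <= 0))
    stop("physical_pos must be positive")
  # enforce ascending bp within chromosome (stable: chromosomes keep order
  # of first appearance re-sorted numerically)
  ord <- order(snps$chromosome, snps$physical_pos)
  if (!identical(ord, seq_len(nrow(snps)))) {
    snps <- snps[ord, , drop = FALSE]
    genotypes <- genotypes[, ord, drop = FALSE]
    rownames(snps) <- NULL
  }
  subjects$is_reference <- as.logical(subjects$is_reference)
  if (anyNA(subjects$is_reference))
    stop("is_reference must be TRUE/FALSE with no missing values")
  dimnames(genotypes) <- list(subjects$subject_id, snps$snp_id)

  structure(list(genotypes = genotypes, snps = snps, subjects = subjects),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$genotypes), "subjects x",
      ncol(x$genotypes), "SNPs on",
      length(unique(x$snps$chromosome)), "chromosome(s);",
      sum(x$subjects$is_reference), "reference subjects;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$genotypes)

## subset by subject and/or SNP index, keeping metadata aligned
subset_gt <- function(data, subjects = NULL, snps = NULL) {
  g <- data$genotypes
  subj <- data$subjects
  sn <- data$snps
  if (!is.null(subjects)) {
    g <- g[subjects, , drop = FALSE]
    subj <- subj[subjects, , drop = FALSE]
    rownames(subj) <- NULL
  }
  if (!is.null(snps)) {
    g <- g[, snps, drop = FALSE]
    sn <- sn[snps, , drop = FALSE]
    rownames(sn) <- NULL
  }
  structure(list(genotypes = g, snps = sn, subjects = subj),
            class = "genotype_table")
}

#' Read PLINK text files
#'
#' Reads a PLINK text fileset (`.ped`/`.map`) into a [genotype_table()].
#' Genotypes are coded additively on `allele_a`, defined per SNP as the first
#' non-missing allele observed when scanning subjects in file order.  A
#' genotype is missing iff either of its two alleles is coded `0`.  The cM
#' column of the `.map` file is used as the genetic position when non-zero.
#'
#' @param ped_path path to the `.ped` file (6 leading columns, then two
#'   allele columns per SNP).
#' @param map_path path to the `.map` file (chromosome, id, cM, bp).
#' @param is_reference logical vector marking reference-pool subjects, or a
#'   single `TRUE` (default) to use every subject.
#' @return a [genotype_table()].
#' @export
read_plink <- function(ped_path, map_path, is_reference = TRUE) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric"))
  names(map) <- c("chromosome", "snp_id", "cm", "bp")
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP ids in ", map_path, ": ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  len <- lengths(fields)
  if (any(len != expected))
    stop("ragged .ped row(s) ", paste(which(len != expected), collapse = ", "),
         ": expected ", expected, " fields, got ",
         paste(unique(len[len != expected]), collapse = "/"))
  ped <- do.call(rbind, fields)
  ids <- ped[, 2L]
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  geno <- matrix(NA_integer_, nrow(ped), m)
  allele_a <- allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    seen <- unique(obs[!is.na(obs)])
    if (length(seen) > 2L)
      stop("SNP ", map$snp_id[j], " is not biallelic: alleles ",
           paste(seen, collapse = ", "))
    allele_a[j] <- if (length(seen)) seen[1L] else "A"
    allele_b[j] <- if (length(seen) > 1L) seen[2L] else "B"
    ok <- !is.na(a1[, j]) & !is.na(a2[, j])
    geno[ok, j] <- (a1[ok, j] == allele_a[j]) + (a2[ok, j] == allele_a[j])
  }

  snps <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                     physical_pos = map$bp,
                     genetic_pos = ifelse(map$cm != 0, map$cm, NA_real_),
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  subjects <- data.frame(subject_id = ids,
                         is_reference = rep_len(is_reference, length(ids)),
                         stringsAsFactors = FALSE)
  genotype_table(geno, snps, subjects)
}

#' Write PLINK text files
#'
#' Inverse of [read_plink()]: writes a `.ped`/`.map` pair such that reading
#' them back reproduces the table (up to allele relabelling for SNPs that are
#' entirely missing).
#'
#' @param data a [genotype_table()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_plink <- function(data, ped_path, map_path) {
  sn <- data$snps
  map <- data.frame(sn$chromosome, sn$snp_id,
                    ifelse(is.na(sn$genetic_pos), 0, sn$genetic_pos),
                    sn$physical_pos)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  g <- data$genotypes
  n <- nrow(g); m <- ncol(g)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    a1[, j] <- ifelse(is.na(gj), "0",
                      ifelse(gj >= 1L, sn$allele_a[j], sn$allele_b[j]))
    a2[, j] <- ifelse(is.na(gj), "0",
                      ifelse(gj == 2L, sn$allele_a[j], sn$allele_b[j]))
  }
  alleles <- matrix("", n, 2L * m)
  alleles[, seq(1L, 2L * m, by = 2L)] <- a1
  alleles[, seq(2L, 2L * m, by = 2L)] <- a2
  lead <- cbind(data$subjects$subject_id, data$subjects$subject_id,
                "0", "0", "0", "-9")
  utils::write.table(cbind(lead, alleles), ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read genotypes from a VCF file
#'
#' Reads biallelic SNP records from a (plain-text or gzipped) VCF into a
#' [genotype_table()].  `allele_a` is the REF allele, so the additive code
#' counts REF copies.  Phase separators are ignored; `./.` is missing.
#' Multi-allelic records are skipped with a message stating how many.
#'
#' @param path path to the VCF file.
#' @param is_reference logical vector (recycled) marking reference subjects.
#' @return a [genotype_table()].
#' @export
read_vcf <- function(path, is_reference = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    message("read_vcf: skipped ", sum(multi), " multi-allelic record(s)")
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # count REF copies; any missing allele ('.') makes the genotype missing
  core <- gsub("\\|", "/", gt)
  split2 <- strsplit(core, "/", fixed = TRUE)
  alle <- matrix(unlist(lapply(split2, function(x) x[1:2])), ncol = 2,
                 byrow = TRUE)
  miss <- is.na(gt) | alle[, 1] == "." | alle[, 2] == "."
  gmat <- (alle[, 1] == "0") + (alle[, 2] == "0")
  gmat[miss] <- NA_integer_
  gmat <- matrix(as.integer(gmat), nrow = nrow(gt), ncol = ncol(gt))

  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  snps <- data.frame(snp_id = ids, chromosome = fix[, "CHROM"],
                     physical_pos = as.numeric(fix[, "POS"]),
                     genetic_pos = NA_real_,
                     allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  subjects <- data.frame(subject_id = colnames(gt),
                         is_reference = rep_len(is_reference, ncol(gt)),
                         stringsAsFactors = FALSE)
  genotype_table(t(gmat), snps, subjects)
}

#' Infer genetic map positions from physical positions
#'
#' Fills in missing genetic positions assuming a constant recombination rate
#' (default 1 cM/Mb, the genome-wide human average).  Positions already
#' supplied are never overwritten, so users of non-human diploid data can
#' provide their own map and bypass the inference entirely.
#'
#' @param snps SNP metadata data frame (as in [genotype_table()]).
#' @param rate recombination rate in cM per Mb; must be non-negative.
#' @return the SNP data frame with `genetic_pos` complete.
#' @export
infer_genetic_map <- function(snps, rate = 1) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("rate must be a single non-negative number (cM/Mb)")
  if (anyNA(snps$physical_pos))
    stop("physical_pos must be present for all SNPs")
  fill <- is.na(snps$genetic_pos)
  snps$genetic_pos[fill] <- snps$physical_pos[fill] * rate / 1e6
  snps
}

#' Reference-pool allele counts at a SNP
#'
#' Counts the alleles among reference-pool subjects at one SNP: `X` copies of
#' `allele_a`, `Y` of `allele_b`, out of `T = X + Y`, twice the number of
#' non-missing reference genotypes.  These counts drive the bias-corrected
#' conditional IBS estimators.
#'
#' @param data a [genotype_table()].
#' @param snp_index column index of the SNP.
#' @return list with elements `X`, `Y`, `T`.
#' @export
allele_counts <- function(data, snp_index) {
  g <- data$genotypes[data$subjects$is_reference, snp_index]
  if (all(is.na(g)))
    stop("SNP ", data$snps$snp_id[snp_index],
         ": no non-missing reference-pool genotypes")
  tt <- 2L * sum(!is.na(g))
  x <- sum(g, na.rm = TRUE)
  list(X = as.integer(x), Y = as.integer(tt - x), T = as.integer(tt))
}

## vectorised allele counts over all SNPs (reference pool); all-missing SNPs
## get T = 0 and are treated as unusable downstream
allele_counts_all <- function(data) {
  g <- data$genotypes[data$subjects$is_reference, , drop = FALSE]
  tt <- 2L * colSums(!is.na(g))
  x <- colSums(g, na.rm = TRUE)
  data.frame(snp_id = data$snps$snp_id, X = as.integer(x),
             Y = as.integer(tt - x), T = as.integer(tt),
             stringsAsFactors = FALSE)
}
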