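#' Bonferroni-type adjustment of the ellipse coverage level
#'
#' With many study pairs, nearly all of them unrelated, an unadjusted
#' unrelated ellipse would leave a fixed fraction of unrelated pairs outside
#' it by chance.  The coverage of the unrelated ellipse is therefore raised
#' to `1 - (1 - coverage) / n_pairs`, where `n_pairs` is the number of study
#' pairs.  Relationship ellipses are not adjusted.
#'
#' @param coverage nominal coverage in (0, 1).
#' @param n_pairs number of study pairs (>= 1).
#' @return the adjusted coverage level.
#' @export
bonferroni_adjust <- function(coverage, n_pairs) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must lie strictly in (0, 1)")
  if (!is.numeric(n_pairs) || n_pairs < 1)
    stop("n_pairs must be >= 1")
  1 - (1 - coverage) / n_pairs
}

#' Fit a bivariate-normal prediction ellipse to a relationship cluster
#'
#' Summarises a cloud of simulated (k0, k1) estimates by its sample mean and
#' covariance, assuming approximate bivariate normality.  A point belongs to
#' the ellipse when its squared Mahalanobis distance from the mean does not
#' exceed the chi-square(2 df) quantile at the coverage level.  Near-singular
#' covariances (e.g. a duplicate/MZ cluster with complete data, where every
#' estimate is exactly (0, 0)) are regularised by a 1e-10 ridge on the
#' diagonal, so that only points at the common location are inside.
#'
#' @param points matrix or data frame with two columns (k0, k1); at least
#'   3 rows.
#' @param coverage coverage level in (0, 1), default 0.95.
#' @param relationship optional label stored with the ellipse.
#' @return object of class `prediction_ellipse`: `mean`, `cov`, `coverage`,
#'   `c` (squared Mahalanobis threshold), `n_sim`, `relationship`.
#' @export
fit_ellipse <- function(points, coverage = 0.95, relationship = NULL) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (k0, k1)")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3L) stop("at least 3 points required to fit an ellipse")
  if (coverage <= 0 || coverage >= 1) stop("coverage must lie in (0, 1)")
  mu <- colMeans(pts)
  S <- stats::cov(pts)
  # ridge-regularise when (near-)singular
  if (!is.finite(det(S)) || det(S) < 1e-18 || rcond(S) < 1e-12)
    S <- S + diag(1e-10, 2L)
  structure(list(relationship = relationship, mean = mu, cov = S,
                 coverage = coverage,
                 c = stats::qchisq(coverage, df = 2L),
                 n_sim = nrow(pts)),
            class = "prediction_ellipse")
}

#' @export
print.prediction_ellipse <- function(x, ...) {
  cat("prediction_ellipse",
      if (!is.null(x$relationship)) paste0("[", x$relationship, "]"),
      sprintf("coverage %.6g, mean (%.4f, %.4f), n_sim %d\n",
              x$coverage, x$mean[1], x$mean[2], x$n_sim))
  invisible(x)
}

#' Ellipse membership
#'
#' `TRUE` iff the squared Mahalanobis distance of the point from the ellipse
#' mean is at most the chi-square threshold (closed boundary).  Vectorised
#' over rows of a two-column matrix.
#'
#' @param point numeric length-2 vector or a two-column matrix of (k0, k1).
#' @param e a [fit_ellipse()] object.
#' @return logical vector.
#' @export
in_ellipse <- function(point, e) {
  pts <- if (is.null(dim(point))) matrix(point, ncol = 2L) else as.matrix(point)
  d2 <- stats::mahalanobis(pts, center = e$mean, cov = e$cov)
  ok <- d2 <= e$c
  ok[!stats::complete.cases(pts)] <- FALSE
  ok
}

## boundary polygon of an ellipse, for plotting
ellipse_boundary <- function(e, n = 181L) {
  theta <- seq(0, 2 * pi, length.out = n)
  R <- chol(e$cov)
  circ <- cbind(cos(theta), sin(theta)) %*% R * sqrt(e$c)
  sweep(circ, 2L, e$mean, `+`)
}

#' Flag study pairs consistent with a close relationship
#'
#' For each non-unrelated relationship, flags the study pairs whose (k0, k1)
#' estimates fall inside that relationship's prediction ellipse (unadjusted,
#' default coverage) and outside the Bonferroni-adjusted unrelated ellipse.
#' Pairs compatible with both a relationship and unrelatedness are left for
#' the analyst (see [query_pair()]), mirroring the judgement call an
#' interactive display would demand.
#'
#' @param study data frame of study estimates (from [estimate_all_pairs()]).
#' @param ellipses named list of [fit_ellipse()] objects, one per simulated
#'   relationship; must contain `unrelated`, already Bonferroni-adjusted for
#'   the number of study pairs.
#' @return data frame of flagged pairs: `subject1`, `subject2`,
#'   `relationship`, `mode`, `k0`, `k1`, sorted by relationship then pair.
#' @export
flag_pairs <- function(study, ellipses) {
  if (!"unrelated" %in% names(ellipses))
    stop("ellipses must include the (adjusted) unrelated ellipse")
  ok <- study$status == "ok"
  pts <- cbind(study$k0, study$k1)
  out_unrel <- !in_ellipse(pts, ellipses$unrelated)
  rels <- setdiff(names(ellipses), "unrelated")
  rows <- lapply(rels, function(r) {
    hit <- ok & in_ellipse(pts, ellipses[[r]]) & out_unrel
    if (!any(hit)) return(NULL)
    data.frame(subject1 = study$subject1[hit], subject2 = study$subject2[hit],
               relationship = r, mode = "automatic",
               k0 = study$k0[hit], k1 = study$k1[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject1 = character(), subject2 = character(),
                      relationship = character(), mode = character(),
                      k0 = numeric(), k1 = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$relationship, out$subject1, out$subject2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Query ellipse memberships for one study pair
#'
#' Deterministic, scriptable replacement for clicking points on an
#' interactive display: reports, for a named pair, its estimates and which
#' prediction ellipses contain it, so any pair of interest can be flagged
#' manually regardless of plotting window.
#'
#' @param study data frame of study estimates.
#' @param ellipses named list of [fit_ellipse()] objects.
#' @param subject1,subject2 subject labels (order-insensitive).
#' @return one-row data frame: pair, `k0`, `k1`, `L`, `status`, and one
#'   logical `in_<relationship>` column per ellipse.
#' @export
query_pair <- function(study, ellipses, subject1, subject2) {
  hit <- (study$subject1 == subject1 & study$subject2 == subject2) |
         (study$subject1 == subject2 & study$subject2 == subject1)
  if (!any(hit)) stop("pair not found: ", subject1, ", ", subject2)
  row <- study[which(hit)[1L], c("subject1", "subject2", "k0", "k1", "L",
                                 "status")]
  for (r in names(ellipses))
    row[[paste0("in_", r)]] <- in_ellipse(c(row$k0, row$k1), ellipses[[r]])
  rownames(row) <- NULL
  row
}
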