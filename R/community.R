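asAbundanceMatrix <- function(table) {
  if (is(table, "AbundanceTable")) abundanceValues(table) else
    as.matrix(table)
}

#' Gini-Simpson diversity index
#'
#' D = 1 - sum(p_i^2) on the renormalized proportions; higher values mean
#' more diverse communities. Accepts percentages or proportions (the index
#' is scale-invariant).
#'
#' @param p non-negative abundance vector with positive sum.
#' @return D in [0, 1).
#' @examples
#' simpsonIndex(c(50, 50))      # 0.5
#' simpsonIndex(rep(10, 10))    # 0.9
#' @export
simpsonIndex <- function(p) {
  if (any(p < 0)) stop("abundances must be non-negative")
  if (sum(p) == 0) stop("abundance vector must not be all zero")
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Pielou evenness
#'
#' Je = H' / ln(S): Shannon entropy (natural log) of the nonzero
#' proportions, normalized by the log richness. Zero-abundance taxa are
#' excluded from S; the index is undefined (NA) with fewer than two
#' nonzero taxa.
#'
#' @param p non-negative abundance vector.
#' @return Je in [0, 1], or NA when fewer than two taxa are present.
#' @examples
#' pielouEvenness(c(0.9, 0.1))  # 0.469
#' @export
pielouEvenness <- function(p) {
  if (any(p < 0)) stop("abundances must be non-negative")
  p <- p[p > 0]
  s <- length(p)
  if (s < 2L) return(NA_real_)
  p <- p / sum(p)
  -sum(p * log(p)) / log(s)
}

#' Bray-Curtis dissimilarity
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i), in [0, 1].
#'
#' @param x,y equal-length non-negative vectors, not both all-zero.
#' @return the dissimilarity.
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all zero")
  sum(abs(x - y)) / tot
}

#' @rdname brayCurtis
#' @param table an [AbundanceTable-class] or samples x taxa matrix.
#' @return \code{brayCurtisMatrix}: a symmetric zero-diagonal matrix of
#'   pairwise dissimilarities.
#' @export
brayCurtisMatrix <- function(table) {
  m <- asAbundanceMatrix(table)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- brayCurtis(m[i, ], m[j, ])
  d
}

permanovaF <- function(d2, groups, n, k) {
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  ssWithin <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng > 1)
      ssWithin <- ssWithin + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / ng
  }
  ssBetween <- ssTotal - ssWithin
  list(F = (ssBetween / (k - 1)) / (ssWithin / (n - k)),
       ssTotal = ssTotal, ssWithin = ssWithin)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Distance-based partition of the total sum of squares: with distances
#' d_ij, SS_total = sum_{i<j} d_ij^2 / n, SS_within is the analogous
#' per-group sum divided by the group size, and pseudo-F =
#' (SS_between/(k-1)) / (SS_within/(n-k)). The p-value is
#' (1 + #{permuted F >= observed F}) / (1 + nPermutations) under seeded
#' permutation of the group labels.
#'
#' @param d square symmetric zero-diagonal distance matrix (or dist).
#' @param groups group labels, one per sample.
#' @param nPermutations number of label permutations.
#' @param seed integer seed for the permutations.
#' @return object of class \code{"PermanovaResult"}: list with
#'   \code{pseudoF}, \code{pValue}, \code{nPermutations}, \code{seed},
#'   \code{df}. \code{pseudoF} is NA (flagged) when the partition is
#'   degenerate (all distances zero).
#' @export
permanova <- function(d, groups, nPermutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("d must be a square symmetric zero-diagonal distance matrix")
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample is required")
  k <- length(unique(groups))
  if (k < 2L) stop("at least two groups are required")
  if (n - k < 1L) stop("residual degrees of freedom are zero (n - k < 1)")
  d2 <- d^2
  obs <- permanovaF(d2, groups, n, k)
  if (obs$ssTotal == 0) {
    res <- list(pseudoF = NA_real_, pValue = NA_real_,
                nPermutations = nPermutations, seed = seed,
                df = c(between = k - 1L, within = n - k))
    class(res) <- "PermanovaResult"
    return(res)
  }
  withr_seed(seed, {
    hits <- 0L
    for (i in seq_len(nPermutations)) {
      f <- permanovaF(d2, sample(groups), n, k)$F
      if (f >= obs$F) hits <- hits + 1L
    }
  })
  res <- list(pseudoF = obs$F, pValue = (1 + hits) / (1 + nPermutations),
              nPermutations = as.integer(nPermutations), seed = seed,
              df = c(between = k - 1L, within = n - k))
  class(res) <- "PermanovaResult"
  res
}

#' @export
print.PermanovaResult <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudoF, x$df[1], x$df[2], x$pValue, x$nPermutations))
  invisible(x)
}

#' Pairwise PERMANOVA comparisons
#'
#' Runs [permanova()] on the sub-matrix of every group pair, optionally
#' adjusting p-values (Benjamini-Hochberg); the default is no adjustment.
#' Pairs without residual degrees of freedom (one sample per group) are
#' skipped with a warning.
#'
#' @inheritParams permanova
#' @param adjust "none" or any method of [stats::p.adjust()].
#' @return data.frame with one row per compared pair: \code{group1},
#'   \code{group2}, \code{pseudoF}, \code{pValue}, \code{pAdjusted}.
#' @export
pairwisePermanova <- function(d, groups, nPermutations = 999L, seed = 1L,
                              adjust = "none") {
  d <- as.matrix(d)
  groups <- as.character(groups)
  gs <- unique(groups)
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    idx <- which(groups %in% pr)
    if (length(idx) < 3L) {
      warning("pair ", pr[1], " vs ", pr[2],
              " has no residual degrees of freedom; skipped")
      return(NULL)
    }
    r <- permanova(d[idx, idx], groups[idx], nPermutations, seed)
    data.frame(group1 = pr[1], group2 = pr[2], pseudoF = r$pseudoF,
               pValue = r$pValue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out))
    out$pAdjusted <- stats::p.adjust(out$pValue, method = adjust)
  out
}

#' Similarity percentage analysis (SIMPER)
#'
#' Decomposes the mean between-group Bray-Curtis dissimilarity into
#' per-taxon contributions: for each pair of groups and taxon i, the mean
#' over all cross-group sample pairs (x, y) of |x_i - y_i| / sum_j(x_j +
#' y_j). Per pair, the contributions sum exactly to the mean between-group
#' dissimilarity; taxa are ranked by contribution.
#'
#' @param table an [AbundanceTable-class] or samples x taxa matrix.
#' @param groups group labels, one per sample.
#' @return named list (one element per group pair "A vs B") of data.frames
#'   with columns \code{taxon}, \code{contribution},
#'   \code{contribution_pct}, ranked by decreasing contribution; each
#'   carries the pair's mean dissimilarity as attribute
#'   \code{"meanDissimilarity"}.
#' @export
simperAnalysis <- function(table, groups) {
  m <- asAbundanceMatrix(table)
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2L) stop("at least two groups are required")
  if (any(table(groups) == 0)) stop("empty group")
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    ia <- which(groups == pr[1]); ib <- which(groups == pr[2])
    contrib <- numeric(ncol(m))
    meanBC <- 0
    np <- 0L
    for (i in ia) for (j in ib) {
      denom <- sum(m[i, ] + m[j, ])
      contrib <- contrib + abs(m[i, ] - m[j, ]) / denom
      meanBC <- meanBC + brayCurtis(m[i, ], m[j, ])
      np <- np + 1L
    }
    contrib <- contrib / np
    meanBC <- meanBC / np
    df <- data.frame(taxon = colnames(m), contribution = contrib,
                     contribution_pct = 100 * contrib / sum(contrib),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$contribution), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "meanDissimilarity") <- meanBC
    df
  })
  names(out) <- vapply(pairs, function(pr) paste(pr, collapse = " vs "),
                       character(1))
  out
}

#' Principal component analysis of an abundance table
#'
#' Filters taxa to those reaching at least \code{minAbundance} percent in
#' at least one sample, mean-centers the columns (unscaled by default:
#' relative abundances share a unit), and eigendecomposes the covariance
#' via [stats::prcomp()]. A deterministic sign convention makes the
#' largest-magnitude loading of every component positive.
#'
#' @param table an [AbundanceTable-class] or samples x taxa matrix of
#'   relative percentages.
#' @param minAbundance percent filter threshold (inclusive).
#' @param scale. also scale columns to unit variance.
#' @return object of class \code{"OrdinationResult"}: list with
#'   \code{scores} (samples x components), \code{loadings} (taxa x
#'   components), \code{varianceExplained} (fraction per component,
#'   non-increasing), \code{centers}, \code{taxa} (the taxa kept), and
#'   \code{degenerate} (TRUE when the filtered table has zero variance).
#' @export
pcaOrdination <- function(table, minAbundance = 0.9, scale. = FALSE) {
  m <- asAbundanceMatrix(table)
  if (nrow(m) < 2L) stop("at least two samples are required")
  keep <- apply(m, 2, max) >= minAbundance
  if (sum(keep) < 2L)
    stop("fewer than two taxa pass the ", minAbundance, "% filter")
  m <- m[, keep, drop = FALSE]
  totVar <- sum(apply(m, 2, stats::var))
  if (totVar == 0) {
    res <- list(scores = NULL, loadings = NULL, varianceExplained = NULL,
                centers = colMeans(m), taxa = colnames(m),
                degenerate = TRUE)
    class(res) <- "OrdinationResult"
    return(res)
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  # sign convention: largest-magnitude loading per component positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  res <- list(scores = pc$x, loadings = pc$rotation,
              varianceExplained = pc$sdev^2 / sum(pc$sdev^2),
              centers = pc$center, taxa = colnames(m), degenerate = FALSE)
  class(res) <- "OrdinationResult"
  res
}

#' @export
print.OrdinationResult <- function(x, ...) {
  if (x$degenerate) {
    cat("OrdinationResult: degenerate (zero variance after filtering)\n")
    return(invisible(x))
  }
  cat("OrdinationResult:", nrow(x$scores), "samples,", length(x$taxa),
      "taxa\n  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$varianceExplained, 4)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample alpha diversity table
#'
#' @param table an [AbundanceTable-class] or samples x taxa matrix.
#' @return data.frame with columns \code{sample_id}, \code{Simpson (D)},
#'   \code{Pielou (Je)}.
#' @export
diversityTable <- function(table) {
  m <- asAbundanceMatrix(table)
  out <- data.frame(
    sample_id = rownames(m),
    simpson = apply(m, 1, simpsonIndex),
    pielou = apply(m, 1, pielouEvenness),
    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "Simpson (D)", "Pielou (Je)")
  rownames(out) <- NULL
  out
}
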