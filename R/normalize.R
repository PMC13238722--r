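## Expression preprocessing shared by differential expression and network
## construction: low-count gene filtering, trimmed-mean-of-M-values (TMM)
## scaling factors, log-CPM and an approximate variance-stabilizing
## transform.

.as_count_matrix <- function(counts) {
  if (is(counts, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(counts, "counts")
  }
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  counts
}

#' Filter low-count genes
#'
#' A gene is removed when it has fewer than \code{min_count} counts in
#' more than \code{max_low_fraction} of the samples. Defaults follow the
#' human profile (5 counts, 70\%); the mouse profile uses 90\%
#' (\code{max_low_fraction = 0.9}). The boundary is strict: a gene low in
#' exactly the threshold fraction of samples is kept.
#'
#' @param counts gene x sample integer matrix (or a SummarizedExperiment
#'   with a \code{counts} assay).
#' @param min_count count threshold defining a "low" observation.
#' @param max_low_fraction maximum tolerated fraction of low samples, in
#'   (0, 1).
#' @return the filtered count matrix.
#' @export
filterGenes <- function(counts, min_count = 5, max_low_fraction = 0.70) {
  m <- .as_count_matrix(counts)
  stopifnot(max_low_fraction > 0, max_low_fraction < 1)
  low_frac <- rowMeans(m < min_count)
  keep <- low_frac <= max_low_fraction + 1e-12
  if (!any(keep)) stop("no genes pass the low-count filter")
  m[keep, , drop = FALSE]
}

## TMM weighted trimmed mean for one sample against the reference.
.tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                      logratio_trim = 0.30, sum_trim = 0.05,
                      a_cutoff = -1e10) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) stop("sample shares no nonzero genes with the reference")
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  fin <- is.finite(M) & is.finite(A) & A > a_cutoff
  M <- M[fin]; A <- A[fin]; obs <- obs[fin]; ref <- ref[fin]
  if (max(abs(M)) < 1e-6) return(1)
  # inverse asymptotic (delta-method binomial) variance weights
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values per sample against a reference column, with
#' 30\% trimming on the log-ratios (M), 5\% on the average log-abundances
#' (A), genes zero in either sample excluded, and precision (inverse
#' asymptotic variance) weighting. Factors are rescaled to geometric
#' mean 1, so depth itself is absorbed by the library sizes and the factors
#' only correct composition bias.
#'
#' @param counts gene x sample count matrix.
#' @param reference reference sample id or index, or \code{"auto"}
#'   (column whose upper-quartile count fraction is closest to the mean
#'   upper quartile).
#' @return named numeric vector of normalization factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, reference = "auto") {
  m <- .as_count_matrix(counts)
  if (ncol(m) < 2) stop("need at least 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("library sizes must be positive")
  if (identical(reference, "auto")) {
    # upper quartiles on genes expressed in at least one sample (library
    # sizes stay those of the full matrix)
    nz <- m[rowSums(m > 0) > 0, , drop = FALSE]
    uq <- apply(nz, 2, quantile, 0.75) / lib
    ref_i <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    ref_i <- match(reference, colnames(m))
    if (is.na(ref_i)) stop("reference sample not found")
  } else {
    ref_i <- as.integer(reference)
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref_i) return(1)
    .tmm_pair(m[, j], m[, ref_i], lib[j], lib[ref_i])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Log2 counts per million
#'
#' \code{log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)}, the
#' effective library size being the raw total scaled by the TMM factor.
#'
#' @param counts gene x sample count matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @param prior_count prior count added to the numerator (default 0.5).
#' @param lib_size optional library sizes; default column sums.
#' @return matrix of log2-CPM values with the input dimnames.
#' @export
logCPM <- function(counts, factors = NULL, prior_count = 0.5, lib_size = NULL) {
  m <- .as_count_matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(m)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  stopifnot(all(factors > 0), length(factors) == ncol(m))
  eff <- lib_size * factors
  out <- log2(t((t(m) + prior_count) / (eff + 2 * prior_count)) * 1e6)
  dimnames(out) <- dimnames(m)
  out
}

#' Approximate variance-stabilizing transform
#'
#' Shifted log: \code{log2(normalized count + pseudo_count)} where the
#' normalized count is the raw count rescaled to a common effective library
#' size. This flattens the negative-binomial mean-variance relation enough
#' for the rank/correlation-based network stage (the slope of log-variance
#' on log-mean drops below 0.3 on NB-simulated data); it is not a full
#' dispersion-fit VST and is documented as an approximation.
#'
#' @param counts gene x sample count matrix.
#' @param factors per-sample TMM factors (default all 1).
#' @param pseudo_count shift before the log (default 2, chosen so the
#'   log-variance vs log-mean slope drops below 0.3 on negative-binomial
#'   simulations at FFPE-like dispersion).
#' @return matrix of transformed values.
#' @export
vstTransform <- function(counts, factors = NULL, pseudo_count = 2) {
  m <- .as_count_matrix(counts)
  if (is.null(factors)) factors <- rep(1, ncol(m))
  eff <- colSums(m) * factors
  norm <- t(t(m) / eff) * mean(eff)
  out <- log2(norm + pseudo_count)
  dimnames(out) <- dimnames(m)
  out
}

#' Filter, normalize and transform a cohort in one step
#'
#' Convenience wrapper: applies \code{\link{filterGenes}},
#' \code{\link{tmmFactors}}, \code{\link{logCPM}} and
#' \code{\link{vstTransform}} and returns a
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}} carrying the
#' filtered counts plus \code{logcpm} and \code{vst} assays, the TMM
#' factors in \code{colData} and any clinical columns passed through.
#'
#' @param counts count matrix or SummarizedExperiment with a \code{counts}
#'   assay (clinical columns in its \code{colData} are retained).
#' @param profile \code{"human"} (filter at 70\% low samples) or
#'   \code{"mouse"} (90\%).
#' @return a SummarizedExperiment with assays \code{counts},
#'   \code{logcpm}, \code{vst}.
#' @export
normalizeCohort <- function(counts, profile = c("human", "mouse")) {
  profile <- match.arg(profile)
  cd <- NULL
  if (is(counts, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(counts)
  }
  max_low <- if (profile == "human") 0.70 else 0.90
  m <- filterGenes(counts, min_count = 5, max_low_fraction = max_low)
  f <- tmmFactors(m)
  lc <- logCPM(m, f)
  vs <- vstTransform(m, f)
  if (is.null(cd)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(m))
  }
  cd$norm_factor <- unname(f)
  cd$lib_size <- unname(colSums(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m, logcpm = lc, vst = vs),
    colData = cd
  )
}
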