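## Differential expression: per-gene linear models on log-CPM with
## mean-variance precision weights (voom-style) and empirical-Bayes
## moderation of the residual variances, followed by Benjamini-Hochberg
## adjustment and DEG calling at the study thresholds
## (|log2FC| > 0 & FDR < 0.05 human; |log2FC| > 1 & FDR < 0.05 mouse).

#' Build a two-group design matrix with optional z-scored covariates
#'
#' The group enters as a 0/1 indicator (second level = 1, contrast
#' loss - presence when levels are presence/loss); numeric covariates are
#' z-scored (mean 0, sd 1) before entering the model, mirroring the
#' handling of age and DV200.
#'
#' @param group factor or character of length n (two levels).
#' @param covariates optional data.frame of numeric covariates.
#' @return design matrix with an intercept, the group indicator and the
#'   z-scored covariates; the group column is named \code{"group"}.
#' @export
buildDesign <- function(group, covariates = NULL) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("group must have exactly 2 levels")
  X <- cbind("(Intercept)" = 1, group = as.numeric(g == levels(g)[2]))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in colnames(covariates)) {
      v <- covariates[[nm]]
      if (!is.numeric(v)) stop("covariates must be numeric")
      s <- sd(v)
      X <- cbind(X, (v - mean(v)) / if (s > 0) s else 1)
      colnames(X)[ncol(X)] <- nm
    }
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  X
}

## per-gene OLS/WLS machinery shared by voomWeights and moderatedFit
.gene_lm <- function(y, design, weights = NULL) {
  n <- ncol(y); p <- ncol(design); G <- nrow(y)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(y), colnames(design)))
  sigma2 <- numeric(G)
  unscaled <- matrix(NA_real_, G, p)
  fitted <- matrix(NA_real_, G, n)
  if (is.null(weights)) {
    qrX <- qr(design)
    XtXinv <- chol2inv(qr.R(qrX))
    for (g in seq_len(G)) {
      cf <- qr.coef(qrX, y[g, ])
      fit <- drop(design %*% cf)
      res <- y[g, ] - fit
      beta[g, ] <- cf
      fitted[g, ] <- fit
      sigma2[g] <- sum(res^2) / (n - p)
      unscaled[g, ] <- sqrt(diag(XtXinv))
    }
  } else {
    for (g in seq_len(G)) {
      w <- weights[g, ]
      sw <- sqrt(w)
      Xw <- design * sw
      qrX <- qr(Xw)
      cf <- qr.coef(qrX, y[g, ] * sw)
      XtXinv <- chol2inv(qr.R(qrX))
      fit <- drop(design %*% cf)
      res <- y[g, ] - fit
      beta[g, ] <- cf
      fitted[g, ] <- fit
      sigma2[g] <- sum(w * res^2) / (n - p)
      unscaled[g, ] <- sqrt(diag(XtXinv))
    }
  }
  list(coefficients = beta, sigma2 = sigma2, stdev_unscaled = unscaled,
       fitted = fitted, df_residual = n - p)
}

#' Mean-variance precision weights (voom-style)
#'
#' Fits per-gene OLS on the log-CPM matrix, smooths the quarter-root
#' residual standard deviations against average log2 count with lowess
#' (span 0.5, clipped at the range ends), and returns per-observation
#' inverse predicted variances evaluated at each observation's fitted
#' log-count.
#'
#' @param logcpm gene x sample log2-CPM matrix.
#' @param design design matrix (see \code{\link{buildDesign}}).
#' @param lib_size per-sample effective library sizes used to map log-CPM
#'   back to log-counts; default 1e6 (i.e. the log-CPM scale itself).
#' @param span lowess span (default 0.5).
#' @return gene x sample matrix of positive finite weights.
#' @export
voomWeights <- function(logcpm, design, lib_size = NULL, span = 0.5) {
  y <- as.matrix(logcpm)
  n <- ncol(y)
  if (n < ncol(design) + 1) stop("fewer samples than design columns + 1")
  if (nrow(y) < 2) {
    warning("single-gene input: falling back to unit weights")
    return(matrix(1, nrow(y), n, dimnames = dimnames(y)))
  }
  if (is.null(lib_size)) lib_size <- rep(1e6, n)
  fit <- .gene_lm(y, design)
  # mean log2 count per gene and quarter-root sd, as in the voom procedure
  sx <- rowMeans(y) + mean(log2(lib_size + 1)) - log2(1e6)
  sy <- sqrt(sqrt(fit$sigma2))
  ok <- is.finite(sx) & is.finite(sy) & fit$sigma2 > 0
  if (sum(ok) < 10) {
    warning("too few genes with positive residual variance: unit weights")
    return(matrix(1, nrow(y), n, dimnames = dimnames(y)))
  }
  lo <- lowess(sx[ok], sy[ok], f = span)
  # per-observation fitted log2 count, clipped into the smoothed range
  fitted_cpm <- fit$fitted
  fitted_cnt <- t(t(fitted_cpm) + log2(lib_size + 1) - log2(1e6))
  fitted_cnt <- pmin(pmax(fitted_cnt, min(lo$x)), max(lo$x))
  pred <- approx(lo$x, lo$y, xout = as.vector(fitted_cnt), rule = 2,
                 ties = "ordered")$y
  w <- matrix(pred^-4, nrow(y), n, dimnames = dimnames(y))
  w[!is.finite(w) | w <= 0] <- 1
  w
}

## Newton solver for trigamma(x) = y
.trigamma_inverse <- function(y) {
  vapply(y, function(t) {
    if (!is.finite(t) || t <= 0) return(Inf)
    if (t > 1e7) return(1 / sqrt(t))
    x <- 0.5 + 1 / t
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / t) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

## Smyth-style moment matching of d0 (prior df) and s0^2 (prior variance)
## from the log residual variances.
.fit_fdist <- function(sigma2, df) {
  ok <- is.finite(sigma2)
  if (sum(ok) < 3) return(list(df_prior = 4, s2_prior = median(sigma2[sigma2 > 0])))
  s2 <- sigma2[ok]
  s2 <- pmax(s2, 1e-5 * median(s2))   # offset exact zeros away from zero
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(df_prior = Inf, s2_prior = exp(emean)))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  if (!is.finite(d0) || d0 <= 0) d0 <- 4
  list(df_prior = d0, s2_prior = s02)
}

#' Moderated per-gene differential expression fit
#'
#' Weighted least squares per gene followed by empirical-Bayes shrinkage of
#' the residual variances toward a common prior estimated by moment
#' matching on the log variances: the posterior variance is
#' \code{(d0*s0^2 + dg*sg^2) / (d0 + dg)} and the moderated t uses
#' \code{dg + d0} degrees of freedom. With \code{d0 = 0} the moderated t
#' equals the ordinary t; as \code{d0 -> Inf} all posterior variances
#' approach \code{s0^2}.
#'
#' @param logcpm gene x sample log2-CPM matrix.
#' @param design design matrix; the tested coefficient is \code{coef_name}.
#' @param weights optional gene x sample precision weights (e.g. from
#'   \code{\link{voomWeights}}).
#' @param coef_name tested coefficient (default \code{"group"}).
#' @return data.frame per gene: \code{gene}, \code{log2FC},
#'   \code{AveExpr}, \code{t}, \code{p_value}, \code{df_total},
#'   plus attributes \code{df_prior} and \code{s2_prior}.
#' @export
moderatedFit <- function(logcpm, design, weights = NULL, coef_name = "group") {
  y <- as.matrix(logcpm)
  if (!coef_name %in% colnames(design)) stop("coef_name not in design")
  if (ncol(y) - ncol(design) < 2) stop("need >= 2 residual degrees of freedom")
  fit <- .gene_lm(y, design, weights)
  dg <- fit$df_residual
  if (mean(fit$sigma2 <= 1e-12) > 0.5) {
    stop("degenerate input: zero residual variance in > 50% of genes")
  }
  hyper <- .fit_fdist(fit$sigma2, dg)
  d0 <- hyper$df_prior; s02 <- hyper$s2_prior
  if (is.finite(d0)) {
    s2_post <- (d0 * s02 + dg * fit$sigma2) / (d0 + dg)
    df_total <- dg + d0
  } else {
    s2_post <- rep(s02, length(fit$sigma2))
    df_total <- Inf
  }
  j <- match(coef_name, colnames(design))
  beta <- fit$coefficients[, j]
  tmod <- beta / (fit$stdev_unscaled[, j] * sqrt(s2_post))
  p <- 2 * pt(-abs(tmod), df = df_total)
  out <- data.frame(
    gene = rownames(y) %||% as.character(seq_len(nrow(y))),
    log2FC = unname(beta),
    AveExpr = unname(rowMeans(y)),
    t = unname(tmod),
    p_value = unname(p),
    df_total = df_total,
    stringsAsFactors = FALSE
  )
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in [0, 1]; NA propagates and is excluded from
#'   the number of tests m.
#' @return adjusted p-values (FDR), capped at 1, same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Call differentially expressed genes
#'
#' Significance at strict inequalities \code{|log2FC| > lfc_min} and
#' \code{FDR < fdr_max}. The study thresholds are \code{lfc_min = 0}
#' (human) and \code{lfc_min = 1} (mouse), both at FDR < 0.05.
#'
#' @param res data.frame from \code{\link{moderatedFit}}.
#' @param lfc_min minimum absolute log2 fold change (strict).
#' @param fdr_max FDR ceiling (strict).
#' @return \code{res} with \code{padj} and logical \code{significant}
#'   columns appended.
#' @export
callDEGs <- function(res, lfc_min = 0, fdr_max = 0.05) {
  stopifnot(lfc_min >= 0, fdr_max >= 0)
  res$padj <- bhAdjust(res$p_value)
  res$significant <- abs(res$log2FC) > lfc_min & res$padj < fdr_max
  res$significant[is.na(res$significant)] <- FALSE
  res
}

#' Run the full two-group differential expression stage
#'
#' Convenience wrapper: builds the design (group + z-scored covariates),
#' computes log-CPM from the counts if needed, derives voom-style weights,
#' fits the moderated model and calls DEGs at the profile thresholds
#' (human: |log2FC| > 0; mouse: |log2FC| > 1, both FDR < 0.05).
#'
#' @param counts gene x sample count matrix (filtered).
#' @param group two-level factor (first level = reference/presence).
#' @param covariates optional numeric covariate data.frame (z-scored
#'   internally), e.g. age and DV200 for the human profile.
#' @param profile \code{"human"} or \code{"mouse"} DEG thresholds.
#' @param factors optional TMM factors (computed if NULL).
#' @return DEG table as from \code{\link{callDEGs}}.
#' @export
runDE <- function(counts, group, covariates = NULL,
                  profile = c("human", "mouse"), factors = NULL) {
  profile <- match.arg(profile)
  m <- .as_count_matrix(counts)
  if (is.null(factors)) factors <- tmmFactors(m)
  lc <- logCPM(m, factors)
  design <- buildDesign(group, covariates)
  eff <- colSums(m) * factors
  w <- voomWeights(lc, design, lib_size = eff)
  res <- moderatedFit(lc, design, weights = w)
  callDEGs(res, lfc_min = if (profile == "human") 0 else 1, fdr_max = 0.05)
}
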