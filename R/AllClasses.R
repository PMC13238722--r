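#' @import methods
#' @importFrom stats approx coef cor dist hclust cutree lowess mad median
#'   pchisq pnorm pt qnorm quantile rbinom rexp rgamma rlnorm rnbinom rnorm
#'   runif sd setNames var prcomp wilcox.test model.matrix complete.cases
#' @importFrom utils head tail
NULL

#' ModuleSet: gene-to-module assignment with eigengenes and connectivity
#'
#' Container for the result of signed weighted co-expression network
#' analysis: one module label per gene (color-style names, with
#' \code{"grey"} marking unassigned genes), the module eigengene matrix
#' (modules x samples), the kME table of gene-eigengene correlations and
#' per-gene connectivity statistics.
#'
#' @slot labels named character vector, one module label per gene.
#' @slot eigengenes numeric matrix, modules x samples; rows named by module.
#' @slot kME numeric matrix, genes x modules, correlation of each gene's
#'   profile with each module eigengene.
#' @slot connectivity data.frame with columns \code{kTotal}, \code{kWithin},
#'   \code{kOut}, \code{kDiff} per gene.
#' @slot power soft-threshold power used to build the adjacency.
#' @slot params list of network parameters used.
#'
#' @exportClass ModuleSet
setClass("ModuleSet",
  representation(
    labels = "character",
    eigengenes = "matrix",
    kME = "matrix",
    connectivity = "data.frame",
    power = "numeric",
    params = "list"
  )
)

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@labels))) {
    msg <- c(msg, "labels must be a named character vector (gene ids)")
  }
  mods <- setdiff(unique(object@labels), "grey")
  if (nrow(object@eigengenes) > 0 && !all(mods %in% rownames(object@eigengenes))) {
    msg <- c(msg, "every non-grey module must have an eigengene row")
  }
  if (nrow(object@connectivity) > 0) {
    need <- c("kTotal", "kWithin", "kOut", "kDiff")
    if (!all(need %in% colnames(object@connectivity))) {
      msg <- c(msg, "connectivity needs kTotal/kWithin/kOut/kDiff columns")
    } else {
      d <- object@connectivity
      if (max(abs(d$kDiff - (d$kWithin - d$kOut))) > 1e-6) {
        msg <- c(msg, "kDiff must equal kWithin - kOut")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdScan: H-score threshold calibration result
#'
#' One row per candidate H-score cutoff with the two-sided rank-sum
#' p-value comparing a transcriptional signature between the PTEN-loss
#' (H-score below or at the cutoff) and PTEN-presence groups, the group
#' sizes, and the selected threshold (smallest p, ties toward the smaller
#' threshold).
#'
#' @slot table data.frame with columns \code{threshold}, \code{n_loss},
#'   \code{n_presence}, \code{statistic}, \code{p_value}, \code{eligible}.
#' @slot selected numeric, the selected threshold.
#' @slot min_group minimum admissible group size used in the scan.
#'
#' @exportClass ThresholdScan
setClass("ThresholdScan",
  representation(
    table = "data.frame",
    selected = "numeric",
    min_group = "numeric"
  )
)

#' SignatureScores: per-sample mean z-scored expression of a gene set
#'
#' @slot name signature name.
#' @slot scores named numeric vector of per-sample scores.
#' @slot coverage fraction of signature genes found in the matrix.
#' @slot genes_used character vector of signature genes present.
#'
#' @exportClass SignatureScores
setClass("SignatureScores",
  representation(
    name = "character",
    scores = "numeric",
    coverage = "numeric",
    genes_used = "character"
  )
)

setValidity("SignatureScores", function(object) {
  msg <- character()
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (object@coverage <= 0 || object@coverage > 1) {
    msg <- c(msg, "coverage must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' CoxPHFit: fitted Cox proportional-hazards model
#'
#' Result of partial-likelihood maximization by Newton-Raphson with Efron
#' handling of tied event times. Hazard ratios are \code{exp(coef)} and the
#' 95\% confidence interval is Wald on the log-hazard scale.
#'
#' @slot coef named coefficient vector.
#' @slot se standard errors from the inverse observed information.
#' @slot var variance-covariance matrix of the coefficients.
#' @slot loglik length-2 numeric: log partial likelihood at beta = 0 and at
#'   the maximum.
#' @slot score_test score (log-rank type) chi-squared statistic at beta = 0.
#' @slot concordance Harrell's C over usable pairs.
#' @slot n,nevent numbers of subjects and events.
#' @slot iter Newton-Raphson iterations used.
#' @slot converged logical convergence flag.
#' @slot linear_predictor per-subject linear predictor at the estimate.
#'
#' @exportClass CoxPHFit
setClass("CoxPHFit",
  representation(
    coef = "numeric",
    se = "numeric",
    var = "matrix",
    loglik = "numeric",
    score_test = "numeric",
    concordance = "numeric",
    n = "integer",
    nevent = "integer",
    iter = "integer",
    converged = "logical",
    linear_predictor = "numeric"
  )
)

setValidity("CoxPHFit", function(object) {
  msg <- character()
  if (length(object@loglik) != 2) msg <- c(msg, "loglik must be length 2 (null, fitted)")
  if (object@converged && diff(object@loglik) < -1e-8) {
    msg <- c(msg, "fitted log-likelihood must not be below the null at convergence")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "ModuleSet", function(object) {
  tab <- sort(table(object@labels), decreasing = TRUE)
  cat("ModuleSet with", length(object@labels), "genes in",
      length(setdiff(names(tab), "grey")), "modules (power =", object@power, ")\n")
  print(head(tab, 10))
  invisible(object)
})

setMethod("show", "ThresholdScan", function(object) {
  cat("ThresholdScan over", nrow(object@table), "candidate H-score cutoffs\n")
  cat("  selected threshold:", object@selected, "\n")
  i <- which(object@table$threshold == object@selected)
  if (length(i) == 1) {
    cat(sprintf("  rank-sum p = %.3g (n_loss = %d, n_presence = %d)\n",
                object@table$p_value[i], object@table$n_loss[i],
                object@table$n_presence[i]))
  }
  invisible(object)
})

setMethod("show", "SignatureScores", function(object) {
  cat(sprintf("SignatureScores '%s': %d samples, coverage %.1f%% (%d genes)\n",
              object@name, length(object@scores), 100 * object@coverage,
              length(object@genes_used)))
  invisible(object)
})

setMethod("show", "CoxPHFit", function(object) {
  cat("Cox proportional-hazards fit (Efron ties):",
      object@n, "subjects,", object@nevent, "events\n")
  hr <- exp(object@coef)
  lo <- exp(object@coef - 1.96 * object@se)
  hi <- exp(object@coef + 1.96 * object@se)
  z <- object@coef / object@se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(coef = object@coef, HR = hr, lower95 = lo, upper95 = hi,
                    se = object@se, p = p)
  print(round(out, 4))
  lr <- 2 * (object@loglik[2] - object@loglik[1])
  cat(sprintf("LR chi2 = %.2f on %d df; concordance = %.3f\n",
              lr, length(object@coef), object@concordance))
  invisible(object)
})

## ---- accessors -------------------------------------------------------------

#' Module labels of a ModuleSet
#' @param object a \code{ModuleSet}
#' @return named character vector of gene-to-module assignments
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ModuleSet", function(object) object@labels)

#' Module eigengene matrix (modules x samples)
#' @param object a \code{ModuleSet}
#' @return numeric matrix
#' @export
setGeneric("moduleEigengenes", function(object) standardGeneric("moduleEigengenes"))

#' @rdname moduleEigengenes
#' @export
setMethod("moduleEigengenes", "ModuleSet", function(object) object@eigengenes)

#' Genes assigned to one module
#' @param object a \code{ModuleSet}
#' @param module module label
#' @return character vector of gene ids
#' @export
setGeneric("moduleGenes", function(object, module) standardGeneric("moduleGenes"))

#' @rdname moduleGenes
#' @export
setMethod("moduleGenes", "ModuleSet", function(object, module) {
  names(object@labels)[object@labels == module]
})

#' kME (module membership) table
#' @param object a \code{ModuleSet}
#' @return genes x modules correlation matrix
#' @export
setGeneric("moduleKME", function(object) standardGeneric("moduleKME"))

#' @rdname moduleKME
#' @export
setMethod("moduleKME", "ModuleSet", function(object) object@kME)

#' Per-gene connectivity statistics
#' @param object a \code{ModuleSet}
#' @return data.frame with kTotal, kWithin, kOut, kDiff
#' @export
setGeneric("connectivity", function(object) standardGeneric("connectivity"))

#' @rdname connectivity
#' @export
setMethod("connectivity", "ModuleSet", function(object) object@connectivity)

#' Selected threshold of a ThresholdScan
#' @param object a \code{ThresholdScan}
#' @return numeric threshold
#' @export
setGeneric("selectedThreshold", function(object) standardGeneric("selectedThreshold"))

#' @rdname selectedThreshold
#' @export
setMethod("selectedThreshold", "ThresholdScan", function(object) object@selected)

#' Scan table of a ThresholdScan
#' @param object a \code{ThresholdScan}
#' @return data.frame of candidates, group sizes and p-values
#' @export
setGeneric("scanTable", function(object) standardGeneric("scanTable"))

#' @rdname scanTable
#' @export
setMethod("scanTable", "ThresholdScan", function(object) object@table)

#' Per-sample signature scores
#' @param object a \code{SignatureScores}
#' @return named numeric vector
#' @export
setGeneric("signatureScores", function(object) standardGeneric("signatureScores"))

#' @rdname signatureScores
#' @export
setMethod("signatureScores", "SignatureScores", function(object) object@scores)

#' Signature coverage (fraction of genes found)
#' @param object a \code{SignatureScores}
#' @return numeric in (0, 1]
#' @export
setGeneric("signatureCoverage", function(object) standardGeneric("signatureCoverage"))

#' @rdname signatureCoverage
#' @export
setMethod("signatureCoverage", "SignatureScores", function(object) object@coverage)

#' @export
#' @describeIn CoxPHFit coefficient vector
#' @param object a \code{CoxPHFit}
setMethod("coef", "CoxPHFit", function(object) object@coef)

#' Hazard ratios with Wald 95\% confidence intervals
#' @param object a \code{CoxPHFit}
#' @return data.frame with HR, lower95, upper95, p
#' @export
setGeneric("hazardRatios", function(object) standardGeneric("hazardRatios"))

#' @rdname hazardRatios
#' @export
setMethod("hazardRatios", "CoxPHFit", function(object) {
  z <- object@coef / object@se
  data.frame(
    term = names(object@coef),
    HR = exp(object@coef),
    lower95 = exp(object@coef - 1.96 * object@se),
    upper95 = exp(object@coef + 1.96 * object@se),
    p = 2 * pnorm(-abs(z)),
    row.names = NULL
  )
})

#' Log partial likelihoods (null, fitted)
#' @param object a \code{CoxPHFit}
#' @return length-2 numeric vector
#' @export
setGeneric("logLiks", function(object) standardGeneric("logLiks"))

#' @rdname logLiks
#' @export
setMethod("logLiks", "CoxPHFit", function(object) object@loglik)

#' Harrell's concordance index of a fit
#' @param object a \code{CoxPHFit}
#' @return numeric in [0, 1]
#' @export
setGeneric("concordanceIndex", function(object) standardGeneric("concordanceIndex"))

#' @rdname concordanceIndex
#' @export
setMethod("concordanceIndex", "CoxPHFit", function(object) object@concordance)

#' Linear predictor of a fit
#' @param object a \code{CoxPHFit}
#' @return per-subject numeric vector
#' @export
setGeneric("linearPredictor", function(object) standardGeneric("linearPredictor"))

#' @rdname linearPredictor
#' @export
setMethod("linearPredictor", "CoxPHFit", function(object) object@linear_predictor)
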