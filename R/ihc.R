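## Immunohistochemistry scoring: core-level QC, H-score computation,
## per-patient aggregation, binary PTEN status and threshold calibration.
##
## Each tissue-microarray core carries a tri-state tumor-presence call, a
## tri-state stromal PTEN stain (the internal control: stromal cells should
## always retain PTEN, so a negative stroma flags a technical problem, not
## biology) and the percentages of epithelial cells at each staining
## intensity.

.qc_reasons <- c("no_tumor", "stroma_negative", "staining_failure", "core_absent")

#' Compute the H-score from staining-intensity percentages
#'
#' H-score = 3 x \%strong + 2 x \%moderate + 1 x \%weak, on percentages of
#' epithelial cells per intensity bin, giving a semi-quantitative value in
#' [0, 300].
#'
#' @param pct_weak,pct_moderate,pct_strong percentages in [0, 100]
#'   (vectorized).
#' @param pct_negative optional percentage of negative cells; when supplied
#'   the four bins must sum to 100 within +/- 0.5 (rounding tolerance).
#' @return numeric H-score(s) in [0, 300].
#' @examples
#' computeHScore(50, 30, 20)  # 170
#' @export
computeHScore <- function(pct_weak, pct_moderate, pct_strong, pct_negative = NULL) {
  p <- cbind(pct_weak, pct_moderate, pct_strong)
  if (any(p < 0 | p > 100, na.rm = TRUE)) {
    stop("intensity percentages must lie in [0, 100]")
  }
  if (!is.null(pct_negative)) {
    tot <- pct_negative + pct_weak + pct_moderate + pct_strong
    if (any(abs(tot - 100) > 0.5, na.rm = TRUE)) {
      stop("intensity percentages must sum to 100 (+/- 0.5)")
    }
  }
  as.numeric(3 * pct_strong + 2 * pct_moderate + 1 * pct_weak)
}

#' Core-level quality control
#'
#' A core is valid iff tumor tissue is present AND the stromal PTEN stain is
#' positive. Invalid cores carry one of the reasons \code{no_tumor},
#' \code{stroma_negative}, \code{staining_failure} or \code{core_absent}.
#' Cores with intensity percentages recorded despite an absent tumor call
#' are contradictory; they are flagged and treated as invalid.
#'
#' @param cores data.frame with columns \code{patient_id}, \code{core_id},
#'   \code{tumor_present} (\code{"present"}, \code{"absent"},
#'   \code{"technical_failure"}), \code{stroma_stain} (\code{"positive"},
#'   \code{"negative"}, \code{"undetermined"}) and the four intensity
#'   percentage columns (may be NA on failed cores).
#' @return the input with logical \code{qc_valid}, character
#'   \code{qc_reason} (NA when valid) and logical \code{contradictory}
#'   columns appended.
#' @export
evaluateCoreQC <- function(cores) {
  stopifnot(is.data.frame(cores),
            all(c("patient_id", "core_id", "tumor_present", "stroma_stain")
                %in% colnames(cores)))
  tp <- as.character(cores$tumor_present)
  ss <- as.character(cores$stroma_stain)
  bad_tp <- !tp %in% c("present", "absent", "technical_failure")
  bad_ss <- !ss %in% c("positive", "negative", "undetermined")
  if (any(bad_tp | bad_ss)) stop("unknown tumor_present / stroma_stain state")

  valid <- tp == "present" & ss == "positive"
  reason <- rep(NA_character_, nrow(cores))
  # precedence: a core that is physically absent/failed trumps stain calls
  reason[!valid & tp == "technical_failure"] <- "core_absent"
  reason[!valid & is.na(reason) & tp == "absent"] <- "no_tumor"
  reason[!valid & is.na(reason) & ss == "negative"] <- "stroma_negative"
  reason[!valid & is.na(reason) & ss == "undetermined"] <- "staining_failure"

  has_int <- if ("pct_strong" %in% colnames(cores)) {
    !is.na(cores$pct_strong) | !is.na(cores$pct_weak) | !is.na(cores$pct_moderate)
  } else rep(FALSE, nrow(cores))
  contradictory <- has_int & tp %in% c("absent", "technical_failure")

  cores$qc_valid <- valid
  cores$qc_reason <- reason
  cores$contradictory <- contradictory
  cores
}

#' Patient inclusion from core-level QC
#'
#' A patient is included iff at least one of their cores passes QC
#' (tumor present with positive stromal stain).
#'
#' @param cores data.frame as accepted by \code{\link{evaluateCoreQC}} (the
#'   QC columns are added if missing).
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{n_cores}, \code{n_valid_cores}, logical \code{included} and a
#'   semicolon-collapsed \code{reasons} string for excluded patients.
#' @export
includePatients <- function(cores) {
  if (nrow(cores) == 0) stop("empty core table")
  if (!"qc_valid" %in% colnames(cores)) cores <- evaluateCoreQC(cores)
  sp <- split(cores, cores$patient_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      patient_id = d$patient_id[1],
      n_cores = nrow(d),
      n_valid_cores = sum(d$qc_valid),
      included = any(d$qc_valid),
      reasons = if (any(d$qc_valid)) NA_character_ else
        paste(unique(d$qc_reason[!is.na(d$qc_reason)]), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Aggregate valid-core H-scores per patient
#'
#' The patient H-score is the arithmetic mean over valid cores (both cores
#' when two are available, the single valid core otherwise).
#'
#' @param h_scores numeric vector of valid-core H-scores for one patient.
#' @return mean H-score.
#' @export
aggregatePatientHScore <- function(h_scores) {
  h_scores <- h_scores[!is.na(h_scores)]
  if (length(h_scores) == 0) stop("no valid cores to aggregate")
  mean(h_scores)
}

#' Score a full core table into per-patient H-scores
#'
#' Runs QC, computes per-core H-scores on valid cores, and aggregates the
#' mean per patient. Excluded patients (no valid core) get NA H-scores.
#'
#' @param cores data.frame of core observations (see
#'   \code{\link{evaluateCoreQC}}).
#' @return data.frame with \code{patient_id}, \code{h_score},
#'   \code{n_valid_cores}, \code{included}.
#' @export
scorePatients <- function(cores) {
  cores <- evaluateCoreQC(cores)
  inc <- includePatients(cores)
  valid <- cores[cores$qc_valid, , drop = FALSE]
  if (nrow(valid) > 0) {
    valid$h <- computeHScore(valid$pct_weak, valid$pct_moderate,
                             valid$pct_strong, valid$pct_negative)
    hs <- vapply(split(valid$h, valid$patient_id), aggregatePatientHScore,
                 numeric(1))
  } else {
    hs <- setNames(numeric(0), character(0))
  }
  inc$h_score <- unname(hs[as.character(inc$patient_id)])
  inc$h_score[!inc$included] <- NA_real_
  inc[, c("patient_id", "h_score", "n_valid_cores", "included")]
}

#' Binary PTEN status from an H-score cutoff
#'
#' Loss iff \code{h_score <= threshold}; with the calibrated cutoff of 0 a
#' patient is PTEN-loss exactly when the H-score is 0.
#'
#' @param h_score numeric H-score(s).
#' @param threshold cutoff in [0, 300).
#' @return character vector, \code{"loss"} or \code{"presence"}.
#' @export
classifyPten <- function(h_score, threshold = 0) {
  stopifnot(length(threshold) == 1, threshold >= 0, threshold < 300)
  ifelse(h_score <= threshold, "loss", "presence")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum null distribution when the combined
#' sample size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. The
#' statistic reported is the Mann-Whitney U of the first group.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with \code{statistic} (U), \code{p_value}, \code{method}.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
rankSumTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) {
    return(list(statistic = n1 * n2 / 2, p_value = 1, method = "degenerate"))
  }
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(all_v))
  if (n <= 12 && !ties) {
    # exact: enumerate all C(n, n1) assignments of ranks to group 1
    combs <- utils::combn(n, n1)
    W <- colSums(matrix(seq_len(n)[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(W - n1 * n2 / 2) >= abs(U - n1 * n2 / 2) - 1e-9)
    return(list(statistic = U, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tab <- table(all_v)
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)  # continuity correction
  z <- max(z, 0)
  p <- min(1, 2 * pnorm(-z))
  list(statistic = U, p_value = p, method = "normal")
}

#' Calibrate the PTEN-loss H-score threshold against a signature
#'
#' For each candidate cutoff t the cohort is split by
#' \code{classifyPten(h, t)} and the two groups' signature scores are
#' compared with a two-sided rank-sum test. The selected threshold is the
#' candidate with the smallest p-value among splits leaving both groups at
#' least \code{min_group} strong; ties break toward the smaller threshold.
#' This reproduces the calibration that identifies H-score = 0 as the most
#' discriminative cutoff for PI3K-AKT-mTOR activity.
#'
#' @param h_scores named numeric vector of per-patient H-scores.
#' @param scores a \code{\link{SignatureScores}} object or named numeric
#'   vector of per-patient signature scores (names = patient ids).
#' @param candidates candidate thresholds; default all distinct observed
#'   H-scores between 0 and the median H-score.
#' @param min_group minimum group size for an admissible split (default 10).
#' @return a \code{\link{ThresholdScan}}.
#' @export
calibrateThreshold <- function(h_scores, scores, candidates = NULL,
                               min_group = 10) {
  if (is(scores, "SignatureScores")) scores <- signatureScores(scores)
  if (is.null(names(h_scores)) || is.null(names(scores))) {
    stop("h_scores and scores must be named by patient id")
  }
  common <- intersect(names(h_scores), names(scores))
  if (length(common) < 4) {
    stop("too few patients shared between H-scores and signature scores")
  }
  h <- h_scores[common]; s <- scores[common]
  if (is.null(candidates)) {
    candidates <- sort(unique(h[h <= median(h)]))
  }
  if (length(candidates) == 0) stop("no candidate thresholds")
  if (any(candidates < min(h) - 1e-9 | candidates > max(h) + 1e-9)) {
    stop("candidates must lie within the observed H-score range")
  }
  candidates <- sort(unique(candidates))
  rows <- lapply(candidates, function(t) {
    status <- classifyPten(h, t)
    nl <- sum(status == "loss"); np <- sum(status == "presence")
    ok <- nl >= min_group && np >= min_group
    if (nl == 0 || np == 0) {
      return(data.frame(threshold = t, n_loss = nl, n_presence = np,
                        statistic = NA_real_, p_value = NA_real_,
                        eligible = FALSE))
    }
    ts <- rankSumTest(s[status == "loss"], s[status == "presence"])
    data.frame(threshold = t, n_loss = nl, n_presence = np,
               statistic = ts$statistic, p_value = ts$p_value, eligible = ok)
  })
  tab <- do.call(rbind, rows)
  elig <- tab[tab$eligible & !is.na(tab$p_value), , drop = FALSE]
  if (nrow(elig) == 0) {
    stop("no candidate threshold leaves both groups >= min_group")
  }
  # smallest p; ties toward the smaller threshold (table is threshold-sorted)
  sel <- elig$threshold[which.min(elig$p_value)]
  new("ThresholdScan", table = tab, selected = sel, min_group = min_group)
}
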