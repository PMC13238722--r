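## End-to-end orchestration: IHC scoring -> threshold calibration ->
## normalization -> differential expression -> network -> module x DEG
## intersection -> module-signature derivation -> signature scoring ->
## survival stratification, with a run manifest.

.stage <- function(manifest, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  manifest$stages[[name]] <- list(wall_time = proc.time()[["elapsed"]] - t0)
  assign("manifest", manifest, envir = parent.frame())
  res
}

.write_artifact <- function(obj, out_dir, name, manifest) {
  if (is.null(out_dir)) return(manifest)
  path <- file.path(out_dir, name)
  if (is.data.frame(obj) || is.matrix(obj)) {
    utils::write.csv(as.data.frame(obj), path, row.names = TRUE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  manifest$artifacts[[name]] <- unname(tools::md5sum(path))
  manifest
}

#' Run the discovery pipeline
#'
#' Executes the full inference chain on a cohort: per-patient H-scores
#' with core-level QC, calibration of the PTEN-loss cutoff against the
#' PI3K-activity signature, TMM normalization, covariate-adjusted
#' moderated differential expression, signed network construction with
#' module detection, module-trait association against PTEN status,
#' module x DEG Jaccard intersection, and derivation of the
#' top-overlapping associated module's signature.
#'
#' @param cores core-level IHC table (see \code{\link{evaluateCoreQC}}).
#' @param clinical clinical table with \code{patient_id}, \code{age},
#'   \code{dv200}, \code{psa}, \code{gleason}, \code{dfs_time},
#'   \code{dfs_event}.
#' @param counts gene x patient count matrix.
#' @param pi3k_genes gene ids of the PI3K-activity signature used for
#'   threshold calibration.
#' @param profile \code{"human"} or \code{"mouse"} parameter profile.
#' @param min_group minimum group size in the threshold scan.
#' @param max_genes network gene cap (top variance).
#' @param out_dir optional directory for stage artifacts (CSV/JSON with
#'   md5 hashes recorded in the manifest).
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return list with \code{patients}, \code{scan}, \code{threshold},
#'   \code{pten_status}, \code{de}, \code{modules}, \code{trait_assoc},
#'   \code{overlap}, \code{selected_module}, \code{signature},
#'   \code{scores}, \code{manifest}.
#' @export
runDiscovery <- function(cores, clinical, counts, pi3k_genes,
                         profile = c("human", "mouse"), min_group = 10,
                         max_genes = 8000, out_dir = NULL, seed = NULL) {
  profile <- match.arg(profile)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(seed = seed, profile = profile,
                   params = list(min_group = min_group,
                                 max_genes = max_genes),
                   stages = list(), artifacts = list())

  patients <- .stage(manifest, "ihc_scoring", function() scorePatients(cores))
  included <- patients[patients$included, ]
  shared <- intersect(included$patient_id, colnames(counts))
  if (length(shared) == 0) {
    stop("pipeline stage 'ihc_scoring' failed: no included patient has counts",
         call. = FALSE)
  }
  manifest <- .write_artifact(patients, out_dir, "patients.csv", manifest)

  cts <- counts[, shared, drop = FALSE]
  norm <- .stage(manifest, "normalization", function() {
    m <- filterGenes(cts, 5, if (profile == "human") 0.70 else 0.90)
    f <- tmmFactors(m)
    list(counts = m, factors = f, logcpm = logCPM(m, f),
         vst = vstTransform(m, f))
  })

  h <- setNames(included$h_score, included$patient_id)[shared]
  pi3k <- .stage(manifest, "pi3k_scoring", function()
    scoreSignature(norm$logcpm, pi3k_genes, "PI3K-AKT-mTOR"))
  scan <- .stage(manifest, "threshold_calibration", function()
    calibrateThreshold(h, pi3k, min_group = min_group))
  threshold <- selectedThreshold(scan)
  status <- factor(classifyPten(h, threshold), levels = c("presence", "loss"))
  manifest <- .write_artifact(scanTable(scan), out_dir, "threshold_scan.csv",
                              manifest)

  cl <- as.data.frame(clinical)
  rownames(cl) <- cl$patient_id
  cl <- cl[shared, , drop = FALSE]
  covars <- if (profile == "human" &&
                all(c("age", "dv200") %in% colnames(cl))) {
    cl[, c("age", "dv200")]
  } else NULL

  de <- .stage(manifest, "differential_expression", function() {
    design <- buildDesign(status, covars)
    eff <- colSums(norm$counts) * norm$factors
    w <- voomWeights(norm$logcpm, design, lib_size = eff)
    res <- moderatedFit(norm$logcpm, design, weights = w)
    callDEGs(res, lfc_min = if (profile == "human") 0 else 1)
  })
  manifest <- .write_artifact(de, out_dir, "de_results.csv", manifest)

  modules <- .stage(manifest, "network", function()
    buildNetwork(norm$vst, profile = profile, max_genes = max_genes))
  trait <- .stage(manifest, "module_trait", function()
    moduleTraitAssoc(moduleEigengenes(modules),
                     data.frame(pten_loss = as.numeric(status == "loss"))))
  manifest <- .write_artifact(trait, out_dir, "module_trait.csv", manifest)

  degs <- de$gene[de$significant]
  overlap <- .stage(manifest, "jaccard_intersection", function() {
    if (length(degs) == 0) stop("no significant DEGs to intersect")
    jaccardOverlap(degs, modules)
  })
  manifest <- .write_artifact(overlap, out_dir, "module_overlap.csv", manifest)

  # the signature module: highest DEG overlap among modules significantly
  # (positively) associated with PTEN loss; fall back to highest overlap
  sig_mods <- trait$module[trait$significant & !is.na(trait$r) & trait$r > 0]
  cand <- overlap[overlap$module %in% sig_mods, , drop = FALSE]
  if (nrow(cand) == 0) cand <- overlap
  selected_module <- cand$module[which.max(cand$jaccard)]

  signature <- .stage(manifest, "signature_derivation", function()
    deriveModuleSignature(modules, de, module = selected_module))
  scores <- .stage(manifest, "signature_scoring", function()
    scoreSignature(norm$logcpm, signature, paste0(selected_module, "_module")))
  manifest <- .write_artifact(as.list(signature), out_dir, "signature.json",
                              manifest)

  list(patients = patients, scan = scan, threshold = threshold,
       pten_status = setNames(as.character(status), shared),
       norm = norm, de = de, modules = modules, trait_assoc = trait,
       overlap = overlap, selected_module = selected_module,
       signature = signature, scores = scores, manifest = manifest)
}

#' Run the survival stratification pipeline
#'
#' Given a gene signature and a cohort: scores the signature, compares
#' extreme quartiles (Q1 vs Q4) by Kaplan-Meier/log-rank, fits
#' multivariable Cox models on PSA + Gleason with and without the z-scored
#' signature, reports the likelihood-ratio comparison and concordance,
#' splits at the median combined risk score, and sub-stratifies the
#' PTEN-loss subset by extreme signature quartiles.
#'
#' @param clinical clinical table (\code{patient_id}, \code{psa},
#'   \code{gleason}, \code{dfs_time}, \code{dfs_event}, optionally
#'   \code{pten_status}).
#' @param norm gene x sample normalized log-expression matrix.
#' @param signature character vector of signature gene ids.
#' @param pten_status optional named status vector overriding the clinical
#'   column.
#' @param out_dir optional artifact directory.
#' @return list with \code{scores}, \code{quartiles}, \code{km_q},
#'   \code{logrank_q1q4}, \code{cox_base}, \code{cox_full}, \code{lr},
#'   \code{risk_split}, \code{logrank_risk}, \code{loss_subset},
#'   \code{manifest}.
#' @export
runStratification <- function(clinical, norm, signature, pten_status = NULL,
                              out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(stages = list(), artifacts = list())

  scores <- .stage(manifest, "signature_scoring", function() {
    s <- scoreSignature(norm, signature, "signature")
    if (signatureCoverage(s) < 0.10) {
      stop(sprintf("signature coverage %.0f%% below 10%%",
                   100 * signatureCoverage(s)))
    }
    if (signatureCoverage(s) < 0.50) {
      warning(sprintf("signature coverage only %.0f%%",
                      100 * signatureCoverage(s)))
    }
    s
  })
  sc <- signatureScores(scores)

  cl <- as.data.frame(clinical)
  rownames(cl) <- cl$patient_id
  shared <- intersect(names(sc), rownames(cl))
  cl <- cl[shared, , drop = FALSE]
  sc <- sc[shared]
  keep <- is.finite(cl$dfs_time) & !is.na(cl$dfs_event) & cl$dfs_time > 0 &
    !is.na(cl$psa) & !is.na(cl$gleason)
  cl <- cl[keep, , drop = FALSE]
  sc <- sc[keep]
  z_sig <- (sc - mean(sc)) / sd(sc)

  quart <- .stage(manifest, "quartile_stratification", function()
    quartileStratify(sc))
  q_lab <- quart$labels
  extreme <- q_lab %in% c("Q1", "Q4")

  km_q <- .stage(manifest, "km_quartiles", function()
    kmEstimate(cl$dfs_time[extreme], cl$dfs_event[extreme],
               droplevels(q_lab[extreme])))
  lr_q <- .stage(manifest, "logrank_q1_q4", function()
    logrankTest(cl$dfs_time[extreme], cl$dfs_event[extreme],
                droplevels(q_lab[extreme])))

  X_base <- cbind(psa = cl$psa, gleason = as.numeric(cl$gleason))
  X_full <- cbind(X_base, signature = z_sig)
  cox_base <- .stage(manifest, "cox_psa_gleason", function()
    coxFit(cl$dfs_time, cl$dfs_event, X_base))
  cox_full <- .stage(manifest, "cox_with_signature", function()
    coxFit(cl$dfs_time, cl$dfs_event, X_full))
  lr <- .stage(manifest, "lr_test", function() lrTest(cox_base, cox_full))

  risk <- .stage(manifest, "median_risk_split", function()
    riskScoreSplit(cox_full))
  lr_risk <- .stage(manifest, "logrank_risk", function()
    logrankTest(cl$dfs_time, cl$dfs_event, risk$labels))

  # PTEN-loss subset sub-stratification (quartiles within the subset)
  status <- pten_status %||%
    (if ("pten_status" %in% colnames(cl)) setNames(cl$pten_status,
                                                   rownames(cl)) else NULL)
  loss_subset <- NULL
  if (!is.null(status)) {
    loss_ids <- intersect(rownames(cl), names(status)[status == "loss"])
    if (length(loss_ids) >= 8 && sd(sc[loss_ids]) > 0) {
      qs <- quartileStratify(sc[loss_ids])
      ex <- qs$labels %in% c("Q1", "Q4")
      sub_cl <- cl[loss_ids, ]
      loss_subset <- list(
        quartiles = qs,
        logrank = if (sum(sub_cl$dfs_event[ex]) > 0)
          logrankTest(sub_cl$dfs_time[ex], sub_cl$dfs_event[ex],
                      droplevels(qs$labels[ex]))
        else list(chisq = 0, df = 1, p_value = 1),
        n_q1 = sum(qs$labels == "Q1"), n_q4 = sum(qs$labels == "Q4"))
    }
  }

  fitsum <- list(
    lr_chisq_full = 2 * diff(logLiks(cox_full)),
    lr_chisq_base = 2 * diff(logLiks(cox_base)),
    lr_added = lr,
    hr = hazardRatios(cox_full),
    concordance_full = concordanceIndex(cox_full),
    concordance_base = concordanceIndex(cox_base)
  )
  manifest <- .write_artifact(fitsum, out_dir, "cox_summary.json", manifest)

  list(scores = scores, quartiles = quart, km_q = km_q, logrank_q1q4 = lr_q,
       cox_base = cox_base, cox_full = cox_full, lr = lr,
       risk_split = risk, logrank_risk = lr_risk, loss_subset = loss_subset,
       manifest = manifest)
}
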