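## Synthetic cohort generator with planted ground truth. Emulates the
## structure of the study cohort: negative-binomial counts with planted
## correlated gene modules, a binary PTEN-loss factor (identical to
## "H-score = 0") that up-shifts a 105-gene PI3K-activity signature and one
## planted stromal module, a zero-inflated right-skewed H-score
## distribution read off two cores per patient with per-core QC failures,
## and censored recurrence times whose hazard falls with the planted
## module signature.

#' Simulation configuration
#'
#' Defaults describe the emulated cohort: 197 patients with two tissue
#' cores each, roughly half of the cohort PTEN-loss (H-score exactly 0), a
#' per-core QC failure rate of 0.5 so that about a quarter of patients
#' lose both cores and are excluded, a planted stromal module whose
#' signature carries a protective hazard ratio of 0.68 per SD, and
#' negative-binomial counts over a handful of planted co-expression
#' modules.
#'
#' @param n_patients number of patients (>= 8).
#' @param n_genes total genes.
#' @param module_sizes planted module sizes; the first module is the
#'   stromal program whose genes form the planted signature.
#' @param module_factor_sd per-sample latent factor SD (log2 units).
#' @param pten_loss_fraction target fraction of PTEN-loss patients.
#' @param pi3k_effect log2 shift of the PI3K-signature genes in loss
#'   samples.
#' @param stromal_effect log2 shift of the planted stromal module in loss
#'   samples.
#' @param nb_dispersion negative-binomial dispersion.
#' @param mean_libsize expected total counts per sample.
#' @param hscore_zero_inflation proportion of exact-zero H-scores; default
#'   equals \code{pten_loss_fraction} (loss status is "H-score = 0").
#' @param core_fail_rate per-core QC failure probability.
#' @param planted_log_hr log hazard ratio per SD of the planted signature.
#' @param censor_rate uniform-censoring intensity (1 = the cohort's
#'   ~110-month administrative window; larger = heavier censoring).
#' @param n_pi3k size of the planted PI3K-activity signature.
#' @param seed master random seed.
#' @return validated configuration list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_patients = 197, n_genes = 2000,
                      module_sizes = c(75, 60, 50), module_factor_sd = 1,
                      pten_loss_fraction = 0.5, pi3k_effect = 1,
                      stromal_effect = 1, nb_dispersion = 0.2,
                      mean_libsize = 1e6, hscore_zero_inflation = NULL,
                      core_fail_rate = 0.5, planted_log_hr = log(0.68),
                      censor_rate = 1, n_pi3k = 105, seed = 1) {
  if (is.null(hscore_zero_inflation)) hscore_zero_inflation <- pten_loss_fraction
  cfg <- list(n_patients = n_patients, n_genes = n_genes,
              module_sizes = module_sizes, n_modules = length(module_sizes),
              module_factor_sd = module_factor_sd,
              pten_loss_fraction = pten_loss_fraction,
              pi3k_effect = pi3k_effect, stromal_effect = stromal_effect,
              nb_dispersion = nb_dispersion, mean_libsize = mean_libsize,
              hscore_zero_inflation = hscore_zero_inflation,
              core_fail_rate = core_fail_rate, planted_log_hr = planted_log_hr,
              censor_rate = censor_rate, n_pi3k = n_pi3k, seed = seed)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg a \code{\link{simConfig}} list.
#' @return invisibly TRUE; stops on an invalid configuration.
#' @export
validateSimConfig <- function(cfg) {
  if (cfg$n_patients < 8) {
    stop("n_patients < 8: downstream quartiles undefined")
  }
  if (sum(cfg$module_sizes) + cfg$n_pi3k > cfg$n_genes) {
    stop("module_sizes (plus the PI3K set) exceed n_genes")
  }
  props <- c(cfg$pten_loss_fraction, cfg$hscore_zero_inflation,
             cfg$core_fail_rate)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$mean_libsize <= 0) stop("mean_libsize must be positive")
  invisible(TRUE)
}

## one pseudo-random stream per output block, derived from the master seed
.block_seeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 4),
           c("counts", "ihc", "clinical", "survival"))
}

## deterministic inverse of the H-score formula: split H into intensity
## percentages (negative fills the remainder)
.hscore_to_pcts <- function(h) {
  t(vapply(h, function(H) {
    H <- max(0, min(300, H))
    if (H <= 100) {
      c(neg = 100 - H, weak = H, mod = 0, strong = 0)
    } else if (H <= 200) {
      m <- H - 100
      c(neg = 0, weak = 100 - m, mod = m, strong = 0)
    } else {
      s <- H - 200
      c(neg = 0, weak = 0, mod = 100 - s, strong = s)
    }
  }, numeric(4)))
}

.simulate_counts <- function(cfg, loss, group_shift = NULL, seed) {
  set.seed(seed)
  n <- length(loss)
  G <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  samples <- names(loss)

  # gene roles: planted modules first, then the PI3K set, then background
  module_of <- rep(NA_integer_, G)
  pos <- 0
  for (m in seq_along(cfg$module_sizes)) {
    module_of[(pos + 1):(pos + cfg$module_sizes[m])] <- m
    pos <- pos + cfg$module_sizes[m]
  }
  pi3k_idx <- (pos + 1):(pos + cfg$n_pi3k)

  base <- rnorm(G, mean = 5, sd = 1.5)            # log2 log-normal baselines
  factors <- matrix(rnorm(cfg$n_modules * n, 0, cfg$module_factor_sd),
                    cfg$n_modules, n)

  mu_log2 <- matrix(base, G, n)
  for (m in seq_len(cfg$n_modules)) {
    idx <- which(module_of == m)
    mu_log2[idx, ] <- mu_log2[idx, ] + rep(factors[m, ], each = length(idx))
  }
  shift <- if (is.null(group_shift)) as.numeric(loss) else group_shift
  mu_log2[pi3k_idx, ] <- mu_log2[pi3k_idx, ] +
    cfg$pi3k_effect * rep(shift, each = length(pi3k_idx))
  idx1 <- which(module_of == 1)
  mu_log2[idx1, ] <- mu_log2[idx1, ] +
    cfg$stromal_effect * rep(shift, each = length(idx1))

  w <- 2^mu_log2
  p <- sweep(w, 2, colSums(w), "/")
  lib <- rlnorm(n, meanlog = log(cfg$mean_libsize) - 0.5 * 0.2^2, sdlog = 0.2)
  mu <- sweep(p, 2, lib, "*")
  counts <- matrix(rnbinom(G * n, mu = mu,
                           size = if (cfg$nb_dispersion > 0)
                             1 / cfg$nb_dispersion else 1e8),
                   G, n, dimnames = list(genes, samples))

  module_membership <- setNames(ifelse(is.na(module_of), "background",
                                       paste0("planted", module_of)), genes)
  module_membership[pi3k_idx] <- "pi3k"
  list(counts = counts, module_membership = module_membership,
       pi3k_genes = genes[pi3k_idx], signature_genes = genes[idx1],
       stromal_factor = factors[1, ])
}

.simulate_ihc <- function(cfg, seed) {
  set.seed(seed)
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  zero <- runif(n) < cfg$hscore_zero_inflation
  h_target <- ifelse(zero, 0,
                     pmin(300, pmax(1, round(rgamma(n, shape = 0.9,
                                                    scale = 72)))))
  reasons <- c("no_tumor", "stroma_negative", "staining_failure", "core_absent")
  rows <- list()
  for (i in seq_len(n)) {
    for (core in 1:2) {
      fails <- runif(1) < cfg$core_fail_rate
      if (fails) {
        reason <- sample(reasons, 1)
        states <- switch(reason,
          no_tumor = c("absent", "positive"),
          stroma_negative = c("present", "negative"),
          staining_failure = c("present", "undetermined"),
          core_absent = c("technical_failure", "undetermined"))
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = ids[i], core_id = paste0(ids[i], "_c", core),
          tumor_present = states[1], stroma_stain = states[2],
          pct_negative = NA_real_, pct_weak = NA_real_,
          pct_moderate = NA_real_, pct_strong = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        h_core <- if (h_target[i] == 0) 0 else
          max(1, min(300, round(h_target[i] + rnorm(1, 0, 5))))
        pc <- .hscore_to_pcts(h_core)
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = ids[i], core_id = paste0(ids[i], "_c", core),
          tumor_present = "present", stroma_stain = "positive",
          pct_negative = pc[1, "neg"], pct_weak = pc[1, "weak"],
          pct_moderate = pc[1, "mod"], pct_strong = pc[1, "strong"],
          stringsAsFactors = FALSE)
      }
    }
  }
  cores <- do.call(rbind, rows)
  list(cores = cores, h_target = setNames(h_target, ids),
       loss = setNames(h_target == 0, ids))
}

.simulate_clinical <- function(ids, seed) {
  set.seed(seed)
  n <- length(ids)
  data.frame(
    patient_id = ids,
    age = round(rnorm(n, 62.8, 6.2)),
    dv200 = round(runif(n, 40, 90), 1),
    psa = round(rlnorm(n, log(6.38), 0.35), 2),
    gleason = sample(6:9, n, replace = TRUE, prob = c(0.35, 0.4, 0.15, 0.1)),
    stringsAsFactors = FALSE
  )
}

.simulate_survival <- function(cfg, z_signature, seed) {
  set.seed(seed)
  n <- length(z_signature)
  lambda0 <- log(2) / 120                       # baseline median 120 months
  lambda <- lambda0 * exp(cfg$planted_log_hr * z_signature)
  t_event <- rexp(n, rate = lambda)
  c_admin <- runif(n, 0, 110 / cfg$censor_rate)
  time <- pmin(t_event, c_admin)
  event <- as.integer(t_event <= c_admin)
  time <- round(pmax(time, 0.1), 1)
  data.frame(dfs_time = time, dfs_event = event)
}

#' Simulate a full synthetic cohort with planted ground truth
#'
#' Generates (i) a core-level IHC table with QC failure states and
#' intensity percentages, (ii) a clinical table with age, DV200, PSA,
#' Gleason and censored recurrence outcomes, (iii) a negative-binomial
#' gene x patient count matrix with planted co-expression modules, and
#' (iv) the ground truth. Loss effects (PI3K and stromal up-shifts) are
#' present exactly in the patients whose H-score is 0, so the true
#' calibration threshold is 0. Identical configuration and seed give
#' bit-identical output; each output block draws from its own derived
#' random stream.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{cores}, \code{clinical}, \code{counts},
#'   \code{truth} (module membership, loss status, true threshold,
#'   planted signature genes, PI3K genes, planted log-HR, latent
#'   signature).
#' @export
simulateCohort <- function(cfg = simConfig()) {
  validateSimConfig(cfg)
  seeds <- .block_seeds(cfg$seed)
  ihc <- .simulate_ihc(cfg, seeds["ihc"])
  loss <- ihc$loss
  cts <- .simulate_counts(cfg, loss, seed = seeds["counts"])
  clinical <- .simulate_clinical(names(loss), seeds["clinical"])

  # planted signature activity: latent stromal factor plus the loss shift,
  # z-scored; the hazard responds to this exact quantity
  raw_sig <- cts$stromal_factor + cfg$stromal_effect * as.numeric(loss)
  z_sig <- (raw_sig - mean(raw_sig)) / sd(raw_sig)
  surv <- .simulate_survival(cfg, z_sig, seeds["survival"])
  clinical <- cbind(clinical, surv)
  clinical$pten_status <- ifelse(loss[clinical$patient_id], "loss", "presence")

  truth <- list(
    module_membership = cts$module_membership,
    loss_status = loss,
    true_threshold = 0,
    signature_genes = cts$signature_genes,
    pi3k_genes = cts$pi3k_genes,
    planted_log_hr = cfg$planted_log_hr,
    z_signature = setNames(z_sig, names(loss))
  )
  list(cores = ihc$cores, clinical = clinical, counts = cts$counts,
       truth = truth, config = cfg)
}

#' Simulate a two-group (knockout-like vs wild-type) count matrix
#'
#' Mouse-like design: \code{n_per_group} samples per group, with the
#' planted stromal module and the PI3K set up-shifted in the
#' knockout-like group by the configured effects.
#'
#' @param cfg a \code{\link{simConfig}} (only the count-generation fields
#'   are used).
#' @param n_per_group samples per group (>= 2; >= 3 recommended).
#' @return list with \code{counts}, \code{group} (factor WT/KO) and
#'   \code{truth}.
#' @export
simulateTwoGroup <- function(cfg = simConfig(), n_per_group = 3) {
  if (n_per_group < 2) stop("need at least 2 samples per group")
  seeds <- .block_seeds(cfg$seed)
  n <- 2 * n_per_group
  group <- factor(rep(c("WT", "KO"), each = n_per_group),
                  levels = c("WT", "KO"))
  ids <- paste0(rep(c("WT", "KO"), each = n_per_group),
                rep(seq_len(n_per_group), 2))
  shift <- as.numeric(group == "KO")
  loss <- setNames(group == "KO", ids)
  cts <- .simulate_counts(cfg, loss, group_shift = shift,
                          seed = seeds["counts"])
  list(counts = cts$counts, group = setNames(group, ids),
       truth = list(module_membership = cts$module_membership,
                    signature_genes = cts$signature_genes,
                    pi3k_genes = cts$pi3k_genes))
}

#' Write a simulated cohort to plain-text files
#'
#' Counts as TSV (genes x samples), core and clinical tables as CSV, the
#' ground truth as JSON.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    cores = file.path(dir, "cores.csv"),
    clinical = file.path(dir, "clinical.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.table(sim$counts, paths["counts"], sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.csv(sim$cores, paths["cores"], row.names = FALSE)
  utils::write.csv(sim$clinical, paths["clinical"], row.names = FALSE)
  truth <- sim$truth
  truth$loss_status <- as.list(truth$loss_status)
  truth$module_membership <- as.list(truth$module_membership)
  truth$z_signature <- as.list(truth$z_signature)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Assemble a cohort SummarizedExperiment
#'
#' Joins the count matrix with the clinical table (as \code{colData}) into
#' a \code{\link[SummarizedExperiment]{SummarizedExperiment}}.
#'
#' @param counts gene x patient count matrix.
#' @param clinical clinical data.frame with a \code{patient_id} column.
#' @return SummarizedExperiment with a \code{counts} assay.
#' @export
cohortSE <- function(counts, clinical) {
  m <- .as_count_matrix(counts)
  clinical <- as.data.frame(clinical)
  rownames(clinical) <- clinical$patient_id
  shared <- intersect(colnames(m), rownames(clinical))
  if (length(shared) == 0) stop("no shared sample ids")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m[, shared, drop = FALSE]),
    colData = S4Vectors::DataFrame(clinical[shared, , drop = FALSE])
  )
}
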