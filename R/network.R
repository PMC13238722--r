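## Signed weighted co-expression network: robust (biweight-mid) correlation,
## signed soft-threshold adjacency, scale-free power selection, topological
## overlap, average-linkage module detection with eigengene merging, and
## module-trait association.

.module_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta"
)

## biweight weights for one vector, with the maxPOutliers cap:
## values beyond the side quantiles are rescaled so at most that fraction
## per side can receive zero weight.
.bicor_prep <- function(x, max_p_outliers) {
  mx <- median(x)
  mad_x <- mad(x, constant = 1)
  if (mad_x == 0) return(NULL)  # caller falls back to Pearson
  u <- (x - mx) / (9 * mad_x)
  if (max_p_outliers < 0.5) {
    qL <- quantile(x, max_p_outliers, names = FALSE)
    qU <- quantile(x, 1 - max_p_outliers, names = FALSE)
    uL <- (qL - mx) / (9 * mad_x)
    uU <- (qU - mx) / (9 * mad_x)
    if (uL < -1) u[u < 0] <- u[u < 0] / abs(uL)
    if (uU > 1) u[u > 0] <- u[u > 0] / uU
  }
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  xc <- (x - mx) * w
  denom <- sqrt(sum(xc^2))
  if (denom == 0) return(NULL)
  xc / denom
}

#' Biweight midcorrelation with outlier capping
#'
#' Robust correlation based on median/MAD biweight weights. Weights are
#' capped so that at most \code{max_p_outliers} of the observations per
#' side can be assigned zero weight. When either vector has MAD 0 the
#' computation falls back to Pearson for that vector (individual
#' fallback); two constant vectors return 0 with a flag attribute.
#'
#' @param x,y numeric vectors (>= 4 observations).
#' @param max_p_outliers maximum proportion of observations per side
#'   allowed to be treated as outliers (default 0.1).
#' @return correlation in [-1, 1]; attribute \code{"undefined"} is TRUE
#'   when both sides were constant.
#' @export
bicorRobust <- function(x, y, max_p_outliers = 0.1) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  xs <- .bicor_prep(x, max_p_outliers)
  ys <- .bicor_prep(y, max_p_outliers)
  pearson_std <- function(v) {
    vc <- v - mean(v)
    d <- sqrt(sum(vc^2))
    if (d == 0) NULL else vc / d
  }
  if (is.null(xs)) xs <- pearson_std(x)
  if (is.null(ys)) ys <- pearson_std(y)
  if (is.null(xs) || is.null(ys)) {
    out <- 0
    attr(out, "undefined") <- TRUE
    return(out)
  }
  r <- sum(xs * ys)
  max(-1, min(1, r))
}

## column-wise bicor matrix (samples x genes input)
.bicor_matrix <- function(X, max_p_outliers = 0.1) {
  G <- ncol(X)
  std <- matrix(NA_real_, nrow(X), G)
  for (j in seq_len(G)) {
    s <- .bicor_prep(X[, j], max_p_outliers)
    if (is.null(s)) {
      v <- X[, j] - mean(X[, j])
      d <- sqrt(sum(v^2))
      s <- if (d == 0) rep(0, nrow(X)) else v / d
    }
    std[, j] <- s
  }
  R <- crossprod(std)
  R[R > 1] <- 1; R[R < -1] <- -1
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}

#' Signed adjacency from a correlation
#'
#' \code{a = ((1 + cor) / 2)^beta}: perfectly anti-correlated genes map to
#' 0, perfectly correlated ones to 1, so modules are co-directional.
#'
#' @param cor correlation value(s) in [-1, 1].
#' @param beta soft-threshold power (>= 1).
#' @return adjacency in [0, 1].
#' @export
signedAdjacency <- function(cor, beta) {
  stopifnot(beta >= 1)
  if (any(cor < -1 - 1e-9 | cor > 1 + 1e-9, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  ((1 + pmin(pmax(cor, -1), 1)) / 2)^beta
}

## scale-free topology fit: regress log10 p(k) on log10 k over bins
.scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_breaks) return(c(r2 = NA_real_, slope = NA_real_))
  cut_k <- cut(log10(k), breaks = n_breaks)
  freq <- tapply(k, cut_k, length)
  km <- tapply(k, cut_k, mean)
  ok <- !is.na(freq) & !is.na(km) & freq > 0 & km > 0
  if (sum(ok) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  lx <- log10(km[ok]); ly <- log10(freq[ok] / sum(freq[ok]))
  fit <- stats::lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  c(r2 = r2, slope = unname(fit$coefficients[2]))
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the signed adjacency (from a signed Spearman
#' correlation, the statistic used at this step) is formed, connectivities
#' k are computed, and the signed scale-free fit R^2 (R^2 times the sign of
#' the negative slope) is evaluated by regressing log10 p(k) on log10 k
#' over connectivity bins. The smallest power reaching \code{r2_target}
#' wins; if none does, the argmax is returned with a warning.
#'
#' @param norm gene x sample normalized expression matrix.
#' @param powers candidate powers (default 1:20).
#' @param r2_target signed R^2 target (default 0.8).
#' @return list with \code{power} and \code{fit_table} (power, signed R^2,
#'   slope, mean and median connectivity).
#' @export
pickSoftThreshold <- function(norm, powers = 1:20, r2_target = 0.8) {
  X <- t(as.matrix(norm))  # samples x genes
  if (ncol(X) < 20) stop("need at least 20 genes")
  sds <- apply(X, 2, sd)
  if (all(sds == 0)) stop("all genes constant")
  R <- cor(X, method = "spearman")
  rows <- lapply(powers, function(b) {
    A <- signedAdjacency(R, b)
    diag(A) <- 0
    k <- rowSums(A)
    sf <- .scale_free_fit(k)
    signed_r2 <- unname(sf["r2"] * sign(-sf["slope"]))
    data.frame(power = b, signed_r2 = signed_r2, slope = unname(sf["slope"]),
               mean_k = mean(k), median_k = median(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(!is.na(tab$signed_r2) & tab$signed_r2 >= r2_target)
  if (length(hit) > 0) {
    power <- tab$power[hit[1]]
  } else if (any(!is.na(tab$signed_r2))) {
    power <- tab$power[which.max(tab$signed_r2)]
    warning("no power reached the scale-free R^2 target; returning argmax")
  } else {
    power <- tab$power[length(tab$power)]
    warning("scale-free fit undefined on this input; returning largest power")
  }
  list(power = power, fit_table = tab)
}

#' Topological overlap similarity
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} with
#' \code{l_ij = sum_u a_iu a_uj}; shared neighbors raise the similarity of
#' a gene pair beyond its direct adjacency. The diagonal is set to 1.
#'
#' @param adjacency symmetric matrix with entries in [0, 1]; the diagonal
#'   is zeroed before the computation.
#' @return TOM similarity matrix in [0, 1] with unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (max(abs(A - t(A))) > 1e-8) stop("adjacency must be symmetric")
  if (any(A < -1e-12 | A > 1 + 1e-12)) stop("adjacency entries must be in [0, 1]")
  diag(A) <- 0
  k <- rowSums(A)
  L <- A %*% A
  kmin <- outer(k, k, pmin)
  tom <- (L + A) / (kmin + 1 - A)
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengene (first principal component)
#'
#' First principal component of the standardized member-gene matrix,
#' rescaled to unit variance and sign-aligned so the mean correlation with
#' the member genes is positive. A single-gene module returns that gene's
#' z-scored profile.
#'
#' @param norm member-gene x sample expression matrix (one module).
#' @return per-sample eigengene, unit variance.
#' @export
moduleEigengene <- function(norm) {
  X <- as.matrix(norm)
  if (nrow(X) == 0) stop("module is empty")
  zs <- t(apply(X, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  if (nrow(X) == 1) {
    e <- drop(zs)
  } else {
    sv <- svd(zs, nu = 0, nv = 1)
    e <- drop(sv$v[, 1])
  }
  s <- sd(e)
  if (s > 0) e <- (e - mean(e)) / s
  cors <- suppressWarnings(apply(zs, 1, function(g) {
    if (sd(g) == 0) 0 else cor(g, e)
  }))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  setNames(e, colnames(norm))
}

.eigengene_matrix <- function(norm, labels) {
  mods <- setdiff(sort(unique(labels)), "grey")
  if (length(mods) == 0) {
    return(matrix(numeric(0), 0, ncol(norm),
                  dimnames = list(NULL, colnames(norm))))
  }
  me <- t(vapply(mods, function(m) {
    moduleEigengene(norm[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(norm))))
  rownames(me) <- mods
  colnames(me) <- colnames(norm)
  me
}

#' Detect modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of \code{1 - TOM}; the tree is
#' cut at a height quantile controlled by \code{deep_split} (deeper split,
#' lower cut: 1 -> 0.995, 2 -> 0.99, 3 -> 0.98, 4 -> 0.95 of the merge
#' heights); clusters below \code{min_module_size} become \code{"grey"};
#' modules whose eigengene dissimilarity (1 - correlation) is below
#' \code{merge_cut_height} are merged iteratively until a fixpoint.
#' Surviving modules are named by size rank using the conventional color
#' order (turquoise, blue, brown, ...).
#'
#' @param diss square dissimilarity matrix (1 - TOM), gene ids as
#'   dimnames.
#' @param norm gene x sample normalized expression (for eigengene
#'   merging).
#' @param min_module_size minimum module size (default 30).
#' @param merge_cut_height eigengene-dissimilarity merge threshold
#'   (human profile 0.1; mouse 0.25).
#' @param deep_split small integer 1-4 (human 1; mouse 2).
#' @return named character vector of module labels.
#' @export
detectModules <- function(diss, norm, min_module_size = 30,
                          merge_cut_height = 0.1, deep_split = 1) {
  D <- as.matrix(diss)
  if (nrow(D) != ncol(D)) stop("dissimilarity must be square")
  genes <- rownames(D)
  if (is.null(genes)) genes <- rownames(norm)
  if (nrow(D) < min_module_size) {
    warning("fewer genes than min_module_size: all grey")
    return(setNames(rep("grey", nrow(D)), genes))
  }
  qmap <- c(`1` = 0.995, `2` = 0.99, `3` = 0.98, `4` = 0.95)
  qq <- qmap[as.character(deep_split)]
  if (is.na(qq)) stop("deep_split must be 1, 2, 3 or 4")
  tree <- hclust(stats::as.dist(D), method = "average")
  cut_h <- quantile(tree$height, qq, names = FALSE)
  cl <- cutree(tree, h = cut_h)
  labels <- setNames(as.character(cl), genes)
  sizes <- table(labels)
  labels[labels %in% names(sizes)[sizes < min_module_size]] <- "grey"

  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    me <- .eigengene_matrix(norm, labels)
    cm <- cor(t(me))
    dm <- 1 - cm
    diag(dm) <- Inf
    mn <- min(dm)
    if (mn >= merge_cut_height) break
    idx <- which(dm == mn, arr.ind = TRUE)[1, ]
    a <- rownames(dm)[idx[1]]; b <- colnames(dm)[idx[2]]
    labels[labels == b] <- a
  }

  mods <- setdiff(unique(labels), "grey")
  sizes <- sort(table(labels[labels %in% mods]), decreasing = TRUE)
  colors <- .module_colors[seq_along(sizes)]
  colors[is.na(colors)] <- paste0("module", seq_along(sizes))[is.na(colors)]
  map <- setNames(colors, names(sizes))
  out <- ifelse(labels == "grey", "grey", map[labels])
  setNames(out, genes)
}

#' Per-gene connectivity statistics
#'
#' \code{kTotal} is the adjacency sum over all other genes, \code{kWithin}
#' over same-module genes, \code{kOut = kTotal - kWithin} and
#' \code{kDiff = kWithin - kOut}.
#'
#' @param adjacency symmetric gene x gene adjacency.
#' @param labels named module labels covering the adjacency's genes.
#' @return data.frame with gene, module, kTotal, kWithin, kOut, kDiff.
#' @export
connectivityStats <- function(adjacency, labels) {
  A <- as.matrix(adjacency)
  diag(A) <- 0
  genes <- rownames(A) %||% names(labels)
  labels <- labels[genes]
  if (any(is.na(labels))) stop("labels must cover all genes")
  k_total <- rowSums(A)
  k_within <- vapply(seq_along(genes), function(i) {
    same <- which(labels == labels[i])
    sum(A[i, setdiff(same, i)])
  }, numeric(1))
  data.frame(
    gene = genes,
    module = unname(labels),
    kTotal = unname(k_total),
    kWithin = unname(k_within),
    kOut = unname(k_total - k_within),
    kDiff = unname(2 * k_within - k_total),
    stringsAsFactors = FALSE
  )
}

#' Gene-eigengene correlations (kME)
#'
#' @param norm gene x sample normalized expression.
#' @param eigengenes module x sample eigengene matrix.
#' @return genes x modules matrix of Pearson correlations.
#' @export
kmeTable <- function(norm, eigengenes) {
  X <- as.matrix(norm)
  ME <- as.matrix(eigengenes)
  out <- suppressWarnings(cor(t(X), t(ME)))
  out[!is.finite(out)] <- 0
  rownames(out) <- rownames(X)
  colnames(out) <- rownames(ME)
  out
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with each trait, two-sided
#' p from the t distribution, BH adjustment across all module x trait
#' pairs; significance at |r| > 0.2 and FDR < 0.05 (the study thresholds).
#'
#' @param eigengenes module x sample matrix.
#' @param traits data.frame of numeric traits, rows aligned to samples.
#' @param r_min absolute-correlation threshold (default 0.2).
#' @param fdr_max FDR threshold (default 0.05).
#' @return data.frame: module, trait, r, p_value, padj, significant.
#' @export
moduleTraitAssoc <- function(eigengenes, traits, r_min = 0.2, fdr_max = 0.05) {
  ME <- as.matrix(eigengenes)
  traits <- as.data.frame(traits)
  if (ncol(ME) != nrow(traits)) stop("samples mismatch eigengenes vs traits")
  n <- ncol(ME)
  rows <- list()
  for (m in rownames(ME)) {
    for (tr in colnames(traits)) {
      v <- as.numeric(traits[[tr]])
      if (sd(v, na.rm = TRUE) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = tr, r = NA_real_, p_value = NA_real_)
        next
      }
      ok <- is.finite(v)
      r <- cor(ME[m, ok], v[ok])
      df <- sum(ok) - 2
      tstat <- r * sqrt(df / (1 - r^2))
      p <- 2 * pt(-abs(tstat), df)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, trait = tr, r = r, p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- bhAdjust(out$p_value)
  out$significant <- !is.na(out$r) & abs(out$r) > r_min & out$padj < fdr_max
  out
}

#' Build the full co-expression network and detect modules
#'
#' End-to-end network stage: optional variance-ranked gene cap (single
#' block), signed adjacency from biweight midcorrelation at the chosen
#' power (14 for the human profile, 18 for mouse, or picked by
#' scale-free fit when \code{power = "auto"}), TOM, module detection with
#' profile-specific deep split and merge height, eigengenes, kME and
#' connectivity.
#'
#' @param norm gene x sample normalized (variance-stabilized) expression.
#' @param profile \code{"human"} (power 14, deepSplit 1, merge 0.1) or
#'   \code{"mouse"} (power 18, deepSplit 2, merge 0.25).
#' @param power soft power, or \code{"auto"} for scale-free selection.
#' @param max_p_outliers bicor outlier cap (default 0.1).
#' @param min_module_size minimum module size (default 30).
#' @param max_genes variance-ranked gene cap for the single-block
#'   computation (default 8000).
#' @return a \code{\link{ModuleSet}}.
#' @export
buildNetwork <- function(norm, profile = c("human", "mouse"), power = NULL,
                         max_p_outliers = 0.1, min_module_size = 30,
                         max_genes = 8000) {
  profile <- match.arg(profile)
  defaults <- if (profile == "human") {
    list(power = 14, deep_split = 1, merge = 0.1)
  } else {
    list(power = 18, deep_split = 2, merge = 0.25)
  }
  X <- as.matrix(norm)
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  v <- apply(X, 1, var)
  if (nrow(X) > max_genes) {
    X <- X[order(v, decreasing = TRUE)[seq_len(max_genes)], , drop = FALSE]
  }
  if (identical(power, "auto")) {
    power <- pickSoftThreshold(X)$power
  } else if (is.null(power)) {
    power <- defaults$power
  }
  R <- .bicor_matrix(t(X), max_p_outliers)
  A <- signedAdjacency(R, power)
  diag(A) <- 0
  tom <- tomSimilarity(A)
  labels <- detectModules(1 - tom, X, min_module_size = min_module_size,
                          merge_cut_height = defaults$merge,
                          deep_split = defaults$deep_split)
  me <- .eigengene_matrix(X, labels)
  kme <- if (nrow(me) > 0) kmeTable(X, me) else
    matrix(numeric(0), nrow(X), 0, dimnames = list(rownames(X), NULL))
  conn <- connectivityStats(A, labels)
  new("ModuleSet", labels = labels, eigengenes = me, kME = kme,
      connectivity = conn, power = as.numeric(power),
      params = list(profile = profile, max_p_outliers = max_p_outliers,
                    min_module_size = min_module_size,
                    merge_cut_height = defaults$merge,
                    deep_split = defaults$deep_split))
}
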