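## Gene-set scoring and module-signature derivation: per-sample mean
## z-scored expression of a signature, Jaccard intersection of DEG sets
## with network modules, derivation of a module signature (module genes
## that are also DEGs) and cross-species homolog mapping.

#' Score a gene signature across samples
#'
#' Subsets the normalized log-expression matrix to the signature genes,
#' z-scores each gene across samples (n - 1 denominator; zero-variance
#' genes contribute 0) and averages the z-scores per sample.
#'
#' @param norm gene x sample normalized log-expression matrix.
#' @param genes character vector of signature gene ids.
#' @param name signature name (used in errors and the result).
#' @return a \code{\link{SignatureScores}} object.
#' @export
scoreSignature <- function(norm, genes, name = "signature") {
  X <- as.matrix(norm)
  if (ncol(X) < 2) stop("need at least 2 samples")
  genes <- unique(genes)
  present <- intersect(genes, rownames(X))
  if (length(present) == 0) {
    stop(sprintf("no genes of signature '%s' found in the matrix", name))
  }
  sub <- X[present, , drop = FALSE]
  z <- t(apply(sub, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  scores <- colMeans(z)
  new("SignatureScores",
      name = name,
      scores = setNames(as.numeric(scores), colnames(X)),
      coverage = length(present) / length(genes),
      genes_used = present)
}

#' Jaccard overlap of a DEG set with every module
#'
#' For each non-grey module, \code{J = |DEG inter module| / |DEG union
#' module|}; the modules with the highest overlap carry the DEG signal in
#' network space.
#'
#' @param degs character vector of DEG ids (non-empty).
#' @param modules a \code{\link{ModuleSet}} or named label vector.
#' @return data.frame: module, module_size, intersection, union, jaccard,
#'   sorted by decreasing Jaccard; attribute \code{"intersections"} holds
#'   the per-module intersected gene lists.
#' @export
jaccardOverlap <- function(degs, modules) {
  if (length(degs) == 0) stop("DEG set must be non-empty")
  labels <- if (is(modules, "ModuleSet")) moduleLabels(modules) else modules
  degs <- unique(degs)
  mods <- setdiff(sort(unique(labels)), "grey")
  inters <- list()
  rows <- lapply(mods, function(m) {
    mg <- names(labels)[labels == m]
    i <- intersect(degs, mg)
    u <- union(degs, mg)
    inters[[m]] <<- sort(i)
    data.frame(module = m, module_size = length(mg),
               intersection = length(i), union = length(u),
               jaccard = length(i) / length(u), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$jaccard), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "intersections") <- inters
  out
}

#' Derive a module signature from the DEG intersection
#'
#' The signature is the set of module genes that are also differentially
#' expressed (the construction behind the 75-gene green-module
#' signature), sorted by gene id for stability. With
#' \code{direction = "up"} only upregulated DEGs are kept.
#'
#' @param module_genes character vector of module gene ids (or a
#'   \code{\link{ModuleSet}} plus \code{module}).
#' @param degs DEG table from \code{\link{callDEGs}} (uses the
#'   \code{significant} flag and \code{log2FC}) or a character vector of
#'   DEG ids.
#' @param module module label when \code{module_genes} is a ModuleSet.
#' @param direction \code{"both"} (default) or \code{"up"}.
#' @return character vector of signature gene ids, sorted.
#' @export
deriveModuleSignature <- function(module_genes, degs, module = NULL,
                                  direction = c("both", "up")) {
  direction <- match.arg(direction)
  if (is(module_genes, "ModuleSet")) {
    if (is.null(module)) stop("give a module label with a ModuleSet")
    module_genes <- moduleGenes(module_genes, module)
  }
  if (is.data.frame(degs)) {
    keep <- degs$significant
    if (direction == "up") keep <- keep & degs$log2FC > 0
    deg_ids <- degs$gene[keep]
  } else {
    deg_ids <- as.character(degs)
  }
  sig <- sort(intersect(unique(module_genes), unique(deg_ids)))
  if (length(sig) == 0) stop("empty module x DEG intersection")
  sig
}

#' Map a signature across species with a homology table
#'
#' Translates gene ids through a two-column source-to-target mapping
#' (e.g. mouse symbols to human): one-to-many mappings are expanded,
#' unmapped ids are dropped and counted.
#'
#' @param genes character vector of source-species gene ids.
#' @param map data.frame with columns \code{source} and \code{target} (or
#'   the first two columns taken as such).
#' @return character vector of mapped target ids (unique, sorted), with
#'   attributes \code{n_unmapped} and \code{n_input}.
#' @export
mapHomologs <- function(genes, map) {
  map <- as.data.frame(map)
  if (!all(c("source", "target") %in% colnames(map))) {
    colnames(map)[1:2] <- c("source", "target")
  }
  genes <- unique(as.character(genes))
  hit <- map[map$source %in% genes, , drop = FALSE]
  out <- sort(unique(as.character(hit$target)))
  if (length(out) == 0) stop("no gene mapped through the homology table")
  attr(out, "n_unmapped") <- sum(!genes %in% map$source)
  attr(out, "n_input") <- length(genes)
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated name, description, then
#' gene ids.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path, description = "") {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
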