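# 2^-ddCt relative expression from replicate Ct tables, hierarchical
# clustering for heat-map row ordering, and long-format stress reports.

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = ct_target - ct_reference; replicates are averaged on
#' the dCt (cycle) scale, the standard Livak reading. ddCt subtracts the
#' calibrator sample's mean dCt per gene, and the reported cell is
#' log2(2^-ddCt) = -ddCt, so the calibrator column is identically zero.
#' Replicate variability is propagated as the SD of replicate dCt.
#'
#' @param ct data.frame with columns \code{gene}, \code{sample},
#'   \code{replicate}, \code{ct_target}, \code{ct_reference} (see
#'   \code{\link{readCtTable}}).
#' @param calibrator Calibrator sample id (e.g. leaf tissue, or the 0 h time
#'   point).
#' @return A \code{\link{DdCtExperiment-class}} (genes x samples) with assays
#'   \code{log2fc} and \code{sd}.
#' @export
deltaDeltaCt <- function(ct, calibrator) {
  stopifnot(all(c("gene", "sample", "replicate", "ct_target",
                  "ct_reference") %in% names(ct)))
  if (!calibrator %in% ct$sample)
    stop("calibrator sample '", calibrator, "' not present", call. = FALSE)
  genes <- unique(ct$gene)
  samples <- unique(ct$sample)
  samples <- c(calibrator, setdiff(samples, calibrator))
  hasCal <- vapply(genes, function(g)
    any(ct$gene == g & ct$sample == calibrator), logical(1))
  if (any(!hasCal)) {
    warning("gene(s) without calibrator measurements dropped: ",
            paste(genes[!hasCal], collapse = ", "))
    genes <- genes[hasCal]
  }
  nrep <- table(ct$gene, ct$sample)
  if (any(nrep[nrep > 0] != 3))
    warning("non-triplicate replicate counts present; accepted as-is")
  dct <- ct$ct_target - ct$ct_reference
  V <- S <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  for (g in genes) {
    calMean <- mean(dct[ct$gene == g & ct$sample == calibrator])
    for (s in samples) {
      v <- dct[ct$gene == g & ct$sample == s]
      if (!length(v)) next
      V[g, s] <- -(mean(v) - calMean)
      S[g, s] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  V[, calibrator] <- 0  # exact calibrator identity
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2fc = V, sd = S),
    metadata = list(calibrator = calibrator))
  new("DdCtExperiment", se)
}

#' Deterministic heat-map row ordering by hierarchical clustering
#'
#' Agglomerative clustering of the gene rows (average linkage, Euclidean
#' metric by default). Rows are sorted by gene id before clustering so the
#' ordering is a pure function of the matrix content, invariant under input
#' row permutation; duplicate rows merge at height zero and end up adjacent.
#'
#' @param x \code{DdCtExperiment} or numeric matrix (genes x samples).
#' @param linkage \code{hclust} agglomeration method (default
#'   \code{"average"}).
#' @param metric \code{dist} metric (default \code{"euclidean"}).
#' @param k Number of groups for the dendrogram cut (default 2, mirroring a
#'   two-category expression split).
#' @return list with \code{order} (gene ids, dendrogram order),
#'   \code{groups} (named cluster assignment from \code{cutree}),
#'   \code{hclust} (the tree).
#' @export
clusterOrder <- function(x, linkage = "average", metric = "euclidean", k = 2) {
  m <- if (is(x, "DdCtExperiment")) log2FoldChanges(x) else x
  stopifnot(is.matrix(m), nrow(m) >= 2, !is.null(rownames(m)))
  m <- m[order(rownames(m)), , drop = FALSE]
  if (all(apply(m, 2, function(col) length(unique(col)) == 1)))
    warning("constant matrix: ordering is arbitrary but deterministic")
  h <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  list(order = rownames(m)[h$order],
       groups = stats::cutree(h, k = min(k, nrow(m))),
       hclust = h)
}

#' Long-format expression report across stress conditions
#'
#' Flattens one expression matrix per condition (each calibrated against its
#' own 0 h / control sample) into a tidy table suitable for heat-map
#' rendering. Conditions with differing sample grids are put on the union
#' grid with missing cells marked NA.
#'
#' @param matrices Named list of \code{DdCtExperiment}s or matrices, one per
#'   condition.
#' @return data.frame with columns \code{gene}, \code{condition},
#'   \code{time}, \code{value}.
#' @export
stressTimecourseReport <- function(matrices) {
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  mats <- lapply(matrices, function(x)
    if (is(x, "DdCtExperiment")) log2FoldChanges(x) else x)
  allTimes <- unique(unlist(lapply(mats, colnames)))
  grids <- lapply(mats, colnames)
  if (!all(vapply(grids, function(g) identical(sort(g), sort(allTimes)),
                  logical(1))))
    warning("inconsistent time grids across conditions; using the union grid")
  rows <- lapply(names(mats), function(cond) {
    m <- mats[[cond]]
    df <- expand.grid(gene = rownames(m), time = allTimes,
                      stringsAsFactors = FALSE)
    df$condition <- cond
    df$value <- mapply(function(g, t)
      if (t %in% colnames(m)) m[g, t] else NA_real_, df$gene, df$time)
    df[, c("gene", "condition", "time", "value")]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$condition, match(out$time, allTimes)), ]
  rownames(out) <- NULL
  out
}
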