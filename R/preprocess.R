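#' Quantile-normalize an expression matrix across arrays
#'
#' Forces every column (array) to share the same value distribution:
#' the rank-wise mean across columns. Ties within a column receive the
#' mean of the rank-wise means over the tied ranks. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param mat numeric matrix (probes x samples), >= 2 columns.
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("mat must be numeric matrix")
  if (ncol(mat) < 2) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Log2-transform a raw intensity matrix
#'
#' @param mat numeric matrix of positive raw intensities.
#' @return log2-scale matrix.
#' @export
log2_transform <- function(mat) {
  bad <- which(!(mat > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity in row(s): ",
         paste(unique(rownames(mat)[bad[, 1]] %||%
                        as.character(bad[, 1])), collapse = ", "))
  }
  log2(mat)
}

#' Floor-filter probes below the global expression floor
#'
#' The floor is the global median of the log2 matrix rounded down to an
#' integer; probes whose profile is completely below the floor (every
#' value strictly less) are treated as unexpressed background and
#' removed.
#'
#' @param mat log2-scale matrix.
#' @param threshold optional fixed floor; default computed from `mat`.
#' @return list: `matrix` (retained rows), `report` list(threshold,
#'   n_dropped, dropped = probe ids).
#' @export
floor_filter <- function(mat, threshold = NULL) {
  threshold <- threshold %||% floor(median(mat))
  below <- apply(mat < threshold, 1L, all)
  if (all(below)) stop("all probes fall below the expression floor (",
                       threshold, ")")
  list(matrix = mat[!below, , drop = FALSE],
       report = list(threshold = threshold,
                     n_dropped = sum(below),
                     dropped = rownames(mat)[below]))
}

#' Collapse probes to genes by the highest-mean representative probe
#'
#' Each gene is represented by its probe with the highest mean
#' expression across all samples; ties break to the lexicographically
#' smallest probe id. Probes absent from the map (or mapped to NA) are
#' dropped and reported.
#'
#' @param mat probe-level matrix with probe rownames.
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @return list: `matrix` (gene-level, gene rownames), `report`
#'   list(n_unmapped, unmapped, representative = data.frame(gene,
#'   probe)).
#' @export
collapse_probes <- function(mat, probe_map) {
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe)) {
    stop("probes mapping to more than one gene are not supported")
  }
  gene <- probe_map$gene[match(rownames(mat), probe_map$probe)]
  unmapped <- rownames(mat)[is.na(gene)]
  keep <- !is.na(gene)
  m <- mat[keep, , drop = FALSE]
  gene <- gene[keep]
  pm <- rowMeans(m)
  ord <- order(gene, -pm, rownames(m))  # per gene: highest mean, then id
  first <- !duplicated(gene[ord])
  rep_idx <- ord[first]
  out <- m[rep_idx, , drop = FALSE]
  rep_tab <- data.frame(gene = gene[rep_idx], probe = rownames(m)[rep_idx])
  rownames(out) <- rep_tab$gene
  if (anyDuplicated(rownames(out))) stop("internal: duplicate gene rows")
  list(matrix = out,
       report = list(n_unmapped = length(unmapped), unmapped = unmapped,
                     representative = rep_tab))
}

#' Full preprocessing pipeline: normalize, log2, floor-filter, collapse
#'
#' Fixed stage order: quantile normalization on the raw scale, log2
#' transform, floor filter at the rounded-down global median, and
#' probe-to-gene collapse. The floor is computed after normalization
#' and log2 transform (an explicit assumption of this pipeline). Input
#' already on the log2 scale skips the transform.
#'
#' @param mat probe-level matrix.
#' @param probe_map data.frame `probe`, `gene`.
#' @param scale `"raw"` or `"log2"` (scale of `mat`).
#' @return list: `matrix` (gene x sample log2 matrix), `report` with
#'   per-stage records.
#' @export
preprocess_expression <- function(mat, probe_map,
                                  scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  mat <- quantile_normalize(mat)
  if (scale == "raw") mat <- log2_transform(mat)
  ff <- floor_filter(mat)
  cp <- collapse_probes(ff$matrix, probe_map)
  list(matrix = cp$matrix,
       report = list(floor = ff$report, collapse = cp$report,
                     n_probes_in = nrow(mat),
                     n_genes_out = nrow(cp$matrix)))
}
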