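#' Standardize gene profiles to zero mean and unit variance
#'
#' @param mat genes x timepoints matrix of time-point means.
#' @return row-standardized matrix (each row mean 0, sd 1).
#' @export
standardize_profiles <- function(mat) {
  sds <- apply(mat, 1L, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance profile(s): ",
         paste(head(rownames(mat)[zero], 5), collapse = ", "))
  }
  (mat - rowMeans(mat)) / sds
}

# Calinski-Harabasz pseudo-F from a kmeans fit
pseudo_f <- function(fit, n) {
  k <- nrow(fit$centers)
  if (k <= 1 || fit$tot.withinss <= 0) return(NA_real_)
  (fit$betweenss / (k - 1)) / (fit$tot.withinss / (n - k))
}

#' K-means clustering with silhouette / pseudo-F selection of K
#'
#' Scans K over `k_min:k_max`; at each K, runs [stats::kmeans()] with
#' `n_restarts` random starts (best within-cluster objective kept),
#' and records the mean Euclidean silhouette width and the
#' Calinski-Harabasz pseudo-F. The returned K maximizes the mean
#' silhouette; ties break to higher pseudo-F, then to smaller K.
#' Degenerate fits (fewer distinct points than centers, or undefined
#' silhouette) are recorded as NA and skipped in the selection, with a
#' warning.
#'
#' @param mat standardized genes x timepoints matrix.
#' @param k_min,k_max K range (k_min >= 2, k_max < number of rows).
#' @param seed integer seed (restarts reproducible).
#' @param n_restarts random restarts per K (default 10).
#' @param iter_max kmeans iteration cap.
#' @return object of class `"cluster_model"`: list(K, centroids,
#'   memberships = named integer vector, selection_trace =
#'   data.frame(K, silhouette, pseudo_F), merge_map).
#' @export
cluster_profiles <- function(mat, k_min = 2, k_max = 20, seed = 1L,
                             n_restarts = 10, iter_max = 50) {
  if (k_min < 2) stop("k_min must be >= 2")
  if (k_max >= nrow(mat)) stop("k_max must be below the gene count")
  ks <- k_min:k_max
  d <- dist(mat)
  local_seed(seed, {
    fits <- vector("list", length(ks))
    sil <- pf <- rep(NA_real_, length(ks))
    for (j in seq_along(ks)) {
      k <- ks[j]
      fit <- tryCatch(
        kmeans(mat, centers = k, nstart = n_restarts,
               iter.max = iter_max),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      fits[[j]] <- fit
      sw <- tryCatch(cluster::silhouette(fit$cluster, d),
                     error = function(e) NULL)
      if (!is.null(sw) && !is.null(dim(sw))) {
        sil[j] <- mean(sw[, "sil_width"])
      }
      pf[j] <- pseudo_f(fit, nrow(mat))
    }
    if (all(is.na(sil))) {
      warning("silhouette undefined for every K (degenerate input); ",
              "falling back to smallest K with a valid fit")
      ok <- which(!vapply(fits, is.null, TRUE))
      if (length(ok) == 0) {
        # fully degenerate (e.g. all rows identical): trivial one-
        # cluster model
        cen <- matrix(colMeans(mat), nrow = 1,
                      dimnames = list("1", colnames(mat)))
        return(structure(list(
          K = 1L, centroids = cen,
          memberships = setNames(rep(1L, nrow(mat)), rownames(mat)),
          selection_trace = data.frame(K = ks, silhouette = sil,
                                       pseudo_F = pf),
          merge_map = setNames(1L, "1")), class = "cluster_model"))
      }
      best <- ok[1L]
    } else {
      cand <- which(sil == max(sil, na.rm = TRUE))
      if (length(cand) > 1) {
        cand <- cand[order(-pf[cand], ks[cand])]
      }
      best <- cand[1L]
    }
    fit <- fits[[best]]
    structure(list(
      K = ks[best],
      centroids = fit$centers,
      memberships = setNames(fit$cluster, rownames(mat)),
      selection_trace = data.frame(K = ks, silhouette = sil,
                                   pseudo_F = pf),
      merge_map = if (ks[best] == 8) default_merge_map() else
        setNames(seq_len(ks[best]), as.character(seq_len(ks[best])))
    ), class = "cluster_model")
  })
}

#' Assign dynamic genes to fitted clusters by centroid correlation
#'
#' Each gene's standardized profile is compared to every centroid by
#' Pearson correlation and assigned to the best-correlated cluster.
#' Ties break to the lowest cluster id (flagged); constant profiles
#' are unassigned (cluster NA, flagged).
#'
#' @param mat genes x timepoints matrix of time-point means (need not
#'   be pre-standardized).
#' @param model a `"cluster_model"` (or a centroid matrix).
#' @return data.frame: gene, cluster, correlation, tie, unassigned.
#' @export
assign_to_clusters <- function(mat, model) {
  centroids <- if (inherits(model, "cluster_model")) model$centroids else
    model
  n <- nrow(mat)
  cluster_id <- integer(n); r_best <- numeric(n)
  tie <- logical(n); unassigned <- logical(n)
  for (i in seq_len(n)) {
    x <- mat[i, ]
    if (sd(x) == 0) {
      cluster_id[i] <- NA_integer_; r_best[i] <- NA_real_
      unassigned[i] <- TRUE
      next
    }
    r <- apply(centroids, 1L, function(cen) cor(x, cen))
    best <- max(r)
    hits <- which(r == best)
    cluster_id[i] <- hits[1L]
    r_best[i] <- best
    tie[i] <- length(hits) > 1
  }
  data.frame(gene = rownames(mat), cluster = cluster_id,
             correlation = r_best, tie = tie, unassigned = unassigned,
             row.names = NULL)
}

#' Fraction of complexes whose super-dynamic members span >= 2 clusters
#'
#' Over complexes with at least two cluster-assigned super-dynamic
#' members, the fraction whose members occupy two or more (optionally
#' merged) clusters. Merging combines clusters with similar temporal
#' behavior via the model's merge map, so the merged fraction is never
#' larger than the unmerged one.
#'
#' @param complex_members named list: complex id -> character vector of
#'   member genes.
#' @param assignments named integer vector gene -> cluster id.
#' @param merge_map optional named map cluster id -> merged group id
#'   (e.g. [default_merge_map()]); NULL = no merging.
#' @return fraction in \[0, 1\] (NaN if no complex qualifies).
#' @export
heterogeneity_fraction <- function(complex_members, assignments,
                                   merge_map = NULL) {
  span <- vapply(complex_members, function(members) {
    cl <- assignments[intersect(members, names(assignments))]
    cl <- cl[!is.na(cl)]
    if (length(cl) < 2) return(NA)
    if (!is.null(merge_map)) cl <- merge_map[as.character(cl)]
    length(unique(cl)) >= 2
  }, logical(1))
  mean(span, na.rm = TRUE)
}
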