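#' Raw time-course chi-squared statistic
#'
#' For a gene with time-point mean profile `x` of length N, the raw
#' statistic is the variance of the time-point means,
#' `sum((x - mean(x))^2) / (N - 1)`. It carries the units of squared
#' log2 intensity; no per-gene experimental error enters here — a
#' single universal error scale is estimated afterwards (see
#' [calibrate_universal_error()]) and maps the statistic onto the
#' standard chi-squared distribution with N - 1 degrees of freedom.
#'
#' @param x numeric vector of time-point means (length >= 2).
#' @return the raw statistic (scalar >= 0).
#' @export
raw_statistic <- function(x) {
  if (length(x) < 2 || any(!is.finite(x))) {
    stop("need >= 2 finite time-point means")
  }
  sum((x - mean(x))^2) / (length(x) - 1)
}

#' Calibrate the universal error scale on candidate-null genes
#'
#' Estimates the single scale factor c such that c * raw_statistic
#' follows the standard chi-squared distribution with N - 1 degrees of
#' freedom for genes with no temporal signal. Candidates default to
#' genes with peak-trough fold change below the dynamic gate (< 2),
#' and c is fit by median matching — the median of the scaled
#' candidate statistics equals the chi-squared median — which is
#' robust to residual contamination of the candidate set by truly
#' dynamic genes. A Kolmogorov-Smirnov distance of the scaled
#' candidate statistics against the reference chi-squared is reported
#' as a diagnostic.
#'
#' @param statistics raw statistics of the candidate-null genes.
#' @param n_timepoints N, number of time points (reference df = N - 1).
#' @param min_candidates minimum candidate count (default 100).
#' @return object of class `"universal_error"`: list(scale_factor,
#'   reference_df, null_gene_count, ks_distance).
#' @export
calibrate_universal_error <- function(statistics, n_timepoints,
                                      min_candidates = 100) {
  statistics <- statistics[is.finite(statistics)]
  if (length(statistics) < min_candidates) {
    stop("only ", length(statistics), " candidate-null genes; need >= ",
         min_candidates, ". Consider relaxing the candidate fold-change ",
         "threshold.")
  }
  df <- as.integer(n_timepoints) - 1L
  med <- median(statistics)
  if (med <= 0) stop("median candidate statistic is zero; cannot calibrate")
  scale_factor <- qchisq(0.5, df) / med
  ks <- suppressWarnings(
    ks.test(statistics * scale_factor, pchisq, df = df)$statistic
  )
  structure(list(scale_factor = unname(scale_factor),
                 reference_df = df,
                 null_gene_count = length(statistics),
                 ks_distance = unname(ks)),
            class = "universal_error")
}

#' Chi-squared p-value of a scaled time-course statistic
#'
#' @param statistic raw statistic(s) from [raw_statistic()].
#' @param calibration a `"universal_error"` object.
#' @return upper-tail p-value(s) at `calibration$reference_df` df.
#' @export
chisq_p_value <- function(statistic, calibration) {
  stopifnot(inherits(calibration, "universal_error"))
  pchisq(statistic * calibration$scale_factor,
         df = calibration$reference_df, lower.tail = FALSE)
}

#' Peak-to-trough fold change of a log2 profile
#'
#' @param x log2-scale time-point means.
#' @return linear fold change `2^(max(x) - min(x))` (>= 1).
#' @export
fold_change <- function(x) 2^(max(x) - min(x))

#' Classify a gene from its p-value and fold change
#'
#' Rule set (p from the calibrated chi-squared test, fold linear):
#' \itemize{
#'   \item non-dynamic: p >= 0.01 and fold < 2
#'   \item dynamic: p < 0.01 and fold >= 2
#'   \item super-dynamic: dynamic and fold >= 4
#'   \item unresolved: everything else
#' }
#'
#' @param p p-value(s) in \[0, 1\].
#' @param fold fold change(s) >= 1.
#' @param alpha significance cutoff (default 0.01).
#' @param fc dynamic fold-change gate (default 2).
#' @param super_fc super-dynamic fold-change gate (default 4).
#' @return character vector of class labels.
#' @export
classify_gene <- function(p, fold, alpha = 0.01, fc = 2, super_fc = 4) {
  stopifnot(all(p >= 0 & p <= 1), all(fold >= 1))
  out <- rep("unresolved", length(p))
  out[p >= alpha & fold < fc] <- "non_dynamic"
  out[p < alpha & fold >= fc] <- "dynamic"
  out[p < alpha & fold >= super_fc] <- "super_dynamic"
  out
}

#' Benjamini-Hochberg adjustment with reclassification report
#'
#' @param p raw p-values.
#' @param fold fold changes matching `p` (for the reclassification
#'   report); optional.
#' @param alpha,fc,super_fc classification gates.
#' @return list: `adjusted` p-values, and when `fold` is given,
#'   `report` = table of raw-class vs adjusted-class counts and
#'   `n_changed`.
#' @export
benjamini_adjust <- function(p, fold = NULL, alpha = 0.01, fc = 2,
                             super_fc = 4) {
  if (length(p) < 1) stop("need >= 1 p-value")
  adjusted <- p.adjust(p, method = "BH")
  out <- list(adjusted = adjusted)
  if (!is.null(fold)) {
    raw_class <- classify_gene(p, fold, alpha, fc, super_fc)
    adj_class <- classify_gene(adjusted, fold, alpha, fc, super_fc)
    out$report <- table(raw = raw_class, adjusted = adj_class)
    out$n_changed <- sum(raw_class != adj_class)
  }
  out
}

#' Classify all genes of a time-course matrix
#'
#' End-to-end classification: per-gene time-point means, raw
#' chi-squared statistics, universal-error calibration on
#' low-fold-change candidate genes, p-values at N - 1 df, peak-trough
#' fold changes, and the four-way class assignment. The default output
#' classifies on unadjusted p-values; Benjamini-Hochberg adjusted
#' values are included for reference when `benjamini = TRUE`.
#'
#' @param mat gene-level log2 matrix, columns `"t<i>_r<j>"`.
#' @param alpha,fc,super_fc classification gates (defaults 0.01/2/4).
#' @param candidate_fc fold-change ceiling defining the candidate-null
#'   set for calibration (default = `fc`).
#' @param benjamini also compute BH-adjusted p-values.
#' @param calibration optionally reuse an existing
#'   `"universal_error"` object instead of calibrating on `mat`.
#' @return list: `table` (data.frame gene, statistic, p_value, adj_p,
#'   fold_change, class), `calibration`.
#' @export
classify_genes <- function(mat, alpha = 0.01, fc = 2, super_fc = 4,
                           candidate_fc = fc, benjamini = TRUE,
                           calibration = NULL) {
  tm <- timepoint_means(mat)
  stat <- apply(tm, 1L, raw_statistic)
  fold <- apply(tm, 1L, fold_change)
  if (is.null(calibration)) {
    calibration <- calibrate_universal_error(stat[fold < candidate_fc],
                                             n_timepoints = ncol(tm))
  }
  p <- chisq_p_value(stat, calibration)
  cls <- classify_gene(p, fold, alpha, fc, super_fc)
  adj <- if (benjamini) p.adjust(p, method = "BH") else rep(NA_real_,
                                                            length(p))
  list(table = data.frame(gene = rownames(mat), statistic = stat,
                          p_value = p, adj_p = adj, fold_change = fold,
                          class = cls, row.names = NULL),
       calibration = calibration)
}
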