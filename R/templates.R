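# Template scoring for domain-interaction models: a candidate's
# interface sequence is scored position-wise against the template's
# interface sequence with a substitution matrix, and standardized
# against scores of shuffled candidate sequences. This is a
# deliberately simple interface-similarity scorer; acceptance keeps
# the z >= 2.33 rule (or best-of-candidates fallback).

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

score_alignment <- function(a, b, mat) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- min(length(a), length(b))
  sum(mat[cbind(a[seq_len(n)], b[seq_len(n)])])
}

#' Z-score of a candidate interface sequence against a template
#'
#' Scores the candidate against the template interface with a
#' substitution-matrix position sum, then standardizes against the
#' scores of `n_shuffles` residue-shuffled versions of the candidate:
#' z = (score - mean(null)) / sd(null). Shuffling makes template
#' selection stochastic across seeds, mirroring how homology-based
#' template pickers behave run to run.
#'
#' @param candidate_seq,template_seq interface sequences (one-letter
#'   amino acid codes; positions are compared index-wise).
#' @param n_shuffles number of shuffled-null sequences (>= 100,
#'   default 1000).
#' @param seed integer seed.
#' @return list(score, z, rejected_degenerate): z is NA and the hit
#'   flagged when the shuffled scores have zero spread.
#' @export
template_zscore <- function(candidate_seq, template_seq,
                            n_shuffles = 1000, seed = 1L) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  mat <- blosum62()
  obs <- score_alignment(candidate_seq, template_seq, mat)
  cand <- strsplit(candidate_seq, "")[[1]]
  local_seed(seed, {
    null <- vapply(seq_len(n_shuffles), function(i) {
      score_alignment(paste(sample(cand), collapse = ""),
                      template_seq, mat)
    }, numeric(1))
    s <- sd(null)
    if (s == 0) {
      list(score = obs, z = NA_real_, rejected_degenerate = TRUE)
    } else {
      list(score = obs, z = (obs - mean(null)) / s,
           rejected_degenerate = FALSE)
    }
  })
}

#' Select an interaction template among candidates
#'
#' A candidate is accepted when its z-score reaches `z_min` (default
#' 2.33); if none does, the best-scoring candidate is accepted as a
#' fallback. Degenerate candidates (undefined z) are never accepted
#' via the z rule.
#'
#' @param candidate_seqs character vector of candidate interface
#'   sequences.
#' @param template_seq template interface sequence.
#' @param z_min acceptance z threshold.
#' @param n_shuffles,seed see [template_zscore()].
#' @return data.frame: candidate, score, z, accepted, best.
#' @export
select_template <- function(candidate_seqs, template_seq, z_min = 2.33,
                            n_shuffles = 1000, seed = 1L) {
  res <- lapply(seq_along(candidate_seqs), function(i) {
    template_zscore(candidate_seqs[i], template_seq, n_shuffles,
                    seed + i - 1L)
  })
  score <- vapply(res, `[[`, numeric(1), "score")
  z <- vapply(res, `[[`, numeric(1), "z")
  degen <- vapply(res, `[[`, logical(1), "rejected_degenerate")
  best <- seq_along(score) == which.max(score)
  accepted <- (!degen & !is.na(z) & z >= z_min) | best
  data.frame(candidate = candidate_seqs, score = score, z = z,
             accepted = accepted, best = best)
}

#' Average a compatibility call over repeated template-selection runs
#'
#' Template selection is stochastic (shuffled-sequence nulls), so the
#' triplet call can differ between runs. This helper repeats a
#' caller-supplied run function over `n_runs` derived seeds and
#' reports the mean XOR likelihood.
#'
#' @param run_fn function(seed) returning `"XOR"` or `"AND"`.
#' @param n_runs number of runs (>= 5 recommended).
#' @param seed base seed; run i uses `seed + i - 1`.
#' @return list(xor_likelihood, calls).
#' @export
average_runs <- function(run_fn, n_runs = 5, seed = 1L) {
  calls <- vapply(seq_len(n_runs), function(i) run_fn(seed + i - 1L), "")
  stopifnot(all(calls %in% c("XOR", "AND")))
  list(xor_likelihood = mean(calls == "XOR"), calls = calls)
}
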