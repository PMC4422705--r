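#' Parse time/replicate design from sample column names
#'
#' Sample columns follow the `"t<timepoint>_r<replicate>"` convention used
#' throughout the package (e.g. `"t3_r2"` = time point 3, replicate 2).
#'
#' @param x character vector of column names.
#' @return data.frame with columns `time` and `replicate` (integers).
#' @export
parse_design <- function(x) {
  m <- regmatches(x, regexec("^t(\\d+)_r(\\d+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed sample names (expected 't<i>_r<j>'): ",
         paste(x[bad], collapse = ", "))
  }
  data.frame(
    time = as.integer(vapply(m, `[`, "", 2L)),
    replicate = as.integer(vapply(m, `[`, "", 3L))
  )
}

#' Per-time-point mean profiles
#'
#' Averages replicates at each time point, yielding the N-vector of
#' time-point means each gene's test statistic and fold change are
#' computed from.
#'
#' @param mat numeric matrix, rows = genes/probes, columns named
#'   `"t<i>_r<j>"`.
#' @return matrix genes x timepoints, columns ordered by time.
#' @export
timepoint_means <- function(mat) {
  des <- parse_design(colnames(mat))
  times <- sort(unique(des$time))
  out <- vapply(times, function(tt) {
    cols <- which(des$time == tt)
    if (length(cols) == 1L) mat[, cols] else rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), paste0("t", times)))
  out
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
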