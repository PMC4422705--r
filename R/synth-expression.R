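#' Temporal archetype shape functions
#'
#' Eight canonical temporal shapes over the differentiation time course,
#' arranged as four induction shapes (1-4) and their repression mirrors
#' (5-8): 1/5 early highly transient, 2/6 early transient, 3/7 early
#' highly sustained, 4/8 early sustained. Each shape is returned on a
#' unit peak-to-trough span so a gene's log2 amplitude can be applied by
#' simple scaling. Shapes are smooth bump / saturation curves; their
#' exact parameterization is a free modelling choice of this package.
#'
#' @param n_timepoints number of equally spaced time points.
#' @param phase_shift shift (in time-point units) applied to the shape,
#'   emulating genes that engage the same program earlier or later.
#' @return matrix 8 x n_timepoints; rows are archetypes 1-8, each row
#'   spans exactly \[0, 1\] (up shapes) or \[-1, 0\] (down shapes).
#' @export
archetype_profiles <- function(n_timepoints, phase_shift = 0) {
  stopifnot(n_timepoints >= 2)
  t <- seq(0, 1, length.out = n_timepoints) - phase_shift / n_timepoints
  up <- rbind(
    exp(-((t - 0.15) / 0.10)^2),          # 1: early highly transient
    exp(-((t - 0.30) / 0.22)^2),          # 2: early transient
    1 - exp(-pmax(t, 0) / 0.08),          # 3: early highly sustained
    1 - exp(-pmax(t, 0) / 0.30)           # 4: early sustained
  )
  # normalize each to unit span on the realized grid
  up <- t(apply(up, 1L, function(x) (x - min(x)) / (max(x) - min(x))))
  out <- rbind(up, -up)
  rownames(out) <- paste0("archetype", 1:8)
  out
}

#' Default merge map for archetype clusters with similar behavior
#'
#' Pairs of clusters whose temporal shapes are variants of the same
#' behavior (transient induction, sustained induction, and their
#' repressed mirrors). Used by [heterogeneity_fraction()].
#'
#' @return named integer vector mapping cluster id 1..8 to merged group.
#' @export
default_merge_map <- function() {
  stats::setNames(c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 3L), as.character(1:8))
}

#' Synthetic time-course design
#'
#' Bundles the parameters of the synthetic expression generator. The
#' defaults mirror the differentiation experiment the pipeline targets:
#' 10 time points sampled in triplicate, eight temporal archetypes, and
#' the observed rough proportions of dynamic (~0.36) and super-dynamic
#' (~0.08) genes.
#'
#' @param n_timepoints number of time points (>= 2).
#' @param n_replicates replicates per time point.
#' @param n_genes number of genes.
#' @param noise_sd replicate noise standard deviation, log2 units.
#' @param baseline_mean mean baseline expression, log2 units.
#' @param baseline_sd between-gene baseline spread, log2 units.
#' @param fraction_dynamic fraction of genes with a temporal program
#'   (includes the super-dynamic subset).
#' @param fraction_super_dynamic fraction with peak-trough span >= 2
#'   log2 units (must be <= fraction_dynamic).
#' @param fraction_below_floor fraction of extra probes generated
#'   entirely below the expression floor, to exercise the floor filter.
#' @param probes_per_gene average probes mapping to each gene (>= 1);
#'   extra probes are attenuated copies so the representative-probe
#'   collapse has work to do.
#' @param archetypes integer subset of 1:8, the temporal archetypes
#'   dynamic genes are drawn from.
#' @param phase_jitter half-width (time-point units) of the uniform
#'   phase shift applied per dynamic gene. The default 0.5 (half a
#'   sampling interval) models modest timing variability among genes
#'   sharing one temporal program while keeping archetypes separable.
#' @param seed integer seed; identical seeds give identical output.
#' @return object of class `"synth_design"` (a validated list).
#' @export
synth_design <- function(n_timepoints = 10, n_replicates = 3,
                         n_genes = 1000, noise_sd = 0.25,
                         baseline_mean = 9, baseline_sd = 1,
                         fraction_dynamic = 0.36,
                         fraction_super_dynamic = 0.08,
                         fraction_below_floor = 0,
                         probes_per_gene = 1, archetypes = 1:8,
                         phase_jitter = 0.5, seed = 1L) {
  if (n_timepoints < 2 || n_genes < 1 || n_replicates < 1) {
    stop("invalid design: counts must be positive (n_timepoints >= 2)")
  }
  if (noise_sd < 0) stop("invalid design: noise_sd must be >= 0")
  if (fraction_dynamic < 0 || fraction_dynamic > 1 ||
      fraction_super_dynamic < 0 || fraction_super_dynamic > 1) {
    stop("invalid design: fractions must lie in [0, 1]")
  }
  if (fraction_super_dynamic > fraction_dynamic) {
    stop("invalid design: fraction_super_dynamic must be <= fraction_dynamic")
  }
  if (!all(archetypes %in% 1:8) || length(archetypes) == 0) {
    stop("invalid design: archetypes must be a nonempty subset of 1:8")
  }
  structure(as.list(environment()), class = "synth_design")
}

#' Generate a synthetic probe-level expression matrix with ground truth
#'
#' Non-dynamic genes get flat mean profiles plus i.i.d. Gaussian
#' replicate noise on the log2 scale; dynamic genes follow one of the
#' eight archetypes scaled to a peak-trough span of 1-2 log2 units
#' (2-4 fold), super-dynamic genes to a span >= 2 (fold >= 4). Each
#' dynamic gene receives a random phase shift so independently drawn
#' genes are uncorrelated in expectation. Super/dynamic gene counts are
#' fixed by rounding the design fractions, so planted class sizes are
#' exact. Optionally, attenuated sister probes and all-below-floor
#' probes are appended so the preprocessing filters are exercised.
#'
#' @param design a [synth_design()].
#' @param scale `"log2"` (default) or `"raw"`; raw output is
#'   `2^log2values`, suitable for the full preprocessing pipeline.
#' @return list with elements:
#'   \item{matrix}{probes x (time x replicate) matrix, columns
#'     `"t<i>_r<j>"`.}
#'   \item{truth}{data.frame: gene, probe (representative), class
#'     (`non_dynamic`/`dynamic`/`super_dynamic`), archetype (NA for
#'     non-dynamic), span (planted log2 peak-trough), phase.}
#'   \item{probe_map}{data.frame: probe, gene (floor probes unmapped,
#'     gene = NA).}
#' @export
synth_expression <- function(design, scale = c("log2", "raw")) {
  stopifnot(inherits(design, "synth_design"))
  scale <- match.arg(scale)
  d <- design
  local_seed(d$seed, {
    n_super <- round(d$n_genes * d$fraction_super_dynamic)
    n_dyn_total <- round(d$n_genes * d$fraction_dynamic)
    n_dyn <- max(n_dyn_total - n_super, 0L)
    n_flat <- d$n_genes - n_super - n_dyn

    genes <- sprintf("G%05d", seq_len(d$n_genes))
    class <- c(rep("super_dynamic", n_super), rep("dynamic", n_dyn),
               rep("non_dynamic", n_flat))
    archetype <- ifelse(class == "non_dynamic", NA_integer_,
                        sample(d$archetypes, d$n_genes, replace = TRUE))
    span <- numeric(d$n_genes)
    span[class == "super_dynamic"] <- runif(n_super, 2.2, 4)
    span[class == "dynamic"] <- runif(n_dyn, 1.2, 1.9)
    phase <- ifelse(class == "non_dynamic", 0,
                    runif(d$n_genes, -d$phase_jitter, d$phase_jitter))
    baseline <- rnorm(d$n_genes, d$baseline_mean, d$baseline_sd)

    prof <- matrix(rep(baseline, d$n_timepoints), nrow = d$n_genes)
    idx_dyn <- which(class != "non_dynamic")
    for (i in idx_dyn) {
      shape <- archetype_profiles(d$n_timepoints, phase[i])[archetype[i], ]
      prof[i, ] <- baseline[i] + span[i] * shape
    }

    cn <- as.vector(t(outer(seq_len(d$n_timepoints),
                            seq_len(d$n_replicates),
                            function(i, j) sprintf("t%d_r%d", i, j))))
    mat <- prof[, rep(seq_len(d$n_timepoints), each = d$n_replicates),
                drop = FALSE]
    if (d$noise_sd > 0) {
      mat <- mat + matrix(rnorm(length(mat), 0, d$noise_sd), nrow = nrow(mat))
    }
    probe <- sprintf("P%05d_1", seq_len(d$n_genes))
    rownames(mat) <- probe
    colnames(mat) <- cn
    probe_map <- data.frame(probe = probe, gene = genes)

    # attenuated sister probes (lower mean, same shape)
    n_extra <- round(d$n_genes * max(d$probes_per_gene - 1, 0))
    if (n_extra > 0) {
      pick <- sample(d$n_genes, n_extra, replace = TRUE)
      extra <- mat[pick, , drop = FALSE] - runif(n_extra, 0.5, 2)
      rownames(extra) <- sprintf("P%05d_2x%04d", pick, seq_len(n_extra))
      mat <- rbind(mat, extra)
      probe_map <- rbind(probe_map,
                         data.frame(probe = rownames(extra),
                                    gene = genes[pick]))
    }

    # unmapped probes entirely below the expected expression floor
    n_floor <- round(nrow(mat) * d$fraction_below_floor)
    if (n_floor > 0) {
      lowmean <- d$baseline_mean - 4 - runif(n_floor, 0, 1)
      low <- matrix(rep(lowmean, ncol(mat)), nrow = n_floor) +
        matrix(rnorm(n_floor * ncol(mat), 0, min(d$noise_sd, 0.2)),
               nrow = n_floor)
      rownames(low) <- sprintf("PFLOOR%04d", seq_len(n_floor))
      colnames(low) <- cn
      mat <- rbind(mat, low)
      probe_map <- rbind(probe_map,
                         data.frame(probe = rownames(low), gene = NA))
    }

    truth <- data.frame(gene = genes, probe = probe, class = class,
                        archetype = archetype, span = span, phase = phase)
    if (scale == "raw") mat <- 2^mat
    list(matrix = mat, truth = truth, probe_map = probe_map)
  })
}
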