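#' Generate a synthetic paralog pair table with planted co-expression
#'
#' Builds `n_pairs` paralogous pairs over a fresh set of dynamic genes.
#' A planted-correlated pair shares one archetype and phase (expected
#' Pearson r well above 0.6); a planted-anticorrelated pair uses the
#' sign-flipped archetype (expected r below -0.6); remaining pairs draw
#' archetypes and phases independently. Divergence covariates are
#' planted with the direction reported for real duplicate pairs:
#' anti-correlated pairs get more Pfam-composition differences, lower
#' sequence identity, larger length differences and older duplication
#' ages than correlated pairs.
#'
#' @param n_pairs number of pairs.
#' @param design a [synth_design()]; supplies time course geometry,
#'   noise and amplitude conventions (pairs are generated as
#'   super-dynamic-amplitude genes).
#' @param correlated_fraction,anticorrelated_fraction planted class
#'   fractions (sum <= 1).
#' @param seed integer seed.
#' @return list with:
#'   \item{pairs}{data.frame: geneA, geneB, planted_class, age_class,
#'     identity_pct, lengthA, lengthB, domainsA, domainsB
#'     (semicolon-separated Pfam-like lists).}
#'   \item{matrix}{log2 expression matrix for the 2*n_pairs genes
#'     (columns `"t<i>_r<j>"`).}
#' @export
synth_paralog_table <- function(n_pairs, design,
                                correlated_fraction = 0.4,
                                anticorrelated_fraction = 0.12,
                                seed = 1L) {
  stopifnot(inherits(design, "synth_design"))
  if (correlated_fraction + anticorrelated_fraction > 1) {
    stop("planted class fractions must sum to <= 1")
  }
  if (2L * n_pairs > 99999L) stop("n_pairs exceeds available gene ids")
  d <- design
  local_seed(seed, {
    n_cor <- round(n_pairs * correlated_fraction)
    n_anti <- round(n_pairs * anticorrelated_fraction)
    n_other <- n_pairs - n_cor - n_anti
    planted <- c(rep("correlated", n_cor), rep("anticorrelated", n_anti),
                 rep("neither", n_other))

    geneA <- sprintf("PLG%05dA", seq_len(n_pairs))
    geneB <- sprintf("PLG%05dB", seq_len(n_pairs))
    cn <- as.vector(t(outer(seq_len(d$n_timepoints),
                            seq_len(d$n_replicates),
                            function(i, j) sprintf("t%d_r%d", i, j))))
    nc <- length(cn)

    profile_of <- function(arch, phase, span, baseline) {
      shape <- archetype_profiles(d$n_timepoints, phase)[arch, ]
      baseline + span * shape
    }
    noisy <- function(prof) {
      x <- rep(prof, each = d$n_replicates)
      if (d$noise_sd > 0) x <- x + rnorm(nc, 0, d$noise_sd)
      x
    }

    mat <- matrix(NA_real_, nrow = 2L * n_pairs, ncol = nc,
                  dimnames = list(rep("", 2L * n_pairs), cn))
    for (i in seq_len(n_pairs)) {
      archA <- sample(1:8, 1L)
      phaseA <- runif(1, -design$phase_jitter, design$phase_jitter)
      spanA <- runif(1, 2.2, 4)
      baseA <- rnorm(1, d$baseline_mean, d$baseline_sd)
      baseB <- rnorm(1, d$baseline_mean, d$baseline_sd)
      if (planted[i] == "correlated") {
        archB <- archA; phaseB <- phaseA
      } else if (planted[i] == "anticorrelated") {
        # archetypes 5-8 are the negations of 1-4
        archB <- ifelse(archA > 4, archA - 4L, archA + 4L)
        phaseB <- phaseA
      } else {
        archB <- sample(1:8, 1L); phaseB <- runif(1, -design$phase_jitter, design$phase_jitter)
      }
      spanB <- runif(1, 2.2, 4)
      mat[2L * i - 1L, ] <- noisy(profile_of(archA, phaseA, spanA, baseA))
      mat[2L * i, ] <- noisy(profile_of(archB, phaseB, spanB, baseB))
    }
    rownames(mat) <- as.vector(rbind(geneA, geneB))

    domain_pool <- sprintf("PF%04d", 1:40)
    age_levels <- c("old", "intermediate", "recent")
    # planted divergence direction: anti-correlated pairs are older,
    # less identical, more domain-divergent, more length-divergent
    age_p <- list(correlated = c(0.58, 0.30, 0.12),
                  anticorrelated = c(0.90, 0.09, 0.01),
                  neither = c(0.70, 0.20, 0.10))
    ident_mu <- c(correlated = 46, anticorrelated = 34, neither = 40)
    ddiff_mu <- c(correlated = 1.3, anticorrelated = 1.7, neither = 1.5)
    ldiff_mu <- c(correlated = 227, anticorrelated = 330, neither = 280)

    age_class <- character(n_pairs)
    identity_pct <- numeric(n_pairs)
    lengthA <- lengthB <- integer(n_pairs)
    domainsA <- domainsB <- character(n_pairs)
    for (i in seq_len(n_pairs)) {
      cl <- planted[i]
      age_class[i] <- sample(age_levels, 1L, prob = age_p[[cl]])
      identity_pct[i] <- min(max(rnorm(1, ident_mu[[cl]], 8), 5), 99)
      n_shared <- sample(1:4, 1L)
      shared <- sample(domain_pool, n_shared)
      ndiff <- rpois(1, ddiff_mu[[cl]])
      extraA <- sample(ndiff + 1L, 1L) - 1L
      extraB <- ndiff - extraA
      domainsA[i] <- paste(c(shared, sample(setdiff(domain_pool, shared),
                                            extraA)), collapse = ";")
      domainsB[i] <- paste(c(shared, sample(setdiff(domain_pool, shared),
                                            extraB)), collapse = ";")
      lengthA[i] <- sample(200:900, 1L)
      ld <- round(abs(rnorm(1, ldiff_mu[[cl]], ldiff_mu[[cl]] / 3)))
      lengthB[i] <- max(lengthA[i] + sample(c(-1, 1), 1L) * ld, 50L)
    }

    list(
      pairs = data.frame(geneA = geneA, geneB = geneB,
                         planted_class = planted, age_class = age_class,
                         identity_pct = identity_pct,
                         lengthA = lengthA, lengthB = lengthB,
                         domainsA = domainsA, domainsB = domainsB),
      matrix = mat
    )
  })
}
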