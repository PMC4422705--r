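#' Pearson correlation of two time-point mean profiles
#'
#' @param a,b numeric profiles of equal length N >= 3.
#' @return list(r, p): Pearson r and the two-sided p-value from the
#'   t transform at N - 2 df; r = NA with `excluded = TRUE` when either
#'   profile has zero variance.
#' @export
pair_pcc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0) {
    return(list(r = NA_real_, p = NA_real_, excluded = TRUE))
  }
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, excluded = FALSE)
}

#' Classify paralogous pairs by expression correlation
#'
#' Restricts pairs to those where both genes are dynamically expressed
#' (dynamic or super-dynamic), computes per-pair Pearson correlations
#' over the time-point mean profiles, and labels pairs correlated
#' (r >= threshold), anticorrelated (r <= -threshold), or neither.
#' Pairs where both genes are super-dynamic are flagged as the
#' super-dynamic stratum.
#'
#' @param pairs data.frame with columns `geneA`, `geneB` (plus any
#'   covariates, carried through).
#' @param mat gene-level log2 matrix, columns `"t<i>_r<j>"`.
#' @param classes data.frame `gene`, `class` (from [classify_genes()]).
#' @param r_threshold correlation threshold (default 0.6).
#' @return input data.frame restricted to both-dynamic pairs, with
#'   added columns `pcc`, `pcc_p`, `pair_class`, `super_stratum`, and
#'   attribute `"n_excluded"` (pairs dropped for a non-dynamic member
#'   or missing/constant profile).
#' @export
classify_pairs <- function(pairs, mat, classes, r_threshold = 0.6) {
  cls <- setNames(classes$class, classes$gene)
  tm <- timepoint_means(mat)
  dyn <- c("dynamic", "super_dynamic")
  ok <- pairs$geneA %in% rownames(tm) & pairs$geneB %in% rownames(tm) &
    cls[pairs$geneA] %in% dyn & cls[pairs$geneB] %in% dyn
  ok[is.na(ok)] <- FALSE
  out <- pairs[ok, , drop = FALSE]
  n <- nrow(out)
  pcc <- pcc_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- pair_pcc(tm[out$geneA[i], ], tm[out$geneB[i], ])
    pcc[i] <- res$r; pcc_p[i] <- res$p
  }
  keep <- !is.na(pcc)
  out <- out[keep, , drop = FALSE]
  out$pcc <- pcc[keep]
  out$pcc_p <- pcc_p[keep]
  out$pair_class <- ifelse(out$pcc >= r_threshold, "correlated",
                           ifelse(out$pcc <= -r_threshold,
                                  "anticorrelated", "neither"))
  out$super_stratum <- cls[out$geneA] == "super_dynamic" &
    cls[out$geneB] == "super_dynamic"
  rownames(out) <- NULL
  attr(out, "n_excluded") <- nrow(pairs) - nrow(out)
  out
}

#' Null distribution of correlations for random gene pairs
#'
#' Samples `n_pairs` unordered random gene pairs (two distinct genes
#' per pair), excluding any annotated paralog pair, and returns their
#' Pearson correlations over time-point mean profiles.
#'
#' @param mat gene-level log2 matrix, columns `"t<i>_r<j>"`.
#' @param genes gene ids to sample from (e.g. the dynamic set).
#' @param n_pairs number of random pairs.
#' @param exclude_pairs optional data.frame `geneA`, `geneB` of
#'   annotated pairs to exclude from the null.
#' @param seed integer seed.
#' @return list: `r` (numeric vector), `mean`, `median`.
#' @export
random_pair_null <- function(mat, genes, n_pairs,
                             exclude_pairs = NULL, seed = 1L) {
  genes <- intersect(genes, rownames(mat))
  if (length(genes) < 2 && n_pairs > 0) {
    stop("need >= 2 genes to sample random pairs")
  }
  if (n_pairs == 0) {
    return(list(r = numeric(0), mean = NaN, median = NaN))
  }
  banned <- character(0)
  if (!is.null(exclude_pairs)) {
    banned <- c(paste(exclude_pairs$geneA, exclude_pairs$geneB, sep = "\r"),
                paste(exclude_pairs$geneB, exclude_pairs$geneA, sep = "\r"))
  }
  tm <- timepoint_means(mat)
  local_seed(seed, {
    r <- numeric(n_pairs)
    for (i in seq_len(n_pairs)) {
      repeat {
        g <- sample(genes, 2L)
        if (!(paste(g[1], g[2], sep = "\r") %in% banned)) break
      }
      r[i] <- cor(tm[g[1], ], tm[g[2], ])
    }
    list(r = r, mean = mean(r), median = median(r))
  })
}

#' Wilcoxon rank-sum comparison of two correlation samples
#'
#' Exact test for small samples (total n <= 50), normal approximation
#' with continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @return list(statistic, p).
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  exact <- (length(a) + length(b)) <= 50
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Multiset difference of two domain-composition lists
#'
#' Counts how many domain copies differ between two proteins' domain
#' compositions: the size of the multiset symmetric difference (a
#' differing domain type on each side counts once per side; a missing
#' copy counts once).
#'
#' @param a,b character vectors of domain types (repeats allowed), or
#'   single `";"`-separated strings.
#' @return non-negative integer count.
#' @export
domain_difference <- function(a, b) {
  split1 <- function(x) {
    if (length(x) == 1 && grepl(";", x)) x <- strsplit(x, ";")[[1]]
    x[nzchar(x)]
  }
  a <- split1(a); b <- split1(b)
  types <- union(a, b)
  ta <- table(factor(a, levels = types))
  tb <- table(factor(b, levels = types))
  sum(abs(ta - tb))
}

#' Divergence contrasts between correlated and anti-correlated pairs
#'
#' Compares the two pair classes on Pfam-composition difference,
#' percent identity and length difference (Wilcoxon rank-sum), and on
#' duplication-age composition (per-age two-sided Fisher tests of the
#' age frequency in anticorrelated vs correlated pairs).
#'
#' @param pairs classified pair table from [classify_pairs()] with
#'   covariate columns `domainsA`, `domainsB`, `identity_pct`,
#'   `lengthA`, `lengthB`, `age_class`.
#' @return list: `summary` data.frame (per-class means of domain_diff,
#'   identity, length_diff), `tests` (Wilcoxon p per feature),
#'   `age` data.frame (age_class, freq_anticorrelated, freq_correlated,
#'   fisher_p).
#' @export
divergence_contrast <- function(pairs) {
  anti <- pairs[pairs$pair_class == "anticorrelated", , drop = FALSE]
  corr <- pairs[pairs$pair_class == "correlated", , drop = FALSE]
  if (nrow(anti) == 0 || nrow(corr) == 0) {
    stop("both pair classes must be nonempty")
  }
  ddiff <- function(df) mapply(domain_difference, df$domainsA, df$domainsB)
  ldiff <- function(df) abs(df$lengthA - df$lengthB)
  da <- ddiff(anti); dc <- ddiff(corr)
  la <- ldiff(anti); lc <- ldiff(corr)
  summary <- data.frame(
    pair_class = c("anticorrelated", "correlated"),
    n = c(nrow(anti), nrow(corr)),
    mean_domain_diff = c(mean(da), mean(dc)),
    mean_identity_pct = c(mean(anti$identity_pct),
                          mean(corr$identity_pct)),
    mean_length_diff = c(mean(la), mean(lc))
  )
  tests <- list(
    domain_diff_p = compare_distributions(da, dc)$p,
    identity_p = compare_distributions(anti$identity_pct,
                                       corr$identity_pct)$p,
    length_diff_p = compare_distributions(la, lc)$p
  )
  ages <- sort(unique(pairs$age_class))
  age <- do.call(rbind, lapply(ages, function(ag) {
    tab <- matrix(c(sum(anti$age_class == ag),
                    sum(anti$age_class != ag),
                    sum(corr$age_class == ag),
                    sum(corr$age_class != ag)), nrow = 2, byrow = TRUE)
    data.frame(age_class = ag,
               freq_anticorrelated = tab[1, 1] / nrow(anti),
               freq_correlated = tab[2, 1] / nrow(corr),
               fisher_p = fisher.test(tab)$p.value)
  }))
  list(summary = summary, tests = tests, age = age)
}
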