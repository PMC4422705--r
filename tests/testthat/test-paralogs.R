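test_that("pair PCC matches the t-transform at N-2 df", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  expect_equal(pair_pcc(x, x)$r, 1)
  expect_equal(pair_pcc(x, -x)$r, -1)
  # r = 0.6 at N = 10 sits just under p = 0.07
  r <- 0.6; n <- 10
  p_oracle <- 2 * pt(-abs(r * sqrt(n - 2) / sqrt(1 - r^2)), n - 2)
  expect_lt(p_oracle, 0.07)
  # construct a pair with r close to 0.6 and compare p to the oracle
  set.seed(2)
  repeat {
    a <- rnorm(10); b <- 0.6 * a + rnorm(10)
    if (abs(cor(a, b) - 0.6) < 0.02) break
  }
  res <- pair_pcc(a, b)
  p_t <- 2 * pt(-abs(res$r * sqrt(8) / sqrt(1 - res$r^2)), 8)
  expect_equal(res$p, p_t, tolerance = 1e-12)
  expect_true(pair_pcc(rep(1, 10), x)$excluded)
})

test_that("pair classification restricts to both-dynamic genes", {
  d <- synth_design(noise_sd = 0.1, seed = 4)
  pt <- synth_paralog_table(60, d, correlated_fraction = 0.5,
                            anticorrelated_fraction = 0.2, seed = 4)
  cls <- data.frame(gene = rownames(pt$matrix),
                    class = "super_dynamic")
  cls$class[1] <- "non_dynamic"   # geneA of pair 1
  out <- classify_pairs(pt$pairs, pt$matrix, cls)
  expect_false(pt$pairs$geneA[1] %in% out$geneA)
  expect_identical(attr(out, "n_excluded"), 1L)
  expect_true(all(out$pcc >= -1 & out$pcc <= 1))
  # strict thresholds
  expect_true(all(out$pair_class[out$pcc >= 0.6] == "correlated"))
  expect_true(all(out$pair_class[abs(out$pcc) < 0.6] == "neither"))
  # threshold monotonicity: higher cutoff, never more members
  out8 <- classify_pairs(pt$pairs, pt$matrix, cls, r_threshold = 0.8)
  expect_lte(sum(out8$pair_class == "correlated"),
             sum(out$pair_class == "correlated"))
  expect_lte(sum(out8$pair_class == "anticorrelated"),
             sum(out$pair_class == "anticorrelated"))
})

test_that("random-pair null is centered at zero and seeded", {
  d <- synth_design(n_genes = 500, fraction_dynamic = 1,
                    fraction_super_dynamic = 0.3, seed = 6)
  m <- gene_matrix(synth_expression(d))
  nn <- random_pair_null(m, rownames(m), 1000, seed = 3)
  expect_lt(abs(nn$mean), 0.1)
  expect_lt(abs(nn$mean), 3 / sqrt(1000))
  expect_identical(random_pair_null(m, rownames(m), 50, seed = 3),
                   random_pair_null(m, rownames(m), 50, seed = 3))
  expect_length(random_pair_null(m, rownames(m), 0)$r, 0)
  expect_error(random_pair_null(m, rownames(m)[1], 5), ">= 2 genes")
})

test_that("annotated paralog pairs are excluded from the null", {
  d <- synth_design(n_genes = 4, fraction_dynamic = 1,
                    fraction_super_dynamic = 1, seed = 2)
  m <- gene_matrix(synth_expression(d))
  g <- rownames(m)
  # ban all pairs except (g1, g2)
  allp <- t(combn(g, 2))
  keep <- allp[, 1] == g[1] & allp[, 2] == g[2]
  excl <- data.frame(geneA = allp[!keep, 1], geneB = allp[!keep, 2])
  nn <- random_pair_null(m, g, 20, exclude_pairs = excl, seed = 1)
  tm <- timepoint_means(m)
  only_allowed_r <- cor(tm[g[1], ], tm[g[2], ])
  expect_equal(nn$r, rep(only_allowed_r, 20))
})

test_that("Wilcoxon comparison uses the exact small-sample test", {
  # enumeration oracle: most extreme ranking of 3 vs 3 has p = 0.1
  res <- compare_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)
  expect_equal(compare_distributions(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # shift invariance of ranks
  set.seed(5)
  a <- rnorm(30); b <- rnorm(35, 0.5)
  expect_equal(compare_distributions(a, b)$p,
               compare_distributions(a + 10, b + 10)$p)
  expect_error(compare_distributions(numeric(0), 1), "nonempty")
})

test_that("domain difference is the multiset symmetric difference", {
  expect_identical(domain_difference(c("A", "B"), c("A", "B")), 0L)
  expect_identical(domain_difference(c("A", "B"), c("A", "C")), 2L)
  expect_identical(domain_difference(c("A", "A", "B"), c("A", "B")), 1L)
  expect_identical(domain_difference("PF1;PF2", "PF2;PF3"), 2L)
  expect_identical(domain_difference(character(0), c("A")), 1L)
})

test_that("divergence contrasts reproduce the planted direction", {
  d <- synth_design(noise_sd = 0.15, seed = 10)
  pt <- synth_paralog_table(400, d, correlated_fraction = 0.45,
                            anticorrelated_fraction = 0.25, seed = 10)
  cls <- data.frame(gene = rownames(pt$matrix),
                    class = "super_dynamic")
  pairs <- classify_pairs(pt$pairs, pt$matrix, cls)
  dc <- divergence_contrast(pairs)
  s <- dc$summary
  anti <- s[s$pair_class == "anticorrelated", ]
  corr <- s[s$pair_class == "correlated", ]
  expect_gt(anti$mean_domain_diff, corr$mean_domain_diff)
  expect_lt(anti$mean_identity_pct, corr$mean_identity_pct)
  expect_gt(anti$mean_length_diff, corr$mean_length_diff)
  # age frequencies per class sum to one
  expect_equal(sum(dc$age$freq_anticorrelated), 1)
  expect_equal(sum(dc$age$freq_correlated), 1)
  # anticorrelated pairs are enriched for old duplications
  old <- dc$age[dc$age$age_class == "old", ]
  expect_gt(old$freq_anticorrelated, old$freq_correlated)
})

test_that("per-age Fisher test matches the hypergeometric oracle", {
  # [10,0;0,10]: p = 2 / choose(20,10)
  tab <- matrix(c(10, 0, 0, 10), nrow = 2)
  expect_equal(fisher.test(tab)$p.value, 2 / choose(20, 10),
               tolerance = 1e-9)
  # identical compositions give p = 1 for every age
  pairs <- data.frame(
    pair_class = rep(c("anticorrelated", "correlated"), each = 10),
    age_class = rep(c("old", "recent"), 10),
    domainsA = "A", domainsB = "A", identity_pct = 50,
    lengthA = 100L, lengthB = 120L)
  dc <- divergence_contrast(pairs)
  expect_true(all(dc$age$fisher_p == 1))
})
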