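test_that("catalog parsing collapses duplicates and flags homo-oligomers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("C1\tTest\tG1;G2;G3",
               "C2\tHomo\tG1;G1",
               "C3\tDup\tG1;G2;G2"), tf)
  cat <- load_complex_catalog(tf)
  expect_identical(cat$size, c(3L, 1L, 2L))
  expect_identical(cat$n_records, c(3L, 2L, 3L))
  expect_identical(cat$homo_oligomer, c(FALSE, TRUE, FALSE))
  writeLines(c("C1\tTest\tG1;G2", "broken line"), tf)
  expect_error(load_complex_catalog(tf), "malformed")
  writeLines("C1\tTest\tG1;;G2", tf)
  expect_error(load_complex_catalog(tf), "empty subunit")
})

test_that("catalog filters drop homo-oligomers, non-expressed, oversized", {
  cat <- load_complex_catalog(data.frame(
    complex_id = c("C1", "C2", "C3", "C4"),
    name = "x",
    subunits = c("G1;G2", "G1;G1", "NX1;NX2",
                 paste(sprintf("G%d", 1:25), collapse = ";"))))
  expressed <- sprintf("G%d", 1:25)
  f <- filter_complex_catalog(cat, expressed)
  expect_identical(f$report$n_homo_oligomer, 1L)
  expect_identical(f$report$n_fully_non_expressed, 1L)
  expect_identical(f$report$n_survivors, 2L)
  # additivity of the report
  with(f$report, expect_identical(
    n_input, n_homo_oligomer + n_fully_non_expressed +
      n_size_excluded + n_survivors))
  # structural stage size gate: < 20 members survive
  fs <- filter_complex_catalog(cat, expressed, size_limit = 20)
  expect_identical(fs$report$n_size_excluded, 1L)
  expect_identical(fs$catalog$complex_id, "C1")
  expect_error(filter_complex_catalog(cat, character(0)), "empty")
})

test_that("composition classification follows the di-chromatic rules", {
  expect_identical(
    classify_composition(c("non_dynamic", "non_dynamic")),
    "all_non_dynamic")
  expect_identical(
    classify_composition(c("non_dynamic", "super_dynamic")),
    "di_chromatic")
  expect_identical(
    classify_composition(c("dynamic", "super_dynamic")),
    "all_dynamic")
  expect_true(is.na(
    classify_composition(c("dynamic", "unresolved"))))
  expect_identical(
    classify_composition(c("dynamic", "unresolved"),
                         mode = "unresolved_as_nondynamic"),
    "di_chromatic")
  expect_error(classify_composition(c("dynamic", "mystery")),
               "unknown")
  # single-class membership can never be di-chromatic
  for (cl in c("non_dynamic", "dynamic", "super_dynamic")) {
    expect_false(identical(classify_composition(rep(cl, 4)),
                           "di_chromatic"))
  }
})

test_that("composition distribution sums to one and rounds as reported", {
  cat <- data.frame(complex_id = sprintf("C%d", 1:20),
                    composition = c(rep("di_chromatic", 11),
                                    rep("all_non_dynamic", 4),
                                    rep("all_dynamic", 5)))
  dist <- composition_distribution(cat)
  expect_equal(sum(dist$fraction), 1)
  expect_identical(dist$percent[dist$composition == "di_chromatic"], 55)
  expect_identical(dist$percent[dist$composition == "all_non_dynamic"],
                   20)
  expect_identical(dist$percent[dist$composition == "all_dynamic"], 25)
})

test_that("generated catalogs classify back to their planted classes", {
  u <- fixture_universe(n_genes = 400, seed = 31)
  cc <- synth_complex_catalog(u$classes[, c("gene", "class")],
                              n_complexes = 40, seed = 31)
  cat <- load_complex_catalog(cc$catalog)
  f <- filter_complex_catalog(cat, u$classes$gene)
  cl <- classify_complexes(f$catalog, u$classes,
                           mode = "unresolved_as_nondynamic")
  planted <- setNames(cc$truth$planted, cc$truth$complex_id)
  called <- setNames(cl$composition, cl$complex_id)
  common <- names(called)[planted[names(called)] %in%
                            c("all_dynamic", "di_chromatic")]
  # planted all-dynamic / di-chromatic labels are recovered whenever
  # the classifier's own gene classes agree with the generator's
  expect_gt(mean(called[common] == planted[common]), 0.8)
})

test_that("co-regulation permutation test behaves as an estimator", {
  u <- fixture_universe(n_genes = 200, seed = 12)
  genes <- rownames(u$matrix)
  # identical profiles: statistic 1, smallest attainable p
  m2 <- u$matrix
  m2["G00002", ] <- m2["G00001", ]
  m2["G00003", ] <- m2["G00001", ]
  res <- coregulation_test(c("G00001", "G00002", "G00003"), m2,
                           n_permutations = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p, 1 / 100)
  # p never below 1/(B+1)
  res2 <- coregulation_test(genes[1:4], u$matrix,
                            n_permutations = 49, seed = 2)
  expect_gte(res2$p, 1 / 50)
  expect_true(coregulation_test("G00001", u$matrix)$skipped)
})

test_that("null-complex co-regulation p-values are roughly uniform", {
  d <- synth_design(n_genes = 300, fraction_dynamic = 0,
                    fraction_super_dynamic = 0, seed = 77)
  m <- gene_matrix(synth_expression(d))
  ps <- vapply(1:120, function(i) {
    members <- withr::with_seed(1000 + i, sample(rownames(m), 4))
    coregulation_test(members, m, n_permutations = 99,
                      seed = i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("network export produces co-membership edges", {
  cat <- data.frame(complex_id = c("C1", "C2"), name = "x",
                    subunits = c("G1;G2;G3", "G1;G4"))
  cls <- data.frame(gene = c("G1", "G2", "G3"),
                    class = c("dynamic", "non_dynamic", "dynamic"))
  net <- export_network(cat, cls,
                        assignments = c(G1 = 2L),
                        fold_changes = c(G1 = 4))
  expect_identical(nrow(net$edges), 4L)  # choose(3,2) + choose(2,2)
  expect_identical(sum(net$nodes$gene == "G1"), 1L)
  expect_identical(net$nodes$class[net$nodes$gene == "G4"],
                   "unresolved")
  expect_equal(net$nodes$abs_log2_fold[net$nodes$gene == "G1"], 2)
  # empty catalog
  net0 <- export_network(cat[0, ], cls)
  expect_identical(nrow(net0$edges), 0L)
  expect_identical(nrow(net0$nodes), 0L)
})
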