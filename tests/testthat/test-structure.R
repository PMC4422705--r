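test_that("interface detection matches a brute-force distance oracle", {
  a <- strand_domain(10, x = 0)
  b_far <- strand_domain(10, x = 50, protein = "q")
  iface <- find_interface(a, b_far, cutoff = 5)
  expect_length(iface$residuesA, 0)
  expect_length(iface$residuesB, 0)
  # identical superimposed copies: every residue interfacial
  iface2 <- find_interface(a, a, cutoff = 5)
  expect_identical(iface2$residuesA, 1:10)
  # staggered strands: brute-force oracle over all atom pairs
  b_mid <- strand_domain(10, x = 4, z0 = 3.5 * 7, protein = "q")
  oracle <- function(dA, dB, cutoff) {
    A <- as.matrix(dA$atoms[, c("x", "y", "z")])
    B <- as.matrix(dB$atoms[, c("x", "y", "z")])
    inA <- inB <- logical(0)
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      if (sqrt(sum((A[i, ] - B[j, ])^2)) <= cutoff) {
        inA <- c(inA, dA$atoms$resno[i]); inB <- c(inB, dB$atoms$resno[j])
      }
    }
    list(residuesA = sort(unique(inA)), residuesB = sort(unique(inB)))
  }
  expect_identical(find_interface(a, b_mid, 5), oracle(a, b_mid, 5))
})

test_that("Kabsch superposition recovers planted rigid transforms", {
  dom <- toy_helix_domain(12)
  # identity
  fit0 <- superpose_domains(dom, dom)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  # pure translation
  domt <- transform_domain(dom, diag(3), c(3, -2, 7))
  fitt <- superpose_domains(dom, domt)
  expect_equal(fitt$rmsd, 0, tolerance = 1e-10)
  expect_equal(fitt$translation, c(-3, 2, -7), tolerance = 1e-10)
  # 90 degree rotation about z plus coordinate noise
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  set.seed(9)
  domr <- transform_domain(dom, R90, c(1, 2, 3))
  domr$atoms[, c("x", "y", "z")] <-
    domr$atoms[, c("x", "y", "z")] + rnorm(nrow(domr$atoms) * 3, 0, 0.1)
  fitr <- superpose_domains(dom, domr)
  # 3-D rmsd of isotropic per-coordinate noise sd 0.1 is sqrt(3)*0.1
  expect_equal(fitr$rmsd, sqrt(3) * 0.1, tolerance = 0.15)
  # recovered rotation within ~1 degree of the planted inverse
  ang <- acos((sum(diag(fitr$rotation %*% R90)) - 1) / 2) * 180 / pi
  expect_lt(ang, 1.5)
  expect_error(superpose_domains(toy_helix_domain(3),
                                 toy_helix_domain(4)),
               "residue numbering")
})

test_that("clash fraction counts interface residues against the oracle", {
  a <- strand_domain(10, x = 0)
  far <- strand_domain(10, x = 30, protein = "q")
  expect_equal(clash_fraction(a, far, 1:10, 1:10), 0)
  # exact copy: total overlap
  expect_equal(clash_fraction(a, a, 1:10, 1:10), 1)
  # boundary: exactly 3 of 20 union residues clash -> 0.15 -> XOR
  b <- strand_domain(10, x = 30, protein = "q")
  b$atoms[b$atoms$resno <= 3, c("x", "y", "z")] <-
    a$atoms[a$atoms$resno <= 3, c("x", "y", "z")]
  frac <- clash_fraction(a, b, interfaceA = 1:10, interfaceB = 1:10,
                         clash_cutoff = 2.5)
  expect_equal(frac, 6 / 20)   # 3 residues clash on each side
  b2 <- strand_domain(10, x = 30, protein = "q")
  b2$atoms[b2$atoms$resno <= 3, c("x", "y", "z")] <-
    a$atoms[a$atoms$resno %in% 4:6, c("x", "y", "z")]
  frac2 <- clash_fraction(a, b2, interfaceA = 4:6, interfaceB = 1:10,
                          clash_cutoff = 2.5)
  expect_equal(frac2, 6 / 13)
  # empty union interface: undefined
  expect_true(is.na(clash_fraction(a, far, integer(0), integer(0))))
})

test_that("compatibility call is XOR at and above the 15% boundary", {
  expect_identical(call_compatibility(0), "AND")
  expect_identical(call_compatibility(0.5), "XOR")
  expect_identical(call_compatibility(0.15), "XOR")  # inclusive
  expect_identical(call_compatibility(0.1499), "AND")
})

test_that("toy triplet calls match geometric ground truth", {
  # zero jitter: 100% agreement over seeds and both placements
  for (s in 1:10) {
    for (mode in c("disjoint", "overlapping")) {
      tr <- synth_toy_triplet(mode, jitter_sd = 0, seed = s)
      res <- call_triplet(tr$modelA, tr$modelB)
      expect_identical(res$call, tr$expected_call)
      expect_lt(res$rmsd, 1e-8)
    }
  }
  # small jitter: >= 95% agreement over 100 seeded triplets
  agree <- vapply(1:100, function(s) {
    mode <- if (s %% 2 == 0) "disjoint" else "overlapping"
    tr <- synth_toy_triplet(mode, jitter_sd = 0.3, seed = s)
    identical(call_triplet(tr$modelA, tr$modelB)$call,
              tr$expected_call)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("clash fraction and call are frame invariant", {
  tr <- synth_toy_triplet("overlapping", jitter_sd = 0.2, seed = 3)
  base <- call_triplet(tr$modelA, tr$modelB)
  R <- withr::with_seed(4, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, byrow = TRUE)
  })
  shift <- c(11, -4, 2)
  mA <- list(hub = transform_domain(tr$modelA$hub, R, shift),
             partner = transform_domain(tr$modelA$partner, R, shift))
  moved <- call_triplet(mA, tr$modelB)
  expect_equal(moved$clash_fraction, base$clash_fraction,
               tolerance = 1e-9)
  expect_identical(moved$call, base$call)
})

test_that("PDB round trip preserves backbone coordinates", {
  dom <- toy_helix_domain(8, protein = "hub", domain_type = "HubDom")
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_domain_pdb(dom, tf)
  back <- read_domain_pdb(tf, protein = "hub", domain_type = "HubDom")
  expect_lt(max(abs(back$atoms$x - dom$atoms$x)), 1e-3)
  expect_lt(max(abs(back$atoms$z - dom$atoms$z)), 1e-3)
  expect_equal(back$atoms$resno, dom$atoms$resno)
  expect_identical(back$atoms$elety, dom$atoms$elety)
})

test_that("triplet enumeration expands hubs into partner pairs", {
  u_classes <- data.frame(
    gene = c("HUB", "P1", "P2", "P3"),
    class = c("non_dynamic", "dynamic", "dynamic", "super_dynamic"))
  make_model <- function(partner, mode, seed) {
    tr <- synth_toy_triplet(mode, seed = seed)
    list(complex_id = "C1", hub = "HUB", partner = partner,
         hub_dom = tr$modelA$hub, partner_dom = tr$modelA$partner,
         accepted = TRUE)
  }
  # three modeled partners on one hub: all on the same face -> 3 calls
  models <- list(make_model("P1", "overlapping", 1),
                 make_model("P2", "overlapping", 2),
                 make_model("P3", "overlapping", 3))
  res <- enumerate_triplets(models, u_classes)
  expect_identical(nrow(res$calls), 3L)  # choose(3, 2)
  expect_true(all(res$calls$call == "XOR"))
  expect_true(all(res$calls$hub_class == "non_dynamic"))
  # rejected template: triplet skipped and counted
  models[[2]]$accepted <- FALSE
  res2 <- enumerate_triplets(models, u_classes)
  expect_identical(nrow(res2$calls), 1L)
  expect_identical(res2$n_skipped, 2L)
  # homo-oligomeric pairing (partner == hub) excluded
  models3 <- list(make_model("HUB", "overlapping", 1),
                  make_model("P1", "overlapping", 2))
  res3 <- enumerate_triplets(models3, u_classes)
  expect_identical(nrow(res3$calls), 0L)
})

test_that("template scoring standardizes against shuffled nulls", {
  tmpl <- "LIVLKAERAGWQH"
  res <- template_zscore(tmpl, tmpl, n_shuffles = 200, seed = 1)
  expect_gt(res$z, 2.33)  # self-match dominates shuffles
  expect_false(res$rejected_degenerate)
  # degenerate: single-letter sequence has zero null spread
  resd <- template_zscore("AAAA", "AAAA", n_shuffles = 100, seed = 1)
  expect_true(resd$rejected_degenerate)
  expect_error(template_zscore(tmpl, tmpl, n_shuffles = 10), ">= 100")
  # reproducible under a seed, stochastic across seeds
  r1 <- template_zscore("LIVLKAER", "LKVLIAER", 200, seed = 5)
  r2 <- template_zscore("LIVLKAER", "LKVLIAER", 200, seed = 5)
  r3 <- template_zscore("LIVLKAER", "LKVLIAER", 200, seed = 6)
  expect_identical(r1, r2)
  expect_false(identical(r1$z, r3$z))
  # selection: weak candidates fall back to best-of-candidates
  sel <- select_template(c("WWWWWWWW", tmpl), tmpl,
                         n_shuffles = 200, seed = 2)
  expect_true(sel$accepted[2])
  expect_true(sel$best[2])
})

test_that("run averaging reports the mean XOR likelihood", {
  calls <- c("XOR", "XOR", "AND", "XOR", "AND")
  i <- 0
  res <- average_runs(function(seed) {
    i <<- i + 1
    calls[i]
  }, n_runs = 5, seed = 1)
  expect_equal(res$xor_likelihood, 0.6)
})
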