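test_that("Fisher's exact test reproduces known and degenerate cases", {
  expect_equal(signif(fisher_count_test(30, 1986, 1, 732), 2), 0.0016)
  expect_equal(fisher_count_test(5, 50, 5, 50), 1)       # equal proportions
  expect_equal(fisher_count_test(0, 10, 0, 10), 1)       # empty margin
  expect_equal(fisher_count_test(5, 10, 0, 10), fisher_oracle(5, 10, 0, 10),
               tolerance = 1e-12)
  expect_error(fisher_count_test(-1, 10, 0, 10), "non-negative")
  expect_error(fisher_count_test(11, 10, 0, 10), "exceeds")
  expect_error(fisher_count_test(0, 0, 0, 0), "zero")
})

test_that("Fisher p agrees with stats::fisher.test and is swap-symmetric", {
  withr::with_seed(42, {
    for (i in 1:50) {
      n1 <- sample(1:60, 1); n2 <- sample(1:60, 1)
      k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
      mine <- fisher_count_test(k1, n1, k2, n2)
      ref <- stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))$p.value
      expect_equal(mine, ref, tolerance = 1e-9)
      expect_equal(mine, fisher_count_test(k2, n2, k1, n1), tolerance = 1e-12)
    }
  })
})

test_that("identical group frequency vectors give fold 1 and t = 0", {
  f <- default_baseline_pfm(9)
  panel <- panel_from_freqs(list(f, f), list(f, f), n = 100L)
  e <- group_enrichment(panel, position = 9)
  expect_equal(e$fold_c2_c1, rep(1, 20))
  expect_equal(e$t_stat, rep(0, 20))
  expect_false(any(e$significant))
})

test_that("swapping group labels inverts the fold and preserves p-values", {
  spec <- generator_spec(n_c1 = 3, n_c2 = 3, peptides_per_allotype = 400,
                         seed = 9)
  panel <- panel_pfms(sample_peptide_panel(spec)$sets)
  flip <- lapply(panel, function(e) {
    r <- if (e$allotype$group == "C1") c("N", "K") else c("S", "N")
    list(allotype = allotype_record(e$allotype$name, r[1], r[2]), pfm = e$pfm)
  })
  a <- group_enrichment(panel, position = 8)
  b <- group_enrichment(flip, position = 8)
  expect_equal(b$fold_c2_c1, 1 / a$fold_c2_c1, tolerance = 1e-12)
  expect_equal(b$p_student, a$p_student, tolerance = 1e-12)
  expect_equal(b$p_welch, a$p_welch, tolerance = 1e-12)
})

test_that("group enrichment matches stats::t.test on non-degenerate cells", {
  spec <- generator_spec(n_c1 = 3, n_c2 = 3, peptides_per_allotype = 400,
                         seed = 12)
  panel <- panel_pfms(sample_peptide_panel(spec)$sets)
  e <- group_enrichment(panel, position = 9)
  pct <- sapply(panel, function(x) 100 * x$pfm$freq[, 9])
  g <- vapply(panel, function(x) x$allotype$group, character(1))
  for (aa in c("L", "V", "I", "F")) {
    ref_s <- stats::t.test(pct[aa, g == "C2"], pct[aa, g == "C1"],
                           var.equal = TRUE)$p.value
    ref_w <- stats::t.test(pct[aa, g == "C2"], pct[aa, g == "C1"])$p.value
    expect_equal(e$p_student[e$aa == aa], ref_s, tolerance = 1e-12)
    expect_equal(e$p_welch[e$aa == aa], ref_w, tolerance = 1e-12)
  }
})

test_that("a planted 2.5x C2 excess of Lys at p8 is flagged and recovered", {
  spec <- generator_spec(n_c1 = 6, n_c2 = 6, peptides_per_allotype = 1000,
                         size_coef = 0,
                         pOmega1_multipliers = list(C2 = c(K = 2.5)),
                         seed = 17)
  panel <- sample_peptide_panel(spec)
  e <- group_enrichment(panel_pfms(panel$sets), position = 8)
  kr <- e[e$aa == "K", ]
  expect_true(kr$significant)
  # effective planted fold after renormalisation of the other 19 residues
  truth_fold <- panel$truth$C2["K", 8] / panel$truth$C1["K", 8]
  expect_lt(abs(kr$fold_c2_c1 - truth_fold) / truth_fold, 0.2)
  expect_lt(abs(truth_fold - 2.5) / 2.5, 0.2)
})

test_that("HYBRID allotypes are excluded and small groups rejected", {
  f <- default_baseline_pfm(9)
  panel <- panel_from_freqs(list(f, f), list(f, f), n = 50L)
  hyb <- list(allotype = allotype_record("C*05:01-N77S", "S", "K"),
              pfm = hlacpep:::pfm_from_freq(f, 50L))
  expect_warning(group_enrichment(c(panel, list(hyb)), 9), "HYBRID")
  expect_error(group_enrichment(panel[c(1, 3, 4)], 9), ">= 2")
})

test_that("position-wise Pearson correlation matches the covariance formula", {
  f <- default_baseline_pfm(9)
  pa <- hlacpep:::pfm_from_freq(f)
  expect_equal(positionwise_correlation(pa, pa, 2), 1)

  v1 <- c(0.5, 0.5, rep(0, 18)); v2 <- c(0, 0, 0.5, 0.5, rep(0, 16))
  m1 <- f; m1[, 5] <- v1
  m2 <- f; m2[, 5] <- v2
  r <- positionwise_correlation(hlacpep:::pfm_from_freq(m1),
                                hlacpep:::pfm_from_freq(m2), 5)
  # direct covariance computation on the two 20-vectors
  hand <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
    sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
  expect_equal(r, hand, tolerance = 1e-12)

  uni <- f; uni[, 5] <- rep(0.05, 20)
  expect_error(positionwise_correlation(hlacpep:::pfm_from_freq(uni), pa, 5),
               "zero variance")
})

test_that("Pearson r is invariant under affine rescaling of either vector", {
  f1 <- default_baseline_pfm(9)
  withr::with_seed(3, {
    f2 <- f1 * matrix(stats::runif(180, 0.5, 2), 20)
  })
  p1 <- hlacpep:::pfm_from_freq(f1)
  p2 <- hlacpep:::pfm_from_freq(f2)
  r0 <- positionwise_correlation(p1, p2, 4)
  f1b <- f1; f1b[, 4] <- 0.002 + 0.3 * f1[, 4]   # affine map, then renorm
  r1 <- positionwise_correlation(hlacpep:::pfm_from_freq(f1b), p2, 4)
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("volume correlation is exact on constructed linear enrichment", {
  vol <- aa_volumes()
  e <- data.frame(aa = names(vol), fold_c2_c1 = 2^(0.01 * vol - 1),
                  log2_fold = 0.01 * vol - 1)
  class(e) <- c("enrichment_table", "data.frame")
  vc <- volume_correlation(e)
  expect_equal(vc$r, 1, tolerance = 1e-12)
  expect_identical(names(vc$table), c("aa", "volume", "log2_fold"))
  expect_error(volume_correlation(e, vol[-1]), "lacks amino acid")
})

test_that("permuted (volume-independent) enrichment rarely correlates strongly", {
  vol <- aa_volumes()
  base <- 0.01 * unname(vol) - 1
  hits <- withr::with_seed(99, {
    sum(vapply(1:100, function(i) {
      e <- data.frame(aa = names(vol), fold_c2_c1 = 2^sample(base),
                      log2_fold = sample(base))
      class(e) <- c("enrichment_table", "data.frame")
      abs(volume_correlation(e)$r) < 0.5
    }, logical(1)))
  })
  expect_gte(hits, 95)
})

test_that("size-linked generation yields a positive volume correlation at p8", {
  spec <- generator_spec(n_c1 = 4, n_c2 = 4, peptides_per_allotype = 1000,
                         seed = 23)  # default size_coef favours large aa in C2
  e <- group_enrichment(panel_pfms(sample_peptide_panel(spec)$sets), 8)
  expect_gt(volume_correlation(e)$r, 0)
})
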