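test_that("LM renormalisation recovers injected loading offsets", {
  set.seed(1)
  m <- matrix(rnorm(200 * 6, 6, 0.5), 200, 6,
              dimnames = list(paste0("p", 1:200), paste0("s", 1:6)))
  # pre-equalised matrix: offsets ~ 0
  r0 <- renormalize_lm(m)
  expect_lt(max(abs(r0$factors)), 0.05)
  # known +0.3 spike on sample 3 is removed (offsets sum to zero, so the
  # spike is recovered relative to the others)
  m2 <- m; m2[, 3] <- m2[, 3] + 0.3
  r <- renormalize_lm(m2)
  expect_lt(abs(r$factors[[3]] - mean(r$factors[-3]) - 0.3), 0.03)
  # row permutation leaves the result unchanged
  perm <- sample(nrow(m2))
  rp <- renormalize_lm(m2[perm, ])
  expect_equal(rp$factors, r$factors, tolerance = 1e-8)
  # idempotence
  r2 <- renormalize_lm(r$matrix)
  expect_lt(max(abs(r2$factors)), 1e-6)
  # mostly-missing sample excluded with a warning
  m3 <- m; m3[1:195, 2] <- NA
  expect_warning(renormalize_lm(m3), "excluded")
})

test_that("batch correction removes injected batch shifts", {
  set.seed(2)
  m <- matrix(rnorm(300 * 8, 6, 0.3), 300, 8,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:8)))
  batch <- rep(c("b1", "b2"), 4)
  # injected +0.5 shift on batch 2
  m_eff <- m; m_eff[, batch == "b2"] <- m_eff[, batch == "b2"] + 0.5
  corr <- suppressMessages(correct_batch(m_eff, batch))
  sep_before <- mean(m_eff[, batch == "b2"]) - mean(m_eff[, batch == "b1"])
  sep_after <- mean(corr[, batch == "b2"]) - mean(corr[, batch == "b1"])
  expect_lt(abs(sep_after), 0.05 * abs(sep_before))
  # without a batch effect the matrix is nearly unchanged (ComBat still
  # removes noise-level per-row batch deviations)
  corr0 <- suppressMessages(correct_batch(m, batch))
  expect_gt(cor(as.vector(corr0), as.vector(m)), 0.98)
  expect_lt(mean(abs(corr0 - m)), 0.1)
  # two identical batches: adjustment is (near) the identity
  m_dup <- cbind(m[, 1:4], m[, 1:4])
  colnames(m_dup) <- paste0("s", 1:8)
  corr_dup <- suppressMessages(correct_batch(m_dup, batch))
  expect_equal(unname(corr_dup), unname(m_dup), tolerance = 0.02)
  expect_error(correct_batch(m, rep("b1", 8)), "2 batches")
})

test_that("best-flyer quantification respects the unique-peptide rule", {
  samples <- paste0("s", 1:4)
  m <- rbind(pepA1 = c(7, 7.2, 7.1, 7.3),
             pepB1 = c(5, 5.1, 5.2, 5.0),
             pepB2 = c(6, 6.1, 6.2, 6.0),
             pepB3 = c(8, 8.1, 8.2, 8.0),
             pepB4 = c(3, 3.5, 3.2, 3.1))
  colnames(m) <- samples
  mapping <- data.frame(
    peptidoform = rownames(m),
    protein = c("A", "B", "B", "B", "B"),
    unique = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    is_phospho = FALSE)
  q <- quantify_protein_groups(m, mapping)
  # single-peptidoform protein: profile equals that peptidoform
  expect_equal(unname(q$profiles["A", ]), unname(m["pepA1", ]))
  # >= 3 unique: the razor peptide (with a different profile) is ignored
  m_alt <- m; m_alt["pepB4", ] <- c(9, 1, 9, 1)
  q_alt <- quantify_protein_groups(m_alt, mapping)
  expect_equal(q_alt$profiles["B", ], q$profiles["B", ])
  # absolute anchor: profile mean equals the best flyer's mean
  expect_equal(mean(q$profiles["B", ]), mean(m["pepB3", ]))
  # phosphopeptidoforms are excluded
  map2 <- mapping; map2$is_phospho[4] <- TRUE
  q2 <- quantify_protein_groups(m, map2)
  expect_equal(mean(q2$profiles["B", ]), mean(m["pepB2", ]))
})

test_that("differential testing recovers injected fold changes", {
  lfc <- rep(0, 300); lfc[1:20] <- 1
  pp <- proteome_sim_params(n_proteins = 300, true_log2_fc = lfc, seed = 21)
  gen <- gen_peptidoform_matrix(pp)
  m <- suppressMessages(correct_batch(renormalize_lm(gen$matrix)$matrix,
                                      gen$samples$batch, gen$samples$group))
  q <- quantify_protein_groups(m, gen$mapping)
  dt <- differential_test(q$profiles,
                          factor(gen$samples$group, c("control", "case")))
  truth <- gen$truth$regulated[match(dt$protein, gen$truth$protein)]
  expect_gte(mean(dt$regulated[truth]), 0.9)           # power
  # recovered effect sizes near 1 log2 unit (global normalisation absorbs
  # a small share when ~7% of rows are regulated)
  expect_equal(mean(dt$log2_fc[truth]), 1, tolerance = 0.15)
  # BH monotonicity in raw-p rank order
  o <- order(dt$p)
  expect_true(all(diff(dt$adj_p[o]) >= -1e-12))
  expect_true(all(dt$adj_p >= dt$p - 1e-12))
})

test_that("scaling one group of a protein shifts its log2 ratio by one", {
  set.seed(9)
  prof <- matrix(rnorm(50 * 8, 6, 0.1), 50, 8,
                 dimnames = list(paste0("P", 1:50), paste0("s", 1:8)))
  grp <- factor(rep(c("control", "case"), each = 4), c("control", "case"))
  d0 <- differential_test(prof, grp)
  prof2 <- prof
  prof2["P1", grp == "case"] <- prof2["P1", grp == "case"] + log10(2)
  d1 <- differential_test(prof2, grp)
  expect_equal(d1$log2_fc[d1$protein == "P1"] -
                 d0$log2_fc[d0$protein == "P1"], 1, tolerance = 1e-9)
  # scaling both groups changes nothing
  prof3 <- prof
  prof3["P1", ] <- prof3["P1", ] + log10(2)
  d2 <- differential_test(prof3, grp)
  expect_equal(d2$log2_fc[d2$protein == "P1"],
               d0$log2_fc[d0$protein == "P1"], tolerance = 1e-9)
})

test_that("peptidoform generation is deterministic and handles dropout", {
  pp <- proteome_sim_params(n_proteins = 50, missing_rate = 0.1, seed = 5)
  a <- gen_peptidoform_matrix(pp)
  b <- gen_peptidoform_matrix(pp)
  expect_identical(a$matrix, b$matrix)
  expect_true(anyNA(a$matrix))
  expect_true(all(rowSums(!is.na(a$matrix)) > 0))
})
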