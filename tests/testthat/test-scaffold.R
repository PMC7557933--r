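test_that("scaffold detection recovers the published cysteine positions", {
  sl <- detect_scaffold(fixtures[fixtures$id == "SlD26", ])
  expect_equal(sl$cys_positions, c(4L, 15L, 20L, 24L, 35L, 40L, 42L, 46L))
  at <- detect_scaffold(fixtures[fixtures$id == "AtD90", ])
  expect_equal(at$cys_positions, c(3L, 15L, 20L, 24L, 32L, 36L, 45L, 47L))
  # degenerate scaffold: all loops empty
  cc <- detect_scaffold("CCCCCCCC")
  expect_equal(cc$gap_vector, rep(0L, 7))
  expect_equal(cc$n_tail, "")
  expect_equal(cc$c_tail, "")
})

test_that("non-canonical cysteine counts raise an error reporting the count", {
  expect_error(detect_scaffold("ACDEF", id = "few"), "1 cysteine")
  expect_error(detect_scaffold(paste(rep("C", 9), collapse = ""), id = "many"),
               "9 cysteines")
})

test_that("scaffold partition reconstructs the sequence on random inputs", {
  set.seed(101)
  for (i in 1:10000) {
    s <- random_scaffold_seq()
    sc <- detect_scaffold(s)
    rebuilt <- paste0(sc$n_tail, "C", paste(sc$loops, collapse = "C"),
                      "C", sc$c_tail)
    if (rebuilt != s) fail(sprintf("reconstruction failed for %s", s))
    if (!identical(sc$gap_vector, nchar(sc$loops))) fail("gap vector mismatch")
  }
  succeed()
})

test_that("connectivity assignment reproduces the experimentally set pairs", {
  sl <- assign_connectivity(detect_scaffold(fixtures[fixtures$id == "SlD26", ]),
                            "standard")
  expect_equal(sl$pairs,
               cbind(from = c(4L, 15L, 20L, 24L), to = c(46L, 35L, 40L, 42L)))
  at <- assign_connectivity(detect_scaffold(fixtures[fixtures$id == "AtD90", ]),
                            "shifted")
  expect_equal(at$pairs,
               cbind(from = c(3L, 15L, 20L, 24L), to = c(32L, 36L, 45L, 47L)))
  cc <- assign_connectivity(detect_scaffold("CCCCCCCC"), "standard")
  expect_equal(cc$pairs, cbind(from = 1:4, to = c(8L, 5L, 6L, 7L)))
})

test_that("both connectivity patterns are perfect matchings on the cysteines", {
  set.seed(11)
  for (i in 1:50) {
    sc <- detect_scaffold(random_scaffold_seq())
    for (p in c("standard", "shifted")) {
      pairs <- assign_connectivity(sc, p)$pairs
      expect_setequal(as.integer(pairs), sc$cys_positions)
      expect_equal(anyDuplicated(as.integer(pairs)), 0L)
    }
  }
})

test_that("spacing-based pattern prediction is exact on the templates and
          depends only on the gap vector", {
  sl <- detect_scaffold(fixtures[fixtures$id == "SlD26", ])
  at90 <- detect_scaffold(fixtures[fixtures$id == "AtD90", ])
  expect_equal(classify_connectivity_pattern(sl)$label, "standard")
  expect_equal(classify_connectivity_pattern(sl)$distance, 0)
  expect_equal(classify_connectivity_pattern(at90)$label, "shifted")
  expect_equal(classify_connectivity_pattern(at90)$distance, 0)

  # AtD212: brute-force L1 against both templates
  at212 <- detect_scaffold(fixtures[fixtures$id == "AtD212", ])
  expect_equal(at212$gap_vector, c(12L, 4L, 3L, 7L, 3L, 15L, 1L))
  d_std <- sum(abs(at212$gap_vector - sl$gap_vector))
  d_shift <- sum(abs(at212$gap_vector - at90$gap_vector))
  cl <- classify_connectivity_pattern(at212)
  expect_equal(cl$distance, min(d_std, d_shift))
  expect_equal(cl$label, if (d_shift < d_std) "shifted" else "standard")

  # invariance to loop residue content: same gap vector, different residues
  gv <- at212$gap_vector
  s1 <- paste0("A", "C", paste(vapply(gv, function(n)
    paste(rep("G", n), collapse = ""), character(1)), collapse = "C"), "C")
  s2 <- paste0("A", "C", paste(vapply(gv, function(n)
    paste(rep("W", n), collapse = ""), character(1)), collapse = "C"), "C")
  expect_equal(classify_connectivity_pattern(detect_scaffold(s1)),
               classify_connectivity_pattern(detect_scaffold(s2)))
})

test_that("tied template distances are reported as unassigned", {
  templates <- list(list(gap_vector = c(1, 1, 1, 1, 1, 1, 1), label = "standard"),
                    list(gap_vector = c(3, 1, 1, 1, 1, 1, 1), label = "shifted"))
  cl <- classify_connectivity_pattern(c(2, 1, 1, 1, 1, 1, 1), templates)
  expect_equal(cl$label, "unassigned")
  expect_equal(cl$distance, 1)
})

test_that("scaffold_table keeps non-canonical sequences flagged, not dropped", {
  ds <- defensin_set(c("ok", "bad"),
                     c(random_scaffold_seq(), "ACDEFGHIK"))
  tab <- scaffold_table(ds)
  expect_equal(tab$canonical, c(TRUE, FALSE))
  expect_equal(tab$n_cys[2], 1L)
  expect_true(is.na(tab$pattern_label[2]))
})
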