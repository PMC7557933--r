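test_that("anchored alignment pads segments to the loop-wise maxima", {
  aln <- anchored_align(fixtures)
  # brute-force expected width from the four scaffolds
  scs <- lapply(seq_len(nrow(fixtures)),
                function(i) detect_scaffold(fixtures[i, ]))
  seg_len <- sapply(scs, function(sc)
    c(nchar(sc$n_tail), sc$gap_vector, nchar(sc$c_tail)))
  expect_equal(ncol(aln$matrix), sum(apply(seg_len, 1L, max)) + 8L)
  # anchor columns are pure cysteine
  for (col in aln$anchor_columns) {
    expect_true(all(aln$matrix[, col] == "C"))
  }
  # de-gapping any row reproduces its sequence
  for (i in seq_len(nrow(fixtures))) {
    expect_equal(gsub("-", "", paste(aln$matrix[i, ], collapse = "")),
                 fixtures$sequence[i])
  }
  # SlD26 loop 6 is the single residue Y followed by gaps
  sl <- which(aln$ids == "SlD26")
  loop6 <- aln$matrix[sl, aln$segment_spans$loop6]
  expect_equal(loop6[1], "Y")
  expect_true(all(loop6[-1] == "-"))
})

test_that("single sequences and identical pairs align trivially", {
  one <- anchored_align(fixtures[1, ])
  expect_equal(paste(one$matrix[1, ], collapse = ""), fixtures$sequence[1])
  two <- anchored_align(defensin_set(c("a", "b"),
                                     rep(fixtures$sequence[4], 2)))
  expect_equal(two$matrix[1, ], two$matrix[2, ])
  expect_error(anchored_align(defensin_set(c("a", "b"),
                                           c(fixtures$sequence[1], "ADE"))),
               "b")
})

test_that("redundancy reduction matches a brute-force all-pairs filter", {
  set.seed(21)
  gd <- generate_defensins(synthetic_spec(n_sequences = 60,
                                          duplicate_fraction = 0.25), seed = 21)
  aln <- anchored_align(gd$defensins)
  kept <- redundancy_reduce(aln, 0.99)
  expect_equal(kept, brute_redundancy(aln$matrix, aln$ids, 0.99))
  # every planted near-duplicate is removed, all originals retained
  planted <- gd$truth$id[!is.na(gd$truth$duplicate_of)]
  expect_true(all(!planted %in% kept))
  expect_true(all(setdiff(gd$truth$id, planted) %in% kept))
})

test_that("planted duplicate groups collapse to one representative each", {
  set.seed(22)
  k <- 5L
  parents <- replicate(k, random_scaffold_seq())
  seqs <- character(0); ids <- character(0)
  for (g in seq_len(k)) {
    seqs <- c(seqs, parents[g], parents[g], parents[g])  # 100% identity twins
    ids <- c(ids, sprintf("g%d_%d", g, 1:3))
  }
  aln <- anchored_align(defensin_set(ids, seqs))
  expect_length(redundancy_reduce(aln, 0.99), k)
  # threshold 1.0 on all-distinct input drops nothing
  distinct <- anchored_align(defensin_set(sprintf("p%d", 1:k), parents))
  expect_length(redundancy_reduce(distinct, 1.0), k)
})

test_that("numericization localises substitutions and zeroes gaps", {
  aln <- anchored_align(defensin_set(c("a", "b"),
                                     rep(fixtures$sequence[4], 2)))
  feats <- numericize(aln)
  expect_equal(feats[1, ], feats[2, ])
  expect_equal(ncol(feats), 5L * ncol(aln$matrix))

  mutated <- sub("^AKH", "AKY", fixtures$sequence[4])
  aln2 <- anchored_align(defensin_set(c("a", "b"),
                                      c(fixtures$sequence[4], mutated)))
  f2 <- numericize(aln2)
  diffcols <- which(f2[1, ] != f2[2, ])
  expect_true(all(diffcols %in% (5L * 2L + 1L):(5L * 3L)))  # column 3 only
})

test_that("classical MDS embeds exact distance matrices", {
  # 3-4-5 right triangle from its distance matrix
  d <- stats::dist(rbind(c(0, 0), c(3, 0), c(0, 4)))
  sp <- project_mds(d, d = 2)
  expect_equal(as.vector(stats::dist(sp$coords)), as.vector(d),
               tolerance = 1e-9)
  # random exactly-embeddable point sets, recovered to 1e-6
  set.seed(31)
  for (i in 1:5) {
    pts <- matrix(rnorm(30 * 3), ncol = 3)
    sp <- project_mds(stats::dist(pts), d = 3)
    expect_lt(max(abs(stats::dist(sp$coords) - stats::dist(pts))), 1e-6)
  }
})

test_that("MDS output is deterministic, sign-fixed, and duplicate-preserving", {
  aln <- anchored_align(fixtures)
  sp <- project_mds(numericize(aln))
  expect_equal(sp$coords, project_mds(numericize(aln))$coords)
  for (j in seq_len(ncol(sp$coords))) {
    expect_gt(sp$coords[which.max(abs(sp$coords[, j])), j], 0)
  }
  expect_true(all(diff(sp$eigenvalues) <= 0))
  dup <- defensin_set(c("a", "b", "c", "d"),
                      c(fixtures$sequence[1], fixtures$sequence[1],
                        fixtures$sequence[3], fixtures$sequence[4]))
  spd <- project_mds(numericize(anchored_align(dup)))
  expect_equal(spd$coords["a", ], spd$coords["b", ], ignore_attr = TRUE)
})

test_that("collinear points trigger dimension reduction with a warning", {
  d <- stats::dist(cbind(c(0, 1, 2, 3), 0))
  expect_warning(sp <- project_mds(d, d = 3), "positive eigenvalues")
  expect_lt(ncol(sp$coords), 3L)
})

test_that("nearest neighbours agree with an exhaustive distance sort", {
  set.seed(41)
  coords <- matrix(rnorm(50 * 2), ncol = 2)
  rownames(coords) <- sprintf("p%02d", 1:50)
  sp <- project_mds(stats::dist(coords), d = 2)
  nn <- nearest_neighbours(sp, "p07", k = 10)
  dq <- sqrt(colSums((t(sp$coords) - sp$coords["p07", ])^2))
  ord <- setdiff(names(sort(dq)), "p07")
  expect_equal(nn$id, ord[1:10])
  # k = n - 1 returns everything else; planted twin ranks first
  expect_setequal(nearest_neighbours(sp, "p07", k = 49)$id,
                  setdiff(sp$ids, "p07"))
  expect_error(nearest_neighbours(sp, "nope", k = 3), "unknown id")
})

test_that("permuting input order leaves distances and silhouettes unchanged", {
  set.seed(51)
  gd <- generate_defensins(synthetic_spec(n_sequences = 20, n_clusters = 2),
                           seed = 51)
  ds <- gd$defensins
  sp1 <- project_mds(numericize(anchored_align(ds)))
  perm <- sample(nrow(ds))
  ds2 <- ds[perm, ]
  sp2 <- project_mds(numericize(anchored_align(ds2)))
  d1 <- as.matrix(stats::dist(sp1$coords))
  d2 <- as.matrix(stats::dist(sp2$coords))[sp1$ids, sp1$ids]
  expect_equal(d1, d2, tolerance = 1e-8)
  lab <- gd$truth$cluster
  s1 <- mean(cluster::silhouette(lab, stats::dist(sp1$coords))[, "sil_width"])
  s2 <- mean(cluster::silhouette(lab[perm], stats::dist(sp2$coords))[, "sil_width"])
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("well-separated synthetic clusters embed with clean silhouettes", {
  gd <- generate_defensins(synthetic_spec(n_sequences = 30, n_clusters = 2,
                                          within_cluster_mutations = 3),
                           seed = 61)
  sp <- project_mds(numericize(anchored_align(gd$defensins)))
  sil <- cluster::silhouette(gd$truth$cluster, stats::dist(sp$coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("per-loop His profiles average correctly over segments and groups", {
  sl <- fixtures[fixtures$id == "SlD26", ]
  prof <- loop_his_profile(sl)
  expect_equal(prof$loop5, 1)  # loop 5 is "SHGD"
  expect_equal(prof$n, 1L)

  nohis <- defensin_set("x", gsub("H", "G", sl$sequence))
  expect_true(all(loop_his_profile(nohis)[, -(1:2)] == 0))

  # two sequences with loop-6 His counts 2 and 4 -> mean 3
  mk <- function(l6) paste0("AC", "GGC", "GGC", "GGC", "GGC", "GGC",
                            l6, "C", "GC")
  ds <- defensin_set(c("a", "b"), c(mk("HHG"), c(mk("HHHH"))))
  expect_equal(loop_his_profile(ds)$loop6, 3)
  expect_error(loop_his_profile(ds, c(a = "g1")), "no group label.*b")
})
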