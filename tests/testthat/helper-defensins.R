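# Shared helpers for the test suite. Oracles here are deliberately
# independent of the package internals they check.

# Random scaffolded sequence built by direct string assembly (independent of
# the package's synthetic generator).
random_scaffold_seq <- function(max_loop = 12L) {
  non_cys <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
  seg <- function(maxlen) {
    len <- sample(0:maxlen, 1L)
    paste(sample(non_cys, len, replace = TRUE), collapse = "")
  }
  paste0(seg(5L), "C",
         paste(vapply(1:7, function(i) seg(max_loop), character(1)),
               collapse = "C"),
         "C", seg(5L))
}

# Brute-force percent identity between two equal-length ungapped sequences.
raw_identity <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  stopifnot(length(a) == length(b))
  mean(a == b)
}

# Brute-force all-pairs greedy redundancy filter on gapped alignment rows,
# written directly from the definition.
brute_redundancy <- function(rows, ids, threshold) {
  ident <- function(r1, r2) {
    shared <- !(r1 == "-" & r2 == "-")
    sum(r1[shared] == r2[shared]) / sum(shared)
  }
  keep <- integer(0)
  for (i in seq_along(ids)) {
    if (!any(vapply(keep, function(j) ident(rows[i, ], rows[j, ]) >= threshold,
                    logical(1)))) {
      keep <- c(keep, i)
    }
  }
  ids[keep]
}

fixtures <- hrdkit::expressed_hrds()
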