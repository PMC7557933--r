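# Atchley's five-factor solution summarising ~500 amino-acid properties:
# I polarity/hydrophobicity, II secondary structure propensity, III molecular
# size, IV codon composition/relative aa composition, V electrostatic charge.
ATCHLEY_FACTORS <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y"),
                  paste0("F", 1:5)))

SEGMENT_NAMES <- c("n_tail", paste0("loop", 1:7), "c_tail")

# Split a scaffold into its nine segments in sequence order.
scaffold_segments <- function(sc) {
  stats::setNames(c(sc$n_tail, as.list(sc$loops), sc$c_tail), SEGMENT_NAMES)
}

#' Cysteine-anchored multiple alignment
#'
#' Aligns scaffold-valid defensins by anchoring the eight conserved cysteines
#' into dedicated columns (the role CysBar plays when constraining a Clustal
#' alignment) and padding each of the nine segments (N-tail, loops 1-7,
#' C-tail) on the right with gaps to the segment-wise maximum length. The
#' construction is deterministic; within-segment residues are not re-aligned.
#'
#' @param ds a [defensin_set]; every sequence must have exactly 8 cysteines.
#' @return An object of class `anchored_alignment`: `ids`, `matrix` (n x L
#'   character matrix with `"-"` gaps), `anchor_columns` (8 pure-cysteine
#'   column indices), and `segment_spans` (named list mapping each segment to
#'   its column indices, possibly empty).
#' @examples
#' anchored_align(expressed_hrds())
#' @export
anchored_align <- function(ds) {
  scaffolds <- vector("list", nrow(ds))
  bad <- character(0)
  for (i in seq_len(nrow(ds))) {
    scaffolds[[i]] <- tryCatch(detect_scaffold(ds$sequence[i], ds$id[i]),
                               error = function(e) NULL)
    if (is.null(scaffolds[[i]])) bad <- c(bad, ds$id[i])
  }
  if (length(bad)) {
    stop("sequences without an 8-cysteine scaffold: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seg_lists <- lapply(scaffolds, scaffold_segments)
  seg_max <- vapply(SEGMENT_NAMES, function(s)
    max(vapply(seg_lists, function(x) nchar(x[[s]]), integer(1))), integer(1))

  width <- sum(seg_max) + 8L
  mat <- matrix("-", nrow = nrow(ds), ncol = width)
  spans <- vector("list", 9L)
  names(spans) <- SEGMENT_NAMES
  anchor_columns <- integer(8L)
  col <- 1L
  for (k in seq_along(SEGMENT_NAMES)) {
    w <- seg_max[[k]]
    spans[[k]] <- if (w > 0L) seq.int(col, col + w - 1L) else integer(0)
    for (i in seq_len(nrow(ds))) {
      seg <- seg_lists[[i]][[k]]
      if (nchar(seg)) {
        mat[i, seq.int(col, col + nchar(seg) - 1L)] <- strsplit(seg, "")[[1]]
      }
    }
    col <- col + w
    if (k <= 8L) {  # cysteine anchor after n_tail and each of loops 1..7
      mat[, col] <- "C"
      anchor_columns[k] <- col
      col <- col + 1L
    }
  }
  structure(list(ids = ds$id, matrix = mat,
                 anchor_columns = anchor_columns, segment_spans = spans),
            class = "anchored_alignment")
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat(sprintf("Cysteine-anchored alignment: %d sequences x %d columns\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  anchors at columns:", paste(x$anchor_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Aligned rows as gapped strings
#' @param a an `anchored_alignment`.
#' @return Named character vector of gapped sequences.
#' @export
alignment_strings <- function(a) {
  stats::setNames(apply(a$matrix, 1L, paste, collapse = ""), a$ids)
}

#' Write an anchored alignment as aligned FASTA
#' @param a an `anchored_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  seqinr::write.fasta(as.list(unname(alignment_strings(a))), names = a$ids,
                      file.out = path, nbchar = 60L, as.string = TRUE)
  invisible(path)
}

# Pairwise identity between two gapped rows: matches among columns that are
# not gap-gap, divided by the number of such columns.
pair_identity <- function(r1, r2) {
  shared <- !(r1 == "-" & r2 == "-")
  if (!any(shared)) return(0)
  sum(r1[shared] == r2[shared]) / sum(shared)
}

#' Greedy redundancy reduction on an anchored alignment
#'
#' Scans sequences in input order and drops any whose identity to an
#' already-retained sequence reaches the threshold; the survivors are the
#' cluster representatives. Identity is computed over alignment columns where
#' at least one of the pair is non-gap.
#'
#' @param a an `anchored_alignment`.
#' @param threshold identity fraction in (0, 1]; the canonical filter removes
#'   sequences with >= 99% identity (`threshold = 0.99`).
#' @return Character vector of retained ids, in input order.
#' @export
redundancy_reduce <- function(a, threshold = 0.99) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- integer(0)
  for (i in seq_along(a$ids)) {
    dup <- FALSE
    for (j in keep) {
      if (pair_identity(a$matrix[i, ], a$matrix[j, ]) >= threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  a$ids[keep]
}

#' Numericise an anchored alignment
#'
#' Encodes each alignment cell as the five Atchley factor scores of its
#' residue (polarity, secondary structure, size, codon composition, charge);
#' gap cells contribute a zero vector. Columns are ordered alignment column by
#' alignment column, factor index fastest.
#'
#' @param a an `anchored_alignment`.
#' @return Numeric matrix, n x 5L, rownames the sequence ids.
#' @export
numericize <- function(a) {
  n <- nrow(a$matrix); L <- ncol(a$matrix)
  out <- matrix(0, nrow = n, ncol = 5L * L)
  for (j in seq_len(L)) {
    resj <- a$matrix[, j]
    nong <- resj != "-"
    if (any(nong)) {
      out[nong, (5L * (j - 1L) + 1L):(5L * j)] <- ATCHLEY_FACTORS[resj[nong], , drop = FALSE]
    }
  }
  rownames(out) <- a$ids
  out
}

#' Project sequences into a low-dimensional sequence space by classical MDS
#'
#' Classical (Torgerson) multidimensional scaling of the Euclidean distances
#' between feature vectors: the squared-distance matrix is double-centred and
#' eigendecomposed, and coordinates are the top-`d` eigenvectors scaled by the
#' square roots of their eigenvalues. Axis signs are fixed so the coordinate
#' of largest magnitude on each axis is positive, making the embedding fully
#' deterministic. If fewer than `d` positive eigenvalues exist, the dimension
#' is reduced with a warning.
#'
#' @param features numeric matrix (rows = sequences, rownames = ids), e.g.
#'   from [numericize()]; or a `dist` object.
#' @param d target dimension (default 2); must satisfy `d <= n - 1`.
#' @return An object of class `sequence_space`: `ids`, `coords` (n x d),
#'   `eigenvalues` (all non-negative retained eigenvalues, non-increasing),
#'   `stress` (relative embedding error), and `distance_metadata`.
#' @examples
#' sp <- project_mds(numericize(anchored_align(expressed_hrds())))
#' sp$coords
#' @export
project_mds <- function(features, d = 2L) {
  if (inherits(features, "dist")) {
    dmat <- features
    ids <- attr(features, "Labels")
    meta <- "precomputed distances; classical MDS"
  } else {
    dmat <- stats::dist(features)
    ids <- rownames(features)
    meta <- "Euclidean distance on per-column Atchley-factor encoding (gaps = 0); classical MDS"
  }
  n <- attr(dmat, "Size")
  stopifnot(n >= 3L)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- as.integer(d)
  stopifnot(d >= 1L, d <= n - 1L)
  fit <- suppressWarnings(stats::cmdscale(dmat, k = d, eig = TRUE))
  pos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
  if (pos < d) {
    warning(sprintf("only %d positive eigenvalues; reducing dimension from %d",
                    pos, d))
    d <- max(1L, pos)
  }
  coords <- fit$points[, seq_len(d), drop = FALSE]
  # deterministic axis orientation
  for (j in seq_len(ncol(coords))) {
    lead <- which.max(abs(coords[, j]))
    if (coords[lead, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- ids
  colnames(coords) <- paste0("MDS", seq_len(d))
  dhat <- stats::dist(coords)
  stress <- sqrt(sum((dmat - dhat)^2) / sum(dmat^2))
  structure(list(ids = ids, coords = coords,
                 eigenvalues = fit$eig[seq_len(d)],
                 stress = stress, distance_metadata = meta),
            class = "sequence_space")
}

#' @export
print.sequence_space <- function(x, ...) {
  cat(sprintf("Sequence space: %d points in %d dimensions (stress %.3g)\n",
              length(x$ids), ncol(x$coords), x$stress))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.sequence_space <- function(x, labels = FALSE, col = 1, ...) {
  graphics::plot(x$coords[, 1], x$coords[, 2], xlab = "MDS1", ylab = "MDS2",
                 col = col, pch = 19, ...)
  if (labels) graphics::text(x$coords[, 1], x$coords[, 2], x$ids, pos = 3, cex = 0.7)
  invisible(x)
}

#' Nearest neighbours of a sequence in the projected space
#'
#' @param space a `sequence_space`.
#' @param query id of the query sequence (excluded from the result).
#' @param k number of neighbours, `k < n`.
#' @return Data frame of `id` and `distance`, the `k` nearest by ascending
#'   Euclidean distance; ties broken by input order.
#' @export
nearest_neighbours <- function(space, query, k = 30L) {
  qi <- match(query, space$ids)
  if (is.na(qi)) stop("unknown id: ", query, call. = FALSE)
  stopifnot(k < length(space$ids))
  dq <- sqrt(colSums((t(space$coords) - space$coords[qi, ])^2))
  ord <- order(dq)
  ord <- ord[ord != qi]
  data.frame(id = space$ids[ord[seq_len(k)]],
             distance = dq[ord[seq_len(k)]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' k-medoids labelling of a sequence space
#'
#' Convenience wrapper over partitioning around medoids for exploring cluster
#' structure in the projection. Cluster boundaries are a modelling choice, not
#' a property of the data; the labelling is optional and `k` is up to the
#' analyst.
#'
#' @param space a `sequence_space`.
#' @param k number of clusters.
#' @return Named integer vector of cluster labels.
#' @export
cluster_space <- function(space, k = 2L) {
  fit <- cluster::pam(space$coords, k = k)
  stats::setNames(fit$clustering, space$ids)
}

#' Per-loop histidine profile of labelled groups
#'
#' For each group, the mean number of histidines falling in each scaffold
#' segment (N-tail, loops 1-7, C-tail). HRD clusters typically concentrate
#' their histidines in loop 5.
#'
#' @param ds a [defensin_set]; all sequences must be scaffold-valid.
#' @param groups named character vector mapping every id in `ds` to a group
#'   label; a single unnamed label recycles to all sequences.
#' @return Data frame: one row per group with columns `group`, `n`, and the
#'   nine segment means.
#' @export
loop_his_profile <- function(ds, groups = "all") {
  if (is.null(names(groups)) && length(groups) == 1L) {
    groups <- stats::setNames(rep(groups, nrow(ds)), ds$id)
  }
  missing <- setdiff(ds$id, names(groups))
  if (length(missing)) {
    stop("no group label for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- t(vapply(seq_len(nrow(ds)), function(i) {
    segs <- scaffold_segments(detect_scaffold(ds$sequence[i], ds$id[i]))
    vapply(segs, function(s)
      if (nzchar(s)) as.numeric(his_count(s)) else 0, numeric(1))
  }, numeric(9L)))
  colnames(counts) <- SEGMENT_NAMES
  lab <- groups[ds$id]
  rows <- lapply(sort(unique(lab)), function(g) {
    sub <- counts[lab == g, , drop = FALSE]
    cbind(data.frame(group = g, n = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(t(colMeans(sub))))
  })
  do.call(rbind, rows)
}
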