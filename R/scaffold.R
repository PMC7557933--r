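#' Detect the eight-cysteine CSab scaffold of a mature defensin
#'
#' Plant defensins carry eight absolutely conserved cysteines forming four
#' disulfide bonds. This partitions a sequence into the N-terminal tail before
#' the first cysteine, seven inter-cysteine loops (loop i lies strictly
#' between the i-th and (i+1)-th cysteine), and the C-terminal tail after the
#' last cysteine. All coordinates are 1-based and count the N-terminal
#' expression-system alanine where present, matching the residue numbering
#' used for disulfide assignments (e.g. "Cys15").
#'
#' @param sequence a single amino-acid sequence, or a one-row [defensin_set].
#' @param id identifier used in messages and results; taken from the set when
#'   `sequence` is a `defensin_set`.
#' @return An object of class `cys_scaffold`: list with `id`, `sequence`,
#'   `cys_positions` (8 strictly increasing 1-based positions), `n_tail`,
#'   `loops` (7 strings), `c_tail`, and `gap_vector` (the 7 loop lengths).
#' @details Sequences without exactly eight cysteines raise an error that
#'   reports the observed count; batch callers may catch it and route such
#'   sequences to a non-canonical bin rather than abort.
#' @examples
#' detect_scaffold(expressed_hrds()[4, ])  # SlD26
#' @export
detect_scaffold <- function(sequence, id = NULL) {
  if (inherits(sequence, "defensin_set")) {
    stopifnot(nrow(sequence) == 1L)
    id <- sequence$id
    sequence <- sequence$sequence
  }
  if (is.null(id)) id <- "query"
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  cys <- which(chars == "C")
  if (length(cys) != 8L) {
    stop(sprintf("sequence '%s' has %d cysteines (8 required for the CSab scaffold)",
                 id, length(cys)), call. = FALSE)
  }
  loops <- vapply(seq_len(7L), function(i) {
    substr(sequence, cys[i] + 1L, cys[i + 1L] - 1L)
  }, character(1))
  out <- list(
    id = id,
    sequence = sequence,
    cys_positions = cys,
    n_tail = substr(sequence, 1L, cys[1] - 1L),
    loops = loops,
    c_tail = if (cys[8] < nchar(sequence))
      substr(sequence, cys[8] + 1L, nchar(sequence)) else "",
    gap_vector = nchar(loops)
  )
  class(out) <- "cys_scaffold"
  out
}

#' @export
print.cys_scaffold <- function(x, ...) {
  cat(sprintf("CSab scaffold of '%s' (%d aa)\n", x$id, nchar(x$sequence)))
  cat("  Cys positions:", paste(x$cys_positions, collapse = ", "), "\n")
  cat("  gap vector:   ", paste(x$gap_vector, collapse = ", "), "\n")
  invisible(x)
}

#' Assign disulfide connectivity to a scaffold
#'
#' Maps cysteine ranks to residue positions under one of two observed
#' patterns. The `standard` plant-defensin pattern pairs C1-C8, C2-C5, C3-C6,
#' C4-C7 (the abc...a'b'c' ladder of the CSab motif). The `shifted` pattern,
#' first resolved in AtD90, pairs C1-C5, C2-C6, C3-C7, C4-C8 and leaves the
#' C-terminus more flexible.
#'
#' @param scaffold a `cys_scaffold` from [detect_scaffold()].
#' @param pattern `"standard"` or `"shifted"`.
#' @return An object of class `disulfide_assignment`: list with `pairs` (a
#'   4 x 2 matrix of 1-based residue positions, each row one bond, lower
#'   position first) and `pattern`. Every cysteine appears in exactly one pair.
#' @examples
#' assign_connectivity(detect_scaffold(expressed_hrds()[4, ]), "standard")
#' @export
assign_connectivity <- function(scaffold, pattern = c("standard", "shifted")) {
  stopifnot(inherits(scaffold, "cys_scaffold"))
  pattern <- match.arg(pattern)
  ranks <- connectivity_rank_pairs(pattern)
  pos <- scaffold$cys_positions
  pairs <- cbind(pos[ranks[, 1]], pos[ranks[, 2]])
  pairs <- t(apply(pairs, 1L, sort))
  dimnames(pairs) <- list(NULL, c("from", "to"))
  structure(list(id = scaffold$id, pairs = pairs, pattern = pattern),
            class = "disulfide_assignment")
}

connectivity_rank_pairs <- function(pattern) {
  switch(pattern,
    standard = cbind(1:4, c(8L, 5L, 6L, 7L)),
    shifted  = cbind(1:4, c(5L, 6L, 7L, 8L)),
    stop("unknown connectivity pattern: ", pattern, call. = FALSE)
  )
}

#' @export
print.disulfide_assignment <- function(x, ...) {
  cat(sprintf("Disulfide assignment for '%s' (%s pattern)\n", x$id, x$pattern))
  for (i in seq_len(nrow(x$pairs))) {
    cat(sprintf("  Cys%d-Cys%d\n", x$pairs[i, 1], x$pairs[i, 2]))
  }
  invisible(x)
}

#' Default cysteine-spacing templates for connectivity prediction
#'
#' The reference gap vectors of SlD26 (experimentally standard connectivity)
#' and AtD90 (experimentally shifted connectivity).
#'
#' @return A list of `list(gap_vector=, label=)` templates.
#' @export
connectivity_templates <- function() {
  fixtures <- expressed_hrds()
  list(
    list(gap_vector = detect_scaffold(fixtures[fixtures$id == "SlD26", ])$gap_vector,
         label = "standard"),
    list(gap_vector = detect_scaffold(fixtures[fixtures$id == "AtD90", ])$gap_vector,
         label = "shifted")
  )
}

#' Predict the connectivity pattern from cysteine spacing
#'
#' A nearest-template classifier on the gap vector (the seven inter-cysteine
#' loop lengths): the query receives the label of the template whose gap
#' vector is closest in L1 (Manhattan) distance. This is a *prediction* from
#' spacing similarity, not an experimental determination: the shifted pattern
#' is expected to recur in defensins whose cysteine spacing resembles AtD90's.
#' Ties between differently-labelled templates return `"unassigned"`.
#'
#' @param scaffold a `cys_scaffold`, or a bare 7-element gap vector.
#' @param templates list of `list(gap_vector=, label=)`; defaults to
#'   [connectivity_templates()].
#' @return list with `label`, `distance` (minimum L1 distance), and
#'   `distances` (named vector over templates).
#' @export
classify_connectivity_pattern <- function(scaffold,
                                          templates = connectivity_templates()) {
  gv <- if (inherits(scaffold, "cys_scaffold")) scaffold$gap_vector else scaffold
  stopifnot(length(gv) == 7L, length(templates) >= 1L)
  d <- vapply(templates, function(t) {
    stopifnot(length(t$gap_vector) == 7L)
    sum(abs(gv - t$gap_vector))
  }, numeric(1))
  names(d) <- vapply(templates, `[[`, character(1), "label")
  best <- which(d == min(d))
  label <- unique(names(d)[best])
  list(
    label = if (length(label) == 1L) label else "unassigned",
    distance = min(d),
    distances = d
  )
}

#' Tabulate scaffolds for a defensin set
#'
#' Runs [detect_scaffold()] and [classify_connectivity_pattern()] over a set.
#' Sequences without exactly eight cysteines are kept with `canonical = FALSE`
#' and NA scaffold columns rather than aborting the batch.
#'
#' @param ds a [defensin_set].
#' @param templates templates for [classify_connectivity_pattern()].
#' @return A data frame with one row per sequence: id, canonical flag,
#'   cysteine count, comma-separated cys positions and gap vector, predicted
#'   pattern label and its L1 distance, and the residue pairs under both the
#'   standard and shifted rules.
#' @export
scaffold_table <- function(ds, templates = connectivity_templates()) {
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    seqc <- ds$sequence[i]
    n_cys <- lengths(regmatches(seqc, gregexpr("C", seqc, fixed = TRUE)))
    if (n_cys != 8L) {
      return(data.frame(id = ds$id[i], canonical = FALSE, n_cys = n_cys,
                        cys_positions = NA, gap_vector = NA,
                        pattern_label = NA, pattern_distance = NA,
                        standard_pairs = NA, shifted_pairs = NA,
                        stringsAsFactors = FALSE))
    }
    sc <- detect_scaffold(seqc, id = ds$id[i])
    cl <- classify_connectivity_pattern(sc, templates)
    fmt_pairs <- function(p) paste(sprintf("%d-%d", p[, 1], p[, 2]), collapse = ",")
    data.frame(
      id = ds$id[i], canonical = TRUE, n_cys = 8L,
      cys_positions = paste(sc$cys_positions, collapse = ","),
      gap_vector = paste(sc$gap_vector, collapse = ","),
      pattern_label = cl$label, pattern_distance = cl$distance,
      standard_pairs = fmt_pairs(assign_connectivity(sc, "standard")$pairs),
      shifted_pairs = fmt_pairs(assign_connectivity(sc, "shifted")$pairs),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
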