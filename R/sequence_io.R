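AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a set of mature defensin sequences
#'
#' A defensin set is the package's central container: a data frame with one
#' row per mature defensin domain (the peptide left after signal-peptide
#' removal) and columns `id`, `sequence`, `taxon`, `notes`. Sequences are
#' uppercased on construction and validated against the 20-letter amino-acid
#' alphabet; ambiguity codes (B, J, O, U, X, Z) and stop symbols are rejected.
#'
#' @param id character vector of unique short identifiers.
#' @param sequence character vector of amino-acid sequences (same length as
#'   `id`). Lowercase input is uppercased silently.
#' @param taxon optional character vector of source taxa.
#' @param notes optional character vector of free-text notes.
#' @return A data frame of class `defensin_set`.
#' @examples
#' defensin_set("demo", "AKHCGKHSKSWNGKC")
#' @export
defensin_set <- function(id, sequence, taxon = NA_character_, notes = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("'id' and 'sequence' must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate ids in defensin set: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sequence)) {
    validate_sequence(sequence[i], id[i])
  }
  out <- data.frame(
    id = id, sequence = sequence,
    taxon = rep_len(as.character(taxon), length(id)),
    notes = rep_len(as.character(notes), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("defensin_set", "data.frame")
  out
}

# Reject empty sequences and any character outside the 20-letter alphabet,
# naming the offending id and 1-based position.
validate_sequence <- function(sequence, id) {
  if (is.na(sequence) || !nzchar(sequence)) {
    stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf(
      "invalid residue '%s' at position %d in sequence '%s'",
      chars[bad[1]], bad[1], id
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.defensin_set <- function(x, ...) {
  cat(sprintf("Defensin set: %d sequence(s)\n", nrow(x)))
  len <- nchar(x$sequence)
  his <- his_count(x$sequence)
  for (i in seq_len(min(nrow(x), 10L))) {
    cat(sprintf("  %-10s %3d aa, %2d His\n", x$id[i], len[i], his[i]))
  }
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Read mature defensin sequences from a FASTA file
#'
#' Permissive reading, strict validation: blank lines are ignored, sequence
#' lines may be wrapped, the header token before the first whitespace becomes
#' the id and the remainder the description. Sequences are uppercased. Any
#' character outside ACDEFGHIKLMNPQRSTVWY raises a validation error naming the
#' id and position; sequence data before the first header raises a parse error
#' naming the line.
#'
#' @param path path to a FASTA file.
#' @return A [defensin_set] with entries in file order; an empty set for an
#'   empty file.
#' @seealso [write_fasta()], [expressed_hrds()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    return(defensin_set(character(0), character(0)))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA at line %d: sequence data before first header",
                 first), call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE, whole.header = TRUE)
  headers <- vapply(recs, function(r) attr(r, "Annot"), character(1))
  headers <- sub("^>", "", headers)
  ids <- sub("\\s.*$", "", headers)
  notes <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), NA_character_)
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  defensin_set(ids, seqs, notes = notes)
}

#' Write a defensin set to FASTA
#'
#' Writes one entry per sequence, wrapped at 60 columns. `read_fasta()` of the
#' result reproduces the input set (round-trip identity).
#'
#' @param ds a [defensin_set] (or anything with `id` and `sequence` columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  seqinr::write.fasta(as.list(ds$sequence), names = ds$id,
                      file.out = path, nbchar = 60L, as.string = TRUE)
  invisible(path)
}

#' The four expressed histidine-rich defensins
#'
#' Returns the mature domains of AtD90 and AtD212 (*Arabidopsis thaliana*),
#' CrD26 (*Capsella rubella*) and SlD26 (*Solanum lycopersicum*) as expressed
#' and purified: each carries the extra N-terminal alanine left by cleavage of
#' the yeast secretion signal, and residue numbering throughout the package
#' counts that alanine as position 1.
#'
#' @return A [defensin_set] with four rows.
#' @examples
#' expressed_hrds()
#' @export
expressed_hrds <- function() {
  defensin_set(
    id = c("AtD90", "AtD212", "CrD26", "SlD26"),
    sequence = c(
      "AHCDHFLGEAPVYPCKEKACKSVCKEHYHHACKGECEYHGREVHCHCYGDYH",
      "ANCDTYLGEVTVYYPCRERDCEAQCYEHYPHSCKGECEHHDHVVHHDNEEEHCHC",
      "ANDCDRFLGEATVSYPCRERECEAQCHEHYEHSCKGECEDHDHDHGHHDHDDHHDHEEHCHCYGH",
      "AKHCGKHSKSWNGKCFHKKCNHWCMEKEDAKYGSCSHGDCYCYYHC"
    ),
    taxon = c("Arabidopsis thaliana", "Arabidopsis thaliana",
              "Capsella rubella", "Solanum lycopersicum")
  )
}

#' Write a tabular report for a defensin set
#'
#' @param x a data frame (e.g. from [physchem_table()] or [scaffold_table()]).
#' @param path output path; format chosen by `format`.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
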