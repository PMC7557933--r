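# Isotope-averaged residue masses (Da); peptide average mass = sum + one water.
RESIDUE_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.0153
H2_AVG_MASS <- 2.0159  # mass lost per disulfide bond (2 x 1.00794)

# Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Side-chain and terminal pKa sets for charge calculations
#'
#' The default `"bjellqvist"` set (C-terminus 3.55; D 4.05; E 4.45; H 5.98;
#' C 9.0; Y 10.0; K 10.0; R 12.0; N-terminus 7.5) is the ExPASy-style
#' convention; it reproduces the reference pI values for the expressed HRDs
#' to 0.1 pH units. Cysteines are treated as titratable even in the oxidized
#' molecule under this convention. An `"emboss"` alternative is provided for
#' comparison; results are not interchangeable between sets.
#'
#' @param name `"bjellqvist"` (default) or `"emboss"`.
#' @return Named numeric vector with elements `Nterm`, `Cterm`, `D`, `E`,
#'   `H`, `C`, `Y`, `K`, `R`.
#' @export
pka_set <- function(name = c("bjellqvist", "emboss")) {
  name <- match.arg(name)
  switch(name,
    bjellqvist = c(Nterm = 7.5, Cterm = 3.55, D = 4.05, E = 4.45, H = 5.98,
                   C = 9.0, Y = 10.0, K = 10.0, R = 12.0),
    emboss = c(Nterm = 8.6, Cterm = 3.6, D = 3.9, E = 4.1, H = 6.5,
               C = 8.5, Y = 10.1, K = 10.8, R = 12.5)
  )
}

as_sequences <- function(x) {
  if (inherits(x, "defensin_set") || is.data.frame(x)) x$sequence else as.character(x)
}

#' Count histidine residues
#'
#' @param x a [defensin_set] or character vector of sequences.
#' @return Integer vector of H counts.
#' @export
his_count <- function(x) {
  seqs <- toupper(as_sequences(x))
  vapply(gregexpr("H", seqs, fixed = TRUE),
         function(m) if (m[1] == -1L) 0L else length(m), integer(1))
}

#' Classify sequences as histidine-rich defensins
#'
#' A mature defensin domain is called histidine-rich (HRD) when it contains at
#' least `cutoff` histidines. The default cutoff of 6 is deliberately
#' semi-arbitrary — typical defensins average ~1.5 His — and is exposed as a
#' parameter.
#'
#' @inheritParams his_count
#' @param cutoff minimum His count (non-negative integer), default 6.
#' @return Logical vector.
#' @export
classify_hrd <- function(x, cutoff = 6L) {
  stopifnot(cutoff >= 0)
  his_count(x) >= cutoff
}

#' Isotope-averaged peptide mass with disulfide correction
#'
#' The reduced mass is the sum of residue average masses plus one water; each
#' disulfide bond removes two hydrogens (2.0159 Da). Canonical CSab scaffolds
#' carry four disulfides.
#'
#' @inheritParams his_count
#' @param n_disulfides number of disulfide bonds (default 4); must not exceed
#'   the available cysteine pairs.
#' @return Data frame with columns `mass_reduced` and `mass_oxidized` (Da).
#' @export
average_mass <- function(x, n_disulfides = 4L) {
  stopifnot(n_disulfides >= 0)
  seqs <- toupper(as_sequences(x))
  reduced <- vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    n_cys <- sum(chars == "C")
    if (2L * n_disulfides > n_cys) {
      stop(sprintf("%d disulfides require %d cysteines; sequence has %d",
                   n_disulfides, 2L * n_disulfides, n_cys), call. = FALSE)
    }
    sum(RESIDUE_AVG_MASS[chars]) + WATER_AVG_MASS
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(mass_reduced = reduced,
             mass_oxidized = reduced - n_disulfides * H2_AVG_MASS)
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch model: the positive contribution sums the N-terminus
#' and K/R/H side chains, each protonated with probability
#' 1/(1+10^(pH-pKa)); the negative contribution sums the C-terminus and
#' D/E/C/Y side chains, each deprotonated with probability 1/(1+10^(pKa-pH)).
#' The resulting charge curve is strictly decreasing in pH.
#'
#' @inheritParams his_count
#' @param ph pH value(s) in (0, 14).
#' @param pka named pKa vector from [pka_set()].
#' @return Numeric: net charge in elementary units. Vectorised over `ph` when
#'   `x` is a single sequence, otherwise over sequences.
#' @export
net_charge <- function(x, ph = 7, pka = pka_set()) {
  seqs <- toupper(as_sequences(x))
  stopifnot(all(ph > 0 & ph < 14))
  one <- function(s, ph) {
    chars <- strsplit(s, "")[[1]]
    pos <- 1 / (1 + 10^(ph - pka[["Nterm"]])) +
      sum(vapply(c("K", "R", "H"), function(a)
        sum(chars == a) / (1 + 10^(ph - pka[[a]])), numeric(1)))
    neg <- 1 / (1 + 10^(pka[["Cterm"]] - ph)) +
      sum(vapply(c("D", "E", "C", "Y"), function(a)
        sum(chars == a) / (1 + 10^(pka[[a]] - ph)), numeric(1)))
    pos - neg
  }
  if (length(seqs) == 1L) {
    vapply(ph, function(p) one(seqs, p), numeric(1))
  } else {
    stopifnot(length(ph) == 1L)
    vapply(seqs, one, numeric(1), ph = ph, USE.NAMES = FALSE)
  }
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge is zero, found by
#' bisection on (0, 14) to |charge| < 1e-4. Because both termini are always
#' titratable the charge curve is strictly decreasing with a sign change, so
#' the root is unique.
#'
#' @inheritParams net_charge
#' @return Numeric vector of pI values.
#' @export
isoelectric_point <- function(x, pka = pka_set()) {
  seqs <- toupper(as_sequences(x))
  vapply(seqs, function(s) {
    f <- function(ph) net_charge(s, ph, pka = pka)
    lo <- 1e-8; hi <- 14 - 1e-8
    if (f(lo) <= 0 || f(hi) >= 0) {
      stop("charge curve has no sign change on (0, 14)", call. = FALSE)
    }
    mid <- (lo + hi) / 2
    while (abs(f(mid)) >= 1e-4 && (hi - lo) > 1e-12) {
      if (f(mid) > 0) lo <- mid else hi <- mid
      mid <- (lo + hi) / 2
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
}

#' GRAVY hydrophobicity index
#'
#' Grand average of hydropathy: the mean Kyte-Doolittle value over residues.
#' Mature plant defensins are typically hydrophilic (negative GRAVY).
#'
#' @inheritParams his_count
#' @return Numeric vector.
#' @export
gravy <- function(x) {
  seqs <- toupper(as_sequences(x))
  vapply(seqs, function(s) mean(KD_HYDROPATHY[strsplit(s, "")[[1]]]),
         numeric(1), USE.NAMES = FALSE)
}

#' Histogram of histidine counts across a set
#'
#' @inheritParams his_count
#' @return Named integer vector: names are His counts (as characters), values
#'   the number of sequences with that count. Empty input gives an empty
#'   vector.
#' @export
his_histogram <- function(x) {
  h <- his_count(x)
  if (!length(h)) return(integer(0))
  tab <- table(h)
  stats::setNames(as.integer(tab), names(tab))
}

#' Physicochemical summary table
#'
#' One row per sequence: length, His count, HRD flag, reduced and oxidized
#' average masses, pI, net charge at pH 7, and GRAVY. Masses and pI are
#' rounded to one decimal, mirroring the precision at which such tables are
#' reported. Sequences with fewer cysteines than `2 * n_disulfides` have
#' their disulfide count capped at the available pairs, so non-canonical
#' sequences in a batch are summarised rather than fatal.
#'
#' @param ds a [defensin_set].
#' @param hrd_cutoff His cutoff for [classify_hrd()].
#' @param n_disulfides disulfide count for [average_mass()].
#' @param pka pKa set from [pka_set()].
#' @return A data frame with class `physchem_table`.
#' @examples
#' physchem_table(expressed_hrds())
#' @export
physchem_table <- function(ds, hrd_cutoff = 6L, n_disulfides = 4L,
                           pka = pka_set()) {
  n_cys <- vapply(strsplit(toupper(ds$sequence), ""),
                  function(ch) sum(ch == "C"), integer(1))
  ss <- pmin(as.integer(n_disulfides), n_cys %/% 2L)
  m <- do.call(rbind, lapply(seq_len(nrow(ds)),
                             function(i) average_mass(ds$sequence[i], ss[i])))
  out <- data.frame(
    id = ds$id,
    length = nchar(ds$sequence),
    his_count = his_count(ds),
    is_hrd = classify_hrd(ds, hrd_cutoff),
    mass_reduced = round(m$mass_reduced, 1),
    mass_oxidized = round(m$mass_oxidized, 1),
    pi = round(isoelectric_point(ds, pka = pka), 1),
    net_charge_ph7 = net_charge(ds, 7, pka = pka),
    gravy = gravy(ds),
    stringsAsFactors = FALSE
  )
  class(out) <- c("physchem_table", "data.frame")
  out
}
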