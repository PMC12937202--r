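# Primer thermodynamics: GC content, Wallace-rule Tm, nearest-neighbor Tm.

#' GC content of an unambiguous sequence
#'
#' @param seq Residue string over {A,C,G,T}.
#' @return (#G + #C) / length, in \[0, 1\].
#' @export
gc_content <- function(seq) {
  chars <- unambiguous_chars(seq)
  sum(chars %in% c("G", "C")) / length(chars)
}

#' Wallace-rule melting temperature
#'
#' Tm = 2(A+T) + 4(G+C) degrees C; the rule the field quotes for short
#' oligos and the scale on which design windows are expressed here.
#'
#' @param seq Residue string over {A,C,G,T}.
#' @return Tm in degrees C.
#' @export
tm_wallace <- function(seq) {
  chars <- unambiguous_chars(seq)
  2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
}

unambiguous_chars <- function(seq) {
  seq <- normalize_residues(seq)
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c("A", "C", "G", "T")))
  if (length(bad)) {
    stop("ambiguous or gap symbol '", chars[bad[1L]], "' at position ",
         bad[1L], ": unambiguous sequence required")
  }
  chars
}

# Unified nearest-neighbor parameters (Allawi & SantaLucia 1997),
# (delta-H kcal/mol, delta-S cal/mol/K) per 5'->3' dinucleotide step.
.NN_STEPS <- list(
  AA = c(-7.9, -22.2), AC = c(-8.4, -22.4), AG = c(-7.8, -21.0),
  AT = c(-7.2, -20.4), CA = c(-8.5, -22.7), CC = c(-8.0, -19.9),
  CG = c(-10.6, -27.2), CT = c(-7.8, -21.0), GA = c(-8.2, -22.2),
  GC = c(-9.8, -24.4), GG = c(-8.0, -19.9), GT = c(-8.4, -22.4),
  TA = c(-7.2, -21.3), TC = c(-8.2, -22.2), TG = c(-8.5, -22.7),
  TT = c(-7.9, -22.2)
)
.NN_INIT_AT <- c(2.3, 4.1)   # per A/T duplex terminus
.NN_INIT_GC <- c(0.1, -2.8)  # per G/C duplex terminus

#' Nearest-neighbor melting temperature
#'
#' Two-state duplex model with the unified Allawi & SantaLucia (1997)
#' parameter set, terminal A/T and G/C initiation penalties, the
#' SantaLucia (1998) monovalent-salt entropy correction
#' 0.368 (N-1) ln\[Na+\], and excess-primer kinetics (the template does not
#' contribute to the strand-concentration term):
#' Tm = 1000 dH / (dS + 0.368 (N-1) ln(Na) + R ln(C_primer)) - 273.15,
#' R = 1.987 cal/mol/K.
#'
#' @param seq Unambiguous primer sequence, length >= 8.
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Primer concentration in nM (default 250).
#' @return Tm in degrees C; strictly increasing in `na_mM`.
#' @export
tm_nearest_neighbor <- function(seq, na_mM = 50, oligo_nM = 250) {
  chars <- unambiguous_chars(seq)
  n <- length(chars)
  if (n < 8L) stop("nearest-neighbor Tm needs length >= 8 (got ", n, ")")
  steps <- paste0(chars[-n], chars[-1L])
  hs <- rowSums(vapply(steps, function(s) .NN_STEPS[[s]], numeric(2)))
  for (term in chars[c(1L, n)]) {
    hs <- hs + if (term %in% c("A", "T")) .NN_INIT_AT else .NN_INIT_GC
  }
  dH <- hs[[1L]]; dS <- hs[[2L]]
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  1000 * dH / (dS + 1.987 * log(oligo_nM * 1e-9)) - 273.15
}

#' Longest homopolymer run
#'
#' @param seq Residue string.
#' @return Length of the longest run of one symbol.
#' @export
max_homopolymer <- function(seq) {
  max(rle(strsplit(normalize_residues(seq), "", fixed = TRUE)[[1L]])$lengths)
}
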