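# The published five-species onchidiid COI panel, and a synthetic
# stand-in template set for its five reference mitochondrial genomes.
#
# The real assay was validated against GenBank COI records
# (MZ831962, NC068813, OP714175, MZ832009, MH054945). Those records are
# not redistributable here and cannot be fetched at test time, so
# synthetic_reference_templates() constructs SYNTHETIC stand-ins: random
# 700-nt backbones carrying the six published primer footprints at
# spacings that reproduce the published amplicon ladder
# {162, 227, 275, 307, 527} bp and the published per-primer
# diagnostic-site counts {8, 7, 9, 7, 7}. They exercise the design and
# in-silico PCR machinery end to end; they are not the organisms' true
# sequences.

# published per-primer diagnostic-site offsets, 0-based from the primer
# 3' terminus (the seventh *P. tumidus* site is moved from offset 24 to
# 18 so it fits the 22-nt footprint; see package docs). The 3' terminus
# of a reverse primer pairs the leftmost plus-strand column of its
# footprint, so template position = footprint start + offset.
.REF_DIAG_OFFSETS <- list(
  Onchidium.stuxbergi  = c(0L, 3L, 6L, 8L, 9L, 11L, 12L, 15L),
  Peronia.verruculata  = c(0L, 3L, 6L, 12L, 15L, 18L, 21L),
  Onchidium.reevesii   = c(0L, 3L, 5L, 6L, 9L, 12L, 15L, 18L, 21L),
  Platevindex.martensi = c(0L, 3L, 6L, 9L, 12L, 18L, 20L),
  Paromoionchi.tumidus = c(0L, 3L, 5L, 9L, 15L, 18L, 21L)
)

.REF_FWD_START <- 101L
.REF_TEMPLATE_LEN <- 700L
.REF_BACKBONE_SEED <- 20160641L

#' Load the published onchidiid COI multiplex panel
#'
#' One universal forward primer and five species-specific reverse
#' primers identifying *Onchidium stuxbergi*, *Peronia verruculata*,
#' *Onchidium reevesii*, *Platevindex martensi* and *Paromoionchis
#' tumidus* by amplicon sizes 162, 227, 275, 307 and 527 bp.
#'
#' @return A [primer_panel].
#' @export
published_panel <- function() {
  read_panel_tsv(system.file("extdata", "onchidiid_coi_panel.tsv",
                             package = "snapPCR", mustWork = TRUE))
}

#' Synthetic stand-in templates for the published panel's references
#'
#' Builds one synthetic 700-nt template per panel species. Each template
#' carries the universal forward footprint at positions 101-123; the
#' target species additionally carries a perfect-match footprint for its
#' own reverse primer ending at position `100 + expected size`, so the
#' predicted amplicon has exactly the published size. Non-target
#' templates match that footprint everywhere except at the species'
#' published number of diagnostic columns (placed at the published
#' offsets from the 3' terminus), where all non-targets share an
#' alternative base — so each reverse primer has >= 7 mismatches,
#' including a 3'-terminal one, on every non-target.
#'
#' These are labelled synthetic stand-ins, not GenBank sequences.
#'
#' @param panel The panel to embed; defaults to [published_panel()].
#' @return List of five species-labelled [sequence_record]s plus an
#'   attribute `diag_columns` (species -> planted diagnostic template
#'   positions).
#' @export
synthetic_reference_templates <- function(panel = published_panel()) {
  species <- names(panel$reverses)
  bases <- c("A", "C", "G", "T")
  with_local_seed(.REF_BACKBONE_SEED, {
    backbone <- sample(bases, .REF_TEMPLATE_LEN, replace = TRUE)
    fwd <- strsplit(panel$forward$sequence, "")[[1L]]
    fcols <- .REF_FWD_START:(.REF_FWD_START + length(fwd) - 1L)
    backbone[fcols] <- fwd
    seqs <- stats::setNames(rep(list(backbone), length(species)), species)
    diag_columns <- list()
    for (sp in species) {
      rp <- panel$reverses[[sp]]
      size <- panel$expected_sizes[[sp]]
      rev_end <- .REF_FWD_START - 1L + size
      foot <- strsplit(revcomp(rp$sequence), "")[[1L]]
      cols <- (rev_end - length(foot) + 1L):rev_end
      offs <- .REF_DIAG_OFFSETS[[sp]]
      dcols <- cols[1L] + offs
      for (s2 in species) {
        seqs[[s2]][cols] <- foot
      }
      for (j in dcols) {
        alt <- sample(setdiff(bases, backbone_at(seqs[[sp]], j)), 1L)
        for (s2 in setdiff(species, sp)) seqs[[s2]][j] <- alt
      }
      diag_columns[[sp]] <- sort(dcols)
    }
    out <- lapply(species, function(sp) {
      sequence_record(paste0("synthetic_", gsub("\\.", "_", sp)),
                      paste(seqs[[sp]], collapse = ""), species = sp,
                      allow_gaps = FALSE)
    })
    attr(out, "diag_columns") <- diag_columns
    out
  })
}

backbone_at <- function(seq_chars, j) seq_chars[j]

#' Species-labelled alignment of the synthetic reference templates
#'
#' The five synthetic stand-ins are identical in length and built on one
#' backbone, so they already form an alignment (no indels).
#'
#' @return A [species_alignment] of the five synthetic templates.
#' @export
synthetic_reference_alignment <- function() {
  species_alignment(synthetic_reference_templates())
}
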