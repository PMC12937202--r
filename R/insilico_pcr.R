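# In-silico PCR: exhaustive primer binding-site search with IUPAC-aware
# mismatch counting and allele-specific 3'-mismatch extension blocking,
# amplicon prediction, multiplex reactions and specificity matrices.
#
# Templates are barcode-length, so the scan is deliberately naive
# (every placement on both strands): correctness and auditability over
# speed.

#' In-silico PCR parameters
#'
#' The blocking rules model allele-specific PCR: a primer with a
#' 3'-terminal mismatch is never extended, and more than
#' `max_mismatch_in_window` mismatches within the last
#' `three_prime_window` nt also block extension. Placements with more
#' than `max_mismatch_total` mismatches are not reported at all.
#'
#' @param max_mismatch_total Max mismatches for a reported binding site.
#' @param three_prime_window 3'-terminal window length, nt.
#' @param max_mismatch_in_window Max mismatches tolerated in the window.
#' @param block_on_terminal_mismatch A mismatch at the 3' terminus always
#'   blocks extension.
#' @param min_amplicon,max_amplicon Product size bounds, bp.
#' @return Object of class `pcr_config`.
#' @export
pcr_config <- function(max_mismatch_total = 3L,
                       three_prime_window = 5L,
                       max_mismatch_in_window = 1L,
                       block_on_terminal_mismatch = TRUE,
                       min_amplicon = 50L,
                       max_amplicon = 2000L) {
  structure(
    list(max_mismatch_total = as.integer(max_mismatch_total),
         three_prime_window = as.integer(three_prime_window),
         max_mismatch_in_window = as.integer(max_mismatch_in_window),
         block_on_terminal_mismatch = isTRUE(block_on_terminal_mismatch),
         min_amplicon = as.integer(min_amplicon),
         max_amplicon = as.integer(max_amplicon)),
    class = "pcr_config"
  )
}

primer_sequence <- function(primer) {
  if (inherits(primer, "primer")) primer$sequence
  else normalize_residues(primer)
}

#' Find primer binding sites on a template
#'
#' Scans every placement of the primer on both strands of an ungapped
#' template. A position counts as a mismatch when the primer and template
#' IUPAC symbols share no base (template ambiguity is conservative toward
#' amplification). For each placement with at most
#' `cfg$max_mismatch_total` mismatches, mismatch offsets are recorded
#' 0-based from the primer's 3' terminus and extendability is derived
#' from the 3' blocking rules.
#'
#' @param template A [sequence_record] (no gaps) or residue string.
#' @param primer A [primer] or residue string (5'->3').
#' @param cfg A [pcr_config()].
#' @return Data.frame of binding sites sorted by start coordinate:
#'   `template_id`, `strand` (`"plus"`/`"minus"`), `start`, `end`
#'   (1-based inclusive template coordinates), `mismatches`,
#'   `mismatch_offsets` (list-column, 0-based from 3'), `extendable`.
#' @export
find_binding_sites <- function(template, primer, cfg = pcr_config()) {
  tid <- if (inherits(template, "sequence_record")) template$id else "template"
  tseq <- if (inherits(template, "sequence_record")) template$residues
          else normalize_residues(template)
  if (grepl("-", tseq, fixed = TRUE)) stop("template contains gaps")
  pseq <- primer_sequence(primer)
  L <- nchar(pseq); N <- nchar(tseq)
  if (L > N) return(empty_sites_df())
  tb <- residue_bits(tseq)
  res <- list()
  for (strand in c("plus", "minus")) {
    # plus: primer 5'->3' along the template, 3' end at start+L-1.
    # minus: primer anneals to the minus strand; its footprint on the
    # plus strand is the reverse complement, 3' end at the footprint start.
    pb <- residue_bits(if (strand == "plus") pseq else revcomp(pseq))
    for (s in 1:(N - L + 1L)) {
      hit <- bitwAnd(tb[s:(s + L - 1L)], pb) > 0L
      mm <- which(!hit)
      if (length(mm) > cfg$max_mismatch_total) next
      offs <- if (strand == "plus") L - mm else mm - 1L
      offs <- sort(offs)
      res[[length(res) + 1L]] <- list(
        strand = strand, start = s, end = s + L - 1L,
        mismatches = length(mm), offsets = offs,
        extendable = is_extendable(offs, cfg)
      )
    }
  }
  if (!length(res)) return(empty_sites_df())
  out <- data.frame(
    template_id = tid,
    strand = vapply(res, `[[`, "", "strand"),
    start = vapply(res, `[[`, 0L, "start"),
    end = vapply(res, `[[`, 0L, "end"),
    mismatches = vapply(res, `[[`, 0L, "mismatches"),
    stringsAsFactors = FALSE
  )
  out$mismatch_offsets <- I(lapply(res, `[[`, "offsets"))
  out$extendable <- vapply(res, `[[`, TRUE, "extendable")
  out[order(out$start, out$strand), , drop = FALSE]
}

is_extendable <- function(offsets, cfg) {
  if (cfg$block_on_terminal_mismatch && 0L %in% offsets) return(FALSE)
  sum(offsets < cfg$three_prime_window) <= cfg$max_mismatch_in_window
}

empty_sites_df <- function() {
  out <- data.frame(template_id = character(0), strand = character(0),
                    start = integer(0), end = integer(0),
                    mismatches = integer(0), stringsAsFactors = FALSE)
  out$mismatch_offsets <- I(list())
  out$extendable <- logical(0)
  out
}

#' Predict amplicons for one primer pair on one template
#'
#' Pairs every extendable plus-strand site of the forward primer with
#' every extendable minus-strand site of the reverse primer downstream of
#' it; product length is the plus-strand span
#' `reverse_end - forward_start + 1` and must lie within the configured
#' bounds.
#'
#' @param template A [sequence_record] or residue string.
#' @param forward,reverse [primer]s or residue strings.
#' @param cfg A [pcr_config()].
#' @return Data.frame of amplicons: `template_id`, `species`,
#'   `forward_primer`, `reverse_primer`, `fwd_start`, `fwd_end`,
#'   `rev_start`, `rev_end`, `length`.
#' @export
amplify <- function(template, forward, reverse, cfg = pcr_config()) {
  tid <- if (inherits(template, "sequence_record")) template$id else "template"
  sp <- if (inherits(template, "sequence_record")) template$species else ""
  fname <- if (inherits(forward, "primer")) forward$name else "forward"
  rname <- if (inherits(reverse, "primer")) reverse$name else "reverse"
  fs <- find_binding_sites(template, forward, cfg)
  fs <- fs[fs$strand == "plus" & fs$extendable, , drop = FALSE]
  rs <- find_binding_sites(template, reverse, cfg)
  rs <- rs[rs$strand == "minus" & rs$extendable, , drop = FALSE]
  if (!nrow(fs) || !nrow(rs)) return(empty_amplicons())
  combos <- expand.grid(f = seq_len(nrow(fs)), r = seq_len(nrow(rs)))
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    f <- fs[combos$f[k], ]; r <- rs[combos$r[k], ]
    len <- r$end - f$start + 1L
    if (f$start >= r$end || f$end >= r$start) return(NULL)
    if (len < cfg$min_amplicon || len > cfg$max_amplicon) return(NULL)
    data.frame(template_id = tid, species = sp,
               forward_primer = fname, reverse_primer = rname,
               fwd_start = f$start, fwd_end = f$end,
               rev_start = r$start, rev_end = r$end,
               length = len, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty_amplicons())
  out[order(out$fwd_start, out$length), , drop = FALSE]
}

empty_amplicons <- function() {
  data.frame(template_id = character(0), species = character(0),
             forward_primer = character(0), reverse_primer = character(0),
             fwd_start = integer(0), fwd_end = integer(0),
             rev_start = integer(0), rev_end = integer(0),
             length = integer(0), stringsAsFactors = FALSE)
}

#' Run a multiplex reaction over a template set
#'
#' The panel's universal forward primer is crossed with every
#' species-specific reverse primer on every template; an empty template
#' list (the no-template negative control) yields an empty result.
#'
#' @param templates List of [sequence_record]s (ungapped).
#' @param panel A [primer_panel].
#' @param cfg A [pcr_config()].
#' @return Named list: template id -> amplicon data.frame (possibly
#'   0-row) with an extra `target_species` column naming the reverse
#'   primer's species.
#' @export
multiplex_pcr <- function(templates, panel, cfg = pcr_config()) {
  out <- lapply(templates, function(tmpl) {
    per <- lapply(names(panel$reverses), function(sp) {
      amps <- amplify(tmpl, panel$forward, panel$reverses[[sp]], cfg)
      if (nrow(amps)) amps$target_species <- sp
      else amps$target_species <- character(0)
      amps
    })
    do.call(rbind, per)
  })
  stats::setNames(out, vapply(templates, `[[`, "", "id"))
}

#' Species-by-primer specificity matrix
#'
#' Entry (i, j) counts amplicons produced on species-i templates by the
#' species-j reverse primer (with the universal forward). A valid panel
#' is diagonal: positive on the diagonal, zero elsewhere.
#'
#' @param panel A [primer_panel].
#' @param templates List of species-labelled [sequence_record]s.
#' @param cfg A [pcr_config()].
#' @return Integer matrix, template species as rows, panel species
#'   (reverse primers) as columns.
#' @export
specificity_matrix <- function(panel, templates, cfg = pcr_config()) {
  tsp <- vapply(templates, `[[`, "", "species")
  if (any(!nzchar(tsp))) stop("all templates must carry a species label")
  rows <- sort(unique(tsp))
  cols <- names(panel$reverses)
  m <- matrix(0L, length(rows), length(cols),
              dimnames = list(template = rows, primer = cols))
  hits <- multiplex_pcr(templates, panel, cfg)
  for (k in seq_along(templates)) {
    amps <- hits[[k]]
    if (!nrow(amps)) next
    tab <- table(amps$target_species)
    m[tsp[k], names(tab)] <- m[tsp[k], names(tab)] + as.integer(tab)
  }
  m
}

#' Is a specificity matrix diagonal?
#'
#' @param m Matrix from [specificity_matrix()] with matching row/column
#'   species.
#' @return `TRUE` iff every diagonal entry is positive and every
#'   off-diagonal entry zero.
#' @export
is_diagonal_specificity <- function(m) {
  common <- intersect(rownames(m), colnames(m))
  if (!length(common)) return(FALSE)
  sq <- m[common, common, drop = FALSE]
  all(diag(sq) > 0L) && sum(sq) == sum(diag(sq)) &&
    all(m[setdiff(rownames(m), common), ] == 0L)
}

#' Write an amplicon report TSV
#'
#' @param hits Result of [multiplex_pcr()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_amplicon_tsv <- function(hits, path) {
  tab <- do.call(rbind, hits)
  if (is.null(tab)) tab <- empty_amplicons()
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
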