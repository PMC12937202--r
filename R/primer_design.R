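# Primer and panel design: universal forward primer in pan-species
# conserved windows, 3'-anchored species-specific reverse primers on
# diagnostic SNPs, and greedy multiplex panel assembly.

#' Design constraints
#'
#' The published assay states no numeric windows; these defaults are
#' calibrated once to admit the published onchidiid panel (primers of
#' 20-23 nt, AT-rich, Wallace Tm near the 60 degree C annealing step)
#' while excluding degenerate designs.
#'
#' @param primer_len Integer range `c(min, max)` of primer lengths.
#' @param tm_range Wallace-Tm acceptance window, degrees C.
#' @param max_tm_spread Max Wallace-Tm spread across a panel, degrees C.
#' @param gc_range GC-fraction window.
#' @param max_homopolymer Longest tolerated single-base run.
#' @param min_diag_in_footprint Minimum diagnostic columns a reverse
#'   primer footprint must cover.
#' @param require_3prime_anchor Reverse primers must end on a diagnostic
#'   SNP (offset 0).
#' @param min_separation Minimum pairwise amplicon size difference, bp.
#' @param min_amplicon,max_amplicon Amplicon size bounds, bp.
#' @param dimer_threshold Max tolerated [dimer_score()] within a panel.
#' @return Object of class `design_config`.
#' @export
design_config <- function(primer_len = c(18L, 25L),
                          tm_range = c(56, 66),
                          max_tm_spread = 10,
                          gc_range = c(0.30, 0.65),
                          max_homopolymer = 4L,
                          min_diag_in_footprint = 1L,
                          require_3prime_anchor = TRUE,
                          min_separation = 25L,
                          min_amplicon = 80L,
                          max_amplicon = 1000L,
                          dimer_threshold = 8L) {
  stopifnot(primer_len[1] <= primer_len[2], tm_range[1] <= tm_range[2],
            gc_range[1] <= gc_range[2], min_separation > 0,
            min_amplicon <= max_amplicon)
  structure(
    list(primer_len = as.integer(primer_len), tm_range = tm_range,
         max_tm_spread = max_tm_spread, gc_range = gc_range,
         max_homopolymer = as.integer(max_homopolymer),
         min_diag_in_footprint = as.integer(min_diag_in_footprint),
         require_3prime_anchor = isTRUE(require_3prime_anchor),
         min_separation = as.integer(min_separation),
         min_amplicon = as.integer(min_amplicon),
         max_amplicon = as.integer(max_amplicon),
         dimer_threshold = as.integer(dimer_threshold)),
    class = "design_config"
  )
}

#' Construct a primer
#'
#' @param name Primer name.
#' @param sequence 5'->3' residue string, unambiguous, no gaps.
#' @param orientation `"forward"` or `"reverse"`.
#' @param target_species Species label, or `"universal"`.
#' @param footprint Optional 1-based inclusive alignment interval
#'   `c(start, end)` of the plus-strand region the primer covers (for
#'   reverse primers, the region whose reverse complement is the primer).
#' @param diagnostic_offsets 0-based distances from the 3' terminus to
#'   diagnostic columns inside the footprint (reverse primers).
#' @return Object of class `primer` carrying `tm_wallace`, `tm_nn` and
#'   `gc` attributes computed from the sequence.
#' @export
primer <- function(name, sequence, orientation, target_species = "universal",
                   footprint = NULL, diagnostic_offsets = integer(0)) {
  orientation <- match.arg(orientation, c("forward", "reverse"))
  sequence <- normalize_residues(sequence)
  unambiguous_chars(sequence)
  if (!is.null(footprint)) {
    stopifnot(length(footprint) == 2L,
              nchar(sequence) == footprint[2] - footprint[1] + 1L)
  }
  if (orientation == "reverse" && length(diagnostic_offsets) &&
      !(0L %in% diagnostic_offsets)) {
    stop("reverse primer '", name,
         "': diagnostic offsets must include the 3' terminus (offset 0)")
  }
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         target_species = target_species,
         footprint = if (is.null(footprint)) NULL else as.integer(footprint),
         tm_wallace = tm_wallace(sequence),
         tm_nn = if (nchar(sequence) >= 8L) tm_nearest_neighbor(sequence)
                 else NA_real_,
         gc = gc_content(sequence),
         diagnostic_offsets = sort(as.integer(diagnostic_offsets))),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s (%s, %s) %s  %dnt Tm(Wallace)=%g GC=%.2f\n",
              x$name, x$orientation, x$target_species, x$sequence,
              nchar(x$sequence), x$tm_wallace, x$gc))
  invisible(x)
}

passes_qc <- function(seq, cfg) {
  n <- nchar(seq)
  n >= cfg$primer_len[1] && n <= cfg$primer_len[2] &&
    {
      g <- gc_content(seq)
      g >= cfg$gc_range[1] && g <= cfg$gc_range[2]
    } &&
    {
      tm <- tm_wallace(seq)
      tm >= cfg$tm_range[1] && tm <= cfg$tm_range[2]
    } &&
    max_homopolymer(seq) <= cfg$max_homopolymer
}

#' Design universal forward primer candidates
#'
#' Enumerates every subsequence of every pan-species conserved window that
#' satisfies the length/Tm/GC/homopolymer constraints. Because the windows
#' are conserved across all species, each candidate matches every species
#' perfectly. Ranking: Wallace Tm closest to the midpoint of
#' `cfg$tm_range`, ties broken by leftmost footprint, then shortest.
#'
#' @param aln A [species_alignment].
#' @param windows Conserved windows from [find_conserved_windows()].
#' @param cfg A [design_config()].
#' @return List of forward [primer] objects, ranked; empty (with a
#'   `snap_warning` condition) when no window admits a primer.
#' @export
design_universal_forward <- function(aln, windows, cfg = design_config()) {
  ref <- aln$seqs[[1L]]
  cand <- list()
  for (k in seq_len(nrow(windows))) {
    ws <- windows$start[k]; we <- windows$end[k]
    for (L in seq(cfg$primer_len[1], cfg$primer_len[2])) {
      if (we - ws + 1L < L) next
      for (s in ws:(we - L + 1L)) {
        seq <- substr(ref, s, s + L - 1L)
        if (!passes_qc(seq, cfg)) next
        cand[[length(cand) + 1L]] <-
          primer(sprintf("F_%d_%d", s, s + L - 1L), seq, "forward",
                 "universal", footprint = c(s, s + L - 1L))
      }
    }
  }
  if (!length(cand)) {
    warning(structure(
      class = c("snap_warning", "warning", "condition"),
      list(message = "no conserved window admits a forward primer",
           call = sys.call())))
    return(list())
  }
  mid <- mean(cfg$tm_range)
  ord <- order(vapply(cand, function(p) abs(p$tm_wallace - mid), 0),
               vapply(cand, function(p) p$footprint[1], 0L),
               vapply(cand, function(p) nchar(p$sequence), 0L))
  cand[ord]
}

#' Design 3'-anchored species-specific reverse primer candidates
#'
#' A reverse primer anneals antiparallel to the plus strand, so its
#' 3'-terminal base pairs the *leftmost* column of its plus-strand
#' footprint and extension proceeds toward the forward primer. For each
#' diagnostic site `s` and each admissible length `L` the candidate's
#' footprint is therefore `[s, s+L-1]`: the primer is the reverse
#' complement of the target species' consensus over that footprint, its
#' 3'-terminal base pairs the target allele at `s`, and it mismatches
#' every non-target template exactly there — the allele-specific
#' blocking mechanism. Candidates crossing a consensus gap or leaving
#' the alignment are skipped; survivors are filtered by
#' Tm/GC/homopolymer and by the number of diagnostic columns covered,
#' then ranked by (diagnostic count desc, Tm closeness, leftmost
#' footprint). `diagnostic_offsets` are 0-based distances from the 3'
#' terminus, i.e. `site column - s`.
#'
#' @param aln A [species_alignment].
#' @param target Target species label.
#' @param sites Diagnostic sites for `target` from
#'   [find_diagnostic_sites()].
#' @param cfg A [design_config()].
#' @return List of reverse [primer] objects, ranked; empty (with a
#'   `snap_warning`) when nothing passes.
#' @export
design_species_reverse <- function(aln, target, sites,
                                   cfg = design_config()) {
  if (cfg$require_3prime_anchor && !nrow(sites)) {
    return(no_reverse(target))
  }
  cons <- species_consensus(aln, target)
  site_cols <- sites$column
  cand <- list()
  for (s in site_cols) {
    for (L in seq(cfg$primer_len[1], cfg$primer_len[2])) {
      end <- s + L - 1L
      if (end > aln$length) next
      foot <- substr(cons, s, end)
      if (grepl("-", foot, fixed = TRUE)) next
      if (any(!strsplit(foot, "")[[1L]] %in% c("A", "C", "G", "T"))) next
      seq <- revcomp(foot)
      if (!passes_qc(seq, cfg)) next
      offs <- site_cols[site_cols >= s & site_cols <= end] - s
      if (length(offs) < cfg$min_diag_in_footprint) next
      cand[[length(cand) + 1L]] <-
        primer(sprintf("R_%s_%d_%d", target, s, end), seq, "reverse",
               target, footprint = c(s, end), diagnostic_offsets = offs)
    }
  }
  if (!length(cand)) return(no_reverse(target))
  mid <- mean(cfg$tm_range)
  ord <- order(-vapply(cand, function(p) length(p$diagnostic_offsets), 0L),
               vapply(cand, function(p) abs(p$tm_wallace - mid), 0),
               vapply(cand, function(p) p$footprint[1], 0L))
  cand[ord]
}

no_reverse <- function(target) {
  warning(structure(
    class = c("snap_warning", "warning", "condition"),
    list(message = paste0("no admissible reverse primer for species '",
                          target, "'"),
         call = sys.call())))
  list()
}

#' Primer-dimer score
#'
#' Slides one primer against the other in every antiparallel annealing
#' register and returns the largest run of contiguous Watson-Crick pairs
#' found in any register (including a primer against itself). Symmetric.
#'
#' @param p,q [primer] objects or plain sequences.
#' @return Integer score; 0 when no register pairs at all.
#' @export
dimer_score <- function(p, q) {
  a <- strsplit(if (inherits(p, "primer")) p$sequence else
                  normalize_residues(p), "")[[1L]]
  b <- strsplit(if (inherits(q, "primer")) q$sequence else
                  normalize_residues(q), "")[[1L]]
  # antiparallel: pair a[i] against rev(b)[i] in every overlap register
  brc <- rev(unname(.IUPAC_COMPLEMENT[b]))
  na <- length(a); nb <- length(brc)
  best <- 0L
  for (shift in (-(nb - 1L)):(na - 1L)) {
    i <- max(1L, 1L + shift):min(na, nb + shift)
    j <- i - shift
    hits <- a[i] == brc[j]
    if (any(hits)) {
      r <- rle(hits)
      best <- max(best, max(r$lengths[r$values]))
    }
  }
  best
}

#' Expected amplicon size on a species' physical template
#'
#' Gel sizes are physical template lengths: the size is the number of
#' non-gap columns of the target species' consensus between the forward
#' footprint start and the reverse footprint end, inclusive.
#'
#' @param aln A [species_alignment].
#' @param species Target species.
#' @param fwd_start,rev_end 1-based alignment columns.
#' @return Expected size in bp.
#' @export
expected_amplicon_size <- function(aln, species, fwd_start, rev_end) {
  cons <- species_consensus(aln, species)
  span <- strsplit(substr(cons, fwd_start, rev_end), "")[[1L]]
  sum(span != "-")
}

#' Assemble a multiplex panel
#'
#' Deterministic greedy search: forward candidates are tried in rank
#' order; for each, species are visited in alphabetical order and the
#' first reverse candidate compatible with the partial panel is taken
#' (amplicon size within bounds, pairwise size separation, pairwise
#' dimer scores, Wallace-Tm spread). The first complete panel wins. On
#' failure a structured `snap_infeasible` condition is signalled naming
#' the constraint that blocked the most candidates.
#'
#' @param aln A [species_alignment].
#' @param forwards Ranked forward candidates.
#' @param reverses Named list: species -> ranked reverse candidates.
#' @param cfg A [design_config()].
#' @return Object of class `primer_panel`: `forward`, `reverses`
#'   (species -> primer), `expected_sizes` (species -> bp),
#'   `min_separation`.
#' @export
assemble_panel <- function(aln, forwards, reverses, cfg = design_config()) {
  if (!length(forwards)) infeasible("no forward primer candidates")
  if (!length(reverses) || any(!vapply(reverses, length, 0L))) {
    infeasible("a species has no reverse primer candidates")
  }
  sp_order <- sort(names(reverses))
  # gap-stripped sizing against each target's consensus, computed once
  cons_chars <- lapply(stats::setNames(nm = sp_order), function(sp) {
    strsplit(species_consensus(aln, sp), "", fixed = TRUE)[[1L]] != "-"
  })
  size_of <- function(sp, fwd_start, rev_end) {
    sum(cons_chars[[sp]][fwd_start:rev_end])
  }
  fail <- c(size_bounds = 0L, separation = 0L, dimer = 0L, tm_spread = 0L,
            orientation = 0L)
  for (fwd in forwards) {
    if (dimer_score(fwd, fwd) > cfg$dimer_threshold) {
      fail["dimer"] <- fail["dimer"] + 1L; next
    }
    chosen <- list(); sizes <- c(); ok <- TRUE
    tms <- fwd$tm_wallace
    for (sp in sp_order) {
      pick <- NULL
      for (rv in reverses[[sp]]) {
        if (rv$footprint[1] <= fwd$footprint[2]) {
          fail["orientation"] <- fail["orientation"] + 1L; next
        }
        size <- size_of(sp, fwd$footprint[1], rv$footprint[2])
        if (size < cfg$min_amplicon || size > cfg$max_amplicon) {
          fail["size_bounds"] <- fail["size_bounds"] + 1L; next
        }
        if (length(sizes) && min(abs(sizes - size)) < cfg$min_separation) {
          fail["separation"] <- fail["separation"] + 1L; next
        }
        ds <- vapply(c(list(fwd), chosen, list(rv)), dimer_score, 0L, q = rv)
        if (max(ds) > cfg$dimer_threshold) {
          fail["dimer"] <- fail["dimer"] + 1L; next
        }
        if (diff(range(c(tms, rv$tm_wallace))) > cfg$max_tm_spread) {
          fail["tm_spread"] <- fail["tm_spread"] + 1L; next
        }
        pick <- rv; break
      }
      if (is.null(pick)) { ok <- FALSE; break }
      chosen[[sp]] <- pick
      sizes <- c(sizes, stats::setNames(
        size_of(sp, fwd$footprint[1], pick$footprint[2]), sp))
      tms <- c(tms, pick$tm_wallace)
    }
    if (ok) {
      return(primer_panel(fwd, chosen, sizes,
                          min_separation = cfg$min_separation))
    }
  }
  binding <- names(fail)[which.max(fail)]
  infeasible(paste0("no feasible panel; binding constraint: ", binding),
             constraint = binding, counts = as.list(fail))
}

infeasible <- function(msg, constraint = NA_character_, counts = list()) {
  stop(structure(
    class = c("snap_infeasible", "error", "condition"),
    list(message = msg, call = sys.call(-1L),
         constraint = constraint, counts = counts)))
}

#' Construct a primer panel
#'
#' @param forward Forward [primer].
#' @param reverses Named list of reverse [primer]s (species -> primer).
#' @param expected_sizes Named numeric, species -> expected amplicon bp.
#' @param min_separation Minimum pairwise size separation the panel
#'   guarantees, bp.
#' @return Object of class `primer_panel`.
#' @export
primer_panel <- function(forward, reverses, expected_sizes,
                         min_separation = 25L) {
  stopifnot(inherits(forward, "primer"),
            forward$orientation == "forward",
            all(names(reverses) %in% names(expected_sizes)))
  sizes <- expected_sizes[sort(names(expected_sizes))]
  if (length(sizes) > 1L) {
    gaps <- diff(sort(sizes))
    if (any(gaps < min_separation)) {
      stop("panel amplicon sizes closer than min_separation (",
           min_separation, " bp)")
    }
  }
  structure(
    list(forward = forward, reverses = reverses[sort(names(reverses))],
         expected_sizes = sizes,
         min_separation = as.integer(min_separation)),
    class = "primer_panel"
  )
}

#' @export
print.primer_panel <- function(x, ...) {
  cat(sprintf("<primer_panel> %d species, ladder: %s (min sep %d bp)\n",
              length(x$reverses),
              paste(sort(x$expected_sizes), collapse = ", "),
              x$min_separation))
  invisible(x)
}

#' Write a panel as JSON
#'
#' @param panel A [primer_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_json <- function(panel, path) {
  ser <- function(p) {
    list(name = p$name, sequence = p$sequence, orientation = p$orientation,
         target_species = p$target_species, footprint = p$footprint,
         tm_wallace = p$tm_wallace, tm_nn = round(p$tm_nn, 3), gc = p$gc,
         diagnostic_offsets = p$diagnostic_offsets)
  }
  obj <- list(forward = ser(panel$forward),
              reverses = lapply(panel$reverses, ser),
              expected_sizes = as.list(panel$expected_sizes),
              min_separation = panel$min_separation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a panel from JSON written by [write_panel_json()]
#'
#' @param path JSON path.
#' @return A [primer_panel].
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path)
  de <- function(p) {
    primer(p$name, p$sequence, p$orientation, p$target_species,
           footprint = if (length(p$footprint)) unlist(p$footprint),
           diagnostic_offsets = unlist(p$diagnostic_offsets))
  }
  primer_panel(de(obj$forward), lapply(obj$reverses, de),
               unlist(obj$expected_sizes),
               min_separation = obj$min_separation)
}

#' Write a panel as a primer TSV
#'
#' Columns mirror the published panel table: `Primer`, `Specificity`,
#' `Primer.Sequence.5.3` and `Size.bp`.
#'
#' @param panel A [primer_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  rows <- rbind(
    data.frame(Primer = panel$forward$name, Specificity = "All",
               Sequence = panel$forward$sequence, Size = NA_integer_),
    do.call(rbind, lapply(names(panel$reverses), function(sp) {
      data.frame(Primer = panel$reverses[[sp]]$name, Specificity = sp,
                 Sequence = panel$reverses[[sp]]$sequence,
                 Size = panel$expected_sizes[[sp]])
    }))
  )
  names(rows) <- c("Primer", "Specificity", "Primer Sequence (5'-3')",
                   "Size (bp)")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a panel from a primer TSV
#'
#' Accepts the four-column layout written by [write_panel_tsv()] (one row
#' with specificity `All`/`universal` = the forward primer; every other
#' row a species-specific reverse with its expected size). Footprints and
#' diagnostic offsets are alignment-specific and are not stored in the
#' TSV.
#'
#' @param path TSV path.
#' @return A [primer_panel].
#' @export
read_panel_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  names(tab) <- c("Primer", "Specificity", "Sequence", "Size")
  is_fwd <- tolower(tab$Specificity) %in% c("all", "universal")
  if (sum(is_fwd) != 1L) stop("panel TSV needs exactly one universal row")
  fwd <- primer(tab$Primer[is_fwd], tab$Sequence[is_fwd], "forward")
  rev_rows <- which(!is_fwd)
  reverses <- stats::setNames(lapply(rev_rows, function(i) {
    primer(tab$Primer[i], tab$Sequence[i], "reverse", tab$Specificity[i])
  }), tab$Specificity[rev_rows])
  sizes <- stats::setNames(as.integer(tab$Size[rev_rows]),
                           tab$Specificity[rev_rows])
  min_sep <- if (length(sizes) > 1L) min(diff(sort(sizes))) else 1L
  primer_panel(fwd, reverses, sizes, min_separation = min_sep)
}
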