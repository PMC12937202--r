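# Synthetic species-labelled alignments with planted ground truth:
# a pan-species conserved window (forward-primer real estate), per-species
# diagnostic SNP blocks whose 3'-most sites form an amplicon size ladder,
# controlled background interspecific divergence, and intraspecific
# haplotype noise. Everything is seeded and byte-reproducible.

#' Specification of a synthetic species panel
#'
#' Defaults emulate the published five-species onchidiid COI world: five
#' species, 30 haplotypes each (the study validated 30 individuals per
#' species), a 658-column barcode, 8 planted diagnostic sites per species
#' (the published primers carry 7-9), a 30-column conserved window for
#' the universal forward primer, substantial interspecific background
#' divergence, and low intraspecific noise that never touches planted
#' sites (the study observed none at primer sites).
#'
#' Planted diagnostic sites for species *i* are laid out in a block whose
#' 3'-most column sits at `window_end + 80 + (i-1) * ladder_spacing`,
#' with sites every `diag_site_step` columns upstream — so the species
#' ladder is feasible by construction.
#'
#' @param n_species Number of species (>= 2).
#' @param haplotypes_per_species Records per species.
#' @param length Alignment columns.
#' @param n_diag_per_species Planted diagnostic sites per species.
#' @param conserved_window `c(start, length)` of the planted conserved
#'   window.
#' @param background_divergence Per-column probability (outside planted
#'   regions) that one species is reassigned a different base.
#' @param intraspecific_rate Per-column, per-haplotype substitution
#'   probability outside planted regions.
#' @param ladder_spacing Distance between consecutive species' diagnostic
#'   block anchors, bp; sets the amplicon ladder spacing.
#' @param diag_site_step Spacing of planted sites within a block.
#' @param seed Integer seed (required; byte-identical output per seed).
#' @return Object of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_species = 5L,
                                 haplotypes_per_species = 30L,
                                 length = 658L,
                                 n_diag_per_species = 8L,
                                 conserved_window = c(101L, 30L),
                                 background_divergence = 0.10,
                                 intraspecific_rate = 0.005,
                                 ladder_spacing = 90L,
                                 diag_site_step = 3L,
                                 seed) {
  if (missing(seed)) stop("a seed is required")
  spec <- structure(
    list(n_species = as.integer(n_species),
         haplotypes_per_species = as.integer(haplotypes_per_species),
         length = as.integer(length),
         n_diag_per_species = as.integer(n_diag_per_species),
         conserved_window = as.integer(conserved_window),
         background_divergence = background_divergence,
         intraspecific_rate = intraspecific_rate,
         ladder_spacing = as.integer(ladder_spacing),
         diag_site_step = as.integer(diag_site_step),
         seed = as.integer(seed)),
    class = "synthetic_panel_spec"
  )
  stopifnot(spec$n_species >= 2L, spec$haplotypes_per_species >= 1L,
            spec$background_divergence >= 0, spec$background_divergence <= 1,
            spec$intraspecific_rate >= 0, spec$intraspecific_rate <= 1)
  planted_layout(spec)  # errors early on overflow
  spec
}

# Deterministic planted-region layout; errors if regions overflow or
# collide.
planted_layout <- function(spec) {
  ws <- spec$conserved_window[1L]
  we <- ws + spec$conserved_window[2L] - 1L
  if (ws < 1L || we > spec$length) stop("conserved window overflows alignment")
  block_span <- spec$diag_site_step * (spec$n_diag_per_species - 1L)
  anchors <- we + 80L + (seq_len(spec$n_species) - 1L) * spec$ladder_spacing
  starts <- anchors - block_span
  if (block_span >= spec$ladder_spacing) {
    stop("diagnostic blocks overlap: increase ladder_spacing")
  }
  if (starts[1L] <= we) stop("first diagnostic block overlaps the window")
  if (anchors[spec$n_species] > spec$length) {
    stop("planted regions overflow the alignment length")
  }
  sites <- lapply(anchors, function(a) {
    sort(a - spec$diag_site_step * (seq_len(spec$n_diag_per_species) - 1L))
  })
  list(window = c(ws, we), anchors = anchors, sites = sites)
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    })
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic species panel with ground truth
#'
#' @param spec A [synthetic_panel_spec()].
#' @return List with `alignment` (a [species_alignment]) and `truth`, a
#'   list holding `diag_sites_by_species` (species -> data.frame of
#'   `column`, `allele`) and `conserved_windows` (data.frame
#'   `start`/`end`). Every truth site satisfies the diagnostic-site
#'   definition and the truth window is conserved across all records, by
#'   construction.
#' @export
generate_species_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  layout <- planted_layout(spec)
  bases <- c("A", "C", "G", "T")
  with_local_seed(spec$seed, {
    L <- spec$length; K <- spec$n_species
    species <- sprintf("sp%02d", seq_len(K))
    base_seq <- sample(bases, L, replace = TRUE)
    cons <- matrix(rep(base_seq, each = K), nrow = K,
                   dimnames = list(species, NULL))
    diag_cols <- sort(unlist(layout$sites))
    window_cols <- layout$window[1L]:layout$window[2L]
    protected <- c(window_cols, diag_cols)
    # background interspecific divergence: one species reassigned per hit
    free_cols <- setdiff(seq_len(L), protected)
    hit <- free_cols[stats::runif(length(free_cols)) <
                       spec$background_divergence]
    for (j in hit) {
      k <- sample.int(K, 1L)
      cons[k, j] <- sample(setdiff(bases, cons[k, j]), 1L)
    }
    # planted diagnostics: target gets a base absent from all others
    truth_sites <- vector("list", K)
    for (i in seq_len(K)) {
      cols <- layout$sites[[i]]
      alleles <- character(length(cols))
      for (t in seq_along(cols)) {
        j <- cols[t]
        alleles[t] <- sample(setdiff(bases, cons[, j]), 1L)
        cons[i, j] <- alleles[t]
      }
      truth_sites[[i]] <- data.frame(column = cols, allele = alleles)
    }
    names(truth_sites) <- species
    # haplotypes: consensus + intraspecific noise outside planted regions
    records <- list()
    for (i in seq_len(K)) {
      for (h in seq_len(spec$haplotypes_per_species)) {
        s <- cons[i, ]
        if (spec$intraspecific_rate > 0) {
          mut <- free_cols[stats::runif(length(free_cols)) <
                             spec$intraspecific_rate]
          for (j in mut) s[j] <- sample(setdiff(bases, s[j]), 1L)
        }
        records[[length(records) + 1L]] <- sequence_record(
          sprintf("%s_h%02d", species[i], h), paste(s, collapse = ""),
          species = species[i]
        )
      }
    }
    list(
      alignment = species_alignment(records),
      truth = list(
        diag_sites_by_species = truth_sites,
        conserved_windows = data.frame(start = layout$window[1L],
                                       end = layout$window[2L])
      )
    )
  })
}

#' Add intraspecific haplotype noise to an existing alignment
#'
#' Substitutions are confined to columns outside every truth diagnostic
#' site (of any species) and outside the truth conserved windows, so the
#' planted truth remains valid afterwards.
#'
#' @param aln A [species_alignment].
#' @param truth Truth list from [generate_species_panel()].
#' @param rate Per-column, per-haplotype substitution probability.
#' @param seed Integer seed.
#' @return A new [species_alignment] with the same ids and species.
#' @export
spike_intraspecific_variants <- function(aln, truth, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(aln)
  bases <- c("A", "C", "G", "T")
  protected <- unique(c(
    unlist(lapply(truth$diag_sites_by_species, `[[`, "column")),
    unlist(mapply(seq, truth$conserved_windows$start,
                  truth$conserved_windows$end, SIMPLIFY = FALSE))
  ))
  free_cols <- setdiff(seq_len(aln$length), protected)
  with_local_seed(seed, {
    records <- lapply(aln$ids, function(id) {
      s <- strsplit(aln$seqs[[id]], "", fixed = TRUE)[[1L]]
      mut <- free_cols[stats::runif(length(free_cols)) < rate]
      mut <- mut[s[mut] %in% bases]
      for (j in mut) s[j] <- sample(setdiff(bases, s[j]), 1L)
      sequence_record(id, paste(s, collapse = ""),
                      species = aln$species[[id]])
    })
    species_alignment(records)
  })
}

#' Per-species consensus templates of an alignment
#'
#' Convenience for closed-loop validation: one ungapped
#' [sequence_record] per species, built from [species_consensus()] with
#' gap columns stripped.
#'
#' @param aln A [species_alignment].
#' @return List of [sequence_record]s, one per species, ids
#'   `<species>_consensus`.
#' @export
consensus_templates <- function(aln) {
  lapply(names(aln$species_index), function(sp) {
    cons <- species_consensus(aln, sp, strip_gaps = TRUE)
    sequence_record(paste0(sp, "_consensus"), cons$sequence, species = sp,
                    allow_gaps = FALSE)
  })
}
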