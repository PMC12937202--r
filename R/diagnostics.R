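# Diagnostic-SNP and conserved-window discovery on species-labelled
# alignments.
#
# A column is diagnostic for a target species when (i) the target is fixed
# for a single unambiguous base there, (ii) that base is absent from every
# other species' observed allele set (ambiguity codes in non-targets count
# as every base they encode), and (iii) no record has a gap in the column.
# Non-target species need not themselves be fixed: a single terminal
# mismatch against every non-target template is all the 3'-anchored primer
# needs.

#' Profile every alignment column
#'
#' @param aln A [species_alignment].
#' @return A list with one profile per column, each a list holding `column`
#'   (1-based index), `alleles_by_species` (species -> sorted set of
#'   observed non-gap symbols), `has_gap`, and `conserved_all` (`TRUE` iff
#'   one identical unambiguous symbol across every record).
#' @export
build_column_profiles <- function(aln) {
  stopifnot(inherits(aln, "species_alignment"))
  m <- alignment_matrix(aln)
  sp_rows <- lapply(aln$species_index, function(ids) m[ids, , drop = FALSE])
  lapply(seq_len(aln$length), function(j) {
    col <- m[, j]
    alleles <- lapply(sp_rows, function(rows) {
      sort(unique(rows[, j][rows[, j] != "-"]))
    })
    uniq <- unique(col)
    list(
      column = j,
      alleles_by_species = alleles,
      has_gap = "-" %in% uniq,
      conserved_all = length(uniq) == 1L && uniq %in% c("A", "C", "G", "T")
    )
  })
}

#' Find fixed species-specific SNP columns
#'
#' @param profiles Output of [build_column_profiles()].
#' @param target Target species label.
#' @return A data.frame with one row per diagnostic site, sorted by column:
#'   `column`, `target_species`, `target_allele`, plus a list-column
#'   `other_alleles` (per-species allele sets at the column).
#' @export
find_diagnostic_sites <- function(profiles, target) {
  if (!length(profiles)) return(empty_sites(target))
  species <- names(profiles[[1L]]$alleles_by_species)
  if (!(target %in% species)) stop("unknown species: ", target)
  rows <- lapply(profiles, function(p) {
    if (p$has_gap) return(NULL)
    ta <- p$alleles_by_species[[target]]
    # target must be fixed for one unambiguous base
    if (length(ta) != 1L || !(ta %in% c("A", "C", "G", "T"))) return(NULL)
    others <- p$alleles_by_species[setdiff(species, target)]
    # ambiguity in a non-target counts as every base it encodes
    other_bases <- unique(unlist(lapply(unlist(others), function(s) {
      .IUPAC_SETS[[s]]
    })))
    if (ta %in% other_bases) return(NULL)
    list(column = p$column, allele = ta, others = others)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty_sites(target))
  out <- data.frame(
    column = vapply(rows, `[[`, integer(1), "column"),
    target_species = target,
    target_allele = vapply(rows, `[[`, "", "allele"),
    stringsAsFactors = FALSE
  )
  out$other_alleles <- I(lapply(rows, `[[`, "others"))
  out[order(out$column), , drop = FALSE]
}

empty_sites <- function(target) {
  out <- data.frame(column = integer(0), target_species = character(0),
                    target_allele = character(0), stringsAsFactors = FALSE)
  out$other_alleles <- I(list())
  out
}

#' Find maximal pan-species conserved windows
#'
#' Maximal runs of consecutive columns with `conserved_all = TRUE` and
#' length at least `min_len`.
#'
#' @param profiles Output of [build_column_profiles()].
#' @param min_len Minimum window length (columns), >= 1.
#' @return A data.frame with 1-based inclusive `start`/`end` columns,
#'   sorted by `start`.
#' @export
find_conserved_windows <- function(profiles, min_len) {
  stopifnot(min_len >= 1)
  cons <- vapply(profiles, `[[`, logical(1), "conserved_all")
  r <- rle(cons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Tabulate diagnostic sites for every species
#'
#' @param aln A [species_alignment].
#' @return Combined data.frame of [find_diagnostic_sites()] results over
#'   all species in `aln`.
#' @export
scan_alignment <- function(aln) {
  profiles <- build_column_profiles(aln)
  res <- lapply(names(aln$species_index), function(sp) {
    find_diagnostic_sites(profiles, sp)
  })
  do.call(rbind, res)
}

#' Write diagnostic sites as TSV
#'
#' Columns: species, column (1-based), allele, and a per-species allele
#' summary `sp1=AC;sp2=G;...`.
#'
#' @param sites Data.frame from [find_diagnostic_sites()]/[scan_alignment()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  summ <- vapply(seq_len(nrow(sites)), function(i) {
    oth <- sites$other_alleles[[i]]
    paste(sprintf("%s=%s", names(oth),
                  vapply(oth, paste, "", collapse = "")), collapse = ";")
  }, "")
  out <- data.frame(species = sites$target_species, column = sites$column,
                    allele = sites$target_allele, other_alleles = summ)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write conserved windows as a BED-like file
#'
#' Internal coordinates are 1-based inclusive; the file uses BED convention
#' (0-based half-open), i.e. `start-1`, `end`.
#'
#' @param windows Data.frame from [find_conserved_windows()].
#' @param path Output path.
#' @param name Region name prefix.
#' @return `path`, invisibly.
#' @export
write_windows_bed <- function(windows, path, name = "conserved") {
  out <- data.frame(chrom = "alignment",
                    start = windows$start - 1L,
                    end = windows$end,
                    name = sprintf("%s_%d", name, seq_len(nrow(windows))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
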