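# Sequence I/O, IUPAC nucleotide handling, species labelling.
#
# Internal alphabet: upper-case IUPAC nucleotide symbols with U normalised
# to T on input; '-' is the gap symbol, allowed in alignments but never in
# primers or PCR templates.

# IUPAC symbol -> set of encoded bases
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

# 4-bit encoding (A=1, C=2, G=4, T=8); compatibility = nonzero bitwAnd.
.IUPAC_BITS <- vapply(.IUPAC_SETS, function(b) {
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b])
}, integer(1))

.iupac_symbols <- names(.IUPAC_SETS)

#' Create a sequence record
#'
#' A lightweight container for one nucleotide sequence with an identifier,
#' an optional species label, and a free-text description.
#'
#' @param id Record identifier (unique within a file).
#' @param residues Residue string over the IUPAC nucleotide alphabet;
#'   `U` is normalised to `T` and letters are upper-cased. Gaps (`-`) are
#'   allowed (alignments) unless `allow_gaps = FALSE`.
#' @param species Species label; `""` for anonymous templates.
#' @param description Free-text description.
#' @param allow_gaps Whether `-` is a legal symbol in `residues`.
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, species = "", description = "",
                            allow_gaps = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- normalize_residues(residues)
  validate_residues(residues, id = id, allow_gaps = allow_gaps)
  structure(
    list(id = id, species = species, residues = residues,
         description = description),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s [%s] %d nt\n", x$id,
              if (nzchar(x$species)) x$species else "unlabelled",
              nchar(x$residues)))
  invisible(x)
}

normalize_residues <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chartr("u", "T", chartr("U", "T", toupper(residues)))
}

validate_residues <- function(residues, id = "<seq>", allow_gaps = TRUE) {
  if (!nzchar(residues)) stop("record '", id, "': empty sequence")
  legal <- c(.iupac_symbols, if (allow_gaps) "-")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% legal))
  if (length(bad)) {
    stop("record '", id, "': illegal character '", chars[bad[1L]],
         "' at position ", bad[1L])
  }
  invisible(TRUE)
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; on top of it the
#' reader normalises case and `U`->`T`, validates every residue against the
#' IUPAC alphabet (naming record and position on failure), rejects duplicate
#' ids, and attaches species labels. Label precedence: explicit
#' `species_map` > a `species=<label>` token in the header > empty.
#'
#' @param path FASTA file path.
#' @param species_map Optional named character vector or two-column
#'   data.frame (record id, species) mapping every record id to a species.
#' @param allow_gaps Whether `-` is legal (alignment input). Default `TRUE`.
#' @return List of [sequence_record] objects.
#' @export
read_fasta <- function(path, species_map = NULL, allow_gaps = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first)) return(list())
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA in '", path, "': line ", first,
         " does not start a record ('>' expected)")
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record id '", ids[duplicated(ids)][1L], "' in ", path)
  }
  if (!is.null(species_map)) {
    species_map <- as_species_map(species_map)
    missing <- setdiff(ids, names(species_map))
    if (length(missing)) {
      stop("species map lacks entries for: ",
           paste(missing, collapse = ", "))
    }
  }
  lapply(seq_along(set), function(i) {
    desc <- sub("^\\S+\\s*", "", headers[i])
    sp <- if (!is.null(species_map)) {
      unname(species_map[[ids[i]]])
    } else {
      m <- regmatches(desc, regexpr("species=\\S+", desc))
      if (length(m)) sub("^species=", "", m) else ""
    }
    sequence_record(ids[i], as.character(set[[i]]), species = sp,
                    description = desc, allow_gaps = allow_gaps)
  })
}

as_species_map <- function(species_map) {
  if (is.data.frame(species_map)) {
    stats::setNames(as.character(species_map[[2L]]),
                    as.character(species_map[[1L]]))
  } else if (is.character(species_map) && !is.null(names(species_map))) {
    species_map
  } else {
    stop("species_map must be a named character vector or 2-column data.frame")
  }
}

#' Read a two-column record-id/species TSV map
#'
#' @param path TSV path, no header, columns `record_id` and `species`.
#' @return Named character vector: record id -> species label.
#' @export
read_species_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("record_id", "species"))
  if (anyDuplicated(tab$record_id)) {
    stop("duplicate record id in species map: ",
         tab$record_id[duplicated(tab$record_id)][1L])
  }
  stats::setNames(tab$species, tab$record_id)
}

#' Write sequence records to FASTA
#'
#' Headers are serialised canonically as `>id species=<label>` (label
#' omitted when empty); sequences are written verbatim.
#'
#' @param records List of [sequence_record] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$species)) paste0(r$id, " species=", r$species) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Reverse-complement an IUPAC nucleotide string
#'
#' Ambiguity codes map to their complements (R<->Y, S<->S, W<->W, K<->M,
#' B<->V, D<->H, N<->N). Gaps are rejected: the operation is defined for
#' primers and templates, not alignment rows.
#'
#' @param seq Residue string (no gaps).
#' @return The reverse complement, 5'->3'.
#' @export
revcomp <- function(seq) {
  seq <- normalize_residues(seq)
  validate_residues(seq, allow_gaps = FALSE)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Do two IUPAC symbols share a base?
#'
#' `TRUE` iff the base sets encoded by `a` and `b` intersect (e.g. A vs R is
#' `TRUE`, A vs Y is `FALSE`). Vectorised over equal-length inputs.
#'
#' @param a,b IUPAC nucleotide symbols (no gaps).
#' @return Logical.
#' @export
iupac_compatible <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(a == "-") || any(b == "-")) stop("gap symbol has no base set")
  ba <- .IUPAC_BITS[a]; bb <- .IUPAC_BITS[b]
  if (anyNA(ba) || anyNA(bb)) stop("not an IUPAC nucleotide symbol")
  bitwAnd(ba, bb) > 0L
}

# residue string -> integer bitmask vector (gap -> 0)
residue_bits <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bits <- .IUPAC_BITS[chars]
  bits[chars == "-"] <- 0L
  unname(bits)
}

#' Assemble a species-labelled alignment
#'
#' @param records List of [sequence_record] objects of identical length,
#'   each carrying a non-empty species label; at least two species.
#' @return Object of class `species_alignment` with fields `ids`, `species`
#'   (named by id), `seqs` (named residue vector), `length` (columns,
#'   1-based), and `species_index` (species -> record ids).
#' @export
species_alignment <- function(records) {
  if (!length(records)) stop("empty alignment")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate record ids in alignment")
  species <- vapply(records, `[[`, "", "species")
  if (any(!nzchar(species))) {
    stop("record '", ids[!nzchar(species)][1L], "' has no species label")
  }
  lens <- vapply(records, function(r) nchar(r$residues), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("records differ in length: alignment required")
  }
  if (length(unique(species)) < 2L) {
    stop("an alignment of at least 2 species is required")
  }
  seqs <- stats::setNames(vapply(records, `[[`, "", "residues"), ids)
  structure(
    list(ids = ids, species = stats::setNames(species, ids), seqs = seqs,
         length = lens[[1L]],
         species_index = split(ids, species)),
    class = "species_alignment"
  )
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("<species_alignment> %d records / %d species / %d columns\n",
              length(x$ids), length(x$species_index), x$length))
  invisible(x)
}

# records x columns character matrix
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Per-species consensus sequence
#'
#' Majority symbol per column among the species' records; ties break to the
#' alphabetically smallest symbol (gap sorts last, so a gap wins only by
#' strict majority). Deterministic.
#'
#' @param aln A [species_alignment].
#' @param species Species label present in `aln`.
#' @param strip_gaps Drop gap columns from the returned string.
#' @return If `strip_gaps = FALSE`, the consensus string (may contain `-`);
#'   otherwise a list with `sequence` (gap-free) and `columns` (the 1-based
#'   alignment columns each retained base came from).
#' @export
species_consensus <- function(aln, species, strip_gaps = FALSE) {
  ids <- aln$species_index[[species]]
  if (is.null(ids)) stop("unknown species: ", species)
  m <- do.call(rbind, strsplit(unname(aln$seqs[ids]), "", fixed = TRUE))
  cons <- apply(m, 2L, function(col) {
    tab <- table(col)
    cand <- names(tab)[tab == max(tab)]
    nongap <- setdiff(cand, "-")
    if (length(nongap)) sort(nongap)[1L] else "-"
  })
  if (!strip_gaps) return(paste(cons, collapse = ""))
  keep <- which(cons != "-")
  list(sequence = paste(cons[keep], collapse = ""), columns = keep)
}
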