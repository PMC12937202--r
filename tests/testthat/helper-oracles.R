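# Independent oracles, kept deliberately separate from the package's
# implementation: set arithmetic is done via Biostrings::IUPAC_CODE_MAP
# (the package uses its own bitmask tables).

iupac_set <- function(sym) {
  if (sym %in% c("A", "C", "G", "T")) return(sym)
  strsplit(unname(Biostrings::IUPAC_CODE_MAP[sym]), "")[[1]]
}

# brute-force diagnostic-site derivation, column by column
oracle_diag_sites <- function(seqs, species, target) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  hits <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    if (any(col == "-")) next
    tset <- unique(col[species == target])
    if (length(tset) != 1 || !(tset %in% c("A", "C", "G", "T"))) next
    other <- unique(unlist(lapply(col[species != target], iupac_set)))
    if (tset %in% other) next
    hits[[length(hits) + 1]] <- data.frame(column = j, allele = tset)
  }
  if (!length(hits)) {
    return(data.frame(column = integer(0), allele = character(0)))
  }
  do.call(rbind, hits)
}

# brute-force conserved-window derivation
oracle_conserved_windows <- function(seqs, min_len) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  cons <- apply(mat, 2, function(col) {
    u <- unique(col)
    length(u) == 1 && u %in% c("A", "C", "G", "T")
  })
  out <- list()
  j <- 1
  while (j <= length(cons)) {
    if (cons[j]) {
      k <- j
      while (k < length(cons) && cons[k + 1]) k <- k + 1
      if (k - j + 1 >= min_len) {
        out[[length(out) + 1]] <- c(j, k)
      }
      j <- k + 1
    } else {
      j <- j + 1
    }
  }
  out
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# position-by-position binding-site scorer; returns, per placement on
# each strand, the 0-based mismatch offsets from the primer 3' end
oracle_binding <- function(template, primer_seq, max_mm) {
  tmpl <- strsplit(template, "")[[1]]
  pr <- strsplit(primer_seq, "")[[1]]
  L <- length(pr); N <- length(tmpl)
  res <- list()
  if (L > N) return(res)
  for (strand in c("plus", "minus")) {
    for (s in 1:(N - L + 1)) {
      offs <- integer(0)
      for (k in 0:(L - 1)) {
        # offset k from the 3' end of the primer
        pchar <- pr[L - k]
        tchar <- if (strand == "plus") {
          tmpl[s + L - 1 - k]
        } else {
          # primer anneals to the minus strand: its base at offset k
          # faces the complement of plus-strand position s + k
          comp_base[[tmpl[s + k]]]
        }
        if (!length(intersect(iupac_set(pchar), iupac_set(tchar)))) {
          offs <- c(offs, k)
        }
      }
      if (length(offs) <= max_mm) {
        res[[length(res) + 1]] <- list(strand = strand, start = s,
                                       offsets = sort(offs))
      }
    }
  }
  res
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# random species-labelled alignment (valid: >= 2 species, equal lengths)
random_alignment <- function(max_species = 5, max_records = 12,
                             max_cols = 60, gap_prob = 0.02,
                             ambig_prob = 0.02) {
  n_sp <- sample(2:max_species, 1)
  n_rec <- sample(n_sp:max_records, 1)
  L <- sample(10:max_cols, 1)
  species <- sprintf("sp%d", c(seq_len(n_sp),
                               sample(n_sp, n_rec - n_sp, replace = TRUE)))
  alphabet <- c("A", "C", "G", "T")
  extras <- c("R", "Y", "S", "W", "K", "M", "N")
  seqs <- vapply(seq_len(n_rec), function(i) {
    chars <- sample(alphabet, L, replace = TRUE)
    amb <- runif(L) < ambig_prob
    chars[amb] <- sample(extras, sum(amb), replace = TRUE)
    gap <- runif(L) < gap_prob
    chars[gap] <- "-"
    paste(chars, collapse = "")
  }, "")
  records <- lapply(seq_len(n_rec), function(i) {
    sequence_record(sprintf("r%02d", i), seqs[i], species = species[i])
  })
  list(aln = species_alignment(records), seqs = seqs, species = species)
}

toy_records <- function() {
  list(
    sequence_record("a1", "ACGTACGT", species = "A"),
    sequence_record("a2", "ACGTACGT", species = "A"),
    sequence_record("b1", "ACGAACGT", species = "B"),
    sequence_record("b2", "ACGAACGT", species = "B"),
    sequence_record("c1", "ACGCACGA", species = "C")
  )
}

toy_alignment <- function() species_alignment(toy_records())
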