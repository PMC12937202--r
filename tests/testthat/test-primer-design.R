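# A 5-species synthetic alignment (seeded) is the main design substrate;
# tiny hand-built alignments cover the footprint arithmetic.

panel_fingerprint <- function(panel) {
  c(panel$forward$sequence,
    vapply(panel$reverses, `[[`, "", "sequence"),
    panel$expected_sizes)
}

small_cfg <- function(...) {
  design_config(primer_len = c(5L, 8L), tm_range = c(10, 40),
                gc_range = c(0, 1), max_homopolymer = 8L,
                min_amplicon = 10L, max_amplicon = 200L,
                min_separation = 5L, ...)
}

test_that("primer objects validate invariants", {
  p <- primer("p1", "ACGTACGTAC", "forward", footprint = c(11, 20))
  expect_equal(p$tm_wallace, tm_wallace("ACGTACGTAC"))
  expect_error(primer("bad", "ACGTACGTAC", "forward", footprint = c(1, 5)))
  expect_error(
    primer("bad", "ACGTACGTAC", "reverse", diagnostic_offsets = c(2, 4)),
    "offset 0"
  )
})

test_that("universal forward candidates stay inside conserved windows", {
  set.seed(3)
  window <- random_dna(30)
  flank1 <- random_dna(10)
  # force divergence outside the window
  recs <- lapply(1:4, function(i) {
    sequence_record(sprintf("r%d", i),
                    paste0(substr("ACGT", i, i), flank1, window,
                           substr("TGCA", i, i)),
                    species = sprintf("sp%d", i))
  })
  aln <- species_alignment(recs)
  profiles <- build_column_profiles(aln)
  cfg <- small_cfg()
  windows <- find_conserved_windows(profiles, cfg$primer_len[1])
  cands <- design_universal_forward(aln, windows, cfg)
  expect_gt(length(cands), 0)
  for (p in cands) {
    inside <- any(p$footprint[1] >= windows$start &
                    p$footprint[2] <= windows$end)
    expect_true(inside)
    expect_equal(substr(aln$seqs[[1]], p$footprint[1], p$footprint[2]),
                 p$sequence)
  }
  # ranking: Tm closeness to window midpoint, leftmost tiebreak
  mid <- mean(cfg$tm_range)
  dev <- vapply(cands, function(p) abs(p$tm_wallace - mid), 0)
  expect_true(all(diff(dev) >= 0))

  # no window long enough -> empty with warning
  expect_warning(
    empty <- design_universal_forward(aln, windows[0, ], cfg),
    class = "snap_warning"
  )
  expect_length(empty, 0)
})

test_that("reverse design anchors the diagnostic SNP at the 3' terminus", {
  # toy alignment: target C has sites at columns 4 (C) and 8 (A)
  aln <- toy_alignment()
  sites <- find_diagnostic_sites(build_column_profiles(aln), "C")
  cfg <- design_config(primer_len = c(5L, 5L), tm_range = c(0, 100),
                       gc_range = c(0, 1), max_homopolymer = 8)
  cands <- design_species_reverse(aln, "C", sites, cfg)
  # anchor site col 4, L = 5: plus-strand footprint [4,8] of C's
  # consensus ACGCACGA -> "CACGA"; primer = revcomp = TCGTG; the 3'
  # base G pairs C's allele at col 4; offsets {0, 4} (cols 4 and 8)
  hit <- Filter(function(p) p$footprint[1] == 4 && p$footprint[2] == 8,
                cands)
  expect_length(hit, 1)
  expect_equal(hit[[1]]$sequence, "TCGTG")
  expect_equal(hit[[1]]$diagnostic_offsets, c(0L, 4L))
  # every candidate is 3'-anchored: its last (3') base pairs the target
  # allele at the footprint's leftmost column
  for (p in cands) {
    expect_true(0L %in% p$diagnostic_offsets)
    allele <- sites$target_allele[sites$column == p$footprint[1]]
    L <- nchar(p$sequence)
    expect_equal(substr(p$sequence, L, L), revcomp(allele))
  }
  # no sites + required anchor -> empty with warning
  expect_warning(
    none <- design_species_reverse(aln, "C", sites[0, ], cfg),
    class = "snap_warning"
  )
  expect_length(none, 0)
})

test_that("reverse design skips footprints crossing gaps or the edge", {
  aln <- species_alignment(list(
    sequence_record("x1", "AC-TACGT", species = "X"),
    sequence_record("y1", "GC-TACGT", species = "Y")
  ))
  sites <- find_diagnostic_sites(build_column_profiles(aln), "X")
  expect_equal(sites$column, 1L)
  cfg <- design_config(primer_len = c(7L, 8L), tm_range = c(0, 100),
                       gc_range = c(0, 1))
  # L=7 footprint [1,7] and L=8 footprint [1,8] both cross the gap at 3
  expect_warning(cands <- design_species_reverse(aln, "X", sites, cfg),
                 class = "snap_warning")
  expect_length(cands, 0)
  # and a site too close to the alignment edge is skipped, not an error
  aln2 <- species_alignment(list(
    sequence_record("x1", "ACGTACGT", species = "X"),
    sequence_record("y1", "ACGTACGA", species = "Y")
  ))
  s2 <- find_diagnostic_sites(build_column_profiles(aln2), "X")
  expect_equal(s2$column, 8L)  # footprint [8, 14+] leaves the alignment
  expect_warning(none <- design_species_reverse(aln2, "X", s2, cfg),
                 class = "snap_warning")
  expect_length(none, 0)
})

test_that("dimer_score: hand cases, symmetry, self-dimer", {
  expect_equal(dimer_score("AAAA", "TTTT"), 4)
  expect_equal(dimer_score("AAAA", "AAAA"), 0)
  # GCGC against itself anneals fully in the aligned register
  expect_equal(dimer_score("GCGC", "GCGC"), 4)
  set.seed(19)
  for (i in 1:50) {
    p <- random_dna(sample(4:20, 1)); q <- random_dna(sample(4:20, 1))
    expect_identical(dimer_score(p, q), dimer_score(q, p))
  }
})

test_that("assemble_panel returns a feasible panel and honors separation", {
  sim <- generate_species_panel(
    synthetic_panel_spec(haplotypes_per_species = 4, seed = 42))
  aln <- sim$alignment
  cfg <- design_config()
  profiles <- build_column_profiles(aln)
  sites <- scan_alignment(aln)
  fw <- design_universal_forward(
    aln, find_conserved_windows(profiles, cfg$primer_len[1]), cfg)
  rv <- lapply(setNames(nm = names(aln$species_index)), function(sp) {
    design_species_reverse(aln, sp,
                           sites[sites$target_species == sp, ], cfg)
  })
  panel <- assemble_panel(aln, fw, rv, cfg)
  expect_s3_class(panel, "primer_panel")
  sizes <- sort(panel$expected_sizes)
  expect_true(all(diff(sizes) >= cfg$min_separation))
  expect_true(all(sizes >= cfg$min_amplicon & sizes <= cfg$max_amplicon))
  tms <- vapply(c(list(panel$forward), panel$reverses),
                function(p) p$tm_wallace, 0)
  expect_lte(diff(range(tms)), cfg$max_tm_spread)
  # every reverse ends on its species' diagnostic allele
  for (sp in names(panel$reverses)) {
    p <- panel$reverses[[sp]]
    expect_true(0L %in% p$diagnostic_offsets)
    expect_gt(p$footprint[1], panel$forward$footprint[2])
  }
  # deterministic: same inputs, same panel
  panel2 <- assemble_panel(aln, fw, rv, cfg)
  expect_identical(panel_fingerprint(panel), panel_fingerprint(panel2))
})

test_that("assemble_panel reports the binding constraint when infeasible", {
  # two species whose only candidate sizes are 100 and 110 with
  # min_separation 25 -> separation infeasibility
  set.seed(23)
  base <- strsplit(random_dna(150), "")[[1]]
  sx <- base; sy <- base
  sx[120] <- "A"; sy[120] <- setdiff(c("C", "G", "T"), base[120])[1]
  sy[110] <- "A"; sx[110] <- setdiff(c("C", "G", "T"), base[110])[1]
  if (sx[120] == base[120]) sx[120] <- "C"
  aln <- species_alignment(list(
    sequence_record("x", paste(sx, collapse = ""), species = "X"),
    sequence_record("y", paste(sy, collapse = ""), species = "Y")
  ))
  cfg <- design_config(primer_len = c(10L, 10L), tm_range = c(0, 100),
                       gc_range = c(0, 1), max_homopolymer = 10L,
                       min_amplicon = 50L, min_separation = 25L,
                       max_tm_spread = 100)
  sites <- scan_alignment(aln)
  profiles <- build_column_profiles(aln)
  fw <- design_universal_forward(
    aln, find_conserved_windows(profiles, 10L), cfg)
  rv <- lapply(setNames(nm = c("X", "Y")), function(sp) {
    cand <- design_species_reverse(
      aln, sp, sites[sites$target_species == sp, ], cfg)
    cand[1]  # one candidate each
  })
  err <- tryCatch(assemble_panel(aln, fw, rv, cfg),
                  snap_infeasible = function(e) e)
  expect_s3_class(err, "snap_infeasible")
  expect_equal(err$constraint, "separation")
})

test_that("panel JSON and TSV round-trip", {
  pan <- published_panel()
  j <- withr::local_tempfile(fileext = ".json")
  write_panel_json(pan, j)
  back <- read_panel_json(j)
  expect_equal(back$forward$sequence, pan$forward$sequence)
  expect_equal(vapply(back$reverses, `[[`, "", "sequence"),
               vapply(pan$reverses, `[[`, "", "sequence"))
  expect_equal(back$expected_sizes, pan$expected_sizes)

  t <- withr::local_tempfile(fileext = ".tsv")
  write_panel_tsv(pan, t)
  back2 <- read_panel_tsv(t)
  expect_equal(back2$expected_sizes, pan$expected_sizes)
})

test_that("published panel ladder separation equals the printed minimum", {
  pan <- published_panel()
  sizes <- sort(pan$expected_sizes)
  expect_equal(unname(sizes), c(162, 227, 275, 307, 527))
  # smallest pairwise difference among the printed sizes: 307 - 275
  expect_equal(min(dist(sizes)), 32)
  expect_equal(pan$min_separation, 32L)
})
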