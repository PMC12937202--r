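write_sim_inputs <- function(dir, seed = 1, haplotypes = 3,
                             background = 0.1, rate = 0.005) {
  spec <- synthetic_panel_spec(haplotypes_per_species = haplotypes,
                               background_divergence = background,
                               intraspecific_rate = rate, seed = seed)
  sim <- generate_species_panel(spec)
  aln <- sim$alignment
  records <- lapply(aln$ids, function(id) {
    sequence_record(id, aln$seqs[[id]], species = aln$species[[id]])
  })
  fa <- file.path(dir, "aln.fasta")
  write_fasta(records, fa)
  map <- file.path(dir, "species.tsv")
  write.table(data.frame(aln$ids, unname(aln$species)), map,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  list(fasta = fa, map = map, sim = sim)
}

test_that("design workflow runs end to end and self-validates", {
  dir <- withr::local_tempdir()
  inp <- write_sim_inputs(dir)
  out <- file.path(dir, "run1")
  res <- run_design_workflow(inp$fasta, inp$map, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("sites.tsv", "conserved_windows.bed", "panel.json",
           "panel.tsv", "specificity.tsv", "gel.tsv", "manifest.json")))))
  expect_true(is_diagonal_specificity(res$specificity))
  expect_s3_class(res$panel, "primer_panel")
  # manifest digests verify against re-hashed inputs
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$input_digests$alignment,
               unname(tools::md5sum(inp$fasta)))
  expect_length(man$outputs, 6)

  # rerun with identical inputs: byte-identical panel JSON
  out2 <- file.path(dir, "run2")
  run_design_workflow(inp$fasta, inp$map, out_dir = out2)
  expect_identical(readLines(file.path(out, "panel.json")),
                   readLines(file.path(out2, "panel.json")))
})

test_that("design workflow rejects a single-species alignment", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "one.fasta")
  write_fasta(list(sequence_record("a", "ACGTACGT", species = "X"),
                   sequence_record("b", "ACGTACGT", species = "X")), fa)
  expect_error(run_design_workflow(fa, NULL, out_dir = dir),
               "at least 2 species")
})

test_that("validate workflow: published panel on stand-in templates", {
  dir <- withr::local_tempdir()
  pan_path <- file.path(dir, "panel.tsv")
  write_panel_tsv(published_panel(), pan_path)
  tmpl <- synthetic_reference_templates()
  fa <- file.path(dir, "templates.fasta")
  write_fasta(tmpl, fa)
  res <- run_validate_panel(pan_path, fa, out_dir = dir)
  expect_true(res$clean)
  counts <- vapply(res$amplicons, nrow, 0L)
  expect_equal(unname(counts), rep(1L, 5))

  # mutate one template's 3'-anchor column: that species drops out
  sp <- tmpl[[1]]$species
  size <- published_panel()$expected_sizes[[sp]]
  rp <- published_panel()$reverses[[sp]]
  # the reverse primer's 3' base faces the leftmost footprint position
  anchor <- 100L + size - nchar(rp$sequence) + 1L
  chars <- strsplit(tmpl[[1]]$residues, "")[[1]]
  chars[anchor] <- setdiff(c("A", "C", "G", "T"), chars[anchor])[1]
  mut <- sequence_record("mutant", paste(chars, collapse = ""),
                         species = sp)
  write_fasta(list(mut), fa)
  res2 <- run_validate_panel(pan_path, fa, out_dir = dir)
  expect_equal(nrow(res2$amplicons$mutant), 0)

  # unknown template species -> error
  write_fasta(list(sequence_record("z", tmpl[[1]]$residues,
                                   species = "Nobody")), fa)
  expect_error(run_validate_panel(pan_path, fa, out_dir = dir),
               "not in panel")

  # empty FASTA -> warning, clean exit
  writeLines(character(0), fa)
  expect_warning(res3 <- run_validate_panel(pan_path, fa, out_dir = dir),
                 "empty")
  expect_true(res3$clean)
})

test_that("config round-trip: defaults JSON is accepted back", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "cfg.json")
  writeLines(default_config_json(), cfg_path)
  cfg <- read_workflow_config(cfg_path)
  expect_equal(cfg$design$min_separation, design_config()$min_separation)
  expect_equal(cfg$pcr$three_prime_window, pcr_config()$three_prime_window)
  expect_equal(cfg$gel$b, gel_model()$b)
  # absent file sections fall back to defaults
  writeLines('{"design": {"min_separation": 40}}', cfg_path)
  cfg2 <- read_workflow_config(cfg_path)
  expect_equal(cfg2$design$min_separation, 40L)
  expect_equal(cfg2$pcr$max_mismatch_total,
               pcr_config()$max_mismatch_total)
})

test_that("snap CLI subcommands run and set exit status", {
  dir <- withr::local_tempdir()
  inp <- write_sim_inputs(dir, seed = 6)
  expect_equal(snap_main(c("scan", "--alignment", inp$fasta,
                           "--species-map", inp$map,
                           "--out-dir", file.path(dir, "scan"))), 0L)
  expect_true(file.exists(file.path(dir, "scan", "sites.tsv")))

  suppressMessages(
    expect_equal(snap_main(c("design", "--alignment", inp$fasta,
                             "--species-map", inp$map,
                             "--out-dir", file.path(dir, "design"))), 0L))
  expect_true(file.exists(file.path(dir, "design", "panel.json")))

  expect_equal(snap_main(c("ispcr",
                           "--panel", file.path(dir, "design", "panel.json"),
                           "--templates", inp$fasta,
                           "--species-map", inp$map,
                           "--out-dir", file.path(dir, "ispcr"))), 0L)

  expect_equal(snap_main(c("simulate", "--seed", "3",
                           "--haplotypes", "2",
                           "--out-dir", file.path(dir, "sim"))), 0L)
  expect_true(file.exists(file.path(dir, "sim", "truth.json")))

  expect_equal(snap_main(c("gel", "--amplicons",
                           file.path(dir, "ispcr", "amplicons.tsv"),
                           "--out", file.path(dir, "gel.tsv"))), 0L)
  expect_output(expect_equal(snap_main("config"), 0L))
  expect_equal(suppressMessages(snap_main("nonsense")), 2L)
  expect_equal(suppressMessages(snap_main(character(0))), 2L)
})
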