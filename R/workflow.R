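# End-to-end workflows: scan -> design -> in-silico self-validation ->
# virtual gel, plus standalone panel validation. Every run emits a
# machine-readable manifest with input/config digests.

#' Read a JSON workflow configuration
#'
#' One document with optional sections `design` ([design_config()]
#' arguments), `pcr` ([pcr_config()] arguments) and `gel`
#' ([gel_model()] arguments `gel_pct`, `a`, `b`). Absent sections use
#' package defaults. (Only JSON is supported: no YAML parser is
#' available in the dependency footprint.)
#'
#' @param path JSON path, or `NULL` for all defaults.
#' @return List with elements `design`, `pcr`, `gel`.
#' @export
read_workflow_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else jsonlite::read_json(path)
  simplify <- function(x) lapply(x, function(v) unlist(v))
  list(
    design = do.call(design_config, simplify(raw$design %||% list())),
    pcr = do.call(pcr_config, simplify(raw$pcr %||% list())),
    gel = do.call(gel_model, simplify(raw$gel %||% list()))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default configuration as a JSON string
#'
#' @return JSON text of every tunable default; the document
#'   [read_workflow_config()] accepts.
#' @export
default_config_json <- function() {
  d <- design_config(); p <- pcr_config(); g <- gel_model()
  jsonlite::toJSON(list(
    design = d[setdiff(names(d), character(0))],
    pcr = unclass(p),
    gel = list(gel_pct = g$gel_pct, a = g$a, b = g$b)
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

run_manifest <- function(command, inputs, config_path, outputs, out_path) {
  digest_of <- function(p) {
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p))
    else NA_character_
  }
  manifest <- list(
    command = command,
    config_digest = digest_of(config_path),
    input_digests = lapply(inputs, digest_of),
    tool_version = as.character(utils::packageVersion("snapPCR")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, out_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the full panel-design workflow
#'
#' scan (diagnostic sites + conserved windows) -> design (universal
#' forward + per-species reverses + panel assembly) -> in-silico
#' self-validation against the per-species consensus templates ->
#' virtual gel. Errors with a `snap_infeasible` condition if design is
#' infeasible, and a plain error if the designed panel fails its own
#' specificity check.
#'
#' @param alignment Path to an aligned FASTA.
#' @param species_map Path to a record-id/species TSV, or `NULL` when
#'   headers carry `species=` tokens.
#' @param config Path to a JSON config, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the panel, the specificity matrix, the
#'   gel table and the manifest. Writes `sites.tsv`,
#'   `conserved_windows.bed`, `panel.json`, `panel.tsv`,
#'   `specificity.tsv`, `gel.tsv` and `manifest.json` under `out_dir`.
#' @export
run_design_workflow <- function(alignment, species_map = NULL,
                                config = NULL, out_dir = ".") {
  cfg <- read_workflow_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smap <- if (!is.null(species_map)) read_species_map(species_map)
  aln <- species_alignment(read_fasta(alignment, species_map = smap))

  profiles <- build_column_profiles(aln)
  sites_all <- scan_alignment(aln)
  windows <- find_conserved_windows(profiles, cfg$design$primer_len[1L])
  write_sites_tsv(sites_all, file.path(out_dir, "sites.tsv"))
  write_windows_bed(windows, file.path(out_dir, "conserved_windows.bed"))

  forwards <- design_universal_forward(aln, windows, cfg$design)
  reverses <- lapply(stats::setNames(nm = names(aln$species_index)),
                     function(sp) {
    design_species_reverse(
      aln, sp, sites_all[sites_all$target_species == sp, , drop = FALSE],
      cfg$design)
  })
  panel <- assemble_panel(aln, forwards, reverses, cfg$design)
  write_panel_json(panel, file.path(out_dir, "panel.json"))
  write_panel_tsv(panel, file.path(out_dir, "panel.tsv"))

  templates <- consensus_templates(aln)
  spec_m <- specificity_matrix(panel, templates, cfg$pcr)
  utils::write.table(spec_m, file.path(out_dir, "specificity.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is_diagonal_specificity(spec_m)) {
    stop("designed panel failed in-silico self-validation ",
         "(non-diagonal specificity matrix); see ",
         file.path(out_dir, "specificity.tsv"))
  }

  lanes <- lapply(names(panel$expected_sizes), function(sp) {
    gel_lane(sp, panel$expected_sizes[[sp]], cfg$gel)
  })
  gel <- render_gel(lanes, model = cfg$gel)
  utils::write.table(gel, file.path(out_dir, "gel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- c("sites.tsv", "conserved_windows.bed", "panel.json",
               "panel.tsv", "specificity.tsv", "gel.tsv")
  manifest <- run_manifest("design",
                           list(alignment = alignment,
                                species_map = species_map),
                           config, outputs,
                           file.path(out_dir, "manifest.json"))
  invisible(list(panel = panel, specificity = spec_m, gel = gel,
                 manifest = manifest))
}

#' Validate a primer panel against template sequences
#'
#' @param panel Path to a panel JSON ([write_panel_json()]) or TSV
#'   ([write_panel_tsv()]).
#' @param templates Path to an (ungapped) template FASTA; species labels
#'   from `species=` header tokens or `species_map`.
#' @param species_map Optional species-map TSV path.
#' @param config Optional JSON config path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `specificity`, `amplicons`, `gel`,
#'   `clean` (`TRUE` iff the matrix is diagonal) and the manifest.
#'   Writes `amplicons.tsv`, `specificity.tsv`, `gel.tsv`,
#'   `manifest.json`.
#' @export
run_validate_panel <- function(panel, templates, species_map = NULL,
                               config = NULL, out_dir = ".") {
  cfg <- read_workflow_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pan <- if (grepl("\\.json$", panel)) read_panel_json(panel)
         else read_panel_tsv(panel)
  smap <- if (!is.null(species_map)) read_species_map(species_map)
  tmpl <- read_fasta(templates, species_map = smap, allow_gaps = FALSE)

  if (!length(tmpl)) {
    warning("empty template FASTA: nothing to validate")
    hits <- list()
    spec_m <- matrix(0L, 0L, length(pan$reverses),
                     dimnames = list(NULL, names(pan$reverses)))
    clean <- TRUE
    gel <- render_gel(list(), model = cfg$gel)
  } else {
    unknown <- setdiff(unique(vapply(tmpl, `[[`, "", "species")),
                       c(names(pan$reverses), ""))
    if (length(unknown)) {
      stop("template species not in panel: ",
           paste(unknown, collapse = ", "))
    }
    hits <- multiplex_pcr(tmpl, pan, cfg$pcr)
    labelled <- Filter(function(r) nzchar(r$species), tmpl)
    spec_m <- if (length(labelled)) {
      specificity_matrix(pan, labelled, cfg$pcr)
    } else {
      matrix(0L, 0L, length(pan$reverses),
             dimnames = list(NULL, names(pan$reverses)))
    }
    clean <- !nrow(spec_m) || is_diagonal_specificity(spec_m)
    lanes <- lapply(names(hits), function(id) {
      gel_lane(id, hits[[id]]$length, cfg$gel)
    })
    gel <- render_gel(lanes, model = cfg$gel)
  }
  write_amplicon_tsv(hits, file.path(out_dir, "amplicons.tsv"))
  utils::write.table(spec_m, file.path(out_dir, "specificity.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(gel, file.path(out_dir, "gel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- run_manifest("validate",
                           list(panel = panel, templates = templates,
                                species_map = species_map),
                           config,
                           c("amplicons.tsv", "specificity.tsv", "gel.tsv"),
                           file.path(out_dir, "manifest.json"))
  invisible(list(specificity = spec_m, amplicons = hits, gel = gel,
                 clean = clean, manifest = manifest))
}
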