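# snapPCR

Species identification by multiplex PCR, designed from a barcode-gene
alignment.

Many groups of morphologically similar animals — the motivating case is
five onchidiid slug species of the South China Sea coast (*Onchidium
stuxbergi*, *Peronia verruculata*, *Onchidium reevesii*, *Platevindex
martensi*, *Paromoionchis tumidus*) — are routinely identified by
sequencing the mitochondrial COI barcode. Sequencing is accurate but
slow and expensive for large-scale screening. A cheaper assay is a
single multiplex PCR whose products separate on an agarose gel: one
**universal forward primer** sitting in a region conserved across all
target species, plus one **species-specific reverse primer** per
species whose 3′-terminal base pairs a **diagnostic SNP** — an
alignment column where the target species is fixed for a base that no
other panel species carries. On a non-target template the primer ends
on a mismatch, *Taq* cannot extend it, and no product forms; each
species therefore yields exactly one band, and the bands are designed
to different sizes so a single lane reads out the species.

snapPCR automates that design and its validation:

| stage | functions |
|---|---|
| alignment I/O, IUPAC handling | `read_fasta()`, `species_alignment()`, `revcomp()`, `iupac_compatible()` |
| diagnostic-SNP / conserved-window scan | `build_column_profiles()`, `find_diagnostic_sites()`, `find_conserved_windows()` |
| primer + panel design | `design_universal_forward()`, `design_species_reverse()`, `assemble_panel()`, `tm_wallace()`, `tm_nearest_neighbor()`, `dimer_score()` |
| in-silico multiplex PCR | `find_binding_sites()`, `amplify()`, `multiplex_pcr()`, `specificity_matrix()` |
| virtual agarose gel | `gel_model()`, `migration_distance()`, `resolvable()`, `render_gel()` |
| synthetic data with ground truth | `synthetic_panel_spec()`, `generate_species_panel()`, `spike_intraspecific_variants()` |
| workflows / CLI | `run_design_workflow()`, `run_validate_panel()`, `snap_main()` |

The core statistic is simple and set-theoretic: column *j* is
diagnostic for species *X* iff *X*'s observed allele set at *j* is a
singleton unambiguous base `{b}`, *b* is absent from every other
species' allele set (IUPAC codes in non-targets count as every base
they encode), and no record has a gap at *j*. Primer QC uses the
Wallace rule Tm = 2(A+T) + 4(G+C) and nearest-neighbor thermodynamics
(unified Allawi–SantaLucia 1997 parameters, SantaLucia 1998 salt
correction). In-silico PCR reports every primer placement with ≤ 3
mismatches and blocks extension on a 3′-terminal mismatch or on > 1
mismatch within the 3′-terminal 5 nt — standard allele-specific PCR
behavior. Gel migration follows d = a − b·log10(size).

## Worked example

Design a panel on a synthetic five-species barcode alignment (30
records, 658 columns, planted truth), then validate it in silico:

```r
library(snapPCR)

sim <- generate_species_panel(synthetic_panel_spec(
  haplotypes_per_species = 6, background_divergence = 0,
  intraspecific_rate = 0, seed = 1))
aln      <- sim$alignment
profiles <- build_column_profiles(aln)
sites    <- scan_alignment(aln)
cfg      <- design_config()

fw <- design_universal_forward(aln, find_conserved_windows(profiles, 18), cfg)
rv <- lapply(setNames(nm = names(aln$species_index)), function(sp)
  design_species_reverse(aln, sp, sites[sites$target_species == sp, ], cfg))
panel <- assemble_panel(aln, fw, rv, cfg)
panel
#> <primer_panel> 5 species, ladder: 210, 300, 387, 479, 570 (min sep 25 bp)
panel$reverses[[1]]
#> <primer> R_sp01_189_210 (reverse, sp01) TGTTGGCTGCTCTTATACGTCC  22nt Tm(Wallace)=66 GC=0.50

specificity_matrix(panel, consensus_templates(aln), pcr_config())
#>         primer
#> template sp01 sp02 sp03 sp04 sp05
#>     sp01    1    0    0    0    0
#>     sp02    0    1    0    0    0
#>     sp03    0    0    1    0    0
#>     sp04    0    0    0    1    0
#>     sp05    0    0    0    0    1
```

The ladder (210, 300, 387, 479, 570 bp) is the set of expected band
sizes, pairwise separated by at least `min_separation` (default 25
bp); the diagonal specificity matrix says each reverse primer
amplifies only its own species — the design's whole point.

The published five-species onchidiid panel ships with the package and
reproduces its printed band sizes on the bundled synthetic stand-in
templates (see `?synthetic_reference_templates` — the real GenBank
records are not redistributable):

```r
pan <- published_panel()
sapply(multiplex_pcr(synthetic_reference_templates(), pan), `[[`, "length")
#>  synthetic_Onchidium_reevesii  synthetic_Onchidium_stuxbergi
#>                           275                            162
#> synthetic_Paromoionchi_tumidus  synthetic_Peronia_verruculata
#>                           527                            227
#> synthetic_Platevindex_martensi
#>                           307
resolvable(pan$expected_sizes, gel_model())$resolvable
#> [1] TRUE
```

## Command line

```sh
SNAP=$(Rscript -e 'cat(system.file("cli/snap.R", package = "snapPCR"))')
Rscript $SNAP simulate --seed 1 --out-dir sim
Rscript $SNAP design --alignment sim/alignment.fasta \
    --species-map sim/species.tsv --out-dir run
Rscript $SNAP ispcr --panel run/panel.json \
    --templates sim/alignment.fasta --species-map sim/species.tsv \
    --out-dir check   # exit 0 = clean panel, 1 = cross-reaction
Rscript $SNAP config   # print every tunable default as JSON
```

Configs are JSON (`--config cfg.json`) with sections `design`, `pcr`
and `gel` mirroring `design_config()`, `pcr_config()` and
`gel_model()`.

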