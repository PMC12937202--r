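---
title: "Designing species-specific multiplex PCR panels from barcode alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing species-specific multiplex PCR panels from barcode alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapPCR)
```

## The assay being modelled

A multiplex species-identification PCR contains one universal forward
primer and, per target species, one reverse primer whose 3′-terminal
base pairs a *diagnostic SNP*: an alignment column where that species
is fixed for a base absent from every other species in the panel. On
the target template the reverse primer matches perfectly and the
reaction yields a product of a species-characteristic size; on every
non-target template the primer's 3′ base sits on a mismatch, the
polymerase cannot extend it, and no product forms. Because each
species' product has a different length, a single agarose lane
identifies the species. snapPCR mechanizes the discovery of the sites,
the design of the primers, the assembly of the size ladder, and the
in-silico validation of the finished panel.

## Definitions and model assumptions

**Diagnostic site.** Column $j$ is diagnostic for species $X$ iff
(i) $X$'s observed allele set at $j$ is one unambiguous base $\{b\}$,
(ii) $b$ appears in no other species' allele set at $j$, and (iii) no
record has a gap at $j$. Non-target species need *not* be fixed: a
single guaranteed terminal mismatch against every non-target template
is all the blocking mechanism requires, so this is the weakest
condition that preserves specificity. IUPAC ambiguity codes in a
non-target count as every base they encode (conservative: they can
only disqualify a column); ambiguity in the target disqualifies the
column outright. Columns with any gap are never diagnostic and never
conserved, because an indel breaks the footprint-length arithmetic a
gel size depends on.

**Strand geometry.** Footprints are 1-based inclusive intervals on
plus-strand alignment columns, matching how diagnostic positions are
conventionally printed. A reverse primer is the reverse complement of
its plus-strand footprint and anneals antiparallel to the plus strand,
so its 3′ terminus pairs the *leftmost* footprint column and extension
runs toward the forward primer. A candidate anchored on site $s$ with
length $L$ therefore has footprint $[s, s+L-1]$, its last (3′) base
complementary to the target allele at $s$. This detail matters: a
mutation at the footprint's left edge blocks amplification, one at the
right edge does not, and the package's tests assert exactly that.

**Amplicon size** is measured on the target's gap-stripped consensus
between the forward footprint start and the reverse footprint end —
gel sizes are physical template lengths, not alignment column spans.

**Extension blocking** (in-silico PCR): a binding site is any
placement on either strand with at most `max_mismatch_total`
IUPAC-incompatible positions (default 3). A site is extendable unless
it has a 3′-terminal mismatch (always blocking, default on) or more
than `max_mismatch_in_window` (default 1) mismatches within the
3′-terminal `three_prime_window` nt (default 5). These thresholds are
standard allele-specific-PCR practice; the underlying assay relies on
the mechanism but publishes no numbers, so the values are this
package's documented choice. Template ambiguity codes count as
matching when compatible — conservative toward *false amplification*,
which is the direction that surfaces risky designs. The scan is
deliberately exhaustive (no k-mer index): templates are barcode-length
and auditability beats speed. No modelling of amplification
efficiency, primer concentration, or product competition is attempted.

## Tunable parameters

`design_config()` defaults, chosen once so that the published
onchidiid panel's six primers (20–23 nt, AT-rich, Wallace Tm near the
assay's 60 °C annealing step) all pass while degenerate designs fail:
primer length 18–25 nt; Wallace Tm 56–66 °C with panel spread ≤ 10 °C;
GC fraction 0.30–0.65; homopolymer runs ≤ 4; amplicons 80–1000 bp with
pairwise ladder separation ≥ 25 bp; at least one diagnostic column per
reverse footprint, with the 3′ anchor mandatory; pairwise
`dimer_score()` (longest contiguous Watson–Crick run over all
antiparallel registers) ≤ 8.

Melting temperatures come in two flavours: the Wallace rule
$T_m = 2(A{+}T) + 4(G{+}C)$, used for ranking and windows because it
is the scale bench protocols quote for short oligos, and a
nearest-neighbor $T_m$ (unified Allawi & SantaLucia 1997 parameters,
terminal initiation penalties, SantaLucia 1998 entropy salt correction
$\Delta S + 0.368\,(N{-}1)\ln[\mathrm{Na}^+]$, excess-primer
kinetics, defaults 50 mM Na⁺ / 250 nM primer) carried as a reported
attribute. The NN implementation is verified against an independently
computed reference table frozen into the test fixtures, to < 0.5 °C.

The gel model is $d = a - b\log_{10}(\text{size})$ with $a = 140$ mm,
$b = 55$ mm per decade for a 2.75 % gel, and minimum resolvable
difference $\max(10, 0.06 \cdot \text{size})$ bp. No published
mobility data underlie these constants; they make a
{162, 227, 275, 307, 527} ladder comfortably resolvable and a 307
vs 312 pair unresolvable, which is ordinary gel practice, and nothing
downstream depends on them.

## Panel assembly

Candidates are ranked deterministically — forwards by Wallace-Tm
closeness to the window midpoint (ties: leftmost, then shortest),
reverses by diagnostic-column count, then Tm closeness, then leftmost
footprint — and `assemble_panel()` runs a greedy search in that order:
for each forward, species are visited alphabetically and the first
reverse compatible with the partial panel (size bounds, ladder
separation, dimer scores, Tm spread) is taken; the first complete
panel wins. Greedy-in-rank-order is not exhaustive, but it is
reproducible, explains its failures (the infeasibility report names
the constraint that rejected the most candidates), and on ladder-bearing
inputs the rank order already encodes the design intent. Identical
inputs and configuration yield byte-identical panels.

## What the synthetic generator emulates — and what it does not

`generate_species_panel()` produces the world the assay assumes: $K$
species (default 5) × 30 haplotypes (the published validation used 30
individuals per species) over 658 columns (the standard COI barcode),
one planted 30-column pan-species conserved window, and per species a
block of 8 planted diagnostic sites (the published primers carry 7–9)
spaced every 3 columns, blocks 90 columns apart so the amplicon ladder
is feasible by construction. Background interspecific divergence
(default 0.10 per column, the order of COI interspecific distance)
reassigns one species a different base at columns outside planted
regions — such columns *genuinely* satisfy the diagnostic definition,
so precision against planted truth is only meaningful at zero
background, and the tests verify extra calls against a brute-force
oracle instead. Intraspecific noise (default 0.005) mutates individual
haplotypes outside planted regions; `spike_intraspecific_variants()`
adds more after the fact, protecting every species' truth columns so
the truth stays valid. Everything is driven by one seed and is
byte-reproducible; the generator restores the caller's RNG state.

Not emulated: indels, rate heterogeneity or any substitution-model
structure, recombination, sequencing error, and real COI base
composition. A green closed-loop test therefore establishes that the
pipeline is internally correct on alignments with the assumed
structure — not that any particular wet-lab panel will amplify.

## The published panel and its stand-in templates

The package bundles the published five-species onchidiid COI panel
(`published_panel()`: one universal forward, five reverses, expected
sizes 162/227/275/307/527 bp). The five GenBank reference records it
was validated against cannot be redistributed or fetched at test time,
so `synthetic_reference_templates()` builds clearly-labelled synthetic
stand-ins: one random 700-nt backbone carrying the real forward
footprint at positions 101–123 and, per species, the real reverse
footprint placed so the product has exactly the published size, with
the published *count* of diagnostic columns (8/7/9/7/7) planted at the
published 3′-relative offsets shared by all non-targets. One printed
*P. tumidus* site lies 24 nt from the 3′ terminus — outside its 22-nt
primer, presumably an artifact of gap columns in the original
alignment's coordinate system — and is moved to offset 18 so the
printed count is preserved. Tests against these stand-ins exercise the
whole engine and reproduce the printed ladder and counts; they do not,
and cannot, verify the primers against the true mitochondrial
sequences.

## Numerical and degenerate-input choices

Coordinates are 1-based inclusive throughout, converted to 0-based
half-open only in BED output. `U` is normalised to `T` and case is
folded on input; species labels resolve as explicit TSV map > header
`species=` token > empty. Consensus calls take the per-column majority
with ties broken alphabetically (a gap wins only by strict majority),
making every downstream artifact deterministic. Empty template lists
(the no-template negative control) return empty results, not errors;
a primer longer than its template simply has no binding sites;
design with no admissible candidates returns an empty list plus a
typed warning, and panel assembly failure raises a typed
`snap_infeasible` condition with the binding constraint named.
Configuration files are JSON only — the dependency footprint
deliberately excludes a YAML parser.

## Known limitations

Design searches target-species consensus sequences; rare haplotypes
diverging at a chosen footprint are only caught if they are in the
alignment (the diagnostic definition then removes the column).
Specificity is evaluated against the panel species and any templates
the user supplies — there is no database-wide search, so
cross-reaction with taxa outside the panel is out of scope. The gel
model is illustrative. The greedy assembler may declare feasible
instances infeasible in adversarial candidate orders, though none have
been observed; an exhaustive fallback was judged not worth the
determinism and runtime cost.
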