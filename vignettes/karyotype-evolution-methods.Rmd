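---
title: "Methods: inferring centromere transitions from annotated assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring centromere transitions from annotated assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
decision rules, the tunable parameters and why their defaults are what
they are, what the karyotype simulator does and does not emulate, and the
numerical conventions that matter for reproducing a result. It states no
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The inference problem

A chromosome's centromere sits inside a pericentromere: a large block of
satellite arrays and transposable elements (TEs) wrapped in
H3K9me3-marked heterochromatin. Between related species the centromere of
a homologous chromosome (a Muller element, in Drosophila terms) can be
terminal in one karyotype and interior in another. Two mechanisms explain
such a shift. A *pericentric inversion* — one breakpoint inside the
pericentromere, one in the euchromatic arm — translocates the centromere
together with part of its flanking DNA, so some genes are pericentromeric
in both configurations. *Centromere repositioning* builds a centromere de
novo in a euchromatic region and silences the old one; no pericentromeric
DNA travels, the old pericentromere decays into an interior
"paleocentromere" island that keeps its gene complement, elevated repeat
content and heterochromatin, and the new pericentromere balloons out of a
small ancestral "seed region" by repeat accumulation. The package turns
those footprints into a per-element decision procedure.

All coordinates are 0-based half-open throughout (BED native; GFF3
shifted by −1 on read and +1 on write), so interval length is always
`end − start`.

## Window statistics

Windowed tracks use non-overlapping tiles by default (`step = window`,
configurable); a chromosome of length `L` gets
`ceiling((L − w)/step) + 1` windows, the trailing window truncated at the
chromosome end and normalised by its actual length. Dropping partial
windows would systematically bias telocentric chromosome ends — exactly
where terminal pericentromeres live — so they are kept. Repeat fractions
merge overlapping annotations per chromosome first, matching
"bases-masked" semantics, so no base counts twice. Chromatin enrichment
is the library-size-normalised ratio
`(signal/signal_total)/(input/input_total)`; windows with zero input are
flagged missing rather than imputed. Spike-in style normalisation is out
of scope. Metagene profiles length-scale gene bodies into a fixed number
of bins, keep flanks at 100 bp resolution, and reverse minus-strand genes
before averaging.

## Pericentromere and paleocentromere calling

`call_pericentromere()` scans windows outward from the centromere anchor
(both directions for interior anchors, producing one merged interval) and
places the boundary at the start of the first run of `min_below = 3`
consecutive windows whose repeat fraction is below the cutoff. The cutoff
is the user's genome-class choice — 0.2 for compact, repeat-poor genomes,
0.4 for repeat-rich ones — and the run requirement exists because a
single euchromatic gap inside a pericentromere should not truncate the
call. Raising the cutoff can only shrink the call (a property the tests
assert). Degenerate inputs are flagged rather than guessed at: an anchor
window already below the cutoff yields an empty call with a warning; a
track entirely above the cutoff yields a whole-chromosome call with a
warning.

`detect_paleocentromeres()` defines the euchromatic background as the
mean repeat fraction outside the called pericentromere, then reports
maximal runs of windows at `repeat_factor = 2.5`× that background,
spanning at least `min_span = 250` kb, lying at least 1 Mb from the
active pericentromere, and (when a chromatin track is supplied) with mean
H3K9me3 enrichment above the chromosome median. Without a chromatin track
the calls are flagged `repeat-only`. The three thresholds are exposed as
arguments; the defaults separate simulated paleocentromeres (~30 % repeat
against a ~6 % euchromatic background) cleanly and echo the empirical
contrast between decayed and active pericentromeric repeat levels.

## Satellite discovery

`find_tandem_arrays()` is a self-contained period-scan detector, not a
reimplementation of alignment-scoring tools. For each candidate period
`p` (4–500 bp) the sequence is compared with itself shifted by `p`;
mismatch runs of ≥ 4 positions (any mismatch at 0 % divergence) and `N`s
break the sequence into candidate segments, which are trimmed to their
first/last matching position. A segment survives if it reaches
`min_copies = 3` copies, its pairwise mismatch rate is at most twice
`max_divergence` (pairwise divergence of two copies is about double their
divergence from the consensus), and — the authoritative criterion — its
units' mean divergence from their majority-rule consensus is at most
`max_divergence`. Overlapping candidates across periods are resolved
longest-first, ties by smaller period, then leftmost; each accepted array
is finally re-probed at the divisors of its period and reported at the
smallest divisor consistent with `max_divergence`. Arrays whose true
period falls below `min_unit` (homopolymers, dinucleotide runs) are
discarded. An independent naive-loop implementation of these same rules
serves as the test oracle on short sequences.

Monomers are canonicalised as the lexicographically minimal string over
all rotations of the unit and of its reverse complement — an invariant,
idempotent class function, so units identical up to rotation or strand
collapse to one key. Abundance histograms rank unit lengths by total
array bp (copy totals are reported alongside, since "most abundant" is
ambiguous between the two; bp is used for the modal length, ties to the
smaller length).

`hor_decompose()` tests whether a unit is itself a higher-order repeat:
candidate fundamental periods are the divisors `p` of the unit length
with `4 ≤ p ≤ length/2`, ascending; the first whose subunits diverge from
their consensus by at most `max_divergence` wins. Restricting candidates
to exact divisors covers the structures this analysis targets (84 = 4 ×
21, 63 = 3 × 21, 168 = 8 × 21); non-divisor HORs are out of scope.

One threshold interaction is deliberate: a single divergence ceiling
cannot make the array detector report an 84-mer *and* let HOR
decomposition split that 84-mer into 21-mers — whichever of the two sees
the 21-bp period as within tolerance claims it. The pipeline therefore
runs the detector at 0.10 but decomposes detected units at a looser 0.18
(`hor_max_divergence`), and the simulator plants HOR subunit divergence
between the two (~14 %). Units are "the same family" below 10 %
divergence, well under typical between-family divergence.

`collapsed_copy_estimate()` scales assembled copies by the
contig-to-genome mean coverage ratio, the standard reading of excess
coverage on a collapsed satellite contig. Y-linked contigs are called by
male/female mean coverage ratio > 1.5 (zero female coverage counts as
infinite ratio).

## Orthology and seed regions

`score_gene_pairs()` replaces protein-alignment bit scores with shared
canonical k-mer counts between coding sequences, normalised by the
shorter sequence's k-mer count (k = 12); users with a real aligner can
supply a precomputed score table and skip this step.
`reciprocal_best_hits()` keeps a pair only when each gene is the other's
*unique* argmax; ties drop the gene from pairing rather than picking
arbitrarily, keeping the map deterministic, and dropped genes are
reported as unmatched. The pair set is symmetric in the two species.

`detect_seed_regions()` projects the derived species' pericentromeric
genes through the map onto the ancestral gene order and reports maximal
runs in which consecutive projected genes are separated by at most
`max_gap = 2` intervening non-projected genes, keeping runs of more than
two genes. The gap tolerance is configurable; "sequential" without any
tolerance would shatter runs on single unannotated or unmapped genes.
Runs broken up by secondary rearrangements are reported as-is — merging
them is left to the user.

## Transition classification

`classify_transition()` compares two element states (anchor, called
pericentromere, pericentromeric gene set, gene order):

1. **conserved** — the orthologs of the `n_flank = 10` genes nearest A's
   anchor are adjacent in B's gene order, mostly pericentromeric in B,
   and the anchor sides agree;
2. **pericentric_inversion** — at least `min_shared = 3` orthologs are
   pericentromeric in both species (a small integer threshold guards
   against annotation noise in repeat-rich regions);
3. **repositioning** — fewer than `min_shared` shared pericentric
   orthologs *and* the median mapped position of A's pericentric genes
   lies at least `far_bp = 2` Mb *and* `far_frac = 10` % of the
   chromosome from B's anchor ("megabases away" made operational; both
   configurable);
4. **ambiguous** — anything else, deliberately including complex
   multi-inversion histories that the evidence cannot resolve.

Evidence fields (shared ortholog count, flanking-ortholog distance in bp
and as a fraction of chromosome length) are always populated. Calls are
invariant to gene-id and chromosome relabelling. `detect_fusion()`
reports element pairs whose orthologs co-locate on one derived
chromosome (≥ 5 genes each side) with the innermost gene of each block as
the junction neighbourhood; three-way co-locations produce one pair per
couple with a warning.

## The karyotype simulator

The simulator is first-class, tested code: it is the ground truth every
detector is validated against. `build_ancestor()` emits the ancestral
karyotype — five large telocentric elements plus a dot — with, per
element: a terminal centromeric satellite array (the anchor) whose
monomer is a higher-order repeat (four ~14 %-diverged copies of a 21-bp
motif), a pericentromere body of TE blocks, satellite stretches and a few
resident genes at ~70–80 % repeat density, and a euchromatic arm with
evenly spaced genes, a 6 % scattered TE background, and three AT-rich
seed windows (GC 0.38 against a 0.45 background). Unplaced contigs
include two Y-linked contigs, one ordinary contig, and one ~14.7 kb
collapsed-satellite contig carrying two perfect 12-mer arrays of 278 and
250 copies with coverage inflated by its true copy ratio (5.5 by
default). Coding sequences are independent random 450-mers inherited
unchanged by derived species, so reciprocal best hits recover the true
ortholog map; the simulator has no substitution model along branches.

Scale is deliberate desk scale: 3 Mb elements with 80 arm genes stand in
for 20–30 Mb chromosomes with thousands — every planted contrast
(boundaries, islands, seeds, GC, coverage ratios) is preserved while a
full multi-species pipeline run stays in minutes. The one place scale
interacts with a default is the repositioning distance: the new
pericentromere is centred at ~82 % of the element so that the
old-pericentromere orthologs end up > 2 Mb and > 10 % of the chromosome
from the new anchor, satisfying the classifier's distance rule at 3 Mb
element size.

`evolve()` replays a logged event list deterministically given the
configuration seed: *reposition* inserts ~450 kb of TE-plus-satellite
blocks (two insertions per inter-gene gap, so no euchromatic stretch
inside the new pericentromere exceeds an analysis window) around a run of
8 arm genes centred on a seed window, then deactivates the old
pericentromere — satellite annotations deleted, every TE feature
truncated to bring the regional TE fraction to 30 % (between empirically
reported paleocentromere levels, above the 6 % background), sequence
replaced in place, heterochromatin flag retained; *pericentric_inversion*
reverses a segment from the chromosome end (inside the terminal
pericentromere) to an intergenic arm point, carrying anchor and part of
the pericentromeric gene complement to the interior; *fusion*
concatenates two elements head-to-head and deactivates one centromere;
*expansion* and *contraction* grow or purge repeat bp. Breakpoints are
never placed inside genes (a placement error is raised; random drawing
re-draws), and every event preserves gene content. Replaying the same
log on the same ancestor with the same seed is byte-identical.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: sequence divergence between orthologs
(real RBH must survive alignment noise), annotation error, assembly gaps
and scaffolding artefacts, TE nesting and fragmentation, satellite
library turnover along a phylogeny, and read-level noise (coverage is
windowed negative binomial, dispersion 20, not simulated reads — the
package tests ratio rules, not mappers).

## Statistical conventions

Region-vs-background comparisons use the two-sided Mann–Whitney U test
with normal approximation and tie correction (delegated to
`stats::wilcox.test`); all-tied data take p = 1 by convention, and groups
with fewer than 3 values skip the test and report medians only. The U
statistic is validated against exhaustive pair counting for small
samples. The unit of observation for GC comparisons is the fixed 10-kb
sub-window (configurable); expression tests run on `log2(FPKM + 1)` —
ranks are transform-invariant, so U and p equal those on raw FPKM and
only the reported medians change. No multiple-testing correction is
applied by default, matching the single-headline-test style of the
analyses this package supports; `p.adjust` can be applied to the returned
p-values where families of tests are run.

The functional partition (exonic / genic-non-exonic / intergenic) merges
overlapping genes and exons and asserts per chromosome that the three
sets are disjoint and cover every base exactly once.

## Numerical choices and limitations

- Table rounding follows print conventions: Mb to 1 decimal, genome
  percentages to 1 decimal, TE-share percentages to the nearest integer;
  totals are exact column sums of the unrounded inputs.
- Pericentromere size accounting sums components before dividing, and a
  zero seed size yields an explicit infinite fold with a degenerate flag.
- The tandem detector's interval edges can extend a few chance-matching
  bases into flanking sequence; complete copies (`floor(copies)`) are the
  robust copy count.
- Boundary precision is window-limited: calls are accurate to ±1 window
  by construction, so fine boundaries (e.g. seed-edge work at gene
  resolution) should be called on windows no wider than the local gene
  spacing — the acceptance tests use 25-kb windows for that purpose.
- Problem sizes used by the test suite: 3 Mb single-element simulations
  for scenario recovery (30 seeded scenarios), 20-seed boundary recovery,
  a 5-element ancestor with sequence for the GC contrast (≥ 100 10-kb
  seed windows), and a two-element, two-scenario pipeline demo.
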