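---
title: "Methods: dyad mapping, accessibility classes and motif sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyad mapping, accessibility classes and motif sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadmapr)
```

# Scope and model

`dyadmapr` quantifies chromatin structure around transcription-factor (TF)
binding sites at the level of sequenced fragments. Three analyses share one
data model — interval tibbles (BED convention: 0-based half-open), fragment
tibbles, and point-event ("dyad") tibbles:

1. **Nucleosome dyad mapping.** The midpoint of an MNase-protected
   mono-nucleosomal fragment estimates the dyad, the centre of the ~147 bp
   of DNA wrapped around the histone octamer. Aggregating dyads around
   aligned TF sites reveals phased nucleosome arrays (regularly spaced
   positions flanking a bound factor) and their changes across conditions.
2. **Accessibility classification.** Transposase insertion density before
   and after induction of a pioneer factor separates the factor's peaks
   into loci it opens (*newly accessible*), loci already open
   (*constitutively accessible*) and loci that stay closed
   (*constitutively inaccessible*).
3. **Motif sampling.** A TF's degenerate consensus occurs far more often
   than the factor binds stably; transient engagement at motif instances
   outside called peaks is detectable only in aggregate, as an enrichment
   of ChIP fragment counts at motif-centred windows over random genomic
   background.

# Coordinate and counting conventions

All coordinates are 0-based half-open; an overlap is at least one shared
bp on the same chromosome (the most permissive reading, matching common
intersect defaults). The centre of an interval is
`floor((start + end) / 2)`, and a fragment midpoint is floored the same
way — deterministic for even widths, and any half-bp bias is far below the
10 bp default bin. Windows at chromosome edges are clamped rather than
discarded, preserving peak counts; edge effects are negligible at the
scales analysed. Fragments are counted in windows by their midpoint, a
single convention shared with dyad counting so that every fragment falls
in exactly one window of a tiling (an any-overlap mode would count long
fragments in several adjacent windows and is intentionally not the
default).

Fragment length is defined from the mate spans of a BEDPE record
(`max(ends) − min(starts)`), the only definition available in
post-alignment fragment files; pipelines that used the aligner's template
length may differ by a few bp in edge cases.

Per-assay policies encode the field's processing conventions: ATAC and
ChIP libraries are deduplicated on the `(chrom, start, end)` key (the only
key fragment files carry); capture MNase retains duplicates, because deep
targeted coverage makes genuine re-observation of identical fragments
likely. Mono-nucleosomal selection keeps lengths in the **closed**
interval 120–170 bp; both bounds are arguments.

# Depth normalization

Counts are compared across libraries after scaling by
`target / library size`. The package-wide default target is 10 million
fragments, a conventional ATAC library size. The accessibility thresholds
(below) are expressed in normalized reads, so the target is a first-class
parameter everywhere rather than a constant: any convention can be swapped
in. The simulation conditions set `norm_target = 1e5`, matched to the
simulated sequencing depth so that the flank threshold of 30 normalized
reads per ±1 kb sits where it is meaningful — closed-background flanks
expect ~5 normalized reads and open flanks ~150–300 under the default
generator (see below).

# The three-class accessibility rules

With normalized centre counts (±200 bp) and flank counts (±1 kb) in the
`pre` (time 0) and `post` libraries, and
`F = (post_centre + 1) / (pre_centre + 1)`:

* **newly accessible** iff `F > 2` and `post_flank > 30`;
* else **constitutively accessible** iff `flank > 30`;
* else **constitutively inaccessible**.

Decisions embedded here, all exposed as arguments:

* *Rule precedence.* The newly-accessible test runs first; the remaining
  peaks split on the flank threshold. This is the only ordering under
  which the three written definitions are mutually exclusive, and it
  guarantees exactly one label per peak.
* *Strict inequalities.* `F = 2` exactly, or a flank of exactly 30, falls
  through to the next rule.
* *Which flank decides the constitutive split.* "Constitutive" describes
  the state irrespective of induction, so the default assesses the time-0
  flank (`constitutive_on = "pre"`); `"post"` and `"either"` are provided
  because the choice is genuinely open, and the label distributions under
  each switch are easy to compare.
* *Pseudocount 1* in `F` keeps fully closed peaks finite and shrinks fold
  changes at very low counts, where they would otherwise be dominated by
  shot noise.

# Signal matrices, metaplots and time-0 ratios

The matrix entry `(i, j)` counts events in
`[c_i − flank + (j−1)·bin, c_i − flank + j·bin)`; `flank` must be
divisible by `bin` so the geometry is exact. Metaplots are unweighted
column means ("reads per peak"), hence invariant under anchor permutation
and linear in anchor-set mixtures. Cross-timepoint dyad maps are
`log2((a + 1)/(r + 1))` with both matrices depth-scaled to the same
target; the units field of the matrix records whether values are raw,
normalized, or log2 ratios so heatmaps are labelled honestly. Defaults are
bin 10 bp with flank 1 kb for metaplots (2 kb in the dyad-map pipeline
wrapper); profile resolution trades against per-bin counts and both are
arguments.

The nucleosome repeat length is estimated as the lag maximizing the
autocorrelation of the demeaned metaplot within 120–280 bp, bracketing
biologically plausible repeat lengths while excluding the trivial lag-0
peak.

# Consensus motif scanning

Scanning uses IUPAC degeneracy on the pattern only; genome `N` satisfies
no non-`N` code (an `N` run can never produce a match). Reverse-strand
matches are found by scanning the reverse-complement pattern and reported
on `−` with the matched sequence reverse-complemented, so the stored
sequence always satisfies the pattern on its reported strand. For
palindromic consensi (e.g. the AP-1 heptamer `TGASTCA`, its own reverse
complement) a position matches on both strands at once; by default such
double-matches collapse to a single `+` site, because they are one
physical binding site — the flag is exposed since the alternative counting
is defensible for strand-resolved analyses.

The analytic spacing of a consensus under i.i.d. base composition is the
reciprocal of the per-position match probability,
`P(forward) + P(reverse complement) − P(both)` under collapsing; each term
is a product of per-position code-set probabilities, and the overlap term
is the product over per-position intersections of the forward and
reverse-complement code sets. For `WGATAR` under uniform composition the
overlap is empty and the spacing is `4096 / 8 = 512` bp; for `TGASTCA`
the forward and reverse-complement match sets coincide, so collapsing
halves the count (8192 bp collapsed, 4096 bp counting strand-events). The
exhaustive k-mer enumeration that decides these constants is kept as a
test oracle.

# Motif-sampling enrichment

Sampling loci are motif sites extended to 200 bp windows, with two
removals: windows overlapping any called ChIP peak (sampling is defined
outside peaks, and peak-proximal signal would dominate), and mutually
overlapping windows — **both** members of an overlapping pair are dropped,
the conservative reading that guarantees no fragment is counted toward two
loci; a keep-one alternative is reachable through the exposed
`remove_mutual` flag of the underlying interval operation.

Background regions are drawn with chromosome probability proportional to
length and uniform starts, with equal number and width as the loci, and no
GC or blacklist matching — assumptions stated here because published
analyses rarely specify them; GC-matched backgrounds would be a natural
extension.

The comparison is a two-sided Mann–Whitney test. The U statistic is
computed from midranks in-package; the p-value uses the exact
distribution when `n1·n2 ≤ 10 000` with no ties, else the normal
approximation with tie and continuity correction (group sizes in real
applications are thousands, where the approximation is excellent). When
every count in both groups is identical the comparison carries no
information: the result is flagged degenerate with `p = 1`.

# The synthetic-data generator

The generator emulates the fragment-level structure the analyses assume,
with exact ground truth:

* one uniform random chromosome (default 3 Mb) in which every spurious
  occurrence of the consensus is rewritten by single-base substitution
  (iterated until the scanner finds none), then one concrete motif
  instance per site planted on a random strand — so the scanner's output
  *is* the planted-site table;
* 300 sites per class on a jittered grid enforcing a minimum inter-site
  distance of twice the phased-array extent (no window of one site reaches
  another's array);
* **MNase dyads** per site from a mixture: a motif-covering nucleosome
  with weight `occupancy_over_motif[class, condition]`, phased components
  at `±k·190` bp (`k ≤ 3`, Gaussian jitter sd 20 bp) with amplitude
  `phase_amplitude[class] × eviction_shift[condition]`, plus 20% uniform
  background; fragment lengths are normal (150 ± 12 bp, clipped to
  100–200 bp) and 10^5 fragments are drawn per condition;
* **accessibility fragments** as Poisson events: background 2×10⁻⁴/bp
  genome-wide plus a class- and condition-specific extra rate within
  ±200 bp of each site (newly accessible: 0.015 → 0.15 events/bp from
  `pre` to `post`; constitutively accessible: 0.10 throughout;
  constitutively inaccessible: 0.001 throughout); lengths uniform
  60–120 bp;
* **ChIP fragments** centred normally (sd 60 bp) on motifs with per-site
  weight proportional to occupancy, competing against a constant
  background weight so that site-derived signal scales near-linearly with
  occupancy in the weak-occupancy regime that models motif sampling.

Default effect directions encode the phenomenology under study: upon
remodeler depletion (`kd`) the motif-covering nucleosome loses occupancy
(0.45 → 0.15 at constitutively inaccessible sites) while the flanking
array gains amplitude (×1.8) — so the kd/control log2 dyad ratio is
negative over the motif and positive at the flanking positions — and
newly accessible sites gain 10-fold transposition after induction.
Magnitudes are free parameters: real studies report directions and figure
amplitudes, not generative rates, so the defaults were chosen once as
values a practitioner would call realistic for a clear-effect dataset and
are documented rather than fitted.

Every emitted dataset draws from its own RNG stream derived from
`(seed, file tag)`, so adding an assay never perturbs another's output and
every file is byte-identical across reruns of one seed.

**What passing tests do and do not show.** The generator has uniform base
composition, no GC or mappability structure, no PCR-duplicate process, no
capture-probe bias, and plants classes with clean effect sizes. Recovery
of ≥95% of planted labels and of the 190 bp repeat therefore validates
the *computations* — window arithmetic, normalization, rule logic, mixture
aggregation — not the biological error rates to expect on real libraries,
which depend on depth, noise and confounders the simulation deliberately
omits.

# Problem sizes and runtime choices

Analyses in the test suite and examples run at: 3 Mb genome, 900 sites,
10^5 MNase fragments and ~10⁴–10⁵ accessibility fragments per condition,
2×10^5 ChIP fragments, 10 Mb for the motif-density check, and 200
replicates for null calibration of the enrichment p-value — sizes chosen
so every statistical check has comfortable power (3σ margins on the
directional effects; KS calibration at n = 200) while a full run stays in
the minutes range on one core.

# Known limitations

* Consensus (IUPAC) scanning, not position-weight-matrix scoring; PWM
  support would change which sites enter the sampling loci.
* No bigWig/BAM I/O: the package starts from fragment-level text formats
  (BEDPE, BED) and writes bedGraph.
* The Mann–Whitney normal approximation is used whenever ties are present;
  for tiny tied samples a permutation test would be preferable.
* Background regions are not GC- or blacklist-matched.
* `classify_peaks` assumes the two libraries are comparable after a single
  global depth scaling; no trended (MA-style) normalization is applied.
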