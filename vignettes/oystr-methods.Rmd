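---
title: "Methods: assembly curation and rolling-circle element annotation with oystr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly curation and rolling-circle element annotation with oystr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oystr)
```

# Scope

`oystr` re-implements, as a tested and reusable pipeline, the bespoke
computational steps needed to curate a highly heterozygous diploid genome
assembly (such as the Pacific oyster's) and to annotate Helitron/Helentron
rolling-circle transposable elements by structure alone:

* k-mer spectrum profiling with genome-size and heterozygosity estimation;
* iterative, length-ordered haplotig purging with an internal approximate
  mapper;
* coverage-based identification of low-accuracy scaffolds with GC
  normalization, and a structural-variant error filter;
* linkage-map marker filtering, scaffold-to-linkage-group assignment, and
  scaffold ordering/orientation;
* a structural screen for intact Helitron-like elements, a Helentron
  substructure screen, 3'-end family clustering, a gene-fragment capture
  screen, and window-based density statistics.

Everything is exercised end-to-end on synthetic genomes with planted ground
truth, generated by the package itself; no external data are required.

# The synthetic-data generator

The generator defines the study conditions under which every downstream
stage is validated. Its defaults encode the structural statistics reported
for intact oyster Helitron-like elements:

* **Length**: Normal with mean 1,092 bp and SD 558 bp. Lengths are
  truncated to `[200, 1984]` — *symmetrically* about the mean — because a
  floor alone (negative or tiny lengths are impossible) would shift the
  realized mean upward by ~15-65 bp. Symmetric truncation preserves the
  mean exactly at the cost of shrinking the realized SD to ~435 bp; no
  downstream quantity depends on the SD.
* **Termini**: every element starts `TC` and ends `CTAG`.
* **Hairpin**: a perfectly self-reverse-complementary span of 16, 18 or
  20 bp (an odd-length span cannot be exactly self-complementary) ending
  5-10 bp upstream of the terminal `CTAG`.
* **Target site**: with probability 0.86 an element inserts between the A
  and the T of a host `AT` dinucleotide, so it is flanked by `A...T` on its
  own strand; this holds on either insertion strand because `A|T` is
  strand-symmetric around the cut. Otherwise a uniformly chosen non-AT
  junction is used.
* **Substructures**: a subTIR in 257/751 of elements; among elements with a
  subTIR, a 5' IR (the reverse complement of the subTIR placed again near
  the 5' end) in 33% and a 5' microsatellite in 1/257. These are the
  fractions observed in the oyster screen, used here as generator rates so
  that recovered rates can be compared against exact binomial bands.

Two generator design choices deserve emphasis because they define what the
tests do and do not show:

**Decoy-free interiors.** Element interiors (the region more than 200 bp
from the 3' terminus) are sampled free of the `TC` dinucleotide and of
internal `CTAG` motifs. The pairing rule of the detector takes, for each 3'
terminus, the *nearest* upstream `TC` at a compatible distance; in
unconstrained random DNA `TC` occurs every ~16-20 bp, so the nearest
compatible `TC` would essentially never be the true element start and
coordinate-exact recovery would be impossible for any detector using this
rule. Constraint sampling makes the true terminus the unique compatible 5'
candidate, turning recovery into a sharp, falsifiable test of the scan
logic. The corresponding limitation is stated under *Limitations*: on real
sequence the detector reports the shortest structurally compatible
interval, not necessarily the full element.

**Exact truth labels.** When a substructure is *not* requested, the
realized terminal windows are rejection-sampled until the package's own
finders report it absent (and when one is requested, until the planted copy
is what the finder sees). Without this, spurious subTIRs arise in ~5% of
50-bp window pairs at the default 10-bp/1-mismatch search, and recovered
rates would drift away from the planted rates through no fault of the
detector. Truth labels therefore mean exactly what they say. Realization
retries never redraw the element's length or substructure flags — those are
drawn once per element — so the planted rates and the length distribution
remain unbiased.

The simulator draws a single RNG seed per call and restores the caller's
RNG state afterwards; identical seeds give byte-identical outputs.

# The structural Helitron scan

A candidate element is an interval whose sequence (on its own strand)
starts `TC`, ends `CTAG`, and carries a hairpin-capable inverted repeat
ending within a configured gap upstream of the terminal `CTAG`. The scan
proceeds per strand: hairpin spans are enumerated, `CTAG` positions with a
supporting hairpin become 3' candidates, each is paired with the nearest
upstream `TC` at a distance within `[min_len, max_len]` (default
`[200, 20000]`, bracketing the ~1.1-kb typical element), and overlapping
candidates on a strand are resolved by fewer hairpin mismatches, then
shorter length, then leftmost position. The reverse strand is scanned on
the reverse complement and mapped back, which makes
`scan(revcomp(G))` exactly the mirror image of `scan(G)`.

**Default hairpin stringency.** The general-purpose hairpin finder
(`find_hairpins()`) defaults to permissive settings: stem at least 6,
at most 1 mispaired stem position, loop unconstrained within a 16-20 bp
span. Those settings are appropriate for exploring a candidate
neighborhood, but they cannot drive a whole-genome scan: with `CTAG`
occurring about once per 256-330 bp per strand and a ~29-position window
for the hairpin end, the expected number of qualifying hairpins per window
under the permissive profile is of order 0.4-0.7, which would produce
thousands of false elements per Mb on random DNA. A precision target of a
few false elements per Mb (needed for the count of "intact" elements to
mean anything — the oyster screen reports ~1.2 intact elements per Mb)
requires the per-window hairpin probability to be below about `1e-3`.
Working through the combinatorics at oyster-like GC, only mismatch-free,
fully self-complementary spans (loop 0, stem 8-10) with a tight
hairpin-to-`CTAG` gap achieve this. `scan_params()` therefore defaults to
`max_mismatch = 0`, `max_loop = 0`, `min_stem = 8`, and a gap of
`[2, 12]` bp — the canonical hairpin placement for this element family
sits a handful of bases upstream of the terminus. Measured false-element
rates on 2-Mb element-free controls at matched GC are 1-4 per Mb. All
knobs remain exposed for sensitivity analyses.

`at_site` is diagnostic, not a filter: requiring it would discard the ~14%
of genuine elements that insert at non-AT junctions.

# Helentron substructures and classification

The subTIR search looks for the longest pair of substrings, one in each
50-bp terminal window, that are reverse complements up to 1 mismatch and at
least 10 bp long, breaking ties toward the termini. Because the search is
maximal, a planted subTIR is typically reported extended by one or two
chance-complementary flanking columns; tests therefore assert containment
of the planted copy rather than exact equality (and exact equality under a
mismatch-free search up to chance extensions). The 5' IR is a match to the
reverse complement of the subTIR within the 5' window, non-overlapping with
the subTIR's own 5' copy. The microsatellite is the longest perfect tandem
run in the 5' window with unit length 1-6, at least 3 full copies and a
span of at least 9 bp.

Classification formalizes the verbal taxonomy: no subTIR is `helitron`;
subTIR plus IR or microsatellite is `helentron_like`; subTIR alone is
`intermediate`. The function is total on all eight flag combinations — a
microsatellite without a subTIR does not make an element Helentron-like.

# k-mer profiling

Canonical k-mers (lexicographic minimum of k-mer and reverse complement;
k odd so no k-mer is its own reverse complement) are counted in C++ into a
depth histogram. The histogram is smoothed with a centered moving average
of width 3. The error cutoff is the depth of the first local minimum —
depth 1 when the histogram rises from the origin, as in error-free
simulations. Peaks are local maxima above the cutoff; when the two most
massive peaks sit at a depth ratio within `[1.6, 2.4]` the lower is the
heterozygous and the higher the homozygous peak, otherwise the spectrum is
treated as single-peaked. This closed-form peak estimator deliberately
replaces a full negative-binomial mixture fit: it is transparent, fast,
and sufficient for parameter-recovery testing; it is *not* a reimplementation
of a mixture-model profiler.

**Genome size** is the total informative k-mer mass divided by the
homozygous peak depth:
`size = sum(d * count(d); d >= cutoff) / hom_peak`.
On error-free haploid simulations this is accurate to better than 1%
(the residual bias comes from the integer peak depth).

**Heterozygosity.** Let `F` be the k-mer mass in the heterozygous peak
region (cutoff to valley) over the total informative mass. For per-base
heterozygosity `h` with independent sites, a k-mer window is disrupted with
probability `a = 1 - (1 - h)^k`; a disrupted window contributes *two*
distinct k-mers (one per haplotype) at half depth, and an intact window one
k-mer at full depth, so the het-peak *mass* fraction is
`2a * (c/2) / (2a * (c/2) + (1 - a) * c) = a` exactly. Inverting gives

```
h = 1 - (1 - F)^(1/k)
```

Recovery on simulated diploids at 1.0%, 2.0% and 3.2% heterozygosity is
within 0.05 percentage points, comfortably inside the 0.5-point band the
tests assert. Misassignment of mass across the valley (the Poisson tails
of the two peaks overlap slightly) contributes only ~0.02 points at 60x
because the two errors nearly cancel.

# Iterative haplotig purge

Contigs are sorted by decreasing length (ties broken lexicographically).
The longest unprocessed contig becomes the reference; all other unprocessed
contigs are mapped against it, and a contig is removed as a haplotig when
its covered fraction is at least 0.30 (inclusive, matching the ">= 30%"
phrasing) *and* its own length exceeds 10 kb — the length condition is read
as applying to the removed contig, since it is the subject of the removal
sentence; the alternative reading (matched stretch > 10 kb) is available
via `map_contig()`'s covered-bp output. The reference is then kept and
removed from the pool together with the just-removed contigs; references
are never re-tested later.

The internal mapper is a `(k = 15, w = 10)` canonical-minimizer sketch:
the query is tiled into 500-bp windows and a window counts as covered by a
target when at least 10 of its minimizers occur in that target; the covered
fraction is covered bases over full query length. Repeat soft-masking drops
minimizers overlapping masked intervals on either side. At 3% haplotype
divergence a 15-mer survives with probability ~0.63, leaving ~55 of ~90
window minimizers matching — detection is far from threshold, while
unrelated contigs share <1% of minimizers. An exact-alignment oracle
(single best local alignment; coverage = aligned query length over query
length) can be injected through `coverage_fun` and is used in the tests to
pin the decision semantics on small contigs.

Keep-list intersection implements the two-method consensus: only contigs
kept by both curation routes survive; the remainder are reported with
reason `external_only`.

# Coverage QC and the SV error filter

Median read depth is computed in non-overlapping 1,000-bp windows (the
final window of a scaffold may be shorter; tiling is exact). GC
normalization bins windows by GC in 2% bins; each bin's factor is the
global median of window medians over the bin median, and bins with fewer
than 10 windows inherit the nearest populated bin's factor. With a single
populated bin the factor is exactly 1. A window is an outlier when its
normalized median deviates from the assembly-wide mean by more than 2 SD
(the mean and SD are assembly-wide: per-scaffold statistics would make
deviation self-referential for small scaffolds); a scaffold is flagged
when its outlier-window fraction *strictly* exceeds 0.70, so 7 of 10
windows does not flag. Flags are invariant under global depth rescaling
because both the normalization factors and the mean/SD band scale with
depth.

An SV record marks an assembly error when its length is at least 50 bp and
`ref / (ref + alt)` is strictly below 0.2; a ratio of exactly 0.2 does not
qualify, a length of exactly 50 bp does. Records with zero total support
are excluded with a warning rather than treated as errors.

One interaction discovered during design: if aberrant-coverage scaffolds
dominate a GC bin, binned-median normalization rescales them toward the
mean and erases the signal. The simulator therefore gives junk scaffolds
the same GC profile as ordinary sequence and keeps them a small fraction of
windows — matching the realistic regime where unplaced junk is a sliver of
the assembly. The QC cannot be expected to work when "junk" forms a
dominant, GC-coherent fraction of all windows.

# Linkage-map anchoring

Markers are retained when aligned with MAPQ strictly above 16 (17 kept, 16
dropped). A scaffold's linkage group is the modal group of its retained
markers; when the runner-up group holds more than 20% of markers the
scaffold is flagged `conflicting` rather than silently resolved. Within a
linkage group, scaffolds are ordered by mean cM; orientation is the sign
of the Spearman correlation between cM and bp (rank correlation, because
the cM-bp relation is monotone but not linear), reported `uncertain` below
|rho| = 0.5 and `unknown` with fewer than two markers. With 20+ markers
per scaffold and 1 cM noise on ~20 cM scaffold spans, exact order recovery
exceeds 95% across 100 seeded trials.

# 3'-end families, capture screen, density statistics

**Pair identity** of terminal 30-mers is computed by global alignment
(match +1, mismatch -1, linear gap -2, end gaps penalized); identity is
matching columns over total alignment columns — the "matching columns /
alignment length" identity definition, pinned to a fixed scoring scheme
because that definition depends on the alignment produced.

**Greedy clustering** processes sequences by decreasing abundance (count
of identical strings), ties by first occurrence; each joins the best
centroid at identity >= 0.80 (a floor, matching the semantics of an
identity-threshold flag) or founds a new family. On well-separated planted
families (within >= 0.93, between <= 0.5) the partition equals
single-linkage clustering computed by brute force. "Conserved 3' ends"
are counted as members of families of size >= 2 by default;
`count_all = TRUE` counts every element, since the choice is a reporting
convention. Density is conserved ends over genome size in Mb, and a
chromosome is enrichment-flagged when its density exceeds the
across-chromosome mean by more than one population SD.

**Capture screen**: each element is translated in six frames, split at stop
codons (so no alignment spans a stop), and each open segment is locally
aligned against each protein under BLOSUM62 with affine gaps (11/1). A
match requires a contiguous alignment-column window longer than 50 residues
at >= 85% identity; the windowed rule mirrors HSP semantics, because an
optimal local alignment can over-extend past a homologous core through
cheap gaps and dilute its identity.

**Window counts**: features are counted once per 100-kb window, in the
window holding the largest share of the feature's length; exact ties go to
the lower-coordinate window, and the total count is conserved by
construction. Pearson correlation between count vectors carries a
closed-form two-sided p-value via `t = r * sqrt((n-2)/(1-r^2))`; Spearman
is available since the correlation type behind a bare "corr" is a
convention. Zero-variance input yields `NA`, never 0.

# Problem sizes used by the tests

Unit tests run on kilobase-scale fixtures. The end-to-end suite uses: a
2-Mb genome with 200 planted elements (and a 2-Mb matched-GC control) for
recovery/precision; 2,000 planted elements for the AT-site band; 100
random 5-kb sequences for the hairpin oracle; 500 terminal 30-mers for
clustering; 20 small contigs plus three seeded diploid simulations for the
purge; three seeded coverage simulations for QC; a 1-Mb haploid and
600-kb diploid pairs at 50-60x for k-mer recovery; and 100 seeded trials
for anchoring. These sizes make the whole suite run in a few minutes on
one CPU while keeping every statistical band meaningful.

# Limitations

* The generator plants substitution-divergence only; no indels, no
  sequencing-error profiles, no quality strings, and no repeat landscape
  beyond what is explicitly planted. Passing tests demonstrate correctness
  of the algorithms under these conditions, not performance on real reads.
* Planted element interiors are decoy-free (see above). On real sequence
  the nearest-TC pairing rule yields the shortest structurally compatible
  interval; downstream statistics that depend only on the conserved 3' end
  are unaffected, but element length distributions from real scans should
  be treated as lower bounds.
* The k-mer profiler is a peak estimator, not a mixture-model fit; it
  assumes a clean bimodal spectrum and will refuse (with an error) rather
  than guess on degenerate histograms.
* The purge's internal mapper is a desk-scale approximate mapper; for
  chromosome-scale contigs an external long-read mapper remains the right
  tool, with `coverage_fun` as the integration point.
* Scaffold-level QC assumes aberrant scaffolds are a minority of windows
  and share the bulk GC distribution.
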