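---
title: "Calling identical-by-state haplotype blocks between assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling identical-by-state haplotype blocks between assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panhap)
```

## The problem and the model

Cultivars of a recently domesticated, inbreeding crop share long chromosomal
segments that are identical-by-state (IBS): not merely similar, but
indistinguishable except for technical noise (assembly Ns, sequencing errors
in low-complexity runs). Three divergence regimes matter:

* **IBS haplotypes** — identity indistinguishable from 100% at the
  resolution tested;
* **near-identical sequence** — ≈99.9–99.99% identity. Under a neutral
  clock, two lineages separated for $t$ years at substitution rate $r$ per
  nucleotide per year retain expected identity
  $100\,(1 - 2rt)$; at the intergenic wheat rate $r = 1.6\times10^{-8}$ and
  $t = 10^4$ years this is 99.968% (`expected_identity(1.6e-8, 1e4)`), i.e.
  *below* the IBS threshold — shared ancestry as old as domestication does
  **not** look identical;
* **introgressions** — segments from wild relatives at < 99.5% identity.

`panhap` calls IBS blocks with two complementary routes and builds the
downstream analyses (lifting, sharing, conservation, marker design) on top.

## Binned-identity caller

For an alignment of length $l$ with $m$ mismatch columns, identity is
$100\,(1-m/l)$. The procedure:

1. drop alignments shorter than `min_aln_len` (default 20,000 bp — short
   alignments are dominated by non-syntenic retrotransposons, whose median
   alignment length in wheat is ≈9.6 kb);
2. assign each surviving alignment to one bin by its reference midpoint
   $\lfloor(s+e)/2\rfloor$ (each alignment votes once; bin $i$ spans
   $[(i-1)B+1,\,iB]$ with $B$ = `bin_size`, default 5 Mbp, finer resolutions
   2.5 and 1 Mbp);
3. a bin is *good* when the **median** of its alignment identities is
   ≥ `threshold` (default 99.99%, i.e. one mismatch per 10 kb — the slack
   below 100% absorbs Ns and errors in low-complexity sequence);
4. stitch maximal runs of bins that start and end on good bins and contain
   no internal run of more than `max_err_run` (default 2) non-good bins.

Numerical choices worth stating:

* the threshold comparison is `>=` with an epsilon of $10^{-9}$ on the
  percent scale; identities derive from integer mismatch counts, so
  exactness is well defined;
* **empty bins count as error bins** and are absorbed like sub-threshold
  ones. N runs in either assembly fragment alignments, and fragments under
  20 kb are filtered, so true blocks legitimately contain alignment gaps;
* a single good bin is a valid block, and blocks never begin or end on an
  error bin — the bounds are the genomic bounds of the first and last good
  bin. Whether the original procedure allowed single-bin blocks or absorbed
  trailing errors is not documented; these choices are the conservative
  reading and are locked in by the exhaustive stitching tests;
* the two-error allowance is per *run* of consecutive errors, not per block
  total ("two consecutive errors" is read literally);
* the median is over raw alignment identities, not bp-weighted — a long and
  a short alignment in the same bin count equally.

Where reciprocal alignments exist, a block is kept only if its lifted
interval overlaps (≥ 1 bp) a block called in the opposite orientation;
the overlap rule is the weakest defensible one since no stricter rule is
documented.

## Gene-window caller

Scaffold-level assemblies cannot be aligned whole-chromosome against each
other, so a second route aligns each projected gene (body ± `flank` bp) of a
reference annotation between cultivars:

1. per (gene, pair), keep the **largest HSP** (ties: higher bitscore, then
   higher identity — a documented tie-break, since none is published);
2. drop genes projected to an unexpected chromosome, genes projected more
   than once there, and alignments whose aligned sequence contains Ns;
3. order survivors by reference gene rank and slide a window of `W`
   (default 25) consecutive survivors, stepping one gene. Consecutive means
   consecutive *among survivors*: windows bridge N-dropped genes rather than
   restarting, because the ordering is applied to the filtered set;
4. in each window remove the `ceiling(trim_frac * W)` lowest-identity
   alignments (3 of 25 at the defaults — the ceiling is forced by "10% of
   25 = 3") and call the window IBS iff the mean of the remainder equals
   100% (within $10^{-9}$);
5. merge overlapping/adjacent IBS windows and report each run from the full
   span of its first gene to the full span of its last gene (midpoints would
   shave real block sequence), lifting into the target assembly when it is
   not the annotation assembly.

The trim has a consequence worth knowing: a divergent feature covered by at
most `ceiling(trim_frac * W)` genes is invisible to the window. At `W = 30`
the trim is 3, so a divergent segment spanning ≈3 genes is absorbed and
windows bridge it. The parameter sweep fixture therefore plants divergent
segments ≈6 genes wide; with narrower segments the precision ordering
between window sizes genuinely inverts, which is a property of the
trimmed mean, not a bug.

`combine_blocks()` merges the two call sets: every binned-caller block plus
each gene-window block that is *not* both overlapping a binned block and
shorter than the bin size ("already represented" is taken as any bp
overlap; nothing stricter is documented). `precision_recall_f1()` and
`parameter_sweep()` score gene-window calls against binned calls — precision
= fraction of gene-window blocks touching a binned block, recall the
converse, F1 their harmonic mean, zero when degenerate.

## Gene-anchored coordinate lift

Intervals move between assemblies via shared gene projections: collect
source genes in the interval, find their target projections (genes projected
more than once in the target are excluded as ambiguous anchors — consistent
with the gene-window filters), sort by target position, and join runs
tolerating gaps of up to `gap = 20` intervening genes. The gap is measured
in the **target assembly's chromosome-wide projected-gene rank**, since
target adjacency is what the sort establishes; the published description
does not define the metric. If at least one run holds `min_run = 10` genes,
all such runs are kept; otherwise only the longest (status
`"longest_only"`). The published text uses both "at least 10" and "more
than 10"; the inclusive reading is implemented and `min_run` is exposed.
Orientation is ignored for coordinates — runs are reported min-to-max.

## Sharing, conservation and positional summaries

Per-pair sharing is the unioned block footprint over the reference size
(invariant to block splitting). Partner coverage at a position counts the
other cultivars sharing a block there, each partner unioned first; the
machinery is IRanges coverage, which is also what the published analysis
used. Regions with coverage ≥ `min_partners = 5` are "highly conserved"
(6 cultivars counting the reference). Block length/gene content is sampled
at fixed 500-kb points (a block is recorded at every point it intersects, so
a 5-Mbp block contributes 10–12 samples depending on phase), medianised in
1% position bins per chromosome, and compartment medians (R1/R2a/C/R2b/R3,
supplied as a boundary table) are taken over the chromosome-level bin
medians while min/max come from raw values. Group comparisons delegate to
`wilcox.test` with Benjamini–Hochberg adjustment.

## Markers and haplotype groups

Over a minimum haplotype block (MHB — the interval with no observed
recombination between groups; the motivating case spans 187–445 Mbp, i.e.
258 Mbp), group profiles are exemplar allele vectors; markers inconsistent
among replicate exemplars are dropped, and groups identical over the
survivors merge into a resolvability class ("H1/H2"). Line assignment
matches non-missing calls against profiles: one hit gives the group, several
give the merged label, none gives a novel label ("N1", "N2", … by first
appearance), and lines below an 80% call rate are "unassigned" — the
missing-call policy is not published, so both knobs are parameters.
`design_panel()` greedily maximises the minimum pairwise Hamming distance
until every pair differs at ≥ `min_diff = 3` markers (redundancy against
single assay failures), breaking ties towards an even physical spread
across the MHB; it operationalises an informal published rule, and real
panels would still be hand-curated after assay testing.

## The synthetic pangenome

The generator is the package's study condition, not a tuning knob. One
ancestral chromosome; planted blocks where a set of cultivars carries a
single shared haplotype (pairwise identity exactly 100% inside, except
where N runs interrupt); i.i.d. background substitutions at pairwise rate
3.2×10⁻⁴ (the 10,000-year expectation above, split evenly between
lineages, with the planted-block haplotype carrying its own half so that
member–non-member pairs still diverge at the full background rate);
introgression-like segments at 0.7% divergence; explicit N runs. Alignment
records are emitted *by construction* — collinear segments cut at N runs
and at block/introgression boundaries, then chunked to `aln_chunk`
(default 100 kb, since real whole-chromosome aligners emit many records,
not one) with exact mismatch counts — plus a few sub-20-kb noise records so
the length filter does real work. Background and planted-haplotype
substitutions avoid gene bodies by default (`genic_conservation`), which is
what makes flankless gene alignments blind to near-identical divergence;
the substitution *count* is still drawn over the full region so genome-wide
calibration holds. Defaults: 3 cultivars, 50-Mbp chromosome, one 20-Mbp
block between cv1 and cv2, 20 genes/Mbp (3-kb bodies), 2 markers/Mbp.

What it does **not** emulate: indels and structural variation (alignment
segmentation stands in for them), recombination/coalescent genealogies,
transposon turnover, polyploid homoeology, and assembly errors beyond N
runs. Passing recovery tests therefore demonstrates the callers' logic
under the stated divergence regimes, not robustness to real assembly
artefacts.

All randomness flows from one mandatory seed in a fixed draw order;
identical spec + seed reproduce byte-identical outputs.

## Problem sizes and runtime

The test suite and acceptance script run on one CPU in minutes: recovery
uses 20 seeded 50-Mbp replicates (5-Mbp bins, a quarter of the planted
block length); the stitching caller is checked against exhaustive
enumeration over every good/bad bin vector up to length 12; calibration
uses whole-pair mismatch totals against binomial 95% intervals; the sweep
fixture is a 10-Mbp, 300-gene chromosome with four planted blocks of
decreasing gene content. These sizes were chosen as the smallest at which
every behaviour of interest (bin-boundary effects, trim absorption, N-loss
at wide flanks) is actually exercised.

## Known limitations

* Identity is computed from mismatch counts supplied by the alignment
  tables; gapped-column conventions are inherited from the upstream
  aligner, not re-derived.
* The binned caller's block bounds are bin-quantised; boundary precision is
  limited to `bin_size` by design.
* `lift_interval()` is gene-anchored only — intervals without gene anchors
  fail to lift, and intergenic boundary placement is approximate.
* Duplicate SNP positions are resolved first-kept, and novel haplotype
  labels depend on input line order; both are deterministic but
  order-sensitive.
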