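---
title: "Comparative UCP1 promoter analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative UCP1 promoter analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prometh)
```

# The problem this package addresses

Uncoupling protein 1 (UCP1) is the effector of non-shivering thermogenesis in
brown adipose tissue (BAT), and the question of what makes its expression
tissue- and species-specific keeps returning to the 5' regulatory region:
a CpG island (CGI) near the transcription start, a ~500 bp distal enhancer
(human anchor-relative position −3488) and a second ~500 bp putative
regulatory region ("PRR", human position −2095).  Comparative analysis of
these features across vertebrates requires four computational steps, each of
which this package implements as a tested, reusable operation:

1. **Orthology via conserved synteny** — only UCP1 genes flanked by TBC1D9
   (5') and ELMOD2 (3') are accepted, so that upstream regions are compared
   between true orthologs (`check_synteny_triplet()`).
2. **Anchor-relative upstream extraction** — strand-normalized windows around
   the gene start (`extract_upstream()`).
3. **Feature detection** — two-tier CGI detection under the
   Gardiner–Garden–Frommer (GGF) criteria (`scan_seeded()`,
   `scan_exhaustive()`) and local-alignment search for the enhancer and PRR
   (`find_element()`).
4. **Methylation and expression arithmetic** — percent methylation from
   methylation-sensitive restriction-digest qPCR (MSRD-qPCR) and from
   bisulfite base counts, and ΔΔCt relative expression
   (`msrd_percent_methylation()`, `bisulfite_percent()`,
   `relative_expression()`).

Because public genome assemblies and wet-lab measurements are not
reproducible at desk scale, every stage is exercised end to end on synthetic
data with machine-readable truth (the generators in `make_*()` /
`simulate_*()`), and the analysis scripts under `analysis/` run the whole
pipeline on a synthetic species panel.

# Coordinates and anchors

All internal coordinates are 0-based half-open.  Reported feature positions
are **anchor-relative signed integers**: position −3488 means 3488 bp
upstream of the anchor, matching the convention in which comparative tables
report "human position −3488".  For a minus-strand gene the extracted window
is reverse-complemented, so regions always read 5'→3' of the gene and
"upstream" is always negative.

The literature this field builds on conflates the transcription start and the
open-reading-frame start (one even finds "translational start site (TSS)").
`region_spec()` therefore makes the anchor explicit (`anchor_kind`,
default `"orf_start"`); when only gene bounds are annotated the two anchors
coincide with the gene boundary.  Whether a published 10 kb enhancer search
and a 5 kb CGI screen used the same anchor per species is generally unstated,
so both spans are plain parameters:

* CGI screen: `span_upstream = 5000`, `span_downstream = 1000`.  The
  downstream margin is required because islands can sit just downstream of
  the start (the hedgehog promoter being the standard example).
* Element search: `span_upstream = 10000`, `span_downstream = 0`.

# CpG-island detection

`cpg_stats()` implements the GGF quantities: G+C fraction, observed CpG
count (CG dinucleotide starts), expected count `#C × #G / length`, and their
ratio.  An island must have length ≥ 200 bp, GC ≥ 0.50 and observed/expected
\> 0.60 (all configurable through `scan_params()`).  When `#C × #G = 0` the
ratio is undefined; it is reported as 0 with `oe_defined = FALSE` and can
never pass — a sequence without C or G has no CpG island.

Two scans implement the two stringency tiers:

* **Seeded scan** (`scan_seeded()`): every position scores +17 at a CG
  dinucleotide start and −1 otherwise (the classic CpG-scanner weights, under
  which a segment scores positively once its CpG-start density exceeds 1/18).
  All maximal positive-scoring segments are extracted with Ruzzo & Tompa's
  linear-time algorithm and filtered by the three criteria.  This mirrors the
  behaviour of maximal-segment CGI screens: it is sharp on dense islands and
  blind to marginal ones.
* **Exhaustive scan** (`scan_exhaustive()`): every window of length ≥ 200
  whose statistics pass the criteria counts; overlapping or abutting
  qualifying windows are merged and the merged interval is reported with its
  own statistics.  The reported base coverage is exactly the union of all
  qualifying windows (the per-start maximum-end optimization is coverage
  equivalent because same-start windows are nested).

`classify_islands()` assigns tier `"high"` to exhaustive islands that overlap
a criteria-passing seeded segment and `"low"` otherwise, and
`species_cgi_call()` collapses a species to
high stringency / low stringency / absent.  The published two-tier vocabulary
does not come with an algorithmic definition of its relaxed pass; defining
"low stringency" as *found only by exhaustive window enumeration* makes the
tiering fully specified and testable against a brute-force oracle.

## Numerical and boundary behaviour worth knowing

* **N handling.** Windows containing any `N` are ineligible by default
  (`max_n_fraction = 0`): assembly gaps should neither create nor bridge
  islands.  `N` counts toward window length only.
* **Merged-interval statistics can dip below the thresholds.**  A union of
  qualifying windows need not itself qualify (each flank extension can
  exhaust the GC budget separately).  Such islands are still reported — they
  are unions of bona-fide qualifying windows — with `criteria_pass = FALSE`
  recording the re-check, preserving auditability without hiding coverage.
* **Boundary over-extension is intrinsic to window-union detection.**  For an
  island of GC fraction $g > 0.5$ embedded in background of GC $b < 0.5$, a
  window extending $f$ bases into the background still satisfies GC ≥ 0.5 up
  to $f^\* \approx L(g-0.5)/(0.5-b)$, and the O/E criterion rarely binds
  because the island's CpGs dominate the window.  Reported exhaustive islands
  therefore extend beyond a planted island by up to $f^\*$ *per side* (for
  the package's GC-0.35 background and $g = 0.6$, about $0.67L$ in total), so
  the *reciprocal* overlap between a planted island and its merged detection
  plateaus around $1/(1+2(g-0.5)/0.15)$ — about 0.4–0.6 — even though the
  planted island itself is essentially always fully covered.  Even a pure-AT
  background caps reciprocal overlap at $1/(4g-1)$.  Detection should
  therefore be judged by coverage of the true island; boundary precision is a
  known limitation of GGF window unions, and the seeded segments (when
  present) provide the sharper localization.
* **Strong islands can bridge.**  Under +17/−1 scoring, two dense islands
  separated by a gap cheaper than their scores form one maximal segment; if
  the bridged segment fails the GC criterion it is filtered from the seeded
  output and the islands are recovered (separately) only by the exhaustive
  scan, i.e. at low stringency.  This is faithful to maximal-segment
  screens rather than a defect.

# Element search

`local_align()` is an affine-gap Smith–Waterman (match +2, mismatch −3, gap
open −5, gap extend −2; a gap of length $L$ costs
`gap_open + (L-1) * gap_extend`).  `N` is a universal mismatch, so runs of
assembly gaps cannot anchor alignments; an all-`N` target yields an empty
alignment of score 0.  Among equal-scoring optima the alignment with the
smallest target start, then smallest target end, is returned; remaining path
ties follow a fixed state preference so output is deterministic.
`percent_identity()` counts identical columns over all aligned columns with
gap columns in the denominator — the convention is stated because published
pairwise identities rarely say which one they used.

`find_element()` combines two alignments:

* the **local** alignment finds the best-conserved core and supplies the raw
  score and `query_coverage` (fraction of the query inside the core);
* a **semi-global** alignment (query end to end, target ends free) places the
  whole element and supplies the reported interval and identity.

The reasons for the second step are quantitative.  A trimmed local core
systematically *overstates* identity (it keeps only the best-scoring
columns) and shifts the reported start when leading element bases are
mutated; measured on generator truth, core-based reporting is biased by +2.5
to +8 identity points at 20–40 % divergence with start errors up to ~23 bp.
The semi-global optimum for a substitution-only homolog is the ungapped
diagonal through the planted copy (an internal gap pair costs $-6-4k$ versus
$-3k$ for $k$ mismatches, so gaps never pay), which makes the reported start
exact and the reported identity equal to the substitution-level identity —
the quantity that published element-level percent identities (e.g. a
human–cow enhancer comparison) describe.  Near 40 % divergence the scoring
scheme's identity breakeven ($\text{mismatch}/(\text{match}-\text{mismatch})
= 60\%$) is reached and *any* maximum-score alignment admits stochastic gap
detours; reported identities can then deviate by a few points from truth.
That regime is at the detection threshold anyway.

Presence requires identity ≥ 60 % *and* core coverage ≥ 0.6.  The thresholds
are defaults chosen so that element pairs around 75 % identity — reported as
present in published comparisons — pass with margin; both are recorded in
every `element_hit`.  Only the forward strand of the (strand-normalized)
region is searched: regulatory-element orientation relative to the gene is
preserved by the extraction step.  Absent hits keep their best sub-threshold
interval, identity and score for audit.

# Methylation and expression arithmetic

**MSRD-qPCR** (`msrd_percent_methylation()`): for a methylation-blocked
enzyme, surviving template measures methylation.  Per replicate,
$$S = 2^{-\left[(Ct^{dig}_{tgt}-Ct^{dig}_{ref}) - (Ct^{mock}_{tgt}-Ct^{mock}_{ref})\right]},$$
and percent methylation is $100\min(S,1)$.  Choices:

* Amplification efficiency is fixed at 2.0 per cycle (the standard ΔΔCt
  assumption); the reference amplicon must not contain the recognition site.
* $S > 1$ (digest amplifying better than mock) arises from noise and is
  clamped to 100 % with a warning.
* Replicates are paired by replicate index when all four arms share indices,
  otherwise a single all-vs-mean estimate is formed; the published protocols
  report "mean ± SEM of ≥ 3 replicates" without pairing detail, and pairing
  cancels plate offsets exactly (the estimator is invariant to adding a
  constant to every Ct of a replicate).
* Reactions flagged as non-amplifying count as $S = 0$: complete digestion of
  an unmethylated template.
* When control digests with a methylation-insensitive isoschizomer (MspI for
  HpaII, MnlI alongside TaiI) are present, their survival $S_c$ gauges
  digestion completeness: `completeness_flag` fires when $S_c$ exceeds
  `tolerance` (default 0.05), and a background-corrected estimate
  $100\,(S-S_c)/(1-S_c)$ (clamped to $[0,100]$) is emitted as well.  The
  published protocols use the insensitive enzyme qualitatively "to correct
  for incomplete digestion" without a formula; both raw and corrected values
  are therefore reported.

**Bisulfite** (`bisulfite_percent()`): the raw per-CpG estimate is
$100\,c/(c+t)$, the binomial ML estimate.  With conversion efficiency
$e < 1$, unconverted unmethylated C inflates the signal by $(1-e)$; the
corrected estimate $100\max(0, c/(c+t)-(1-e))/e$, clamped to $[0,100]$,
inverts the expectation $m + (1-m)(1-e)$.  Zero-coverage positions are
reported as missing rather than dropped, mirroring failed pyrosequencing
assays.

**Expression** (`relative_expression()`): per tissue
$\Delta Ct = Ct_{tgt} - Ct_{ref}$, fold $= 2^{-\Delta\Delta Ct}$ against a
calibrator tissue whose fold is 1 by construction.

`find_sites()` locates recognition sites (IUPAC-aware pattern matching via
Biostrings); `N` never matches; palindromic sites (CCGG, ACGT) are counted
once, non-palindromic ones (CCTC) optionally on both strands.

# The synthetic-data generators

The generators define the study conditions under which everything is
validated:

* **Background DNA** (`make_promoter()`, `make_triplet_genome()`): a
  first-order chain with GC 0.35 and the C→G transition suppressed to 0.2 of
  its independence expectation — the classic CpG depletion of vertebrate bulk
  DNA.  Under these constants, 10 kb of background produces no CGI call and
  no element presence across 100 seeds at default thresholds.
* **Islands** (`make_island_sequence()`): a first-order chain whose C→G
  transition probability is tuned by bisection against the chain's stationary
  distribution so the expected O/E hits the target, with the base
  distribution adjusted by a short fixed-point iteration so stationary GC
  hits the target; sequences are resampled (≤ 100 attempts) until realized
  stats fall within ±0.03 (GC) and ±0.1 (O/E), else an error names the
  violated bound.  Infeasible targets (O/E above the $q=1$ maximum) error up
  front.
* **Homologs** (`mutate_element()`): Bernoulli substitutions (never to the
  same base) and optional single-base indels, never within 10 bp of the
  element ends so position-fidelity checks stay well defined; the edit record
  makes truth identity exactly computable.
* **Ct tables** (`simulate_ct()`): $Ct = \text{baseline} - \log_2 S +
  \mathcal N(0,\sigma)$ with $S = m + (1-m)(1-d)$ for a blocked enzyme,
  $1-d$ for the insensitive control, 1 for mock and for the site-free
  reference; $S = 0$ emits a flagged sentinel at the maximum cycle.
* **Bisulfite counts** (`simulate_bisulfite()`):
  $c \sim \text{Binomial}(\text{depth},\, m + (1-m)(1-e))$.

Every generator is a pure function of its arguments including the seed.

What the generators deliberately do **not** model: repeat content, real
assembly gaps and coverage structure, isochores and genome-scale GC
heterogeneity, primer and amplification-efficiency effects, pyrosequencing
signal processing, and biological replicate structure beyond i.i.d. noise.
Passing tests therefore demonstrate the *arithmetic and algorithmic*
correctness of the pipeline under controlled truth, not performance on real
assemblies.

# Problem sizes used by the test-suite and acceptance script

The suite validates the exhaustive scanner against an $O(L^2)$ brute force on
100 random sequences of 300–2000 bp at mixed GC; plants 20 islands
(250–800 bp, GC 0.55–0.70, O/E 0.7–1.2) in 10 kb backgrounds and scans 100
feature-free backgrounds; checks the aligner against a memoized-recursion
oracle on 50 pairs ≤ 60 bp; plants element homologs at divergence 0–0.4;
and runs 200-seed simulations for the MSRD (noise sd 0.2 cycles, 3
replicates) and bisulfite (depth 1000, $e = 0.98$) estimators.  These sizes
keep each property statistically meaningful while the whole suite stays
desk-scale.

# Known limitations

* Exhaustive-island boundaries over-extend into flanking sequence by design
  (see above); use coverage, not reciprocal overlap, to judge detection, and
  seeded segments for sharp localization.
* Reported element identities are biased by at most a few points once
  divergence approaches the scoring breakeven (~40 % under the default
  scores); presence calls there depend on the configured thresholds, as they
  must.
* The species presence matrix reports whatever species it is given; it does
  not arbitrate between a table caption and a species list that disagree
  about the count (published tables have been known to do so).
* Methylation estimates assume perfect doubling per cycle and a single pool
  of template; allele-specific methylation and PCR bias are out of scope.
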