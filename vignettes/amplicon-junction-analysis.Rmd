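---
title: "Characterizing rearrangement junctions in amplified genome regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing rearrangement junctions in amplified genome regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amprearr)
```

## The problem

Gene amplification in tumour cells takes two cytogenetic forms:
extrachromosomal circles (double minutes, *dmins*) and intrachromosomal
tandem blocks (homogeneously staining regions, *hsrs*). When a xenografted
tumour carrying dmins converts to an hsr over serial passages, the amplified
DNA is shuffled: fragments of the source regions — some only tens of base
pairs long — are fused at novel junctions, lost, or newly created. The
sequence at each fusion seam carries a mechanistic signature: blunt seams
and 1–2 bp microhomologies point to non-homologous or
microhomology-mediated end joining (NHEJ/MMEJ); templated inserts and
hypermutated flanks would instead implicate replicative template-switching
mechanisms (FoSTeS/MMBIR).

`amprearr` implements the corresponding analysis as a reusable, tested
pipeline over junction calls, a reference, and read-depth tracks:

1. **Coverage**: bin depth (3 kb default), call amplified segments, and do
   interval arithmetic between amplification states.
2. **Junctions**: filter calls, compute two-sided microhomology, call
   untemplated insertions from spanning sequences, search insert templates
   in breakend flanks, and scan ±50 bp flanks for variants.
3. **Null model**: the random-joining microhomology distribution and an
   exact enrichment test.
4. **Clustering**: max-gap single-linkage grouping of breakpoints, with
   cross-passage persistence.
5. **Contigs**: junction-arm adjacency links, greedy chain assembly, and
   coordinated-junction-pair detection.
6. **Comparison**: shared/lost/gained junction algebra between passages.
7. **Simulation**: a generative amplicon model that emits all pipeline
   input formats together with complete truth tables.

## Coordinates and conventions

Internally every position is 1-based. A breakend is `(chrom, pos, orient)`:
orientation `"+"` means the reference upstream of `pos` is retained (a
fragment *ends* at `pos`), `"-"` means downstream is retained (a fragment
*starts* at `pos`). On disk, BEDPE-style junction tables, BED and bedGraph
are 0-based half-open, converted exactly on read/write.

Fragment lengths, cluster gaps and cluster spans are all computed as
**position differences** (`pos_high − pos_low`). Published cluster tables
print gaps and spans with exactly this arithmetic (a 61 bp gap between arms
at 54,668,755 and 54,668,816 is also printed as a 61 bp contig fragment),
and adopting one convention everywhere keeps every reported number directly
comparable with such tables.

## Two-sided microhomology

Let `A` be the retained sequence ending at the first arm's breakend, read
in the orientation of the fused molecule, and `B` the retained sequence
starting at the second arm's breakend. Two extensions are measured against
the *reference*:

* `mh_right`: the longest `k` such that the first `k` bases of `B` equal
  the reference continuation past `A`'s breakend;
* `mh_left`: the longest `k` such that the last `k` bases of `A` equal the
  reference immediately preceding `B`'s breakend.

`mh_len = mh_left + mh_right` equals the number of alternative breakpoint
placements of the junction — the property the test suite checks against a
brute-force enumeration of every shift. Inverted fusions are handled by
reverse complementation; breakends within the 50 bp window of a contig edge
are computed with a truncated window and flagged.

A junction carrying an untemplated insertion has its microhomology reported
as 0: the seam bases are attributed to the insertion, and the two calls are
mutually exclusive by construction.

## The random-joining null

If two independent sequences are joined bluntly, each side of the seam
matches the other flank's reference continuation with per-base probability
`p = Σ f_b²` (`1/4` for uniform composition), so each side's microhomology
is geometric and their sum `K` has

P(K = k) = (k + 1) (1 − p)² pᵏ.

For uniform composition, P(K = 0) = 9/16 = 0.5625 and
**P(K ≥ 1) = 7/16 = 43.75 %**, i.e. 44 % to the nearest percent. The suite
validates this closed form against exhaustive enumeration of all 4⁸ flank
pairs of length 4 per side before relying on it, and a Monte-Carlo twin
(`mh_null_fraction_mc()`) reproduces it through the same caller used on
real junctions. Composition enters only through `p`; uniform composition is
the default because it is the assumption under which the published 44 %
expectation is exact.

`mh_enrichment_test()` is an exact one-sided binomial test of
`#(mh ≥ 1)` against P(K ≥ 1). Exact tests on discrete data are
conservative, so the object also carries the mid-p
(`P(X > k) + ½ P(X = k)`), the calibrated tail quantity; the calibration
property in the test suite asserts KS-uniformity of the mid-p under null
draws, while reported inference uses the conservative exact p-value.

## Clustering and persistence

`cluster_breakpoints()` is deterministic single linkage: per chromosome,
sorted breakends are chained while consecutive distances are ≤ `max_gap`.
The default `max_gap = 2000` bp separates the largest published
within-cluster gap (1823 bp) from the smallest between-cluster separation
(all > 2 kb), and both arms of a junction are clustered as independent
breakends. `assign_new_breakpoints()` assigns later-passage breakends to an
existing cluster when within `max_gap` of its span and re-clusters the
remainder. Note that this distance rule absorbs any new breakpoint group
that falls *inside* an existing cluster's span; a published table that
lists such a group as a separate new cluster cannot be reproduced by any
distance rule, and the package follows the rule, not the table, in that
case.

## Contigs

A retained fragment shows up in a junction table as a *facing* breakend
pair: on one chromosome, a `"-"` breakend (fragment start) below a `"+"`
breakend (fragment end), at most `max_link` apart and from two different
junctions. `build_arm_links()` enumerates all such candidates (length 0 is
a single-base fragment whose two arms share a coordinate). Assembly is
greedy: each breakend keeps its shortest candidate link, a link survives
only if both ends keep it, and a breakend whose shortest candidates tie is
ambiguous — the default policy breaks the chain there and flags it, because
in the wet-lab workflow this ambiguity was resolved by PCR, not
computation. Surviving links give every junction at most one link per arm,
so components are simple paths (linear contigs) or cycles (circular
contigs, the expected dmin topology, flagged). Inter-fragment distances are
reported per consecutive fragment pair; for two-junction contigs the
distance between the two outer arms is reported instead, matching the
published table's convention for single-fragment contigs.

`find_coordinated_pairs()` flags junction pairs whose four arms co-locate
pairwise at two loci (≤ `max_intra`, default 2 kb) that are themselves
remote (≥ `min_inter`, default 100 kb, or on different chromosomes) — the
geometry expected when two double-strand breaks in juxtaposed regions were
repaired concomitantly.

## Cross-passage comparison

`match_junctions()` defaults to exact arm equality (`tol = 0`) because
junctions confirmed by capillary re-sequencing are mapped to the base; a
tolerance is available for noisier callers, matched greedily by summed arm
distance. Greedy and optimal bipartite matching coincide at tolerances of a
few bp; the greedy choice is transparent and documented as a limitation for
large tolerances.

## The simulator

`simulate_amplicon()` generates the structures the analysis assumes, so
that every caller can be tested against generative truth:

* **Source regions and copy steps.** Two 1 Mb chromosomes with two source
  regions each by default; fragments are cut at all breakpoints, a small
  fraction (default 5 %) is dropped to create internal unamplified holes,
  and each molecule (circle or chain) draws a copy number
  `max(1, Poisson(15))` — amplification centred on 15-fold over a baseline
  of 3–4× coverage, the regime of the motivating data.
* **Clustered breakpoints.** 12 clusters by default, each with 2–7 breaks
  over a uniform 100–2500 bp span, anchors at least 10 kb apart (rejection
  sampling), plus Poisson singletons. Anchors are uniform within source
  regions: no sequence determinant of cluster placement is modelled because
  none is known.
* **Microhomology-biased joining.** Free fragment ends are chained into
  closed circles (dmin mode) or one linear chain (hsr mode); the partner of
  the current open end is sampled with weight `(1 + β)^mh` over the
  candidate ends' two-sided flank microhomology (default β = 2; β = 0 is
  exactly the random-joining null, and the sampler then skips the weight
  computation entirely, which is an identity, not an approximation). Joins
  that would re-fuse the two sides of one cut are excluded — such a seam
  restores the reference and is invisible to sequencing.
* **Insertions.** With probability 0.3 a join instead receives an
  untemplated insert of i.i.d. uniform bases (geometric length, mean 8,
  capped at 42), matching the reported 30 % insertion rate and the absence
  of templated copies. Inserts are drawn canonical — their boundary bases
  do not continue either flank's reference — so the maximal-attribution
  insertion caller recovers exactly the generated insert.
* **Passage transition.** Each fragment is lost independently (default
  0.4); a junction dies with either flanking fragment. New breaks (default
  0.3 per surviving fragment) split fragments, and all free ends are
  re-fused with the same biased sampler into the new topology (hsr by
  default). Fates (`retained`/`lost`/`new`) are recorded per fragment and
  junction.
* **Observables.** Read support is Poisson with mean proportional to copy
  number; depth is `baseline + copies × depth_per_copy` with Poisson
  counting noise emitted as 100 bp tiles of per-base Poisson sums (the
  3 kb-bin statistics are identical to per-base emission at a fraction of
  the track size); spanning sequences are built from the realized flanks,
  inserts and microhomologies.

What the generator does **not** emulate: read-level artefacts (mapping
error, chimeric support), GC- or mappability-dependent coverage bias,
repeat-mediated mis-calls, selection across passages beyond i.i.d. loss,
and any sequence preference at breakpoints. Passing tests therefore show
the *callers* are correct against the generative model, not that the model
captures every property of real tumour sequencing data.

## Numerical and scale choices

* Anchor seeds for spanning-sequence alignment are 15 bp exact matches,
  extended base-by-base across the seam; in a few-kb flank window a 15-mer
  collision is vanishingly unlikely, and this avoids a full aligner
  dependency. Variants inside the seed region defeat anchoring and raise an
  explicit error.
* Insert-template search and flank-variant scanning use
  `Biostrings::pairwiseAlignment` (local and global respectively); template
  hits require ≥ 90 % of insert bases matched, and inserts shorter than
  20 bp are flagged unsearched.
* Amplified-segment calling: runs of 3 kb bins at ≥ 3× baseline, bridging
  at most 2 cold bins and discarding runs under 2 bins — parameters chosen
  so a ~20 kb unamplified hole inside an amplified region survives as a
  hole. The baseline is supplied or estimated as the median bin depth
  outside candidate regions.
* Test and example problem sizes (200 kb single-chromosome simulations for
  oracle batteries, 2 Mb two-chromosome fixtures for the end-to-end run,
  10⁴–10⁵ Monte-Carlo joins) were chosen as the smallest scales at which
  the checked statistics have comfortable margins of error.

## Known limitations

* The pipeline consumes junction calls; it does not call junctions from
  reads, and no VCF BND emission is provided.
* Coverage work is bin-level only: no GC/mappability correction and no
  multi-level copy-number decomposition.
* Repeat-class attribution of breakpoints is accepted only as a
  user-supplied BED annotation.
* Insert-template search is restricted to breakend flank windows, not the
  whole genome.
* Whether the two amplified chromosomes entered the amplicon together or
  independently is not identifiable from junction data; the simulator
  exposes both as modes without claiming either.
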