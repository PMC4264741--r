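---
title: "Structural variant discovery from read-pair signatures: methods and design"
author: "svcallr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural variant discovery from read-pair signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Paired-end and mate-pair sequencing reads are sequenced from the two ends of
a DNA fragment of roughly known length. When a fragment spans a structural
variant (SV) breakpoint, its two reads map to the reference in a
configuration that a fragment from an unrearranged genome cannot produce:
an inflated or deflated apparent insert size, an unexpected relative
orientation, or two different chromosomes. Copy-number variants additionally
shift the local depth of coverage. svcallr turns these two signal classes
into unified SV calls: deletions (DEL), tandem duplications (DUP),
inversions (INV), short insertions (INS) and translocations (TRA).

## The insert-size model

For each library we collect same-chromosome pairs in the majority
orientation and estimate the insert-size distribution; the insert size is
the *outer* distance (rightmost aligned end minus leftmost start),
recomputed from the alignments because SAM TLEN conventions vary between
aligners. The location estimate is the median. For the scale, note that the
sample necessarily contains SV-spanning pairs whose inserts are extreme
outliers; a plain standard deviation over "all pairs" would be inflated by
the very signal we want to detect. We therefore use the robust equivalent
1.4826 x MAD by default (`robust = FALSE` restores the plain SD) and floor
it at 1 bp so that degenerate simulated data cannot produce zero-width
windows. A pair is *discordant* when its mates map to different
chromosomes, when its orientation deviates from the library majority, or
when its insert falls outside median &plusmn; k&sigma; k defaults to 3
(&asymp;0.3% two-sided tail under a Gaussian insert distribution) and is
configurable independently of the clustering window. The majority
orientation is auto-detected, so short-insert paired-end (FR) and
long-insert mate-pair (RF) libraries need no flag. Reads with MAPQ 0 are
treated as non-uniquely mapped and excluded (default MAPQ cutoff 20);
duplicate-flagged pairs are dropped.

## Streaming hard clustering

Discordant pairs are streamed in (chromosome, leftmost-position) order.
A pair joins an open cluster when both of its read start positions lie
within twice the insert-size standard deviation (2&sigma;) of the cluster's
running mean start positions, its strand signature matches exactly, and —
for same-chromosome pairs — its insert size is within 2&sigma; of the
cluster's running mean insert size. Among eligible clusters it joins the
one minimising the Euclidean distance in the (&alpha;, &beta;) plane of the
two read positions, ties broken toward the earlier-created cluster;
otherwise it seeds a new cluster. Membership is hard: each pair belongs to
exactly one cluster, so cluster supports always sum to the discordant-pair
count. Running means update incrementally after each addition
(`freeze_means` fixes them at the seed, for users who prefer
first-come-anchored clusters). Clusters whose mean start falls more than
2&sigma; behind the scan position are closed; because the closure horizon
equals the membership window, the streaming result is identical to an
exhaustive clusterer that considers every cluster for every pair — a
property the test suite verifies against an independently written
brute-force reference on randomized instances.

With a long-insert library the pairs spanning one junction have start
positions spread over roughly the insert length (~3 kb), which is much
wider than the 2&sigma; window (~600 bp). One junction therefore yields a
*chain* of adjacent clusters rather than a single cluster. This is a direct
consequence of the similarity criteria, not an artifact; all clusters in a
chain produce breakpoint intervals containing the true breakpoint, and the
junction-adjacent cluster's interval edge estimates it most tightly.
Downstream metrics are therefore defined per locus: an SV is recovered when
*some* call of the correct type brackets both true breakpoints, and a call
is false when its uncertainty intervals lie away from every true breakpoint.

### Support cutoff

Clusters with too few members are discarded. The cutoff scales with
coverage as `max(2, round(coverage / 10))`. The coverage relevant to pair
support at a junction is the *physical* (fragment-span) coverage —
`n_pairs x median insert / genome size` — which for a 3-kb mate-pair
library at 30x base coverage is roughly 900x, giving a cutoff near 90.
Junction chains at that depth have supports of 100–220, while clusters
assembled from the insert-size tail of concordant fragments rarely exceed
a handful of members, so the two populations separate cleanly. For
short-insert paired-end data physical and base coverage nearly coincide.
`min_support` overrides the heuristic.

### Breakpoint intervals

Each cluster yields two intervals guaranteed, up to model assumptions, to
contain the breakpoints. On a side whose reads tile up to the junction from
the left (read strand equal to the concordant left-read strand), the
breakpoint lies in `[max(alpha) + read_len, max(alpha) + median_is)`;
mirrored constructions apply to the right-tiling and to strand-flipped
sides (the everted side of a tandem duplication, the interior of an
inversion), where the junction provably lies on the opposite side of the
reads. If a construction empties (median insert shorter than the read), a
fallback window of width 4&sigma; centred on the cluster mean is used.

### Typing

The cluster's signature determines the type: different chromosomes &rarr;
TRA; both mates on one strand &rarr; INV; expected orientation with insert
beyond median + k&sigma; &rarr; DEL, below median &minus; k&sigma; &rarr;
INS; everted orientation &rarr; DUP (tandem); anything else — e.g. an
expected-orientation cluster whose mean insert sits inside the concordant
band — is COMPLEX and left to manual interpretation. Signatures are
defined relative to the library's expected orientation, so FR and RF
libraries give identical calls on the same variants. INS here means
"insert shorter than expected": novel insertions longer than the library
insert are split-read territory and out of scope. Dispersed duplications
present as TRA/COMPLEX and are reported as such.

## Depth-of-coverage ratio analysis

Reads are counted in sliding windows (default step = window/2) by their
5'-most mapped base, a single-point assignment that makes disjoint-window
counts sum exactly to the read count. The window size adapts to coverage
and genome size: `genome_size x target / min(total_sample, total_ref)`
rounded up to 100 bp, targeting ~100 reads per window in the shallower
library. Per window we report the library-size-normalised
`log2((count_sample/total_sample)/(count_ref/total_ref))` and a two-sided
probability from a Gaussian approximation to the log ratio of two Poisson
counts (variance `(1/count_sample + 1/count_ref)/ln(2)^2` on the log2
scale); zero-count windows are flagged and evaluated with a +0.5
continuity correction. The probability model is a deliberate, documented
stand-in (`ratio_model = gaussian_poisson`) chosen for calibration (the
type-I error at p &lt; 0.05 is 0.05 &plusmn; 0.01 in the null simulations)
and simplicity; GC-content and mapability corrections are out of scope and
the method relies on a reference sample sequenced under matched conditions,
ideally pooled from several normal samples. Segments are maximal runs of at
least `min_consecutive` windows beyond `ratio_threshold` with one sign;
zero-count windows participate via the corrected ratio so homozygous losses
do not break runs. The defaults (0.3, 3) suit heterozygous events; for the
haploid-genome simulation studies, where true events shift log2 by
&plusmn;1, the end-to-end analyses use (0.5, 5), which keeps the expected
number of Poisson-noise segments per genome below 0.1 while leaving an
&ge;5-window margin on every simulated event.

## Artifact filters

*Realignment rescue.* A discordant pair may be a mapping artifact of a
concordant fragment. For each discordant pair we locally realign each
mate's sequence (both strands, affine-gap local alignment, match 1 /
mismatch &minus;1 / gap open 2 / extend 1) against the reference window
where a concordant placement relative to the other mate would fall (other
mate &plusmn; median insert &plusmn; 4&sigma;). An alignment covering
&ge;90% of the read at &ge;90% identity reclassifies the pair as
concordant and removes it. Pairwise local alignment is the correct
primitive for a read-vs-window check; a multiple-alignment engine adds
nothing here.

*Annotation tracks.* Calls are scored for the exact fraction of their span
(for translocations: either breakpoint interval) covered by the union of
each user-supplied BED track — segmental duplications, RepeatMasker,
self-chain alignments. Above the per-track threshold (default 0.5) a call
gains a FILTER tag; `annotate` mode (default) keeps everything tagged,
`remove` drops tagged calls. The thresholds and the annotate-vs-remove
choice are exposed because no principled universal value exists; annotate
is the conservative default since removal destroys information.

## Evidence integration

DEL/DUP cluster calls absorb a sign-consistent coverage segment at
reciprocal overlap &ge; 0.5 (one-to-one, best overlap first), keeping the
cluster's sharper coordinates and gaining the segment's mean log2 ratio;
sign conflicts leave both calls and tag the cluster call
`discordant_evidence`. INV/TRA/INS never merge with coverage segments.
Unmatched segments become imprecise `<DEL>`/`<DUP>` calls with SUPPORT=0.
Output is VCF 4.2 (symbolic ALTs; translocations as paired BND records
with MATEID cross-references; POS is the base before the breakpoint,
CIPOS/CIEND carry the interval uncertainty), BEDPE and bedGraph. No
timestamps are written, so reruns are byte-identical.

## The simulator

The built-in simulator is first-class, tested code: it builds a donor
genome from non-overlapping SV specs by splicing reference blocks
(deletions remove, tandem duplications repeat, inversions
reverse-complement, insertions add novel sequence, translocations exchange
arms), then draws fragments uniformly from the donor with Normal insert
lengths (truncated at twice the read length) and reports each read at its
*exact* reference coordinate derived from the block provenance — no
aligner runs, which isolates the caller's logic from aligner behaviour.
SV-spanning pairs thereby carry exactly the signatures the typing module
expects; this is the keystone end-to-end oracle. Reads that would cross a
junction within the read (split-read territory) or fall wholly in novel
insertion sequence are resampled. Substitution errors are applied i.i.d.
to the emitted bases. What the simulator deliberately does *not* model:
alignment ambiguity and mismapping, indel/quality error structure, GC and
mapability bias, chimeric library artifacts, diploidy/heterozygosity.
Passing tests therefore demonstrate the correctness of the discovery logic
under its stated model, not robustness to real-data mapping noise — that
is what the realignment and repeat filters, exercised on constructed
artifact fixtures, are for.

## Study conditions and problem sizes

The default scenario is two 2-Mb chromosomes carrying 2 DEL, 1 DUP, 1 INV
(5–20 kb) and 1 reciprocal TRA, sequenced at 30x as an RF mate-pair
library with 3000 &plusmn; 300 bp inserts, 50-bp reads and 0.5%
substitution error (~1.2 M pairs). Replicated studies (breakpoint-CI
coverage over 20 seeds) use the same SV classes, sizes, coverage and
library on two 400-kb chromosomes so that a full replicate set stays in
the minutes range on one CPU; per-replicate behaviour is identical in kind
because every length scale of the problem (insert, read, window, event
size) is unchanged. Calibration checks use 10,000 Poisson windows; effect
recovery uses 60 windows of 100 expected reads.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based only at VCF
  emission. BED/BEDPE stay 0-based.
* &sigma; floored at 1 bp; window size rounded up to 100 bp; tie-breaks in
  cluster assignment go to the earlier-created cluster, making the engine
  fully deterministic (re-running on the same input reproduces identical
  clusters and bytes).
* Fewer than 50 usable pairs abort insert-model estimation with a clear
  error rather than returning unreliable thresholds.
* Unsorted input is rejected naming the first out-of-order record;
  orphaned mates are counted and reported, never silently dropped.

## Known limitations

Complex rearrangement chains are reported piecewise (COMPLEX clusters) and
require manual interpretation. Events smaller than the discordancy
threshold (k&sigma; &asymp; 900 bp at the default library) are invisible
to the pair signal, and events smaller than a few windows are invisible to
the coverage signal; split-read evidence, which would close this gap, is
intentionally out of scope. The coverage probability model ignores
overdispersion beyond Poisson; with real libraries a matched reference and
the segment-level run requirement absorb most of it, but p-values on single
windows should not be over-interpreted.
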