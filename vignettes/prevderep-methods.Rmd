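---
title: "Methods: prevalence-ranked genome collections and k-mer profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prevalence-ranked genome collections and k-mer profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevderep)
```

## The problem

Reference-based profiling of human gut shotgun metagenomes is only as good
as the reference collection. Public repositories hold hundreds of thousands
of prokaryotic genomes and metagenome-assembled genomes (MAGs), but most of
them are rare or irrelevant in healthy human guts, while redundant
near-identical assemblies inflate databases without adding classification
power. `prevderep` implements a screening-and-dereplication strategy that
builds a gut-prevalence-ranked, non-redundant genome collection and then
profiles samples against it with a hardened k-mer classifier:

1. **Deduplicate the metagenome panel.** Within each sequencing project,
   near-identical samples are collapsed by complete-linkage clustering of
   MinHash (MASH) distances at a 0.05 diameter and represented by their
   medoid, so heavily sampled sub-populations do not bias prevalence
   estimates.
2. **Screen and rank genomes.** Every candidate genome is sketched
   (s = 1,000 bottom hashes of canonical 21-mers, singletons kept) and its
   containment in each panel metagenome's full k-mer inventory is converted
   to a sequence identity *I*. A genome qualifies if *I* ≥ 0.95 in at least
   one metagenome; its prevalence score is the mean of *I* over the whole
   panel (non-detections contribute 0), and genomes are ranked by it.
3. **Dereplicate greedily by rank.** The top-ranked unassigned genome
   becomes a centroid; genomes within ANI distance *D* of it join the
   cluster and leave the pool. A coarse sketch-distance pre-filter
   (D_mash ≫ D) avoids computing ANI against everything. This runs at
   *D* = 0.025 (a "half species radius", 97.5 % identity), and the
   resulting centroids are re-clustered at *D* = 0.05 (the conventional
   species boundary).
4. **Classify and harden.** Reads are classified by a lowest-common-ancestor
   (LCA) k-mer classifier built from the representatives. Species whose
   reads cover fewer distinct database k-mers than a depth-scaled threshold
   (2,000 per million reads) are zeroed as false positives, and remaining
   supra-species reads are redistributed to species with Bayesian weights
   estimated from the database itself.
5. **Summarize communities.** Core species (prevalence strictly above 0.70
   in a cohort), CLR-transformed PCA ordination (pseudo-count 10),
   project-level average-linkage dendrograms, and genome-accumulation
   (rarefaction) curves.

## Sketching model and the screen identity

All k-mer work uses canonical k-mers: the lexicographic minimum of a window
and its reverse complement, so both strands hash identically. Hashes are
computed by a seeded splitmix64 finalizer over the 2-bit-encoded k-mer and
masked to 53 bits so they remain exact integers in R doubles; the seed is
recorded in every sketch, and only sketches sharing k and seed are
comparable. Nothing downstream depends on matching any external tool's hash
values — only internal consistency matters, and every estimator is
calibrated against exact set operations on full inventories in the tests.

Jaccard similarity between two sketches uses the merged bottom-s estimator:
among the s smallest hashes of the union of the two sketches, the fraction
present in both. This is the estimator with binomial error
√(J(1−J)/s), which the acceptance suite verifies empirically at s = 1,000.
The MASH distance is D = −(1/k)·ln(2j/(1+j)), capped at 1 for disjoint
sketches.

Containment screening looks up the genome's s = 1,000 sketch hashes among
*all* distinct hashes of a metagenome and maps the containment fraction c to
an identity through I = 1 + (1/k)·ln(2c/(1+c)) (I := 0 at c = 0). This
transform is deliberately *soft*: at k = 21 the containment needed for
I = 0.95 is only c ≈ 0.212, far below the ≈ 0.35 expected from a genome
that is actually 95 % identical to something in the sample. The
qualification rule inherits this softness by design — it asks whether a
genome is plausibly contained, not for a precise distance. Shared hashes
are counted independently per genome; no winner-take-all reassignment
between competing genomes is performed.

Genome sketches keep singleton k-mers (assemblies are low-error and small
genomes would lose signal); metagenome sample sketches for deduplication
drop them (sequencing-error k-mers are predominantly singletons). The full
inventories used as the metagenome side of screening keep all distinct
hashes. Multi-contig genomes contribute k-mers per contig; no artificial
junction k-mers are formed.

## Sample deduplication

Complete linkage guarantees that every cluster's diameter (maximum pairwise
distance) stays within the 0.05 threshold. The implementation agglomerates
with an explicit deterministic tie-break — among merges of equal height,
the pair whose smallest sample label sorts first wins — because downstream
byte-identical reproducibility is a stated contract and standard
implementations leave ties platform-dependent. The medoid (minimum distance
sum, ties to the lexicographically smallest label) represents each cluster.
Samples with empty sketches cannot be placed in distance space; they are
excluded and flagged. An optional minimum-read-count pre-filter (1,000,000
reads is the conventional curation cut) can be applied first.

## Fragment ANI

Average nucleotide identity is re-implemented in a fragment + k-mer form:
the query genome is cut into consecutive 3,000 bp fragments, each
fragment's distinct canonical k-mers (k = 15) are looked up in the
reference's full inventory, and the containment c is inverted through the
k-mer survival model to a per-base identity c^(1/k). Fragments with
identity below 0.8 are treated as unmapped, and ANI is the mean identity of
mapped fragments. Under the substitution-only mutation model the expected
containment of a fragment at per-base divergence d is (1−d)^k, so
c^(1/k) is an (asymptotically) unbiased estimator of 1−d — the acceptance
suite verifies |(1−ANI) − d| < 0.005 at d ∈ {0.01, 0.025, 0.05} on 100 kb
genomes. The softened screen transform used for metagenome containment is
*not* used here: it underestimates distances by ln(2/(1+c))/k (≈ 0.011 at
these scales), which would blur the 0.025 clustering threshold; screening
and ANI answer different questions and get different inversions. k = 15 is
used rather than a longer k so that fragments retain a strong matched
fraction out to d ≈ 0.05, and kept odd so no k-mer is its own reverse
complement. The estimate is query-directional (query = candidate,
reference = centroid, mirroring how the greedy clustering uses it);
symmetry holds to within ~0.01 on similar-sized genomes. A candidate with
no mapped fragments has undefined ANI and is never assigned to a cluster.

## Greedy rank-ordered clustering

The greedy pass always takes the best-ranked remaining genome as centroid,
pre-filters the remaining pool by sketch distance (0.08 for D = 0.025; 0.1
for D = 0.05 — margins chosen because empirically almost all genome pairs
within those ANI distances fall under those sketch distances), confirms
membership by fragment ANI, and removes the cluster. Determinism follows
from the rank order; rank ties are broken lexicographically by genome id
with no source-based priority. Quality filtering (completeness ≥ 50 %,
contamination ≤ 5 %, completeness − 5×contamination ≥ 50) is applied
*before* clustering: it is stricter than filtering representatives
afterwards and guarantees no low-quality genome can consume a cluster as
its centroid. The species-level pass reuses the original prevalence ranks
for the 97.5 %-level centroids rather than re-scoring them; the ranking is
a property of the genome, not of the clustering level.

## LCA classifier, false-positive filter, redistribution

The database maps every distinct canonical 31-mer of the input genomes to
the LCA of all species containing it, and records per-node distinct-k-mer
inventories. Plain canonical k-mers are used instead of a
minimizer-compacted scheme, and unique-k-mer accounting is exact rather
than sketched: at the scales this package targets both are affordable, the
classification semantics are identical, and exactness makes the test
surface much stronger (the LCA map is compared k-mer-by-k-mer against a
brute-force oracle).

A read is classified by scoring every root-to-leaf path with the number of
its k-mer hits on the path's nodes and calling the deepest node of the
best path; ties across paths resolve to the LCA of the tied leaves, which
naturally yields genus-level calls for reads whose k-mers are shared across
a genus. Zero hits means unclassified. Paired reads are treated as two
independent reads.

The false-positive filter computes the real-valued threshold
T = 2000 × total_reads / 1e6 and zeroes every species whose observed
distinct database k-mers fall strictly below T (kept at exactly T). Zeroed
reads are removed from the classified total — they are neither reassigned
nor moved to unclassified — mirroring the "zero the report, then
re-estimate" order of operations. Zeroing is applied at species rank by
default with an `all_ranks` switch, since the published procedure names
the species-level report.

Redistribution probabilities are estimated from the database itself:
read-length (default 100 bp) fragments are slid over every database genome
(stride `fragment_step`, default 1) and classified against the finished
k-mer map; the per-species call frequencies give P(node | species). A
node's direct reads are then shared among its surviving descendant species
proportionally to P(node | species) × current species read mass. When every
surviving species under the node has zero mass, the conditional
probabilities alone are used rather than discarding the reads; nodes with
no surviving descendant species keep their reads as an explicit unassigned
remainder. Counts are fractional and conserve exactly:
Σ species + unassigned = classified − filtered.

A host decoy genome can be included as an ordinary database entry mapped to
its own species node; its calls are then excluded from microbial totals by
dropping that species from the abundance table.

## Community statistics

Presence for prevalence purposes means readcount > 0 after filtering and
redistribution. Core species require prevalence strictly greater than the
0.70 cut. The CLR transform adds the pseudo-count 10 to raw readcounts
(not to proportions — CLR is scale-invariant, so proportions would only
change the pseudo-count's meaning) and centers log counts per sample. PCA
runs on the CLR matrix, column-centered, unscaled; components are signed so
each component's largest-magnitude loading is positive, making outputs
reproducible across eigensolvers. Project-level structure uses the mean
cross-project sample distance and average linkage. Rarefaction counts, per
random permutation of the panel, the cumulative number of genomes first
qualified (I ≥ 0.95) at each step; the final point is permutation-invariant
by construction.

## Synthetic data: what it does and does not emulate

The generators draw uniform i.i.d. genomes, apply independent per-base
substitutions (no indels — so expected identity is exactly 1 − rate and
ANI calibration has a closed-form truth), and sample reads with
length-weighted genome choice, uniform positions, both strands, and
independent substitution errors. Taxonomies are rank-complete
(root → domain → genus → species) with round-robin genus assignment.

This suffices to validate the estimators, thresholds, and bookkeeping,
but real data differ in ways the tests deliberately do not cover: genomes
have repeats and shared mobile elements (k-mer containment between real
species is not ~0), assemblies are fragmented and contaminated, reads have
structured error profiles and quality scores, and real strain variation
includes indels and rearrangements. Passing tests therefore demonstrate
correctness of the method's logic and calibration under its stated model,
not field accuracy on real gut data.

## Numerical and engineering choices

- **Hash space.** 53-bit hashes stored in doubles (R has no native 64-bit
  integer); collision probability at the largest fixtures (~10⁷ distinct
  k-mers) is negligible, and hashes serialize exactly as integer strings.
- **Tie-breaks.** All of them are deterministic and documented: linkage
  merges (smallest label), medoids (smallest label), ranking (genome id),
  classifier path ties (LCA).
- **Artifact round-trips.** Pipeline artifacts that feed later stages
  numerically (distances, screen identities, abundances) are rounded to
  12 decimals before writing so that a resumed run reading them back is
  byte-identical to a fresh run; 12 decimals is far below any decision
  threshold in the method.
- **Fragments.** The trailing genome remainder shorter than one ANI
  fragment is dropped; fragment hashing deduplicates within fragment.
- **Degenerate inputs.** Empty sketches are flagged, not fatal, and
  excluded from clustering; two empty sketches have undefined Jaccard and
  raise an error; ANI with no mapped fragments is undefined and treated as
  farther than any threshold; reads shorter than k are unclassified and
  logged separately; the stats stage skips ordination below 2 samples or
  2 species.
- **Problem sizes in the tests.** Calibration uses 20 kb sequence pairs
  (Jaccard), 100 kb genomes with 20 replicate mutants per rate (ANI), a
  60-genome/12-group panel at 50 kb (dereplication), and a 10-species
  25 kb-genome mixture with 50,000 × 150 bp reads at 0.5 % error
  (classification). These sizes give the estimators enough k-mers that
  their sampling noise sits well inside the asserted tolerances while the
  whole suite stays fast; the pipeline demo uses 12 genomes of 20 kb and
  six 3,000-read samples.
- **Redistribution stride.** `fragment_step = 1` replicates the every-
  position convention for conditional-probability estimation; fixtures use
  a stride of 5, which changes the estimates negligibly on i.i.d. genomes.

## Known limitations

- The ANI model is substitution-only; indels and rearrangements in real
  genomes make fragment containment a biased proxy at a given nominal ANI.
- Prevalence scores average identities over all panel metagenomes
  including non-detections; with small panels the score is dominated by
  breadth of occurrence rather than within-sample identity.
- The classifier holds the whole k-mer map in memory; it is a desk-scale
  re-implementation, not a replacement for production classifiers at
  hundred-gigabase database scale.
- Cross-project sample duplicates are not collapsed (deduplication is
  within-project by design).
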