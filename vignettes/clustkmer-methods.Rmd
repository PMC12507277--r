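---
title: "clustkmer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clustkmer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustkmer)
```

## The problem

Functional profiling of shotgun metagenomes requires mapping short
nucleotide reads to proteins. Alignment against a protein database is
expensive, and short reads frequently align comparably well to many
homologous proteins from different taxa ("multi-mapping"), making the
per-protein assignment ambiguous even when the *function* is clear.
clustkmer targets the function directly: reads are assigned to
taxa-agnostic **clusters of homologous proteins**, treated as single
functional units, using only amino-acid k-mer statistics — no alignment.

## The model

Given a clustered protein database, the model stores for every amino-acid
k-mer $w$ and every cluster $C$ containing it the frequency

$$\mathrm{freq}_C(w) \;=\; \frac{\#\{\text{occurrences of } w \text{ in
proteins of } C\}}{|C|},$$

where $|C|$ is the number of proteins in the cluster and occurrences are
counted with multiplicity within a protein, so $\mathrm{freq}_C(w)$ can
exceed 1 for motifs repeated within cluster members. Conceptually this is
a two-level (nested) map $w \mapsto (C \mapsto \mathrm{freq}_C(w))$;
internally it is a keyed table of **integer counts** with cluster sizes
held separately, and the division is done on demand. That makes the
representation exact, order-independent (building the model from permuted
input yields an identical table) and bit-stable under save/load. Absent
$(w, C)$ pairs have frequency 0 and are never stored.

A query read $r$ is classified as follows:

1. six-frame translation (forward offsets 0/1/2, then the reverse
   complement at offsets 0/1/2 — a fixed order, for reproducible output);
2. frames containing a stop codon ("truncated" frames) are discarded;
3. all overlapping k-mers of the surviving frames are pooled, and the
   score for each cluster is the cumulative frequency
   $$s_{r,C} = \sum_{w \in r} \mathrm{freq}_C(w);$$
4. the read is assigned to $\arg\max_C s_{r,C}$, provided the maximum
   exceeds the threshold (strictly; default 3), and is annotated with the
   cluster representative's name.

The intuition: k-mers found in few clusters ("deterministic" k-mers in
the limit of a single cluster) pin the assignment, while broadly shared
k-mers contribute similar terms to many clusters and mostly cancel in the
arg-max.

## Parameters that matter

* **k** (amino acids; default 5). Selected by `select_k()`: each database
  protein is truncated into `segments_per_protein` (default 50) evenly
  spaced overlapping segments, each segment is classified at the
  amino-acid level, and accuracy is the fraction of segments returned to
  their own cluster. Accuracy saturates by k = 5 while the number of
  distinct k-mers (the model size) keeps growing sharply with k, so k = 5
  is the default. The truncation protocol leaves segment length open; we
  default to 50 aa — the residue span of a 150-nt read — and expose it as
  an argument.
* **threshold** (score units; default 3, strict `>`). Governs the
  coverage/precision trade-off and is tuned to short (100–200 nt) reads;
  longer reads pool more k-mers and may warrant higher thresholds. For
  reads from proteins unseen by the model, `roc_threshold()` recovers a
  threshold from scored reads with agreement labels by capping the
  empirical false positive rate (default 0.05).
* **distinct_kmers** (default off). The score above sums over k-mer
  *occurrences*; with the flag each distinct k-mer counts once. The
  summation over "$w \in r$" is ambiguous between the two readings; the
  per-occurrence reading is the default because repeated motifs carry
  real signal, and both paths are tested.

## Numerical and convention choices

* **Genetic code**: the standard table (identical to the bacterial table
  at codon level); shipped as a plain-text fixture and cross-checked
  against Biostrings in the tests. No initiator-codon special-casing:
  the first codon translates like any other.
* **Ambiguity**: `N` bases translate to `X`; `X`-containing k-mers are
  silently dropped rather than failing the read, so degraded reads remain
  classifiable from their clean k-mers. A frame is invalidated only by a
  stop codon. Input is case-insensitive; `U` is read as `T`.
* **Ties**: broken by the lexicographically smallest cluster id. The
  original first-maximum-in-iteration-order behaviour is effectively
  random; a deterministic rule makes output reproducible across runs and
  platforms.
* **Degenerate inputs**: reads with no complete codon produce six empty,
  valid frames and score 0; reads whose every frame is truncated, or with
  no in-model k-mer, are reported unclassified (score 0) rather than
  dropped, so output rows are one-to-one with input reads.
* **Streaming**: `classify_stream()` is a single pass in bounded chunks;
  memory is governed by the model, not the input file. Malformed records
  are reported by record number.

## What the synthetic data does (and does not) establish

`generate_cluster_db()` emulates the statistical structure the method
assumes: each cluster descends from an independent random ancestor, and
members substitute residues independently at rate
`1 - intra_cluster_identity` (default 0.8, i.e. ~68% expected
member-to-member identity). Coding sequences are attached by uniform
stop-avoiding reverse translation. Because ancestors are independent,
inter-cluster k-mer sharing sits at the ~5% per-residue background and
5-mer collisions between clusters are rare — deliberately close to the
regime where the classifier should work.

The read simulators implement two mutation procedures: a binomial
per-base rate (mutations drawn as $\mathrm{Binomial}(L, \text{rate})$
positions without replacement over the full source, each substituted with
a different base, *then* a window of the read length is cut), and a
guaranteed amino-acid-change mode that replaces the codons of `m` chosen
residues in a frame-aligned window with codons of different amino acids,
so re-translation differs at exactly `m` positions. The "concatenate a
reverse translation" phrasing of the latter procedure is implemented as
in-place codon replacement — the only reading that yields a read of the
stated length with the guaranteed change count.

A green test on this world establishes internal correctness (scoring
matches a brute-force oracle; counts are conserved; simulators deliver
their stated distributions) and qualitative behaviour (high accuracy and
coverage at low mutation rates, graceful degradation at higher ones). It
does **not** establish performance on real metagenomes: real protein
families share promiscuous domains and low-complexity motifs across
clusters, real clusters are built by CD-HIT-style identity clustering
rather than a star phylogeny, read length and error profiles vary, and
database-scale effects (millions of k-mers, thousands of clusters) change
the score background. The shipped `greedy_cluster()` is a containment-
similarity fixture, documented as not equivalent to CD-HIT.

## Evaluation statistics

`accuracy_and_coverage()` reports correct/classified and
classified/input. `multimap_resolution()` is the fraction of reads with
hits to two or more proteins whose hit proteins all fall in one cluster.
`agreement()` calls a read correct when any of its (optionally
identity-filtered) hit proteins belongs to the assigned cluster — a
non-empty overlap — and also reports the share of hit-bearing reads
recovered (sensitivity) alongside agree/(agree+disagree);
note the identity floor changes the denominator, so agreement with and
without a floor are not ordered. `per_cluster_concordance()` restates the
agreement flags per assigned cluster. `keyword_homogeneity()` tokenizes
member names case-insensitively, strips punctuation and a shipped
stopword list, and reports the fraction of members carrying the modal
token (ties: lexicographically smallest). `roc_threshold()` computes
AUROC by the Mann-Whitney rank statistic with midrank ties and scans
unique scores for the smallest cutoff meeting the FPR cap.

## Known limitations

* Scores are length-dependent; the default threshold presumes short
  reads.
* One cluster per read: multi-domain proteins and operon-spanning reads
  are inherently misrepresented by any single-label short-read method.
* Novel proteins without homology to any modelled cluster cannot be
  classified, only rejected by the threshold.
* The greedy fixture clusterer orders by length and uses k-mer
  containment; it is for generating test worlds, not for building
  production cluster databases.
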