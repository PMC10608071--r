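---
title: "Classifying mushroom sesquiterpene synthases: models and methods"
author: "mushSTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mushroom sesquiterpene synthases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mushSTS)
```

## The scientific problem

Sesquiterpene synthases (STSs) convert the universal C15 precursor farnesyl
pyrophosphate (FPP), or its isomer (3R)-nerolidyl diphosphate (NPP), into the
hundreds of sesquiterpene scaffolds found in mushroom-forming fungi. In
basidiomycetes these enzymes fall into four sequence clades, and each clade
is tied to one initial cyclization chemistry:

| clade | substrate   | ring closure | first carbocation intermediate |
|-------|-------------|--------------|--------------------------------|
| I     | (2E,6E)-FPP | 1,10         | (E,E)-germacradienyl cation    |
| II    | (3R)-NPP    | 1,10         | (Z,E)-germacradienyl cation    |
| III   | (2E,6E)-FPP | 1,11         | trans-humulyl cation           |
| IV    | (3R)-NPP    | 1,6          | (6R)-beta-bisabolol cation     |

Because clade membership constrains the chemistry, placing an
uncharacterized enzyme into a clade and looking at its nearest
experimentally characterized relatives is a practical way to predict its
likely product profile before any wet-lab work. `mushSTS` packages that
inference chain: a curated reference set of 174 characterized mushroom STSs
(from 35 species; 172 with sequence data and a clade label), a catalytic
motif scanner, a distance/neighbor-joining phylogenetic core, a clade
classifier with mechanism annotation, and a synthetic benchmark generator.

```{r}
db <- load_reference()
db
summarize_clades(db)
```

## The curated reference tables

The two packaged TSVs are verbatim transcriptions of the published summary
tables of characterized mushroom STSs: gene name, species, accession,
ordered product list, clade and citation in one table; the printed
aspartate-rich (Motif I) and NSE (Motif II) strings plus Pfam domain labels
in the other. Transcription choices worth knowing:

* Merged print cells were resolved so each row is self-contained (two
  entries share their neighbor's product/clade cell in print).
* Duplicate accessions and "not available" entries are preserved as
  printed; they are data quirks, not errors.
* Two entries are printed as not analyzed; they carry `clade = "unassigned"`
  and are excluded from clade summaries, leaving the 172 clade-assigned
  enzymes.
* Product names are normalized deterministically (Greek letters spelled
  out, superscripts inlined, whitespace collapsed to hyphens, a one-entry
  alias table for a printed spelling variant); the printed string is always
  retained alongside.
* "Major product" means the first-listed product; later ranks are side
  products. This matches how the source tables order products.

Two printed summary numbers are *not* reproducible from the tables and are
deliberately not asserted anywhere: the distinct-species count over clade-II
rows is 21 (printed prose says 22), and strict 9-position NSE matching over
the printed Motif II strings yields 158 rather than the printed 161 (the
published motif discovery tool's match criteria are not stated, and several
printed strings are truncated or absent). Similarly, a strict sweep for
DExxD finds 86 strings versus a printed 87. The counts the package asserts
(clade sizes 33/41/50/48, 12/8 alpha-muurolene major/minor in clade I,
8 sole-product gamma-cadinene enzymes in clade IV, 53 DD(N)xxD strings) all
reproduce exactly.

## The motif model

STSs carry two metal-binding motifs that coordinate the Mg²⁺ cluster
ionizing FPP/NPP: the aspartate-rich region (canonical forms `DExxD` and
`DD(N)xxD`, generalized `D(D/E/N)xx(D/E)`) and the NSE triad (`NDxxSxxxE`).
The package treats these fixed consensus patterns as the motif model; no
motif discovery is performed, because the downstream use is the patterns
themselves. The grammar is minimal: an uppercase letter fixes a residue,
`x` matches any residue (including the ambiguity letter `X`), and
`(A/B/C)` allows alternatives at one position. `DD(N)xxD` is read as
`D(D/N)xxD` — five positions with D or N in second position — which is the
only reading under which the five-residue printed motif strings can match,
and which reproduces the printed count of 53 exactly.

```{r}
scan_motif(c(LdSTS1 = "AADELSDAANDLYSYNMEAA"), sts_patterns()$aspartate)
classify_motif1(c("DELSD", "DDLSD", "DNVSD", "DDAFQ"))
```

Scanning reports *all* matches, overlapping included, at 0-based offsets on
the unaligned protein; selection of "the" catalytic pair is a separate,
explicit step. `locate_catalytic_pair()` requires the aspartate-rich hit to
sit upstream of the NSE hit with a start-to-start spacing inside a
configurable window (default 60–260 residues, an explicit knob since the
architecture is only loosely constrained); among several valid pairs the
spacing closest to the window midpoint wins. When both motif kinds are
present but never in the required order and window, both components are
reported absent — ordering is part of the architecture. Candidate screening
(`screen_candidates()`) keeps sequences inside a length window (default
250–700 residues, the reference enzymes' range) that carry an NSE or
aspartate-rich hit; on unrelated random proteins the generalized
aspartate-rich pattern fires by chance in a small fraction of sequences, so
the screen is a high-recall filter, not a classifier.

## The phylogenetic core

Distances are computed with **pairwise deletion**: for each sequence pair
only alignment columns where neither row has a gap are compared; columns
with the ambiguity letter `X` are removed the same way, since `X` carries no
information. Three models are available: the raw proportion of differing
sites (`p`), the Poisson correction `d = -log(1 - p)`, and the
maximum-likelihood distance under the Jones–Taylor–Thornton (JTT) model.
The JTT exchangeabilities and stationary frequencies are packaged as a
plain-text file of the published values; the rate matrix is normalized so
the mean rate at stationarity is 1, making all distances "expected
substitutions per site". The ML distance maximizes

d(a, b) = argmax over t of Σ over sites log( π(aᵢ) · P(aᵢ → bᵢ | t) )

with `P(t) = exp(Qt)` obtained from one eigendecomposition of the
symmetrized rate matrix. Optimization is R's bracketed golden-section /
parabolic scalar search on t ∈ [1e-8, 10] at tolerance 1e-6; an optimum
pinned at the bracket end raises an error rather than returning a
saturated guess. No rate heterogeneity across sites is modeled. Equivalence
with any particular legacy implementation is not promised — only
model-consistent estimation, which the tests verify by simulating under the
packaged model and recovering the generating divergence, and by
cross-checking against an independent implementation of the same published
model.

Trees are built with Saitou–Nei **neighbor joining** using the
Studier–Keppler criterion Q(i,j) = (n−2)·d(i,j) − Rᵢ − Rⱼ. Ties in Q are
broken by the lexicographically smallest label pair, so tree building is
deterministic without any seed. Negative branch-length estimates are clamped
to zero (standard practice; noted here because it biases very short edges).
On additive matrices NJ provably recovers the generating topology and
branch lengths, which is the package's strongest correctness lever: a
property test feeds it hundreds of random trees through their path-distance
matrices.

**Bootstrap** supports resample alignment columns with replacement,
rebuild the tree per replicate, and report for each internal edge of the
full-data tree the fraction of replicates containing the same bipartition.
Replicate `r` derives its RNG state as `substream_seed(seed, r)`, so
supports are bit-for-bit reproducible and independent of replicate order;
replicates that produce an undefined distance (a pair with zero comparable
resampled columns) are skipped and the support denominator uses completed
replicates only. Supports are serialized as internal node labels in Newick.

## Clade assignment and product prediction

A query is first brought into the reference coordinate frame: if its length
already equals the alignment width it is taken as pre-aligned, otherwise it
is globally aligned (BLOSUM62, affine gaps) against the majority consensus
of the reference alignment and threaded into the consensus's columns. Query
residues inserted relative to the consensus are dropped — a deliberate
simplification that keeps the pipeline free of external alignment tools;
users who care about insertions can supply a pre-aligned query.

Three assignment methods:

* `nn` — clade of the single nearest reference; confidence `1 − d₁/d₂`
  (clamped to [0,1]), a documented heuristic.
* `knn` (default, k = 5) — majority clade of the k nearest references;
  ties break by smallest mean distance, then lexicographic clade label;
  confidence is the vote share. k = 5 is robust to a single aberrant
  neighbor while staying local.
* `placement` — the query is inserted into an NJ tree of the references;
  its sister group (the smaller leaf set adjacent to its attachment node)
  votes; confidence is the share of bootstrap replicates agreeing.

Product prediction collects the major (first-listed) products of the k
nearest characterized references, skipping entries with no detected product
and products recorded only as unknown sesquiterpenes, and ranks candidates
by supporting-neighbor count (ties alphabetically). The neighbor-majority
rule is an explicit reconstruction of "predict from the nearest
characterized relatives"; the source study does not state a formal rule, so
this one is documented as the package's own. Clade V, used by some other
classifications for TRI5-type enzymes, is intentionally not a label here:
the four-clade scheme subsumes those enzymes under clade IV.

```{r}
bench <- make_clade_benchmark(benchmark_config(n_per_clade = 6, n_decoys = 0),
                              seed = 19)
truth <- setNames(bench$truth$clade, bench$truth$id)
a <- assign_clade(setNames(bench$sequences["cIV_03"], "query"),
                  bench$alignment[setdiff(names(truth), "cIV_03")],
                  truth, method = "knn", k = 5)
a
```

## The synthetic benchmark: what it emulates, and what it does not

Real reference sequences cannot be redistributed with the package, so the
benchmark generator builds a world with the statistical structure the
analysis assumes. One root sequence is drawn from the JTT stationary
frequencies; four clade ancestors evolve from it along backbone branches of
half the configured inter-clade divergence (so any two ancestors are
separated by the full value); each family then expands on its own random
tree (topology uniform over labeled topologies, branch lengths exponential)
under site-independent CTMC simulation with `P(t) = exp(Qt)`. Clade-typical
motif strings — sampled verbatim from the packaged motif table rows of that
clade's members, e.g. `DExxD`-family strings for clades I–III and
`DD(N)xxD`-family strings with TRI5-like NSE variants for clade IV — are
planted at clade-specific offsets and kept invariant during evolution.
Decoys are i.i.d. stationary sequences. Optional indels delete alignment
columns per family (never inside motifs), giving pairwise deletion real
work.

Defaults state the intended world: 4 clades × 12 sequences, length 350,
inter-clade divergence 1.0 substitutions/site, intra-clade branch mean
0.08, 20 decoys, no indels. These match the scale of the curated set
(dozens of sequences per clade, 300–600 aa enzymes) and produce clearly
separated families — intra-clade distances around 0.2, inter-clade around
2 — while generating in well under a second. The offsets (aspartate motif
start drawn in 80–110, start-to-start spacing 120–160) keep the planted
catalytic pair inside the default 60–260 spacing window.

What a green benchmark test establishes: the pipeline's machinery —
threading, distances, NJ, voting — correctly recovers family structure at
divergences like those in the real data. What it does **not** establish:
performance on real enzymes, where families share clade-specific residue
signatures beyond the two motifs, alignments have genuine indel structure,
and family boundaries are less clean. The held-out accuracy criterion
(≥ 0.95 with knn, k = 5) is a statement about this stated world, not about
the biological reference set.

## Numerical choices and degenerate inputs

* Distances: undefined pairs (zero comparable sites) are `NA` values, not
  errors, until tree building, which refuses them and names the offending
  pairs.
* ML distance: identical sequences short-circuit to 0; transition
  probabilities are floored at 1e-300 inside the log.
* NJ: negative branch-length estimates clamp to 0; Q-ties break
  lexicographically.
* Newick serialization uses ape; branch lengths are written at full
  precision internally and 6 decimals in CLI outputs.
* All randomness flows from one integer seed through
  `substream_seed(seed, r)`, a linear congruential derivation kept below
  2³¹.
* Motif scanning of a sequence shorter than the pattern returns an empty
  hit table; `parse_products` is total (never errors).

## Known limitations

* The profile threading drops query insertions; highly divergent queries
  with long insertions lose those residues from the distance computation.
* The JTT ML distance assumes stationary composition and no rate
  heterogeneity; compositionally biased sequences (e.g. low-complexity
  regions) bias the estimate relative to the p-distance.
* The motif screen is high-recall, low-precision on random sequence; it is
  a pre-filter for classification, not evidence of function.
* Mechanism annotation is a fixed clade-level map; individual enzymes in a
  clade can deviate (acyclic products occur in clades II–IV, and
  viridiflorol synthesis is known from both 1,10 and 1,11 routes), so the
  annotation is a prior, not a verdict.
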