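---
title: "Methods: the white-fat-browning screening cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the white-fat-browning screening cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(browningscreen)
```

`browningscreen` implements a five-stage in-silico screen for drug
repositioning against the browning of white adipose tissue. This vignette
is the package's account of what each stage computes, which knobs matter,
and what the shipped synthetic data does and does not establish.

## The cascade and its assumptions

The pipeline is a funnel of set-valued operations. Each stage consumes a
gene table (a `gene_set`: a tibble of `gene_id`, `symbol`, deduplicated by
id, ordered alphabetically by symbol for determinism) and emits a smaller
one, until anchor augmentation, the single expanding step.

**Literature mining.** Genes are associated with documents in a local
corpus; a query returns every gene linked to at least one document whose
keyword text contains the query phrase as a case-insensitive exact
substring. We deliberately use no stemming, tokenization or entity
recognition: the published screens of this kind rely on an external
text-mining index whose internals are not auditable, and an exact
substring rule is the simplest contract whose behaviour a reviewer can
verify by reading the corpus file. The assumption is that the corpus's
keyword text is already curated (our generator plants query phrases
verbatim); free-text corpora would need a real NLP layer. The three query
lists are intersected by gene id — a gene must be linked to all three
phrasings of the brown-fat literature to survive.

**Two-stage enrichment.** Stage 1 tests the intersection against
biological-process gene sets; stage 2 tests the union of the surviving
terms' member genes against pathway gene sets. The statistic is the
hypergeometric upper tail $P(X \ge k)$ for an overlap of $k$ of the
query's $n$ genes with a term of size $K$ in a universe of $N$ genes.
The two-stage wiring reflects the screen's logic: processes first to
capture the biology, then pathways over the process genes to find
druggable signalling context.

**Network stage.** An undirected simple graph is built over the
pathway-stage genes, keeping interactions with confidence at or above a
threshold (inclusive); isolates are noted and removed; degree and Freeman
betweenness are computed per node; *key nodes* are those meeting or
exceeding both network-wide means. The dual mean threshold is a blunt but
transparent hub criterion — it assumes the interesting regulators are
simultaneously locally connected (degree) and globally bridging
(betweenness).

**Anchor augmentation.** Hub selection discards well-understood effector
genes that sit at the network's edge. The cascade therefore merges the
member genes of one designated stage-1 term — by default *brown fat cell
differentiation*, the process most directly tied to the phenotype — back
into the target list. The union is deduplicated; key genes keep their
order, novel anchor genes follow alphabetically, and a `source` column
records provenance.

**Drug funnel.** A flat drug catalog (name, targets, global development
status, mechanism-of-action class, boolean development-detail flag) is
filtered in four order-independent steps: at least one target in the
final gene list; status in a whitelist of mature development stages;
detail flag true; mechanism class not blacklisted. The detail flag
deserves a note: in the published workflow this judgment came from manual
inspection of trial records, which is not mechanizable, so the catalog
schema carries the outcome as data rather than pretending to recompute it.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| query terms | the three brown-fat phrasings | the screen's published framing |
| stage-1 cutoff (corrected p) | 1.00e−07 | keeps lipid-metabolism processes, rejects generic terms; 1e−08 was too strict and 1e−06 too lax in the source screen |
| stage-2 cutoff (corrected p) | 1.00e−06 | pathway sets are larger and fewer, so the cutoff relaxes one decade |
| correction | BH | the standard enrichment-tool default; Bonferroni/none available for sensitivity |
| universe size N | the GMT's gene union, overridable | the honest default when the annotation service's universe is unknown; supply the real N when you have it |
| confidence threshold | 0.900 | the "highest confidence" interaction tier; inclusive comparison |
| anchor term | brown fat cell differentiation | most enriched, most phenotype-proximal process |
| status whitelist | launched, phase I/II/III, pre-registration, registered | drugs with real development maturity |
| mechanism blacklist | β1-AR agonists/antagonists, IL-6 antagonists, CREBBP inhibitors | cardiovascular off-target risk and systemic hazards |

## Numerical choices

*Hypergeometric tail in log space.* Each term
$\binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$ is evaluated as
`lchoose` sums and the series combined with a log-sum-exp, so tails far
below 1e−300 remain finite and accurate; the naive product underflows at
realistic enrichment strengths. The summation index starts at
$\max(k,\, n-(N-K))$, the support's lower edge. Invalid count
combinations are rejected with an explicit error rather than returning
`NaN`. The suite checks the implementation against exhaustive enumeration
of every draw for all parameter combinations with $N \le 12$ (tolerance
1e−12) and against R's reference distribution function in log space at
extreme parameters.

*Correction.* Terms with zero overlap are excluded *before* correction:
they carry no evidence and would only inflate the number of tests. BH is
the step-up with cumulative-minimum enforcement capped at 1 (delegated to
`p.adjust`); corrected values are always at least the raw values,
matching the "corrected p" column of published enrichment tables.

*Betweenness convention.* Undirected, unnormalized, endpoints excluded,
fractional attribution across equally short paths, each unordered pair
counted once — the Freeman definition as computed by standard network
tools (delegated to `igraph`; a brute-force all-simple-paths enumerator
in the test suite provides the independent check, 200 seeded graphs of up
to 7 nodes at 1e−9). A `double_count_pairs` flag doubles every value for
comparison with tools that sum over ordered pairs; it cannot change who
is selected, since means double too.

*Key-node comparison.* Both sides are rounded to 10 decimal places before
the `>=` test, so a node exactly at its mean (complete graphs, symmetric
stars) is never dropped by floating-point noise. Centrality means are
computed over the analyzed network — after isolate removal — matching the
order of operations of the source screen (isolate noted in the
interaction service, centrality run downstream on the pruned graph).

*Ordering and ties.* Every output is deterministically ordered:
enrichment by corrected p then term name, gene sets alphabetically,
centrality by decreasing degree then gene. Reruns on identical inputs are
byte-identical; no timestamps enter data files.

*Score dialects.* Interaction ingest accepts both the 0–999 integer
combined-score dialect (divided by 1000) and 0–1 decimals, detected by
any score exceeding 1; self-pairs are dropped and unordered duplicates
collapsed to their maximum confidence.

*Degenerate inputs.* Empty intermediate stages warn and propagate — a
screening cascade legitimately empties under strict thresholds, and the
funnel then reports zeros — while malformed files (missing columns,
unknown status tokens, dangling document links, empty target lists) error
at ingest naming the violated contract.

## What the synthetic generator emulates

`simulate_bundle()` writes all four input files plus a JSON truth
manifest, deterministically per seed. Its defaults are the package's
standing study conditions, chosen once to mirror the published screen's
shape at desk scale:

- a genome of 2 000 genes; three query lists of 60 genes sharing a
  25-gene core, planted in document keyword text, plus 100 background
  genes on neutral documents;
- three planted biological-process terms whose overlaps with the core (13,
  10, 12 genes — the anchor overlap matching the published anchor row's 13
  symbols) put them far below the 1e−07 cutoff, among 20 decoy terms of
  10–50 genes whose expected overlap is below one gene; two planted
  pathway terms (overlaps 15 and 12) among 20 decoys at stage 2;
- a network over the stage-2 genes with 3 hubs wired to each other and to
  every peripheral node at confidence ≥ 0.90, one planted isolate whose
  only links are sub-threshold, and 60 decoy edges strictly below 0.90 so
  the confidence screen cleanly separates planted topology (a config flag
  could overlap the ranges for stress tests, but the default keeps the
  separation exact);
- a drug catalog with 33 eligible drugs in the published class
  composition (18 PPAR-γ agonists, 4 β3-AR agonists, 1 insulin
  sensitizer, 3 insulins, 6 lipase clearing factor stimulants, 1 other)
  plus planted casualties for each funnel stage: 30 off-target, 20
  wrong-status, 10 without development detail, 6 blacklisted.

Generation is self-validating: the bundle is re-run through the package's
own enrichment, centrality and funnel functions, and generation *fails*
if any decoy passes a cutoff, any hub misses a mean threshold, or any
non-eligible drug survives. This keeps the manifest an actual guarantee
rather than an intention.

What the generator does **not** emulate: real literature text (keyword
fields contain the query phrases verbatim), annotation-term overlap
structure (decoys are sampled independently, real GO terms nest),
degree-distribution-matched networks (the planted topology is
hub-dominated by construction), and the proprietary drug catalog.
Consequently, passing tests establish that the *algorithms* implement
their contracts and that the cascade recovers planted signal — they do
not establish that the published gene lists would re-emerge from live
services, whose counts (380/131 text-mining genes, the service p-values,
the centrality means 32.00/5.56, the 622/158/81/33 drug counts) depend on
database states that cannot be reconstructed offline. Those published
gene tables enter the package as verbatim fixtures instead, typos
included ("LPN1", and two rows whose printed member count differs by one
from the printed symbols; the symbol lists are treated as authoritative
because together with the key genes they reproduce the published 18-gene
final list exactly, and the fixture-loading tests pin the 70- and 27-gene
stage unions).

## Problem sizes

The shipped suite runs the hypergeometric oracle over every valid
parameter combination with $N \le 12$ (about 4 000 cases), the
betweenness oracle over 200 seeded random graphs of up to 7 nodes, and
the end-to-end planted-recovery property over 20 generator seeds; the
acceptance script re-measures recovery over 10 seeds. These sizes keep a
full run in tens of seconds while exercising every code path; the
generator scales to larger genomes and catalogs by config if heavier
stress runs are wanted.

## Known limitations

- The substring text-matching rule cannot distinguish gene mentions from
  incidental phrase hits in real abstracts; it is faithful to a curated
  keyword corpus only.
- The universe size $N$ dominates the tail probabilities; with the
  GMT-union default, p-values are conservative relative to a
  whole-genome universe. Published service p-values are not
  reproducible without the service's universe and correction.
- The dual-mean key-node rule is scale-dependent: adding peripheral nodes
  lowers both means and can promote borderline nodes. It should be read
  as a screening heuristic, not a centrality-theoretic optimum.
- One anchor term is supported per run by design; merging several anchor
  terms is possible by calling `augment_with_anchor()` repeatedly, which
  is associative and idempotent.
- The development-detail filter encodes a manual judgment as input data;
  the package cannot audit it.
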