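---
title: "Retrosynthetic fragmentation and fragment enrichment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrosynthetic fragmentation and fragment enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrofrag)
```

## The problem

Small molecules — drugs, metabolites, screening hits — are built from
recurring chemical building blocks. Given a set of molecules that share a
property (say, ligands of one protein family, or one pharmacological class),
decomposing each molecule into fragments along chemically sensible bonds and
asking *which fragments occur more often than chance* is the small-molecule
analogue of term-enrichment analysis for gene sets. retrofrag implements
this pipeline in three stages: rule-based fragmentation, similarity
clustering of the fragment universe, and hypergeometric enrichment of
fragments (or fragment clusters) against a background library with FDR
control.

## Fragmentation model

Molecules are given as SMILES; cleavage rules as SMARTS patterns carrying
atom maps `:1` and `:2` on two bonded atoms. A rule designates every bond
whose endpoints match maps 1 and 2 as *cleavable*. Two conventions apply:

* **Ring bonds are never cut.** Cutting a single ring bond does not split a
  molecule into two pieces, so a ring bond matching a rule is dropped at
  match time. Classical retrosynthetic rule sets target acyclic linker
  bonds anyway.
* **Cut sites are hydrogen-capped.** A fragment is an ordinary molecule:
  each cut valence is saturated with hydrogen, and no attachment-point
  dummy atoms are introduced. Downstream counting and fingerprinting
  therefore treat fragments exactly like molecules.

Fragment size is measured in heavy (non-hydrogen) atoms, and the user's
minimum size `-n` is inclusive: `-n 4` keeps 4-atom fragments.

### The bond-compatibility graph and extensive mode

Not every set of cleavable bonds can be cut simultaneously: cutting too many
bonds leaves slivers below the minimum size. Cleavable bonds become nodes of
an undirected *compatibility graph*; a node is kept only if its solo cut
leaves both pieces at or above `min_size` (a bond that already fails alone
can never be part of a feasible cut set, since cutting more bonds only
shrinks pieces), and an edge joins two nodes iff cutting both bonds together
also leaves no undersized piece. Maximal sets of mutually compatible bonds
are the maximal cliques of this graph, enumerated with the Bron–Kerbosch
algorithm (with pivoting; output order is deterministic).

Extensive mode must generate *every* fragment of at least `min_size` heavy
atoms that some feasible fragmentation can produce. Cutting only each full
maximal clique would miss fragments that arise when a subset of a clique is
cut — cutting both ester bonds of diethyl succinate yields two ethyls and
succinic acid, but only the single-bond cuts yield the 8-atom half-ester.
Pairwise compatibility also does not imply joint feasibility: the three
ester bonds of triacetin are pairwise compatible at `min_size = 4`, yet
cutting all three strands a 3-atom glyceryl core. retrofrag therefore
processes each maximal clique by enumerating its *jointly feasible* bond
subsets and cutting each of them. Every feasible cut set is itself a clique
and hence lies inside some maximal clique, so this enumeration produces
exactly the union of fragments over all feasible fragmentations. Three
useful properties follow and are verified in the test suite against a
brute-force oracle that enumerates every bond subset directly:

* the result equals the brute-force union on every fixture molecule;
* raising `min_size` never adds a fragment (monotone shrinkage);
* single-mode output (below) is always a subset of extensive output.

Subset enumeration within a clique is exponential in the clique size; a
guard refuses cliques of more than 20 mutually compatible bonds, which in
practice requires an unusually large molecule and a permissive rule set.

### Single mode

Without extensive mode one deterministic fragmentation is returned: bonds
are visited in match order (bond index, then rule order) and greedily added
to the cut set unless the addition would strand a piece below `min_size`;
the final set is cut once. The greedy set is jointly feasible by
construction, which is why its fragments always appear in the extensive
output.

### Per-molecule deduplication

A molecule's fragment set is a set of canonical SMILES: two cuts producing
the same acetyl fragment contribute one entry, matching the frequency
stage's rule that multiple instances within one molecule count once.

## Chemistry layer

SMILES/SMARTS handling is split between an internal parser and OpenBabel:

* An internal SMILES parser builds the annotated molecular graph (element,
  aromatic flag, formal charge, explicit hydrogen counts, bond orders,
  ring-membership flags via bridge detection). Stereochemistry and isotopes
  are read and ignored — fragment identity is constitutional.
* An internal SMARTS matcher (backtracking subgraph embedding) supports a
  documented subset: element symbols, `#n`, `*`, `A`/`a`, `Hn`, `Dn`, `Xn`,
  `R`/`R0`, charges, the `!`/`&`/`,`/`;` logic, bond expressions
  `- = # : ~ @` and atom maps. Recursive SMARTS is not supported; the
  shipped RECAP/BRICS/CCQ-style rule files are re-encoded within this
  subset, with degree and ring primitives approximating recursive
  environment checks. No installed R package exposes indexed SMARTS
  matches, which this matcher provides (the match tells *which* bond to
  cut); its behaviour is validated in the tests against an independent
  cheminformatics toolkit.
* Canonicalization is delegated to OpenBabel (via ChemmineOB), so isomorphic
  graphs map to one canonical string and aromaticity perception follows a
  standard toolkit. Canonicalization is idempotent and cached per session.

## Fingerprints and clustering

Fragment similarity uses a linear-path fingerprint in the style of the FP2
default of common toolkits: every simple path of 1–7 heavy atoms is encoded
as its sequence of (element, aromaticity, charge) labels and bond orders,
read in the lexicographically smaller direction, and hashed into a
fixed-width bit vector (default 1024 bits, `--fp-bits`). Single-atom paths
of uncharged, non-aromatic C, N and O are excluded, hydrogens are ignored.
The hash is the documented rolling hash
`h <- (131 h + byte) mod (2^31 - 1)`, reduced modulo the width. Bit-exact
compatibility with any external fingerprint layout is *not* claimed: all
similarity contracts in this package are expressed through the Tanimoto
coefficient of its own fingerprints, and `cluster_fragments()` accepts a
precomputed similarity matrix for callers who prefer an external
fingerprint.

Tanimoto similarity is the set form |a∩b|/|a∪b|, defined as 0 when both
vectors are empty so that featureless fragments cluster deterministically.
Clustering builds a graph with an edge wherever similarity is **at least**
the threshold (the cutoff is inclusive: `-c 0.8` reads as "at least 0.8
similar") and takes connected components, i.e. single-linkage at the
threshold. Cluster ids are assigned by descending size, then by
representative string; the representative is the member with the highest
mean similarity to the other members, ties broken lexicographically —
deterministic and stable across platforms. Raising the threshold only
refines the partition.

## Frequency and enrichment

The frequency stage counts, per fragment, the number of molecules whose set
contains it. Enrichment compares a foreground table against a background
table that must contain every foreground fragment (results are meaningless
otherwise, and the condition is enforced with a fatal error naming the
offending fragment).

The p-value of a unit (fragment or cluster) is the hypergeometric upper
tail P(X ≥ k), computed through the survival function of `stats::phyper`
for numerical stability; the tests sweep every consistent configuration
with N ≤ 12 against exact binomial-coefficient summation. Two sampling
universes are offered because the choice is genuinely underdetermined:

* **occurrences** (default): the population is the multiset of background
  fragment occurrences — N = sum of background unit counts, n = sum of
  foreground unit counts;
* **molecules** (`--universe molecules`): the GO-style universe — N and n
  are background and foreground molecule counts.

Only units with at least one foreground occurrence are tested, and the
Benjamini–Hochberg correction uses m = number of tested units; testing
absent units would only pad the correction with p = 1 hypotheses. BH is
the explicit step-up (cumulative minimum) procedure, cross-checked in the
tests against `stats::p.adjust`. Fragment-level and cluster-level analyses
are corrected separately. Both raw p-values and FDRs are always reported;
no significance cutoff is hard-coded.

## The synthetic validation library

`make_enriched_library()` builds the study design used throughout
validation: background molecules are single-ester compounds LEFT–C(=O)O–RIGHT
assembled from fixed scaffold pools (benzoyl, cyclohexanecarbonyl, pentanoyl
and furoyl acids; butyl, benzyl, 2-methylbutyl and cyclohexylmethyl
alcohols), so that fragmentation at `min_size = 4` yields exactly one acid
and one alkane/arene fragment per molecule. The planted moiety is the
benzoyl group, whose acid fragment (benzoic acid) is the enrichment target.
The foreground is drawn *as a subset of the background* — this guarantees
the containment requirement by construction and makes the no-signal
calibration exact: a uniformly random foreground subset satisfies the
hypergeometric null. Defaults are 40 background molecules, 10 foreground
molecules, a planted rate of 0.25 in the background and 1.0 in the
foreground — small enough to validate quickly, large enough that the
planted fragment separates decisively (its upper-tail p is ~1e-7 under the
defaults). Designs with foreground rate ≤ background rate are flagged as
degenerate in the truth record.

What the generator does *not* emulate: drug-like chemistry diversity,
molecules with many interacting cleavable bonds, fragment universes large
enough to stress the 1024-bit fingerprint, or correlated fragment
co-occurrence beyond the one planted moiety. Passing the planted-recovery
and calibration checks therefore demonstrates correctness of the machinery,
not performance on real chemical libraries.

## Numerical and edge-case choices

* `min_size` must be ≥ 1; `-n 0` is a usage error.
* Duplicate molecule ids abort (frequency counts depend on identity);
  unnamed molecules get `mol<k>` by position.
* Unparseable SMILES lines are skipped with a warning and counted;
  `--strict` promotes them to errors.
* The `.frag` interchange format is this package's own dialect (TSV:
  id, parent SMILES, comma-separated sorted canonical fragments, `-` for
  empty); fragment strings are re-validated as canonical on read.
* Sorting of fragments and cluster members uses byte (C-locale) order so
  outputs are identical across locales; reruns are byte-stable because the
  pipeline has no hidden randomness.
* Exit codes: 0 success, 2 usage/input error, 1 internal error.

## Validation problem sizes

The shipped validation uses 100 random graphs of up to 10 nodes for the
clique oracle, the 10-molecule golden library at minimum sizes 1–4 against
the brute-force fragmentation oracle, the exhaustive N ≤ 12 hypergeometric
sweep, 1000 random vectors for the BH cross-check, 200 null foreground
draws for calibration and 100 seeded replicates for planted-signal
recovery. These sizes were chosen so the whole suite validates in about a
minute while each check still exercises the property it names.

## Known limitations

* No recursive SMARTS, stereochemistry-aware fragment identity, or
  ring-opening fragmentation.
* The shipped RECAP/BRICS/CCQ files are re-encodings within the supported
  SMARTS subset, not byte-exact copies of the published rule sets; use your
  own rule file where fidelity to a specific published set matters.
* Extensive mode's subset enumeration is exponential within a clique
  (guarded at 20 bonds per clique).
* The fingerprint is intentionally simple; for large heterogeneous fragment
  universes an external fingerprint via the similarity-matrix seam may
  separate chemistry better.
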