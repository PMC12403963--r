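---
title: "k-mer splits: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{k-mer splits: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(splitkit)
```

## The model

Let *X* be the set of input genomes. Every distinct canonical k-mer is
assigned the subset *A ⊆ X* of genomes it occurs in (after the
per-genome abundance filter). Each occurrence pattern *A* with
*∅ ≠ A ≠ X* is read as the phylogenetic split *A | X∖A*, weighted by the
number of distinct k-mers with that exact pattern. The intuition: a
sequence segment shared by exactly the genomes of *A* witnesses their
common history and their separation from the rest. K-mers present in
all genomes are uninformative; k-mers private to one genome support
only that genome's trivial split. Since every k-mer has exactly one
occurrence pattern, each k-mer supports at most one split, and the
split weights sum (together with the all-genome patterns) to the total
number of distinct indexed k-mers — a conservation property the test
suite checks against a naive dictionary oracle.

The raw split system is usually contradictory, so it is filtered
greedily by decreasing weight:

* **strict** (alias **tree**): keep a split iff it is pairwise
  compatible with everything kept so far. Two splits *A₁|B₁*, *A₂|B₂*
  are compatible iff one of *A₁∩A₂*, *A₁∩B₂*, *B₁∩A₂*, *B₁∩B₂* is
  empty. The result is realizable as a unique unrooted tree (at most
  |X|−3 non-trivial splits), built by `splits_to_tree()`.
* **weakly**: keep a split iff every triple with two already-kept
  splits is weakly compatible — no four taxa x₀,x₁,x₂,x₃ exist on which
  the three splits realize all three pairings {x₀,xᵢ}|{xⱼ,xₗ}. Weakly
  compatible systems are what SplitsTree draws as split networks.

Both definitions are the standard ones from split-system theory. Note a
consequence worth spelling out: the three splits *ab|cd*, *ac|bd*,
*ad|bc* of a quartet are **not** jointly weakly compatible — the four
taxa themselves are the forbidden configuration (equivalently, all
seven splits on four taxa would exceed the n(n−1)/2 bound on weakly
compatible systems). The implementation follows the quartet definition,
which the tests enforce by exhaustive enumeration; any two of the three
quartet splits are of course admissible, which is what the familiar
"box" in a split network shows.

`tree` and `strict` are implemented as aliases: both request the
greedy pairwise-compatible filter. We found no observable difference in
how the two names are used and document the aliasing rather than invent
a distinction.

## Assumptions and when they hold

The method assumes that shared k-mers predominantly reflect shared
ancestry. That holds when divergence is low enough that a k-mer
survives unmutated across the clade sharing it, and k is large enough
that identical k-mers rarely arise by chance (4⁻ᵏ per pair of
positions). It degrades with high divergence (shared k-mers vanish),
heavy recombination/horizontal transfer (patterns conflict — visible as
weakly-compatible networks rather than trees), and tiny k (chance
collisions).

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 31 (DNA), 10 (protein) | k-mer length. 31 is the community default for bacterial-scale DNA comparisons: long enough that random 31-mer collisions are negligible, short enough to survive typical intra-species divergence, and odd so no DNA k-mer equals its own reverse complement. 10 gives protein k-mers comparable information content (20¹⁰ ≈ 4²¹·⁶). Defaults are package choices, stated here rather than inherited from any fixed convention. |
| `m` | 4096 | Number of index partitions. A key's partition is its fixed-width bit encoding read as an unsigned integer modulo m (computed by Horner's rule mod m; a constant-time rolling update is provided and tested to agree). The partition is the unit of mutual exclusion for concurrent ingestion, so m is chosen orders of magnitude above any plausible worker count. |
| `qualify` | 1 | Minimum within-genome multiplicity of a canonical k-mer (counted across all of a genome's files) before it is registered. 1 = no filtering (assemblies); 2–3 suppress sequencing-error k-mers in read data. Per-genome overrides via the file-of-files `! n` suffix let reads and assemblies coexist. |
| `filter` | none | `strict`/`tree`, `weakly`, or none (all splits). |
| `bootstrap`, `seed` | off | Replicate count and RNG seed; per-replicate streams are derived from (seed, replicate index) so results do not depend on processing order. |
| `support_flag` | 0.75 | Support below this fraction marks a split as low-confidence in reports and plots. |
| `code` | off | NCBI translation table id; enables amino-acid mode with automatic translation of DNA-like records. |

## The abundance filter

Counting is per canonical key, per genome, summed over the genome's
files. The streaming formulation (a seen-once set for threshold 2, a
counter map above) is a memory optimization of the same semantics; this
implementation computes the per-genome multiplicity table in one
vectorized pass, which is exactly equivalent and is validated against a
count-then-threshold oracle. Canonical (not strand-specific) k-mers are
counted, so a fragment and its reverse complement reinforce each other —
the natural choice for unstranded read data.

Index construction uses singleton promotion: a key seen in one genome
so far lives in a singleton map (key → genome); its first observation
in a second genome transfers it to the occurrence table (key → genome
bit set). Genomes are scanned in worker-interleaved order but merged in
canonical input order, so the index is identical for every worker
count — determinism the acceptance tests check byte-for-byte on the
serialized outputs.

## Bootstrap resampling

With n distinct indexed k-mers, a replicate simulates drawing n k-mers
uniformly with replacement and re-weights each split by the draws
landing on its x supporting k-mers: weight\* ~ Binomial(n, x/n)
(`method = "per_kmer"`, the marginal of the multinomial draw; mean x,
variance x(1−x/n)). Each replicate is then filtered like the original
data, and a split's support is its survival frequency.

A second sampler, `method = "per_split"`, draws a single
p ~ Binomial(n, 1/n) — the multiplicity of one individual k-mer — and
sets weight\* = x·p. It has the same mean but variance x²(1−1/n), and
every split vanishes with probability (1−1/n)ⁿ ≈ 1/e per replicate
regardless of its weight, capping attainable support near 63%. Because
a support ceiling below the conventional 75% flagging threshold would
make support values meaningless, the per-k-mer sampler is the default
and the per-split variant is kept for sensitivity analysis. Both are
tested against their closed-form moments.

Support is evaluated for every pre-filter split; the filtered set is
annotated by lookup, and `consensus_splits()` keeps splits above a
support threshold carrying their *original* (not resampled) weights.
Splits that appear only inside replicates are counted for nothing: they
have no original weight to annotate.

## Amino-acid mode

Records are classified as DNA iff ≥ 95% of their characters fall in
{A,C,G,T,N,U} — protein sequences essentially always contain other
letters, while the threshold tolerates ambiguity codes in real DNA; the
threshold is exposed for unusual inputs. DNA-like records are
translated codon-by-codon in frame 1 (inputs are expected to be gene
predictions, so no frame search): trailing 1–2 nt are dropped, codons
containing non-ACGT characters give `X`, and stop codons emit `*`.
Neither `X` nor `*` belongs to the 20-letter k-mer alphabet, so both
break k-mer windows exactly like `N` in DNA mode — no k-mer spans a
stop. Codon tables come from Biostrings (NCBI tables 1–6, 9–16,
21–26). Translating then indexing is tested to commute with indexing
externally translated proteins.

## Numerical and representational choices

* **Canonical form**: lexicographic min of k-mer and reverse
  complement (DNA); identity (protein).
* **Split normalization**: a split is stored as the side *not*
  containing the first taxon, making the representation unique and —
  for compatible sets — turning the stored sides into a laminar family
  from which `splits_to_tree()` builds the tree directly.
* **Greedy tie-break**: equal weights are ordered by smaller side
  cardinality, then lexicographically by (zero-padded) side membership.
  This makes filtering deterministic across platforms; ties are
  otherwise arbitrary and no biological meaning is claimed.
* **Weights** are raw distinct-k-mer counts. `derive_splits()` takes a
  `weighting` hook (weight, side size, taxon count → numeric) for
  length-normalized or otherwise transformed weightings.
* **Degenerate inputs**: an empty index yields an empty split set with
  `total_kmers = 0`; a genome shorter than k contributes nothing and
  warns; resampling a split set with `total_kmers = 0` errors;
  filtering an already-conforming set is a no-op (idempotence is
  tested).
* **Full precision round-trips**: TSV weights are printed with 17
  significant digits, NEXUS confidences as percentages; writers and
  readers round-trip equal split sets, which the tests assert.

## The simulator, and what passing tests do not show

`simulate_genomes()` evolves a uniform random root sequence down a
random-binary, caterpillar or balanced tree with i.i.d. per-site
substitutions per branch (uniform among the three alternative bases);
`simulate_reads()` samples fixed-length reads uniformly with strand
flips and i.i.d. substitution errors, tracking error provenance so the
abundance filter can be scored exactly. Default study conditions used
by the acceptance checks: 8 taxa, 50 kb, 1% substitutions per branch
(recovery); coverage 30, 100 bp reads, 2% error, threshold 2 (reads).

The simulator deliberately omits indels, rearrangements, recombination,
repeats, GC bias, coverage bias and realistic quality models. Passing
recovery tests therefore demonstrates correctness of the *machinery*
(indexing, filtering, bootstrap, serialization) under the stated model,
not robustness to the full complexity of real genomes; on real data the
weakly filter, abundance filter and bootstrap support exist precisely
to absorb what the simulator leaves out. The problem sizes above keep
the full suite comfortably fast while staying in the regime where the
model's signal assumptions hold; none of the empirical numbers quoted
anywhere in the documentation are asserted beyond what the tests and
`scripts/acceptance.R` recompute.

## Known limitations

* The k-mer index is held in memory as R character-keyed structures;
  the design targets correctness and moderate scale, not the
  engineering throughput of a compiled implementation.
* `workers` controls scheduling only; R evaluates single-threaded, so
  it is a determinism contract, not a speedup.
* NEXUS output targets the SplitsTree 4 splits block; the `TRAITS`
  block carrying group labels/colors is a documented annotation that
  other NEXUS consumers will skip.
* No six-frame translation or ORF calling: amino-acid mode expects
  gene predictions or proteins.
* Paths containing `;` or `!` cannot be expressed in the file-of-files
  dialect and are rejected rather than guessed at.
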