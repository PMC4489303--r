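---
title: "Pseudo-component feature vectors: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-component feature vectors: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psekit)
```

## The problem

Machine-learning methods need fixed-length numeric inputs, but biological
sequences have arbitrary length. A sequence $S = R_1 R_2 \cdots R_L$ over a
residue alphabet (DNA, RNA or the 20 amino acids) must therefore be mapped
to a vector of fixed dimension that still reflects its composition and, if
possible, its sequence order. psekit implements the 28 published feature
modes that the pseudo-component family of encoders provides for this task —
14 for DNA, 6 for RNA and 8 for protein — behind one registry
(`list_modes()`, `extract_features()`), in three categories.

## The three model families

### Oligomer composition

`Kmer` counts every length-$k$ window (step 1) and divides by the window
count $L - k + 1$, giving a frequency vector over all $A^k$ k-mers in
lexicographic order ($A$ = alphabet size). `RevKmer` (DNA only) additionally
collapses each k-mer with its reverse complement into one
strand-independent feature, keyed by the lexicographically smaller member;
the class count is $4^k/2$ for odd $k$ and $(4^k + 4^{k/2})/2$ for even $k$.
Composition vectors are local: they carry no information about where along
the sequence a k-mer occurs.

### Physicochemical autocorrelation

Each selected physicochemical index turns the sequence into a numeric track
$P_u(i)$, $i = 1..T$, $T = L - g + 1$, where $g$ is the oligomer length of
the index (1 for amino acids, 2 for dinucleotides, 3 for trinucleotides)
and the index values are standardized (see below). With track mean
$\bar P_u$, the features are

$$\mathrm{AC}(u, \ell) = \frac{1}{T-\ell} \sum_{i=1}^{T-\ell}
  (P_u(i) - \bar P_u)(P_u(i+\ell) - \bar P_u), \qquad \ell = 1..\mathit{lag}$$

for auto covariance, and the analogous product of two *different* tracks
for cross covariance, over all ordered property pairs. One engine
parameterized by $g$ yields all nine published modes: DAC/DCC/DACC
(dinucleotides, DNA and RNA), TAC/TCC/TACC (trinucleotides, DNA) and
AC/CC/ACC (amino acids); the combined modes concatenate the auto block then
the cross block.

**Denominator convention.** Published formulations differ between dividing
by the number of summed pairs $T-\ell$ and by $T-\ell-1$. psekit divides by
the pairs count $T-\ell$, and takes $\bar P_u$ over the sequence's own
track. Downstream values are sensitive to this choice, which is why it is
stated here rather than buried in code.

### Pseudo-component composition

The pseudo compositions blend a composition vector $f_1..f_{A^k}$
(normalized to sum 1) with $\lambda$ sequence-order correlation tiers
through a weight $w$:

$$d_u = \frac{f_u}{1 + w\Phi} \;(u \le A^k), \qquad
  d_{A^k+v} = \frac{w\,c_v}{1 + w\Phi},$$

where $c_1..c_m$ are the correlation values and $\Phi = \sum_v c_v$. Every
vector sums to exactly 1, and the total pseudo-component mass is
$w\Phi/(1+w\Phi)$ — strictly increasing in $w$ when $\Phi > 0$ (a property
the test suite asserts).

Two coupling functions generate the correlation tiers. *Parallel*
correlation averages squared differences over the selected properties,

$$\theta_j = \frac{1}{T-j}\sum_{i=1}^{T-j} \frac{1}{\Lambda}
 \sum_{u=1}^{\Lambda} \left[P_u(i) - P_u(i+j)\right]^2, \qquad j = 1..\lambda,$$

giving one non-negative tier per lag ($m = \lambda$). *Series* correlation
keeps properties separate via products,

$$\tau_{(j-1)\Lambda+u} = \frac{1}{T-j}\sum_{i=1}^{T-j} P_u(i)\,P_u(i+j),$$

giving $m = \lambda\Lambda$ tiers, which psekit orders lag-major,
property-minor (`tau.lag1.Twist`, `tau.lag1.Tilt`, `tau.lag2.Twist`, ...).
The published mode set is recovered by fixing the composition tuple size,
the correlation oligomer length and the coupling: PseDNC is
$(k=2, g=2, \text{parallel})$ with the six structural dinucleotide
properties; PseKNC is $(k = \text{user},\ g=2, \text{parallel})$ — the
correlations stay on **dinucleotides** regardless of $k$, following the
formulation it extends (the engine exposes the correlation oligomer length
separately, so a $g = k$ variant remains possible); PC-/SC-PseTNC-General
use $k = g = 3$; PC-PseAAC and SC-PseAAC use $k = g = 1$ with the classic
hydrophobicity/hydrophilicity(/side-chain mass) scales, so SC-PseAAC has
dimension $20 + 2\lambda$. The protein "-General" modes differ from the
classic pair only in the allowed property universe (all 547 built-ins, or a
user file).

## Physicochemical indices and standardization

Every index is standardized to zero mean and unit variance over its
complete oligomer set before entering any correlation formula, using the
**population** standard deviation (divide by $N$): the 16 dinucleotides, 64
trinucleotides or 20 amino acids are the whole population, not a sample.
Standardization makes magnitudes comparable across properties, is
idempotent, and preserves rank order. A constant index cannot be
standardized and is rejected as degenerate. `extract_features()` and the
engine functions take a `standardize` toggle (default `TRUE`) because some
historical implementations consumed pre-scaled tables; the packaged tables
are raw and the default reproduces the standard convention.

**Provenance of the built-in tables.** The package exposes the four
documented slots — 148 DNA dinucleotide, 12 DNA trinucleotide, 22 RNA
dinucleotide and 547 amino-acid indices. The amino-acid table is real data
for 534 of its 547 entries: the three classic pseudo-composition scales
(Eisenberg consensus hydrophobicity, Hopp–Woods hydrophilicity, side-chain
mass) are hand-entered, and 531 complete, non-constant entries come from
the AAindex compilation shipped with the seqinr package, keyed by AAindex
accession; 13 clearly labelled `SYNTHETIC-AA-*` entries complete the
documented count. The nucleotide tables keep the canonical property names
(Twist, Tilt, Roll, Shift, Slide, Rise and their RNA analogues;
Bendability and Nucleosome for trinucleotides) so default selections match
field conventions, but their numeric *values* are synthetic calibration
values drawn once, with a fixed recorded seed, from physically plausible
ranges (helical-step degrees and ångströms); the redistributable source
compilations were not available to package. The filenames say so
(`*.synthetic.tsv`), and `data-raw/make_property_tables.R` regenerates
them. Because every formula standardizes indices first and none of the
package's correctness guarantees depend on particular index values, all
mathematics, tests and dimension contracts are unaffected; only
applications that need the *original* published index values should supply
them through `parse_user_index()` / `props_file`, which is the same channel
used for user-defined indices.

A six-property dinucleotide fixture (`dna_structural6.tsv`, the PseDNC
default set) is shipped separately so the math tests never depend on the
full tables; a test asserts it stays consistent with the main table.

## Defaults and parameter ranges

* `w = 0.05` for pseudo modes — the conventional default of the original implementations of these
  encoders (used both in their display examples and in the
  recombination-spot application with λ = 3). `lambda` has **no** default: its legal range
  ($\lambda \le T-1$) depends on sequence length, so a silent default
  would fail unpredictably; `lambda = 0` is allowed and yields the bare
  composition.
* Default property sets: PseDNC and the DNA/RNA dinucleotide General
  modes use the six structural properties; the trinucleotide General
  modes use Bendability + Nucleosome (a package choice — no canonical
  default is published); PC-PseAAC(-General) uses hydrophobicity,
  hydrophilicity and side-chain mass; SC-PseAAC(-General) uses
  hydrophobicity and hydrophilicity. Autocorrelation modes have **no**
  default and require an explicit selection, again because no canonical
  default is published.
* `k` is capped at 6 (nucleic) and 3 (protein), mirroring the input limits of the
  original web implementations; `allow_large_k` (CLI `--unsafe-k`) lifts the cap for
  stand-alone use. Protein `Kmer` at `k = 3` is 8000-dimensional.
* Batch semantics are all-or-nothing: if any sequence violates a length
  requirement the whole call fails naming the offending ids, because a
  silently shortened feature matrix corrupts downstream learning.

## Numerical and degenerate-input choices

Frequencies are exact rationals accumulated in doubles; vectors sum to 1
within 1e-12 and the pseudo blend preserves that bound. Homopolymers give
exactly zero autocovariance and zero theta (every deviation vanishes) —
asserted as identities, not tolerances. Ambiguity codes (N, gaps, U in
DNA, B/J/O/U/X/Z in protein) are rejected at validation with id, position
and character: every formula indexes exact oligomers, so one unresolvable
position would poison every window containing it; rejection is the only
lossless contract. Ties in RevKmer canonicalization (self-complementary
k-mers) resolve to the k-mer itself. The LIBSVM writer omits zeros with
1-based ascending indices; dense writers print 8 significant digits by
default (configurable) — below formula tolerance, above float noise; the
displayed precision of the original service is not published, so 8 is a
package choice.

## What the synthetic generator emulates — and what it does not

`random_sequences()` draws residues i.i.d. uniform over the alphabet with
lengths uniform in a range, under a caller-supplied seed (the global RNG
state is saved and restored). That suffices for the package's guarantees,
which are *formulaic*: engine-vs-oracle equality, normalization bounds,
strand invariance and dimension contracts hold for any sequence, so
uniform sequences probe them as well as genomic ones. What uniform
sequences do **not** emulate is the composition bias, repeat structure and
long-range correlation of real genomes and proteomes; passing tests
therefore say nothing about the *predictive usefulness* of any feature
mode on a real classification task, only that the features are computed
exactly as defined.

The brute-force oracles (`oracle_features()`) recompute every mode family
with dictionary tallies and explicit double loops, sharing no code with
the engines. Test problem sizes — roughly 50–120 random sequences of
length 10–200 per family, 100+ instances per guarantee — keep the full
suite under a minute while exercising every code path; they are stated
here as the package's chosen verification scale.

## Known limitations

* The nucleotide index *values* are synthetic placeholders (above); use
  `props_file` to supply published compilations where exact
  reproduction of historical feature values matters.
* The exact membership of the original 547-entry amino-acid snapshot is
  not reproducible from a current AAindex release; the packaged table
  matches the documented cardinality and is mostly-real, not
  byte-identical to any historical snapshot.
* Higher-level pseudo components built from functional domains, gene
  ontology or evolutionary profiles are out of scope; the user-defined
  property channel is the only extension point.
* No classifier is included: the package generates features, by design.
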