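# psekit

Fixed-dimension numeric feature vectors from DNA, RNA and protein
sequences, for machine learning.

Biological sequences have arbitrary length, but SVMs, random forests and
neural networks want fixed-length numeric inputs. psekit converts a
sequence S = R₁R₂⋯R_L into such a vector through any of **28 feature modes
established in the pseudo-component literature** — 14 for DNA, 6 for RNA, 8 for protein — in three
families:

* **Composition** — `Kmer` frequencies over all A^k k-mers; `RevKmer`
  (DNA) collapses each k-mer with its reverse complement into one
  strand-independent feature.
* **Autocorrelation** — covariance of standardized physicochemical
  tracks along the sequence: `DAC`/`DCC`/`DACC` (dinucleotides),
  `TAC`/`TCC`/`TACC` (trinucleotides), `AC`/`CC`/`ACC` (amino acids),
  e.g. AC(u, ℓ) = Σᵢ (P_u(i) − P̄_u)(P_u(i+ℓ) − P̄_u) / (T − ℓ).
* **Pseudo composition** — composition blended with λ sequence-order
  correlation tiers via weight w: d_u = f_u / (1 + wΦ) and
  d_{A^k+v} = w·c_v / (1 + wΦ), with parallel (squared-difference) or
  series (product) coupling: `PseDNC`, `PseKNC`, `PC-/SC-PseDNC-General`,
  `PC-/SC-PseTNC-General`, `PC-/SC-PseAAC(-General)`. Every vector sums
  to 1.

Built-in physicochemical index tables cover the four documented slots
(148 DNA dinucleotide, 12 DNA trinucleotide, 22 RNA dinucleotide, 547
amino-acid indices; see the vignette for provenance — the nucleotide
values are labelled synthetic calibration values), and user-defined
index files plug into every property-driven mode. Output writers produce
LIBSVM sparse text, CSV and tab-delimited matrices.

## Worked example

```r
library(psekit)

seqs  <- random_sequences("DNA", 2, 60, 80, seed = 4)   # or read_fasta("file.fasta") |> validate_alphabet("DNA")
feats <- extract_features(seqs, "PseDNC", lambda = 10, w = 0.05)
glance(feats)
#> # A tibble: 1 × 9
#>   mode   alphabet n_sequences dimension     k   lag lambda     w n_properties
#>   <chr>  <chr>          <int>     <int> <int> <int>  <int> <dbl>        <int>
#> 1 PseDNC DNA                2        26     2    NA     10  0.05            6
```

26 features = 16 dinucleotide frequencies + λ = 10 correlation tiers;
each row sums to exactly 1, and the tiers (θ₁..θ₁₀) carry the
sequence-order signal weighted by w = 0.05:

```r
feats[, 1:6]
#> # A tibble: 2 × 6
#>   id         AA     AC      AG     AT     CA
#>   <chr>   <dbl>  <dbl>   <dbl>  <dbl>  <dbl>
#> 1 seq001 0.0292 0.0365 0.00731 0.0439 0.0219
#> 2 seq002 0.0462 0.0198 0.0396  0.0396 0.0396

write_libsvm(feats)[1]
#> "+1 1:0.029237256 2:0.03654657 3:0.0073093139 4:0.043855883 ..."

heatmap_matrix(feats, ncols = 8)   # row-major grid + label map, NA-padded
autoplot(feats)                    # ggplot tile view of the same grid
```

`tidy()` gives the long form (`id`, `index`, `feature`, `value`);
`list_modes("PROTEIN")` shows the schema of every mode;
`oracle_features()` recomputes any mode with deliberately naive
brute-force code for cross-validation. A thin command-line wrapper ships
at `inst/cli/psekit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","psekit.R",package="psekit"))')" \
  dna --mode PseDNC --lamada 10 -w 0.05 -f svm input.fasta
```

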