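---
title: "Embedding-based pairwise protein alignment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding-based pairwise protein alignment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embalign)
```

## The problem and the model

Classical pairwise protein alignment scores a residue match by looking the
two letters up in a substitution matrix such as BLOSUM62. Those log-odds
tables encode average substitution propensities and work well above roughly
35% pairwise identity, but in the "twilight zone" (below 20–35% identity,
and especially below 10–12%) homologous sequences routinely share structure
while sharing almost no letter identity, and substitution scores carry
little signal.

`embalign` replaces the table lookup with a similarity computed between
*contextual embeddings*: per-residue feature vectors produced by a protein
language model, which depend on the whole sequence context rather than on
the letter alone. For query residue $x_i$ and target residue $y_j$ the match
score is

$$\delta(x_i, y_j) = s \cdot \cos\!\big(\mathrm{Emb}(x_i), \mathrm{Emb}(y_j)\big),$$

with scale $s = 10$ by default. Alignment itself is unchanged: an
affine-gap dynamic program, Smith–Waterman (local, the default) or
Needleman–Wunsch (global), run over this position-specific score matrix
with gap penalties of $-11$ (open) and $-1$ (extend). Keeping the classical
DP and swapping only the scorer is the point: the whole improvement in the
twilight zone comes from the embedding similarity.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `scale` | 10 | score units per unit cosine | Puts embedding scores on a scale comparable to substitution scores so that the standard gap penalties remain sensible. Cosine lies in $[-1, 1]$, so entries lie in $[-10, 10]$. |
| `gap_open` | −11 | score units | Standard position-independent opening charge; covers the first gapped position. |
| `gap_extend` | −1 | score units per extra gapped position | A gap run of length $k$ costs $-11 - (k-1)$. |
| `mode` | `"local"` | local / global | Local alignment performs better on benchmark references; global is provided for comparison. |

Substitution-matrix scoring (`load_substitution_table`,
`substitution_score_matrix`) is retained as the baseline; BLOSUM62 and
BLOSUM45 are built in (via Biostrings' canonical tables) and any NCBI-style
matrix text file can be loaded. Scores for residues outside a table's
alphabet fall back to its `X` wildcard column.

## The embedding contract

An embedding backend is an *adapter*: a function from a residue string to an
$L \times d$ matrix with exactly one row per residue. Language-model
tokenizers add padding and special tokens; the adapter must strip them, and
`embed_with_adapter()` treats any row-count mismatch as a contract
violation. Known model dimensions: ProtT5-XL-U50 emits $d = 1024$,
ESM2-T36-3B emits $d = 2560$. The package itself ships no model weights —
real backends plug in through the adapter, embeddings can be precomputed
and loaded from whitespace text matrices (`save_embeddings` /
`load_embeddings`, with `seq_id` and `model_tag` carried in `#` header
lines), and a deterministic `mock_embedder()` exercises the contract in
tests. For ESM-2 style multi-layer backends the choice of layer belongs to
the adapter; the convention here is the final hidden layer.

A known artefact of ProtT5 embeddings is that the first few residues of any
two sequences tend to show inflated cosine similarity. No positional
masking or correction is applied: the raw cosine is used at every position,
and hybrid schemes (substitution scores for the first few residues) are
deliberately not implemented, since they do not improve benchmark accuracy.

## The synthetic generator

Because real embeddings require a multi-gigabyte model, the package
includes a generator that plants a known alignment into a pair of synthetic
embedding matrices (`random_pair_spec`, `generate_synthetic_pair`):

* For each planted pair $(i, j)$, a shared latent unit vector $z$ is drawn;
  row $i$ of A is $\mathrm{normalize}(z + \varepsilon_1)$ and row $j$ of B
  is $\mathrm{normalize}(z + \varepsilon_2)$, with noise components i.i.d.
  $\mathcal{N}(0, \sigma^2/d)$. The expected planted cosine is
  $\approx 1/(1+\sigma^2)$ (so $\sigma = 0.5$ gives $0.8$); unplanted rows
  are independent random unit vectors with expected pairwise cosine near 0
  for large $d$.
* The planted pairs form long collinear blocks separated by a small number
  of indel events (default 3 per sequence) plus flanks. This geometry
  matters: homologous pairs diverge by a few insertion/deletion events, not
  by independently scattered matches. A generator that scatters planted
  indices independently implies an indel event at nearly every position,
  and the *optimal* affine-gap alignment then correctly refuses to bridge
  isolated pairs — the planted reference would be unrecoverable even at
  zero noise through no fault of the aligner.
* Residue letters are drawn uniformly over the 20-letter alphabet, so the
  same fixture drives both scorers: embedding scoring sees the planted
  structure, substitution scoring sees (by construction) letters that are
  uninformative about it. This makes the embedding-vs-BLOSUM contrast on
  synthetic data a *direction-only* analogue of the real benchmark
  comparison, not an effect-size estimate.

Defaults are fixed at lengths 120/120, 100 planted pairs, $d = 256$,
$\sigma = 0.2$. What the generator does **not** emulate: the geometric
structure real language models impose (anisotropic embedding spaces, the
first-residue artefact above, correlations between neighbouring residues),
realistic residue composition, or any relationship between letters and
embeddings. Passing the synthetic recovery tests therefore demonstrates
correctness of the scoring-and-alignment machinery, not benchmark accuracy
on real proteins — the latter requires the external benchmark and a real
model, as described in the README.

## Evaluation

`column_pairs()` reduces any pairwise alignment to its set of aligned
residue index pairs (gap columns excluded). Against a reference set $R$ and
test set $T$:

* **SP** $= |T \cap R| / |R|$. For pairwise alignments every column holds
  one pair, so SP equals the total-column score. The reference denominator
  (rather than the test denominator) is the reading consistent with that
  SP = TC identity; SP is therefore recall-style, and adding spurious test
  pairs cannot change it (precision feeds F1 instead).
* **F1** is the harmonic mean of recall $|T \cap R|/|R|$ and precision
  $|T \cap R|/|T|$, 0 for an empty test alignment.

Pairwise identity of a reference is the fraction of its gapless columns
with identical residues — the "aligned residue pairs" convention; columns
with a gap in either row count in `alignment_length` (residues and gaps)
but not in identity. Reference pairs are extracted from an MSA per
unordered row pair with dual-gap columns removed, so each pair contains
exactly the residues of its two sequences.

`bin_results()` summarizes evaluation rows by identity (default bins
$[0,10), [10,20), \dots$ percent) or by reference alignment length
(default $[0,500), [500,1000), \dots$ columns). Bins with fewer than 10
alignments are flagged suppressed and report no mean, to avoid skewed
averages; the per-bin count of SP = 0 alignments is reported as a column
rather than as a special code path. Values at or past the last edge are
clamped into the final bin with a warning.

`sample_score_distributions()` reproduces the diagnostic that motivates the
scoring function: per MSA it samples up to 100 aligned residue pairs from
the first 5 pairwise references ("aligned" distribution) and scores 4
random residues from each of 5 random sequences against each other across
distinct sequences ("random" distribution, 160 pairs per MSA — the
protocol's "roughly matching" sample size). With an informative scorer the
aligned distribution shifts right; with a substitution matrix both remain
centred near zero on low-identity data.

## Numerical and design choices

* **Gap convention.** A run of $k$ gaps costs
  $\mathrm{open} + (k-1)\,\mathrm{extend}$; the alternative
  ($\mathrm{open} + k\,\mathrm{extend}$) is a one-line change in the C++
  core. Direct transitions between gap-in-query and gap-in-reference states
  are allowed and charged a fresh open, so adjacent gap runs in the two
  rows are two runs.
* **Tie-breaking.** Traceback prefers diagonal, then up (query residue vs
  gap), then left, choosing predecessor state match > gap-in-query >
  gap-in-reference at every step; among equal-scoring local maxima the end
  cell with smallest $i+j$, then smallest $i$, wins, and on an exact tie
  between stopping and extending the local traceback stops. Comparisons are
  exact floating-point equality — no epsilon — which is reproducible
  because the traceback recomputes the same expressions the fill computed.
  Alignments are therefore byte-reproducible, but at exact ties other
  implementations may return a different co-optimal alignment with the same
  score.
* **Global end gaps** are penalized like interior gaps (a true global
  alignment, no semi-global variant).
* **Degenerate inputs.** A zero-norm embedding row scores 0 against
  everything (with a warning); it cannot occur with real language-model
  output. Cosines are clamped to $[-1, 1]$ against floating-point drift.
  An all-non-positive score matrix yields the empty local alignment with
  score 0. Embedding scores enter the DP at full precision; no rounding.
* **Oracle.** `brute_force_align()` enumerates every monotone set of
  aligned index pairs with affine gap costs charged per maximal run,
  independently of the DP recurrences, and applies the same tie-breaking
  rule; the test suite requires score *and* pair-list agreement with both
  DP modes. The score audit (`score_audit`) recomputes every emitted
  alignment's score from its structure.

## Problem sizes used in the checks

Test and acceptance runs use: 200 random matrices up to $5\times5$ for
oracle equivalence (plus 150 integer-valued tie-stress matrices and 40
under equal open/extend, where all gap interleavings tie); 100 random
instances for the score audit; 10 seeds at $\sigma = 0.2$ for the recovery
mean and 30 seeds per level for the six-level noise sweep (the sweep means
sit near the SP ceiling, where adjacent levels differ by ~0.003, so the
smaller sample would be dominated by Monte Carlo noise); 20 seeds for the
planted-vs-random score contrast; MSAs of 2–10 rows for the extraction
count law. The full suite runs in well under a minute on one CPU.

## Limitations

* The package authors the scoring and alignment machinery; it does not ship
  or run a language model. Accuracy claims on real proteins depend entirely
  on the embedding backend plugged in.
* Embedding-based local alignment can still fail on some very-low-identity
  pairs (producing SP = 0 alignments where a substitution baseline finds
  partial signal); the evaluation layer surfaces these as the `n_zero_sp`
  column rather than hiding them in means.
* The DP is a dense $O(mn)$ implementation — appropriate for pairs, far too
  slow for all-vs-all homolog search without an indexing/filtering front
  end, which is out of scope.
* MSF support covers the common interleaved dialect (via seqinr); benchmark
  XML annotation, core-column masking and RSF are out of scope.
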