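---
title: "Aligning protein complexes by clustering chain superpositions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning protein complexes by clustering chain superpositions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimeralign)
```

## The problem

Two protein complexes are structurally similar when their chains match
individually *and* are arranged the same way in space. Comparing complexes
therefore has two coupled sub-problems: which query chain corresponds to
which target chain (the chain assignment), and how good the resulting
complex-level superposition is. Enumerating all injective chain mappings is
factorial in the chain count; tools that do assignment refinement by
dynamic programming over chain pairs are accurate but slow at database
scale.

`multimeralign` implements a fast alternative built on one geometric
observation: if query chain A matches target chain A' and query chain B
matches target chain B', and the two complexes really are the same
assembly, then the rigid superposition that lays A' onto A is the *same*
transform that lays B' onto B — both equal the complex-level superposition.
A set of chain-to-chain alignments is jointly realizable exactly when their
superpositions (nearly) coincide. So instead of searching over mappings,
the package aligns every query chain against every target chain, writes
each alignment's superposition as a 12-component vector (nine rotation
entries, three translations), and looks for dense clusters among these
vectors. A cluster in which no chain occurs twice *is* a candidate chain
assignment; the best one is scored with a complex TM-score.

## Pipeline

For a query complex Q (chains $C_Q$) and target T (chains $C_T$):

1. **Chain alignment** (`align_chains`): all $C_Q \times C_T$ pairs are
   aligned with an iterative structure aligner (below).
2. **Superposition matrix** (`build_matrix`): each alignment contributes
   one row $(u_{11},\dots,u_{33},t_x,t_y,t_z)$ of its superposition of the
   target chain onto the query chain.
3. **Column filtering** (`filter_columns`): a column whose values barely
   vary carries no signal for separating superpositions. The criterion is
   the coefficient of variation $s/|\bar{x}|$; when $|\bar{x}| < 1$ the
   standard deviation itself is used (the CV degenerates near zero mean).
   Columns with criterion below 0.1 are excluded.
4. **Normalization** (`normalize_columns`): retained columns are z-scored
   so unitless rotation entries and Angstrom-scale translations contribute
   comparably to Euclidean distances.
5. **Iterative clustering** (`iterative_cluster`): DBSCAN with
   `minPts = 2` runs at a radius that starts at the minimum pairwise
   distance and grows by 0.1 (normalized units) up to the maximum pairwise
   distance. Clusters that reuse a chain are *rescued*: members are
   admitted in order of distance from the initiating core point and
   admission stops at the first chain reuse. The largest valid clusters
   seen anywhere on the radius grid are kept as candidates; iteration
   stops early when no larger or additional distinct cluster can exist.
6. **Scoring** (`score_assignment`, `best_alignment`): each candidate's
   matched chains are concatenated — query chains in their file order,
   target chains in the order of their matches — and a complex TM-score is
   computed over the concatenated alignment. The candidate maximizing the
   sum of query- and target-normalized scores wins.

## The chain aligner

The chain aligner is a TM-align-style iterative method, deliberately
self-contained (no 3Di alphabet, no prefilter — those belong to the fast
sequence-encoded comparison family, and the clustering core accepts
externally computed alignments through its list-based interface anyway):

* **Seeds**: gapless threading of fragments of length
  $\min(L, 20)$ at stride $\max(1, L/10)$ over both chains, plus one
  sequence-identity Needleman–Wunsch alignment.
* **Refinement**: given the current superposition, every residue pair is
  scored $1/(1 + (d_{ij}/d_0)^2)$, realigned by dynamic programming with a
  gap-opening penalty of $-0.6$ (no extension penalty, free end gaps), and
  re-superposed by Kabsch's SVD method on the new pair set. A step is
  accepted only if the alignment score does not decrease, so each seed's
  score trace is non-decreasing; iteration stops when the pair set is
  stable or after 30 rounds.
* **Selection**: converged pair sets are deduplicated, ranked by their
  alignment score, and the leading ones are evaluated with the full
  TM-score search; the seed maximizing
  `tm_query_norm + tm_target_norm` wins, ties going to the earlier seed.
  There is no randomness anywhere in the aligner.

$d_0$ follows the standard TM-score length scale
$d_0(L) = 1.24\,(L-15)^{1/3} - 1.8$ for $L > 21$, else $0.5$ Å. Exact
parity with TM-align is a non-goal; correctness is checked against
independent oracles (closed-form superposition, exhaustive-seed searches)
rather than against TM-align output.

## TM-score and its two normalizations

`tm_score` maximizes $\frac{1}{L_{norm}} \sum_i 1/(1 + (d_i/d_0)^2)$ over
rigid superpositions, seeding from contiguous alignment fragments of
lengths $L_a, L_a/2, L_a/4$ at stride $\max(1, L_a/10)$ and refining each
seed by iterating Kabsch on the subset of pairs closer than
$\max(d_0, 4.5)$ Å until the subset is stable.

A complex alignment carries both normalizations, by the total residue
count of the query ($L_Q$) and of the target ($L_T$), *including unmatched
chains* — unaligned residues contribute zero terms but inflate the
denominator, as in the usual TM-score semantics. A design point worth
spelling out: the package computes **one** superposition search with
$d_0(\min(L_Q, L_T))$ and divides the same unnormalized sum by $L_Q$ and
$L_T$. Running two independent searches with the two different $d_0$
values would make the identity
$\mathrm{tm}_q \cdot L_Q = \mathrm{tm}_t \cdot L_T$ hold only
approximately; sharing the sum makes it exact, which downstream code and
the test suite rely on. The $\min$ is chosen because it is the stricter
distance scale of the two.

Concatenation order is fixed to the query file's chain order. The TM
search makes the score insensitive to this choice up to search error, but
determinism requires fixing it. No pseudo-bond is introduced between
concatenated chains: distances are only ever computed within aligned
pairs, so chain boundaries need no special handling.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gap_penalty` | -0.6 | DP gap-opening penalty (score units; no extension penalty) |
| `max_iters` | 30 | refinement rounds per seed |
| `seed_fragment_len` | 20 | threading fragment length (residues) |
| `seed_stride` | 10 | fragment stride denominator: stride = max(1, L/10) |
| `cv_threshold` | 0.1 | column-informativeness cutoff (unitless) |
| `cv_absolute_mean` | TRUE | use abs(mean) in the CV |
| `sd_denominator` | "n" | population sd for column statistics |
| `epsilon_delta` | 0.1 | DBSCAN radius increment (normalized units) |
| `random_core_start` | FALSE | randomized DBSCAN start (robustness testing) |
| `tm_threshold` | 0.65 | report cutoff on the complex TM-score in search mode |
| `tm_threshold_norm` | "max" | normalization the cutoff applies to |

Notes on the genuinely open choices:

* **CV sign and sd denominator.** The filtering rule is stated as
  s.d./mean without addressing sign or the n vs n−1 convention. Columns
  are signed (rotation entries in $[-1,1]$, translations of either sign),
  so the absolute mean keeps the criterion meaningful for negative means;
  the population denominator makes the two-row case exact (two values
  $\mu \pm a$ give sd exactly $a$). Both are exposed in `mm_config`.
* **Deterministic DBSCAN start.** Classic DBSCAN picks a random core
  point; the package uses the lowest-index unvisited core point instead.
  Determinism (bit-identical reruns, stable candidate lists) is worth more
  than fidelity to an irrelevant randomization; `random_core_start = TRUE`
  restores the randomized behaviour for robustness experiments. A side
  effect: when a merged cluster is repeatedly rescued across the radius
  grid, the rescue always starts from the same lowest-index seed, so the
  candidate list holds distinct chain pairings only — it approaches its
  theoretical bound (the larger chain count) but need not reach it, and
  the early-stop test is then simply never triggered early, which costs a
  few extra cheap iterations and nothing else.
* **Rescue distance space.** Distances to the initiating core point are
  measured in the same filtered, normalized space used for clustering.
* **Candidate ties and deduplication.** Valid clusters *at least as
  large* as the current best are admitted (ties kept); candidates
  describing the same chain pairing through different matrix rows are
  kept once.
* **Which normalization the 0.65 cutoff applies to** is ambiguous in
  search settings; the package defaults to the larger of the two
  (`"max"`), the permissive reading, and exposes
  `query`/`target`/`avg` alternatives.
* **Clustered-database expansion.** Aligner-based search produces no
  E-value, so cluster expansion uses a TM threshold instead (default 0.3,
  deliberately permissive so that marginal representatives still trigger
  alignment of their members). `expand_threshold = 0` expands everything
  and is exactly equivalent to exhaustive search — a tested invariant.
* **Monomer handling.** Multimeric queries reject monomeric targets by
  default; `include_monomers = TRUE` reverses this.

## Degenerate inputs and numerical corner cases

* Chains with fewer than 3 Cα atoms are dropped on reading (Kabsch needs
  three non-collinear points); rank-deficient point sets raise a
  degenerate-geometry error rather than returning a spurious rotation.
* A single chain alignment (monomer vs monomer) bypasses filtering and
  clustering entirely and is reported as a one-pair complex alignment.
* If *every* column is excluded — all superpositions effectively
  identical — the normalized matrix has zero columns, all rows are at
  mutual distance 0, and one cluster of all rows is rescued. This is the
  physically correct reading of "uninformative": nothing distinguishes
  the superpositions.
* Retained columns with zero variance (possible only through that
  fallback) are centred but not divided.
* Neighbourhood radii are inclusive (distance ≤ epsilon), and the radius
  grid includes the maximum pairwise distance.
* DP tie-breaks prefer diagonal moves; equal-scoring alignment seeds
  resolve to the earlier seed; equal-scoring candidates resolve by more
  aligned residues, then lexicographically smallest chain pairing.

## What the synthetic fixtures do and do not show

The fixture generator (`make_chain`, `make_complex_pair`,
`random_fixture_pair`) builds compact self-avoiding Cα walks with
consecutive spacing 3.8 ± 0.05 Å, bond-angle jitter, and a radius of
gyration confined to the protein-like scaling $\approx 2.2\,L^{0.38}$ Å.
Complexes place 2–4 such chains (30–60 residues each) without steric
overlap; the target is one global rigid transform of the query with
chains renamed, permuted, and perturbed by Gaussian noise of
$\sigma \in [0, 4]$ Å. The planted pairing and transform are recorded, so
every test has exact ground truth. A decoy variant transforms each chain
independently: chains still match individually while the complex geometry
does not — precisely the failure mode that chain-assignment methods must
not reward. All randomness flows from one integer seed through a local
generator scope; reruns are bit-identical and the caller's RNG state is
untouched.

What these fixtures do *not* emulate: secondary structure and realistic
backbone geometry, flexible or partially disordered regions, domain
motions between conformers, missing interior residues, sequence homology
between distinct chains, and crystallographic artifacts. Passing tests
therefore demonstrate the correctness of the assignment-by-clustering
machinery under rigid-body similarity plus isotropic noise — the regime
the method's own geometric premise addresses — not performance on real
remote homologs, which depends mostly on the strength of the underlying
chain aligner. Chains with missing interior residues are aligned
positionally on whatever Cα atoms exist.

## Problem sizes

The shipped test-suite and the acceptance script work at desk scale,
chosen to exercise every code path with exact brute-force cross-checks:
100 seeded complex pairs with 2–4 chains of 30–60 residues for the
assignment-recovery check (every injective mapping scored exhaustively),
1,000 random point sets for the superposition closed form, 200 point
clouds for clustering parity, and a 30-complex clustered database (10
planted clusters of 3) for the search-equivalence check. Chain counts
beyond 4 are covered by the same machinery (the factorial brute force,
not the pipeline, is what limits the *checks* to 4 chains).

## Known limitations

* The chain aligner is sequential (no non-sequential/order-independent
  alignment) and unaccelerated; database search cost grows with the
  product of chain counts. The optional length-ratio prescreen only
  skips hopeless pairs and never changes results above threshold.
* No E-values or statistical significance — ranking and cutoffs are in
  TM units throughout.
* Only the first model of multi-model files is read, and the file's
  chains are the complex: no biological-assembly generation from
  symmetry operators, no nucleic-acid or ligand alignment.
* The clustering can in principle return a partial assignment when a
  matched chain's superposition is an outlier (heavy noise); the
  TM-score then simply counts the unmatched residues against the score.
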