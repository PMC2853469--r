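---
title: "Residue-level potentials with a Shuffled Reference State: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level potentials with a Shuffled Reference State: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srspot)
```

## The model

`srspot` derives pairwise, distance-dependent, residue-level statistical
potentials from protein chains reduced to Cβ interaction centers, and scores
candidate models with them. The core quantity is the Boltzmann inversion

$$E(i,j,o,b) \;=\; -\ln \frac{f'_{\mathrm{obs}}(b \mid i,j,o)}{f_{\mathrm{ref}}(b \mid i,j,o)} \quad [kT],$$

with residue types $i,j$, orientation class $o$, and Cβ–Cβ distance bin $b$.
Both frequencies are *conditional distributions over distance bins within
each $(i,j,o)$ cell*. The alternative — joint normalization over all cells —
is a defensible convention too; the conditional one was chosen because it
makes the Sippl smoothing blend (below) a proper mixture of two
distributions on the same support, and because per-cell offsets cancel in
rank-based model comparison, which is the intended use. Only energy
*differences between models* matter; no RT factor is applied.

### Representation

* Each residue contributes one interaction center, its Cβ atom. Glycine
  (and any residue lacking a CB record but carrying N/CA/C) gets a virtual
  Cβ placed by internal coordinates in the N–CA–C frame: bond CA–CB
  1.53 Å, angle N–CA–CB 110.5°, dihedral C–N–CA–CB +122.8° under the NeRF
  construction used here, which reproduces the ideal L-alanine Cβ to 3·10⁻³ Å
  and always yields the L-chirality signed volume. These are canonical
  stereochemistry values; the source method names no numbers.
* Ordered pairs $(i \to j)$ are classified by the Cα→Cβ vectors
  $\mathbf a$ (residue $i$), $\mathbf b$ (residue $j$) and the inter-Cα
  vector $\mathbf c$: *parallel* when $\mathbf a\cdot\mathbf b > 0$,
  *antiparallel facing* when $\mathbf a\cdot\mathbf b \le 0$ and
  $\mathbf a\cdot\mathbf c > 0$, *antiparallel away* otherwise. Ties sit in
  the non-positive branch by construction. The classification is total,
  rigid-motion invariant, and symmetric only in its parallel class; both
  ordered directions are counted, so oriented and non-oriented tables are
  commensurable (collapsing the three classes reproduces the non-oriented
  table exactly — this identity is tested).
* Distance bins: $[0,4)$ Å, then 1-Å bins, half-open $[lo, hi)$, up to a
  configurable cutoff (default 20 Å, 17 bins). The half-open convention —
  4.0 Å falls in the *second* bin — is arbitrary but fixed and serialized
  with every table. 20 Å is a conventional long-range cutoff for residue
  potentials; the cutoff is configuration, not a constant.
* No minimal sequence separation: sequence neighbours count.

### Reference states

The **classic** reference redistributes the observed per-condition totals
$N(o,b)$ over type pairs with pooled weights
$w_{ij} = N_{ij}/N$: every type pair is assigned the same distance profile,
the average over all residue types. The **Shuffled Reference State** (SRS)
instead permutes residue identities uniformly within each chain while all
coordinates stay fixed. It therefore conditions on each chain's exact
geometry *and* composition; its defining property, verified in the tests,
is that it preserves per-chain type marginals, which pooled averaging (and
quasi-chemical mole-fraction mixing) does not.

Two SRS implementations are provided. `shuffled_reference_mc()` performs
the literal randomization — by default 1000 label shuffles with per-shuffle
seeds derived deterministically from one master seed — and is retained for
fidelity testing (every shuffle conserves the observed geometry exactly;
the Monte Carlo mean converges to the closed form as $1/\sqrt{n}$).
`shuffled_reference_exact()` is the closed-form expectation of the same
randomization: each ordered position pair $(p,q)$ of a chain with
composition counts $c$ and length $n$ contributes
$c_i c_j / (n(n-1))$ (or $c_i(c_i-1)/(n(n-1))$ for $i=j$) to its fixed
$(o,b)$ slot. It is the recommended production path — identical expectation,
no sampling noise. Virtual-Cβ positions stay with their spatial location
during shuffling; only labels move.

### Sparse-data smoothing

Observed conditional distributions are blended with the reference profile by
the Sippl weighting, $f' = \frac{1}{1+m\sigma} g + \frac{m\sigma}{1+m\sigma}
f_{\mathrm{obs}}$, where $m$ is the cell's observation count and $\sigma =
1/50$ (the scheme's original value; exposed as configuration). An empty cell
therefore receives the reference profile exactly ($E = 0$), and smoothing
guarantees finite energies wherever the reference has mass. A bin with zero
reference mass and zero observed mass is assigned $E = 0$; zero reference
mass under *nonzero* observations is an error with the offending cell
reported, since it indicates mismatched training inputs.

### Variants

`RF_CB` (classic, non-oriented), `RF_CB_OD` (classic, oriented),
`RF_CB_SRS`, `RF_CB_SRS_OD`. The variant implies both the orientation
dimension and the admissible reference method; `build_energy_table()`
refuses inconsistent combinations. Tables serialize to a self-describing
tabular text format carrying variant, binning, smoothing and provenance
(chain count, reference method, shuffle count, seed).

## Training-set selection

`passes_training_filters()` encodes the selection rules for training
chains: X-ray structures, resolution strictly better than 2.1 Å, R-value
strictly better than 0.2, at least 50 residues, no incomplete, modified or
nonstandard residues, missing residues at the termini only, no
co-crystallized ions. Operational choices the rules leave open:

* *Ions*: any single-atom HETATM species triggers rejection; waters are
  exempt. *Internal missing residues*: gaps in author numbering strictly
  between the first and last observed residue.
* *Completeness*: a residue is usable when CA is present and a Cβ center
  exists or can be built; a non-glycine residue without a CB atom counts as
  incomplete. Non-X-ray entries simply fail the X-ray criterion.
* *Identity culling* (< 40% pairwise): greedy retention processing chains
  best-resolution-first, with identity defined as identical aligned
  positions over the shorter sequence length under global alignment
  (BLOSUM62, gap open 10, extend 0.5). Whether the published criterion was
  applied per chain or per entry is unknowable from the method description;
  per chain is implemented.
* Altlocs resolve to the highest occupancy, ties to file order.

## Model scoring and benchmarking

`score_model()` sums table energies over all ordered in-range pairs;
out-of-range and degenerate pairs are tallied, never silently dropped, so
`n_pairs_scored + n_pairs_skipped = n(n-1)` always holds. Scores are
rigid-motion invariant and additive over spatially separated components.

Benchmarking consumes decoy manifests (GDT_TS values are *inputs*;
no superposition engine is included, only the
$(GDT_{P1}+GDT_{P2}+GDT_{P4}+GDT_{P8})/4$ combiner with a monotonicity
check). Ranks bin GDT_TS in 2.5-unit steps anchored at the set maximum
(100 when the native is present, which reproduces the 14-bin worst-case gap
to a 65-GDT_TS model). When the native is present and the minimum-energy
record is not the native, ranks of non-natives are computed among
non-natives and incremented by one, so the best non-native gets rank 2
regardless of the gap — and a weaker selection gets one more than its
non-native rank. That extension of the rank-2 rule to non-best selections
is under-determined by its one-sentence description; the `+1` offset scheme
is the implemented reading. Energy ties break by lexicographic model id —
breaking toward higher GDT_TS would leak the answer.

Decoy-set selection implements the four admission rules (all-atom flag;
best model ≥ 65 GDT_TS; most-populated exact-length cluster, ties to the
longer length; one seeded-random representative per absolute 2.5-unit bin).

Scoring functions are compared with paired one-tailed Wilcoxon signed-rank
tests (alternative: row ranks lower than column ranks). Zero differences
are dropped and reported; tied absolute differences get average ranks. For
up to 25 effective pairs the null is enumerated exactly over all $2^n$ sign
assignments (Gray-code C++ loop); above that, a normal approximation with
continuity and tie correction. The exact branch reproduces
`stats::wilcox.test` to machine precision on tie-free data, and the
$n=6$, all-wins case gives $p = 1/64$ by construction. Whether the original
analysis used the exact or approximate null is unknown; the size-based
switch is standard practice.

## The synthetic-data module

The generator exists so that every other module is testable without
external downloads, and its defaults are a fixed "stated world":

* **Chains**: $n$ Cβ centers placed by self-avoiding random placement
  (hard core 4.0 Å) in a sphere sized for a protein-like density of
  0.006 residues/Å³ (~1 residue per 167 Å³), giving a mean
  nearest-neighbour distance near 5 Å. Cα sits 1.53 Å from Cβ in a random
  direction; an `orientation_bias` knob aligns a fraction of Cα→Cβ vectors
  with +z so orientation-dependent variants have recoverable signal.
  Consequence of the 4.0 Å hard core: the 0–4 Å bin carries no mass in
  synthetic data and its energies are identically zero by the empty-bin
  convention — real structures, where sub-4 Å Cβ contacts are vanishingly
  rare, motivate the floor.
* **Interacting ensembles**: chain coordinates are fixed, then labels are
  re-equilibrated by composition-preserving label-swap Metropolis sweeps
  targeting $P(\text{labels}) \propto e^{-H}$, where $H$ counts each
  unordered in-range contact once (half the ordered-pair sum — with the
  full ordered sum every contact is double-counted and recovered energies
  come out at twice the truth). Swap moves preserve composition exactly,
  so the ensemble's null is *precisely* what the SRS conditions on; the
  chain satisfies detailed balance (verified against exact Boltzmann
  enumeration on a 4-residue fixture, total-variation < 0.01).
* **Decoy benchmarks**: per-target GDT_TS values with at least one model at
  the 65-unit admission threshold, and energies
  $-\rho\,z(\mathrm{GDT}) + \sqrt{1-\rho^2}\,\varepsilon$ for a controllable
  energy–quality correlation $\rho$.

What the generator does **not** emulate: backbone connectivity, sterics
beyond the hard core, secondary structure, real amino-acid composition, or
the heterogeneity of crystallographic metadata. A green recovery test
establishes that the estimator inverts its own generative model — not that
the potential ranks real CASP models well, which requires the external
decoy data the benchmark module is built to consume.

### The recovery experiment and its regime

The end-to-end oracle trains `RF_CB_SRS` on an ensemble generated with
known pair energies and asks for Pearson $r \ge 0.9$ between recovered and
true energies (200 chains × 100 residues). Its stated world: six uniform
types, dense random symmetric couplings $\mathcal N(0, 0.4^2)$ kT in the
contact bins 1–3 (4–7 Å), correlation computed over *all* active-type
cells. Two design points deserve the explanation:

* *Weak, dense couplings.* With sparse strong couplings (±1 kT on three
  pairs) the fixed-composition ensemble develops genuine induced
  interactions: attractive partners crowd every other type out of the small
  contact shells, so non-coupled pairs acquire real positive contact
  energies which the potential *correctly* reports ($r$ at the coupled
  cells stays ≥ 0.99) but which cap the all-cell correlation near 0.86 at
  any coupling scale. That is ensemble physics, not estimator error; the
  clean-oracle reading of the recovery test is the weak-coupling
  (linear-response) regime, where the direct term dominates.
* *Conditional-normalization offsets.* Enrichment inside the contact shell
  forces depletion elsewhere in each $(i,j)$ conditional; far bins
  therefore carry small compensating energies. They are part of the
  convention and are included in the correlation.

Measured at the frozen world: $r = 0.93$, regression slope 0.94.

### Null calibration

Training `RF_CB_SRS` on label-shuffled (null) data at 200 chains × 100
residues must give $|E| \le 0.1$ kT everywhere. The fixture uses a
four-letter uniform composition: the alphabet size is not part of the
stated scale, and four letters put per-cell counts in the thinnest
populated bin (4–5 Å) at the level the real 375-chain training set attains
per 20×20 cell — the criterion then probes estimator bias rather than raw
Poisson noise in a deliberately starved corner. Measured: max $|E| = 0.07$ kT.

## Numerical and interface choices

* Half-open bin boundaries; ties in orientation dot products to the
  non-positive branch; energy ties in selection to lexicographic model id;
  length-cluster ties to the longer length; altloc ties to file order.
  Every tie-break is deterministic and documented.
* All randomized paths (shuffles, generators, per-bin representatives) are
  seed-reproducible; `select_decoys()` restores the caller's RNG state.
* Serialized formats are self-describing tabular text with `#key value`
  headers and explicit format versions; readers refuse unknown versions
  and row-count mismatches.
* The CLI uses DCF configuration files (R's native key–value format; no
  YAML parser is available in the target environment) with `--key value`
  overrides, rejects unknown keys, logs to standard error only, and exits
  0/1/2 for success/user error/data error.

## Known limitations

* The PDB reader handles the fixed-width subset needed for training and
  scoring (ATOM/HETATM, EXPDTA, REMARK 2/3 resolution and R-value); mmCIF
  is not supported.
* Identity culling calls one global alignment per retained-candidate pair;
  for thousands of chains a pre-clustering step would be advisable.
* `RF_CB_SRS_OD` tables trained on small chain sets can have thinly
  populated orientation cells; the Sippl blend keeps them finite but close
  to the reference — more chains, not a larger σ, is the remedy.
* The benchmark's `with_native` mode requires an explicit native record per
  target; it does not infer nativeness from GDT_TS = 100.
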