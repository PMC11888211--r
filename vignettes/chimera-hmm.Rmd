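---
title: "Detecting PCR chimeras in AIRR-seq V genes with a structured HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting PCR chimeras in AIRR-seq V genes with a structured HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vchimera)
```

## The problem

Every PCR cycle applied to a V(D)J amplicon library can leave incompletely
extended fragments that prime a different template in a later cycle. The
products are chimeras: single reads whose left part derives from one template
and whose right part derives from another. In adaptive immune receptor
repertoire sequencing (AIRR-seq) such artifacts are particularly damaging
because a chimera of two genuine rearrangements looks like a heavily mutated
— hence biologically interesting — sequence. What makes the setting tractable
is that the germline V alleles a rearrangement can derive from are known:
detection can be cast as asking whether a query is better explained as a
mutated copy of one germline V, or as a mutated splice of two of them.

`vchimera` answers that question with a hidden Markov model run in the
coordinate system of a multiple sequence alignment (MSA) of the germline V
database. Queries arrive already aligned to their best-matching allele (the
standard AIRR Rearrangement columns produced by annotators such as IgBLAST),
and `thread_query()` projects each query onto MSA columns through that
existing alignment, so no aligner is ever invoked.

## The model

For $N$ germline references and $K$ mutation-rate classes
$M_1 < \dots < M_K$, the HMM has $2NK$ states: each (reference, rate) pair
exists in a *non-chimeric* copy $U$ (no template switch so far) and a
*chimeric* copy $C$ (switched at least once). Observations are the query
symbols at the $L$ MSA columns. Emissions at a state with rate $m$ are

* $1 - m$ when the query base matches the reference base,
* $m/3$ when it mismatches (uniform substitution model),
* $1$ when the query symbol is `-` or `N` (emission-neutral, used for
  uncovered columns, deletions and ambiguous bases).

A reference gap opposite a query base is scored as a mismatch $m/3$; the
emission law is otherwise only defined over reference nucleotides, and this
choice is isolated in `emission_prob()`.

The initial distribution is uniform over the $NK$ non-chimeric states.
Transitions from state $i$ to $j$ are

* $1 - \psi - \mu$ for $i = j$,
* $\mu/(K-1)$ between rate classes of the same reference and same label,
* $\psi/\big((N-1)K\big)$ into a chimeric state of a *different* reference,
* $0$ into a non-chimeric state of a different reference.

The zero in the last line is the construction that makes the terminal states
meaningful: any path ending in $U$ never switched, so the Forward algorithm
gives the posterior chimera probability directly,

$$P(\mathrm{chimera} \mid O) =
  \frac{\sum_{i \in C} \alpha_L(i)}{\sum_i \alpha_L(i)}.$$

When $N = 1$ the reference-switching branch is vacuous and its mass folds
back into the self transition (similarly for $\mu$ when $K = 1$), so rows
always sum to one and a single-reference database provably yields posterior
zero.

### Linear-time recursions

The textbook Forward induction costs $O(L(NK)^2)$, prohibitive for a 50-gene
database with 15 rate classes. Because the transition matrix has only four
distinct entry types, the induction for each target state needs just three
precomputed aggregates of the previous column — the global sum, the
same-reference same-label sum, and the both-label same-reference sum — giving
$O(LNK)$ total. The same decomposition applies to the backward pass, and a
max-with-argmax version of it to Viterbi. The dense quadratic recursion is
kept in the package as `forward_quadratic_oracle()` (and an internal dense
Viterbi) purely as an independent cross-check; the test suite verifies
agreement to a relative error of $10^{-10}$ on hundreds of random instances,
and the unit tests assert the linear growth of the per-column operation count
via an instrumented counter rather than wall-clock time.

### Numerical scheme

The forward pass uses per-column rescaling (each column of $\alpha$ is
normalized to sum one and the log of the normalizer is accumulated), not
log-space arithmetic — scaling keeps the inner loop branch-free and
vectorizable, and the log-space dense oracle cross-checks it. The scaled
backward pass shares the forward scale factors so that
$\sum_i \hat\alpha_t(i)\hat\beta_t(i) = 1$ at every column, which the tests
assert. A rate class with $m = 0$ is legal: it simply explains no mismatched
column, and scaling is unaffected as long as any state has positive mass. The
only true degeneracy — every state assigning zero probability to some column,
possible only when all rates are zero — raises an explicit error. Viterbi
runs in log space; predecessor ties are broken toward the lowest state index,
which pins down the reported breakpoint inside homology tracts where the
switch column is genuinely ambiguous (the breakpoint is reported as the first
column of the new segment).

## The two methods

**DB ("discretized Bayesian")** uses a shared grid of rate classes. For
immunoglobulin-like data the default is 15 classes equally spaced on
$[0, 0.25]$, covering somatic hypermutation (SHM) loads up to 25%; for T-cell
receptor data, which lacks SHM, a single fixed class at $m = 0.005$ absorbs
sequencing error. `receptor_preset()` encodes both.

**BW** uses two states per reference ($K = 1$) and a continuous per-reference
mutation rate fitted by Baum–Welch EM, initialized at 0.05. Expected mismatch
and informative-emission counts are accumulated from the posterior state
occupancies, pooled over the $U$ and $C$ copies of each reference and over
the whole dataset — per-query rates would be unidentifiable for short reads,
and pooling the two labels is the natural reading of "one rate per
reference". The M-step is the clamped ratio of those counts (floor $10^{-6}$,
ceiling 0.3; references with no occupancy keep their previous rate, and the
clamp provably cannot break EM monotonicity because the expected
complete-data log-likelihood is concave in each rate). $\psi$ is a user prior
and is never re-estimated. The loop stops when the total log-likelihood
improves by less than $10^{-3}$ or after 10 iterations; when the iteration
cap is hit, one final E-step refreshes the posteriors under the last fitted
rates.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| $\psi$ | $10^{-4}$ | per-column switch rate to a different reference |
| $\mu$ | $10^{-3}$ | per-column switch rate between rate classes |
| threshold | 0.95 | posterior at or above which a query is called chimeric (`>=`) |
| DB grid | 15 classes on $[0, 0.25]$ | SHM discretization for IG data |
| TR rate | 0.005 | single class for sequencing error |
| BW init | 0.05 | starting per-reference rate |

No published value exists for $\psi$ and $\mu$; they are priors the user may
tune. The defaults were chosen from first principles: over an
$L \approx 300$-column V gene the prior probability of at least one switch is
roughly $L\psi \approx 3\%$, small enough that a non-chimeric query cannot
reach the 0.95 threshold on prior mass alone, while a true chimera of
diverged parents gains a likelihood-ratio factor of order $(3/m)^d$ for $d$
discriminating columns, which dwarfs the $\psi$ penalty already at $d$ of a
few. The calibration simulations below validate the choice; the defaults were
fixed before those simulations were run and not revisited.

## The simulation framework

The simulator is first-class, tested code, because every calibration claim
rests on it.

* `synth_germline_set()` generates a family-structured germline database:
  one root per family at pairwise divergence `between_div`, genes within a
  family at `within_div`, gap-free. Divergence targets are hit by inverting
  the two-branch substitution relation $d = 2r - \tfrac{4}{3}r^2$
  (`divergence_to_rate()`). The defaults — 50 genes in 7 families,
  `within_div = 0.06`, `between_div = 0.30`, $L = 300$ — mirror the human
  IGHV locus: about 50 functional genes in 7 families, sibling genes roughly
  90–95% identical, families 60–75% identical, and a 300 nt V region.
* `build_genotype()` draws one allele per gene uniformly from a full allele
  database, the usual construction of a personalized genotype.
* `simulate_dataset()` emits exactly `round(n_total * chimera_rate)` chimeras
  (matching the fixed 500/9,500 split of a 10,000-read, 5%-chimerism study
  design, rather than a Bernoulli draw). Non-chimeras are one reference
  mutated uniformly at a difference-from-reference rate (DFR); chimeras join
  two *distinct*, independently mutated alleles at a breakpoint uniform on
  $[2, L]$, so each parent contributes at least one column. Same-allele
  chimeras are excluded from truth because they are undetectable by
  construction in a reference-based method. The emitted AIRR table carries
  perfect alignments against the *left* parent — a deliberate stress, since a
  real annotator would likewise assign a chimera to one plausible allele.
* `evaluate_detection()` reports the tie-averaged rank AUC (via pROC) and
  threshold confusion counts.

What the simulator does **not** emulate: clonal lineage structure and
non-uniform gene usage, position- and context-biased SHM, indels, quality
scores, and multi-breakpoint chimeras. Passing the calibration suite
therefore shows that the model is well calibrated under uniform mutation and
uniform usage; on real data, SHM hotspots and skewed repertoires can only be
said to be handled to the extent the emission model's uniform-rate assumption
approximates them.

## What the tests compute

The acceptance suite regenerates the study conditions at full scale — 9,500
non-chimeric queries per mutation level on the 50-gene synthetic set — and
checks that DB mode flags none of them at DFR 0%, 5%, 10% and 20%, and BW
mode at most 6 of 9,500 at 20%; that a 10,000-read, 5%-chimerism simulation
at DFR 0 separates chimeras with AUC at least 0.99; and that sensitivity at
the 0.95 threshold is at least 0.9 among chimeras whose parents differ at 10
or more of the 60 columns around the breakpoint (30 on each side — a window
wide enough to carry the likelihood signal, narrow enough to condition on
local detectability). Chimeras of near-identical parents are "perfect fakes"
and no reference-based method can see them; conditioning on flank divergence
is what makes the sensitivity claim falsifiable. These problem sizes are the
package's chosen study conditions; `scripts/acceptance.R` re-runs the 20% DFR
calibration from scratch with a caller-supplied seed.

## Known limitations

* Only the V region is modeled; D/J breakpoints are out of scope.
* Same-allele chimerism is invisible to any reference-based method.
* The uniform emission model ignores substitution bias and SHM hotspots; a
  hotspot-aware emission would need position-specific rates the model keeps
  deliberately simple (one free parameter per state).
* An incomplete reference database inflates chimera calls, because a missing
  allele's reads are best explained as recombinants of present alleles. The
  recombination table (`tabulate_recombinations()`) is the diagnostic: a
  missing allele shows up as an overrepresented gene pair.
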