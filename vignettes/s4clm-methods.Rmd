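---
title: "Chemical language modeling with structured state-space layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical language modeling with structured state-space layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(s4clm)
```

## The model

`s4clm` implements a chemical language model (CLM): an autoregressive
sequence model over SMILES tokens that learns, from a corpus of molecules,
both the *syntax* of the notation (balanced branches, matched ring bonds,
legal valences) and the *semantics* of the chemistry it encodes, and then
generates new molecules token by token.

The sequence layer is a structured state-space model (S4). Each channel
carries an independent single-input single-output linear dynamical system

$$x_k = \bar{A}\,x_{k-1} + \bar{B}\,u_k, \qquad
  y_k = \bar{C}\,x_k + \bar{D}\,u_k,$$

with hidden state $x_k \in \mathbb{C}^N$. Unrolling the recurrence from
$x_{-1} = 0$ shows that the same system acts on a whole sequence as a causal
convolution

$$y = u * \bar{K}, \qquad \bar{K}_k = \bar{C}\bar{A}^k\bar{B},$$

plus the skip term $\bar{D}u$. This duality is the architectural point:
training runs in the convolutional form (the whole molecular string is
processed at once, with FFTs), while generation runs in the recurrent form
(one token per step, constant work per token). Both paths share the same
parameters, and the package tests enforce their numerical agreement — on
random systems (relative error below $10^{-4}$) and on trained models at
the logit level (absolute error below $10^{-3}$).

### Structured parameterization

Learning an unconstrained $\bar{A}$ is unstable. The continuous-time state
matrix is therefore kept in diagonal-plus-low-rank (DPLR) form
$A = \Lambda - PQ^{*}$ and initialized from the HiPPO-LegS operator (the
scaled Legendre memory operator), expressed in the eigenbasis of its normal
part so that $\mathrm{Re}(\Lambda) = -\tfrac12$: every mode decays, and the
bilinear (Tustin) discretization

$$\bar{A} = (I - \tfrac{\Delta}{2}A)^{-1}(I + \tfrac{\Delta}{2}A), \qquad
  \bar{B} = (I - \tfrac{\Delta}{2}A)^{-1}\Delta B$$

maps the spectrum into the closed unit disk. $\Lambda$, $P$, $Q$, $B$, $C$,
$\Delta$ (one step size per channel, log-parameterized) and $D$ are all
learned; $P$ and $Q$ are initialized equal but trained independently.

Three kernel computation routes coexist and are cross-checked in the test
suite:

* **`"cauchy"`** — the structured generating-function path: the truncated
  kernel generating function is evaluated at the $L$-th roots of unity via
  Cauchy dot products (Woodbury identity on the DPLR resolvent, with the
  $(I - \bar{A}^L)$ truncation correction folded into $\bar{C}$), then
  inverted with one FFT;
* **`"naive"`** — materialized matrix powers $\bar{C}\bar{A}^k\bar{B}$, the
  in-repo oracle, intended for the moderate state sizes used here
  ($N \le 64$);
* **`"recurrence"`** — explicit state stepping, used during training
  because backpropagation needs the state trajectory anyway.

### Gradients

No automatic differentiation framework is used: the backward pass is
derived by hand. Complex parameters follow the conjugate-gradient
convention ($G = \partial L/\partial\,\mathrm{Re} + i\,\partial
L/\partial\,\mathrm{Im}$), under which a holomorphic linear map $y = ax$
backpropagates as $G_x = \bar{a}\,G_y$. The chain runs: cross entropy →
output head → layer norms → channel mixing → GELU → causal convolution
(FFT-based correlations for both the input and the kernel gradient) →
back-propagation-through-time along the kernel recurrence → the bilinear
discretization (solves against $M^{H}$) → $(\Lambda, P, Q, B, \Delta)$.
The whole path is validated against central finite differences in the test
suite via directional derivatives.

### Architecture

Token embedding → `n_blocks` × [layer norm → per-channel state-space
convolution (+ skip $D$) → GELU → channel-mixing linear → residual] →
final layer norm → projection to vocabulary logits. Every stage except the
state-space convolution is position-wise, so causality is inherited from
the convolution; a dedicated test perturbs position $k{+}1$ and asserts
logits at $k$ are unchanged.

Default sizes are deliberately desk-scale: 2 blocks, width 96 (64 in the
bundled studies), state size $N = 16$, chosen so that a full
pre-train/generate/evaluate cycle runs in minutes on one CPU core. All of
them are configuration fields; nothing in the code assumes these values.

## Tokenization, curation, encoding

The tokenizer uses the standard SMILES token classes with precedence
bracket atoms `[...]` > `%nn` ring labels > `Cl`/`Br` > single characters,
and guarantees that concatenating tokens reproduces the input string.
Corpus curation mirrors common CLM practice: keep molecules over
C, H, O, N, S, P, F, Cl, Br, I only; strip a fixed counter-ion list and
then discard anything still multi-fragment; remove stereochemistry; remove
charges where a trivial protonation-state change neutralizes the molecule
and discard the rest (each such decision is per-record and deterministic);
keep canonical SMILES of at most 100 tokens; deduplicate after
canonicalization. Where the underlying preprocessing conventions are
ambiguous — salt-stripping versus wholesale discarding of salted entries —
the package strips first and discards only what remains disconnected,
which keeps the parent compound of simple salts; the policy object makes
the switches explicit.

Sequences are encoded as `[BOS] tokens [EOS] [PAD…]` with a fixed
per-corpus content length (default 100, `"auto"` fits the longest training
molecule). PAD carries no loss; EOS is scored. Likelihoods are therefore
invariant to padding length, which is tested.

Chemistry itself — canonicalization with valence checks, descriptors,
Morgan fingerprints, Bemis–Murcko scaffolds, substructure search — is
delegated to RDKit through a bundled batch-mode Python helper
(`inst/python/chem_tools.py`), the standard toolkit for this work. Two
descriptors (synthetic-accessibility and natural-product likeness) are
fragment-frequency scores computed by the package itself against reference
corpora supplied at call time, because the published fragment-contribution
data files are not redistributable with the package; they follow the same
log-odds-of-circular-fragments construction as the originals and are
documented as estimates.

## Training and transfer learning

Pre-training minimizes next-token cross entropy with teacher forcing in
convolutional mode. The optimizer is Adam; the structured state-space
parameters ($\Lambda, P, Q, \log\Delta$) use a halved learning rate and,
like all parameters here, no weight decay — the customary regime for this
architecture family, adopted because the layer's spectrum is sensitive to
large steps. Complex parameters keep separate second-moment estimates for
real and imaginary parts.

Fine-tuning continues training on a small task-focused set with early
stopping on validation cross entropy: patience 5 epochs, tolerance
$10^{-5}$ loss units (an improvement smaller than the tolerance counts as
no improvement). The vocabulary and model shape never change; fine-tuning
molecules not expressible in the pre-training vocabulary are dropped with
a warning. The last five epoch snapshots are retained so that generation
campaigns can pool designs across trailing checkpoints.

## Generation and scoring

Generation always runs the recurrence, starting from BOS with zeroed
states, sampling from

$$p_i = \frac{e^{y_i/T}}{\sum_j e^{y_j/T}}$$

over the unnormalized logits $y$. The logit reading is deliberate: only
then does $T = 1$ recover the model's own distribution, $T \to 0$ the
greedy argmax, and larger $T$ a flatter law (token-level entropy is
non-decreasing in $T$, which is tested). Truncated designs (no EOS within
the length cap) are kept and counted as invalid unless they happen to
parse — a conservative accounting choice. The campaign driver sweeps
$T \in \{1.0, 1.25, 1.5, 1.75, 2.0\}$ across the trailing fine-tuning
checkpoints; at the published protocol scale (5 checkpoints × 5
temperatures × 10,240 designs) that is 256,000 designs per campaign.

Molecule ranking uses the joint log-likelihood
$\mathcal{L}(M) = \sum_i \log p(t_i)$ (content tokens plus EOS, each
conditioned on the true prefix) and the bias-corrected score
$\mathcal{L}_{\text{score}} = \mathcal{L}(M_{\text{ft}}) -
\mathcal{L}(M_{\text{pt}})$, which removes general-chemistry likelihood so
that target-specific signal drives the ranking. Enrichment is reported as
recall@k — the fraction of all actives placed in the top $k$ — matching
the fraction-of-known-actives axis convention of retrospective screens;
precision@k is available behind a flag since the normalization is a known
ambiguity of that convention. Exact score ties are broken by a seeded
shuffle.

## Evaluation

* **Validity / uniqueness / novelty** are counted over the total generated
  batch: parseable; distinct canonical forms among the valid; unique forms
  absent from the training set.
* **Error taxonomy** for invalid designs, with precedence branching
  (unbalanced parentheses) > ring (unmatched ring labels) > bond
  (parseable but valence-impossible) > other (residual parse failures).
  The fixtures module can *corrupt* valid molecules into each category,
  and a property test checks classifier label = requested label across
  hundreds of random corruptions.
* **Property profiles** (clogP, QED, Bertz complexity, SA estimate,
  NP-likeness, sp³ carbons, aliphatic rings, spiro atoms, molecular
  weight, largest fused ring system, heavy atoms) with mean ± sd and
  two-sample Kolmogorov–Smirnov distances (×100, in percent) to training
  and test sets. A distribution's KS distance to itself is 0%; disjoint
  supports give 100%.
* **Rediscovery** of held-out actives, exact (identical canonical
  structure) or relaxed (Tanimoto similarity on Morgan fingerprints,
  radius 3, 2048 bits, strictly above 60%).
* **Scaffold diversity**: Bemis–Murcko scaffolds, fingerprinted and
  grouped by single-linkage clustering cut so that scaffolds merge exactly
  when their similarity exceeds 60% — i.e. connected components of the
  threshold graph; the single-linkage realization is a package choice
  since the linkage is not fixed by convention. Acyclic designs form a
  dedicated no-scaffold cluster.
* **Prospective selection**: keep unique novel designs, rank by
  fine-tuning log-likelihood, take the top 5,000, split at 60% scaffold
  similarity to the fine-tuning set, group each list by nearest
  fine-tuning molecule, keep the best bias-corrected scorer per group.

Thresholds use strict inequalities (`> 0.6`), with boundary cases pinned
in tests.

## The synthetic-fixture generator

Every stage is testable without external databases. The generator builds
molecules *constructively*: atoms are emitted with explicit valence
bookkeeping (C/N/O chains, carbonyl decorations, halogen terminals) and
rings come from closed, valence-safe templates (benzene, pyridine,
cyclohexane, cyclopentane, furan) with fresh ring-closure digits per
nesting level — so every string parses by construction, which is verified
post hoc. Defaults (heavy-atom budget 16 ± 5 clipped to [4, 32], ring
probability 0.15, branch probability 0.25, 3,000 training molecules for
the end-to-end studies) were chosen once to emulate the drug-like regime —
canonical strings well under 100 tokens, a mix of rings, branches and
heteroatoms — at a scale where a full pre-training run takes minutes on
one CPU.

Planted bioactivity sets make enrichment measurable: actives all carry a
sulfonamide motif, which the motif-free base alphabet (no sulfur) cannot
produce by accident, and both labels are re-verified by substructure
search. The *default* grammar alphabet does include sulfur chains, so a
pre-training vocabulary built from it covers the motif's tokens and
fine-tuning on planted actives never hits out-of-vocabulary drops.

For overfitting studies the fixtures module provides a dedicated
*memorization corpus* with an exactly computable accuracy ceiling. For any
corpus of $n$ distinct strings, a teacher-forced argmax predictor must
lose at least one position per non-majority string wherever prefixes
branch, capping next-token accuracy at $1 - E/T$ with $E \ge n-1$ branch
losses over $T$ scored tokens; for short strings that cap sits well below
99%, no matter how well the model fits. `memorization_corpus()` therefore
builds one ~100-token backbone molecule plus $n-1$ single-point,
valence-safe variants — a caterpillar prefix tree with $E = n-1$ exactly —
pushing the cap to $1 - (n-1)/(n(L+1)) \approx 99.04\%$ and making
"memorized" operationally checkable: the trained model should sit at the
ceiling and greedily regenerate the backbone. What passing these tests shows is that the pipeline's machinery —
transfer learning, likelihood scoring, ranking, enrichment statistics —
works end to end; it does not show that the model captures real
bioactivity landscapes, whose structure–activity relationships are far
subtler than a planted substructure. Likewise the grammar corpus exercises
syntax learning, not the property distributions of ChEMBL- or
COCONUT-scale chemistry.

## Numerical choices and degenerate inputs

* Bilinear discretization throughout; a singular $(I - \tfrac{\Delta}{2}A)$
  aborts with a diagnostic (it cannot occur at the HiPPO initialization,
  whose spectrum lies in the open left half-plane).
* Softmax and log-likelihoods use max-subtraction; $T = 0$ never consults
  the random stream; exact logit ties resolve to the first index.
* The kernel's generating-function path special-cases $z = -1$ (where the
  bilinear resolvent collapses to $\tfrac{\Delta}{2}B$).
* Empty fingerprints (e.g. the empty scaffold of an acyclic molecule)
  have similarity 0 to everything by convention.
* Curation of an empty or fully-filtered corpus warns and returns an
  empty vector; generation length is capped at the model's content length.
* Checkpoints embed a vocabulary hash; loading or cross-model scoring
  with a mismatched vocabulary fails loudly.

## Problem sizes used in the bundled studies

The test suite and the acceptance script train three models: a
32-molecule memorization probe (2 blocks, width 64, N = 16, ~110 epochs on
the backbone-plus-variants corpus), a 3,000-molecule syntax study
(2 blocks, width 64, N = 32), and a fine-tuning run on a few dozen
planted actives. These sizes are the
package's own scaled-down study design: large enough that syntax learning,
transfer learning and enrichment are measurable, small enough to run
routinely on a single core.

## Known limitations

* Pure-R numerics: throughput is roughly half a second per gradient step
  at the default sizes — ample for the bundled studies, not for
  millions-of-molecules corpora.
* One SISO system per channel mixed by position-wise layers, as in the
  reference S4 design; no bidirectional or selective (input-dependent)
  state spaces.
* Sampling is plain temperature sampling; no beam search, nucleus/top-k,
  or scaffold-constrained decoding.
* The SA/NP descriptor estimates depend on the user-supplied reference
  corpora and are not numerically comparable to the published
  fragment-contribution scores.
* Stereochemistry is stripped during curation; the pipeline models flat
  molecular graphs.
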