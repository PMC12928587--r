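---
title: "Suppressive subnetworks in masked protein language models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressive subnetworks in masked protein language models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(subnetlm)
```

## The problem

Masked protein language models (PLMs) learn to predict amino-acid
identities at corrupted positions from sequence context, and in doing so
absorb a great deal of structural regularity. `subnetlm` asks *where* that
knowledge lives: it learns a binary mask **m** over a model's weights so
that the masked model — the *subnetwork* `f(x, m ⊙ θ)` — loses its
language-modeling ability on one structural category of inputs (the
*suppression* set) while behaving like the full model everywhere else (the
*maintenance* set). If a small set of weights can be zeroed to destroy
performance on one CATH class or one secondary-structure state without
collateral damage, that category is factorized in the weights.

Suppression targets are declared with `suppression_spec()` at two levels:

* **sequence level** — all domains whose CATH label, truncated to a chosen
  hierarchy level (Class, Architecture, Topology, Homologous Superfamily),
  equals a target label; every position of those sequences is suppressed;
* **residue level** — all positions annotated with one 3-state secondary
  structure code (H/E/L, reduced from DSSP's 8 states by
  H,G,I→H; E,B→E; T,S,-→L). The suppressed positions J* of each sequence
  are suppressed; the complementary positions J′ are maintained.

## Training objective

The mask is learned by minimizing a weighted sum of three terms
(`combine_losses()`), all computed over the 20-letter amino-acid support
and averaged over their included positions, in nats:

* **suppression** (`suppression_loss()`): the KL divergence from the
  subnetwork's predictive distribution to the uniform distribution over
  the 20 amino acids, on suppressed positions. Its minimum (0) is reached
  when the subnetwork is reduced to uniform guessing there — perplexity 20.
* **maintenance-KL** (`maintenance_kl()`): the KL divergence from the
  subnetwork's predictive distribution to the *unmasked* model's
  distribution on the same maintained positions, with the baseline treated
  as a constant.
* **maintenance-MLM** (`mlm_loss()`): the negative log-likelihood of the
  true residues at positions selected by the standard masked-LM corruption
  scheme (`make_corruption_plan()`: each position selected independently
  with probability 0.15; of the selected positions, 80% are replaced by
  the mask token, 10% mutated to a random amino acid, 10% left unchanged),
  restricted at residue level to the selected positions falling on
  maintained residues (M ∩ J′). The maintenance-KL term alone would be
  satisfied by matching the baseline even where the baseline is wrong;
  this term keeps actual token recovery intact.

All three terms see *corrupted* inputs: each minibatch sequence is passed
through the corruption scheme before any loss is computed. The maintenance
KL is scored at every position of the corrupted sequence, protecting both
the context-driven predictions and the "copy the visible token" behavior
of the full model. The suppression KL is scored, by default, only at the
corruption-selected positions (`train_config(supp_scope = "corrupted")`);
scoring it at all positions is available via `supp_scope = "all"` but is
not the default for a reason worth recording: at visible positions the
predictive distribution of a masked LM is dominated by the input token
itself, and an all-position KL-to-uniform spends most of its gradient on
destroying that class-agnostic copying pathway. Empirically this prunes
machinery shared by all classes — maintenance perplexity degrades as fast
as suppression. Restricting the suppression signal to the corrupted
positions targets exactly the context-conditional predictions that
perplexity evaluation measures, and yields selective suppression.

## Differentiable masking

Each maskable weight slot *i* carries a real logit `l_i`. A continuous
score is sampled per optimization step (`sample_scores()`):

    s_i = sigmoid( -(1/τ) [ l_i + log(u_i / (1 - u_i)) ] ),  u_i ~ U(0,1)

and binarized by a strict threshold, `m_i = 1(s_i > T)` (`binarize()`).
Note the sign convention: a *large* logit gives a *low* score, so pruned
slots are those whose logits rise. The logistic noise makes the sampled
binary mask stochastic — over draws, `P(s_i > 1/2) = sigmoid(-l_i)` — so
training explores different mask configurations. Gradients flow through
the binarization by the straight-through estimator: the gradient with
respect to `m` is used unchanged as the gradient with respect to `s`
(`straight_through_grad()`). Through the Hadamard product the gradient of
the loss with respect to `m_i` is the weight-space gradient times the
stored weight, `∂L/∂m_i = ∂L/∂(W_eff)_i · W_i`. At evaluation time the
mask is the deterministic noise-free binarization of `sigmoid(-l_i/τ)`
(`eval_mask()`); sparsity is the percentage of zeros (`sparsity()`).

Masking scope follows the usual subnetwork convention: only the attention
and feed-forward *projection weight matrices* of each block are maskable.
Embeddings, biases and layer-norm parameters are left intact and never
appear in the manifest (`maskable_index()`).

Numerical choices: τ = 0.5 and T = 0.5 by default, no annealing; uniform
noise is clamped to [1e-6, 1 - 1e-6]; probabilities are floored at 1e-9
inside logarithms; all logits start at -5 so the initial subnetwork keeps
essentially every weight (starting from the full model is the conservative
choice — sparsity grows only where the objective demands it).

## The toy testbed

No full-scale PLM is bundled; instead the package ships a complete
desk-scale testbed so that every stage of the method is exercisable and
testable end to end.

**Synthetic corpus** (`synthetic_spec()` / `generate_corpus()`). Three
sequence classes stand in for CATH classes. Each class has (i) a distinct
residue-frequency profile — 85% of emission mass on six class-typical
residues — and (ii) three class-specific 10-residue motifs, stamped 3–5
times per sequence. A segment process plants 3-state annotations
(helix-like runs of 4–12, strand-like 3–8, loop-like 2–6 residues), and
the per-position emission mixes the class profile with a state-typical
profile (weight 0.25), giving residue states distinct local composition.
Sequences are 64–96 residues long, 150 per class, split 70/20/10. The
profile separation is enforced by a minimum pairwise total-variation
distance so sequence-level suppression always has a learnable signal.

What this emulates: category-specific composition and local motif
structure, planted per-residue annotations, and the dataset conventions
(length filtering, splits) of a CATH-style corpus. What it does not:
long-range contact structure, evolutionary redundancy, realistic length
distributions, annotation noise, or anything about real protein families.
Passing tests on this testbed show the *method* behaves as specified —
they say nothing about how strongly a given real PLM factorizes real
structural categories.

**Toy model** (`build_toy_model()`). A two-block pre-norm transformer
encoder (width 64, four heads, feed-forward 256, tanh-approximation GELU)
with learned token embeddings, sinusoidally initialized position
embeddings, and a linear MLM head over the 20-letter support. Special
tokens (`<mask>`, `<pad>`, `<unk>`) are never predicted: every predictive
distribution is over the 20 amino acids, which makes "uniform guessing"
exactly perplexity 20. The K = 98,304 maskable slots are the projection
entries of both blocks. The forward and backward passes are written
directly in R matrix algebra (minibatches stacked row-wise with
block-diagonal attention); the backward pass is verified against central
differences in the test suite, which is what makes the straight-through
mask gradients trustworthy.

Noncanonical residues (X, B, Z, U, O) map to `<unk>` by default and are
excluded from every loss; `tokenize(..., noncanonical = "reject")`
rejects such records instead.

**Pretraining** (`pretrain_toy()`). Standard MLM training with Adam.
The pipeline used by the acceptance script runs 3,000 steps at batch 16
(learning rate 2e-3 decaying linearly to 2e-4), which brings held-out
masked-token perplexity to roughly 8.5 — far below both uniform guessing
(20) and the corpus unigram model (~19) — by learning the composition,
state and motif structure. Training much beyond this overfits the
450-sequence corpus (validation perplexity rises again), so 3,000 steps
is the reference configuration: large enough that suppression has real
signal to find, small enough to run on a laptop CPU in minutes.

## Mask training loop

`train_subnetwork()` freezes the model weights (a cryptographic hash is
checked before and after) and optimizes only the logits with Adam
(learning rate 0.05, λ = (1,1,1), batch 8 per side, up to 600 steps).
Each step draws one suppression and one maintenance minibatch of equal
size, which keeps the λ weights interpretable when the two sides have
very different sizes. Every 50 steps the deterministic evaluation mask is
scored on validation data and the snapshot maximizing the composite

    score = suppression perplexity - 10 · max(0, maintenance perplexity - baseline)

is retained; training stops early after six snapshots without
improvement. The penalty of 10 encodes the asymmetry of the goal:
maintenance degradation is a failure mode, higher suppression perplexity
is the objective. Three seeds (mask init, noise, data order) are recorded
in the config and make runs bit-reproducible. A NaN loss aborts with the
component values in the message.

Two control partitions (`make_control_spec()`) probe whether suppression
exploits shared structure: suppressing N *random* sequences, or a random
fraction of positions per sequence. A random set shares no category
signal, so its subnetwork cannot find category-specific weights; its
suppressed/maintained perplexity ratio stays close to 1 while a matched
class-suppression subnetwork's ratio is far larger.

## Evaluation

`stratified_perplexity()` corrupts each sequence with the standard scheme
(deterministic per-record seeds, two replicates by default), feeds the
*identical* corrupted inputs to the masked and unmasked model, and pools
the NLLs of true tokens at the selected positions by split
(train/validation/test), side (suppression/maintenance) and model
(subnetwork/baseline). Residue-level partitions route each scored
position to its own side's cell. Empty strata are reported as absent, not
zero. `per_layer_pruning()` reports the percentage of each layer's slots
zeroed; its slot-weighted mean equals the overall sparsity by
construction.

`delta_metric_stats()` consumes externally computed structure metrics
(RMSD/TM-score/pLDDT for subnetwork and baseline predictions of the same
inputs; this package never runs folding) and reports, per metric, paired
t-tests on the suppression and maintenance deltas and a two-sample
Kolmogorov-Smirnov test comparing |Δ_supp| against |Δ_maint|. Tests are
two-sided; significance at 0.05 is reported, never enforced. KS p-values
use the exact small-sample null distribution up to 25 observations per
sample and the asymptotic distribution beyond; the test suite checks both
paths against brute-force oracles (closed-form t, full ECDF sweep, exact
permutation enumeration). Identical paired values yield a zero t statistic
(rather than the 0/0 failure of the textbook formula), reading "no change"
as exactly that.

## Design decisions in open territory

* **Aggregation.** The mean (not sum) over included positions is used in
  every loss, so λ weights do not silently re-scale with sequence length
  or batch composition.
* **MLM orientation.** The maintenance-MLM term is implemented as a
  negative log-likelihood so that the combined objective is *minimized*
  coherently alongside the two KL terms.
* **Residue-level MLM restriction.** The scored set is M ∩ J′ — corrupted
  positions on *maintained* residues. (An alternative reading restricts to
  the suppressed annotation instead; that would reward recovering exactly
  the residues being suppressed, contradicting the objective's intent.)
* **Length bounds.** The 64–1024 dataset filter keeps both endpoints
  (bounds read inclusively).
* **Splits.** Uniform random splits by default; stratification by CATH
  Class is available via `split_dataset(stratify_by_class = TRUE)` for
  corpora with very uneven class frequencies.
* **Ties at the threshold.** `s = T` maps to 0 (strict inequality), so a
  degenerate all-`T` score vector prunes everything rather than nothing.
* **Evaluation-time mask.** The noise-free binarization is used rather
  than a sampled mask, making every reported perplexity deterministic.

## What scales down, and what does not

One quantitative behavior of the full-scale setting does *not* survive the
reduction to a two-block, 98,304-slot model, and it is worth being precise
about why. At full scale, coarse-category suppression can drive suppressed
perplexity to near-uniform (about 20) while pruning under 3% of maskable
parameters. On the toy model the same configuration reaches a suppressed /
baseline perplexity ratio of about 1.8 at 2.6% sparsity, and the ratio
does not reach 2 until roughly 5% of slots are pruned. Two effects
compound here. First, a single class's machinery is a much larger
*fraction* of a 98k-slot model than of a 650M-parameter one — the same
direction as the observed trend that sparsity shrinks as categories get
finer relative to model capacity. Second, with a well-trained baseline at
perplexity ~8, doubling means exceeding the corpus-unigram ceiling
(~19): a mask can only *remove* computation, and once all
context-processing relevant to the suppressed class is ablated,
predictions fall back on the marginal residue distribution stored in the
embeddings and output head — which are deliberately outside the masking
scope. Pushing beyond that ceiling toward uniform requires conditional
cancellation of the head's prior, which pruning alone cannot build at this
capacity. The test suite asserts the full-scale expectation as stated and
lets it fail on the toy model rather than weakening it; the sparsity bound
and the maintenance bound both hold.

## Known limitations

* The testbed's class signal is deliberately strong; real structural
  categories overlap far more, and the sparsity/perplexity trade-off
  observed here should not be quantitatively extrapolated to real PLMs.
* The toy model is two blocks deep; per-layer pruning profiles are
  correspondingly coarse.
* Structure-metric statistics treat inputs as exchangeable pairs; any
  phylogenetic or family structure among them is the caller's problem.
* Mask training is CPU-bound R; it is meant for models of this scale, not
  as a general PLM training harness.
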