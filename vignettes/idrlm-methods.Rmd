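---
title: "Modeling and generating intrinsically disordered regions with idrlm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and generating intrinsically disordered regions with idrlm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intrinsically disordered regions (IDRs) lack a stable fold, so
structure-based generative design does not apply to them. What *is*
observable at scale is the statistics of natural disordered sequences:
their compositional biases (proline/serine/glycine enrichment, depletion of
order-promoting aliphatics and aromatics), their charge patterning, their
low local complexity, and their short linear motifs. `idrlm` implements a
complete, desk-scale pipeline for learning and exploiting those statistics:

1. **Curation** — extract IDRs from per-residue AlphaFold confidence
   (pLDDT) traces, low confidence being a well-established proxy for
   disorder.
2. **Fill-in-the-middle (FIM) tokenization** — represent each IDR together
   with its flanking sequence so a causal language model can infill a
   disordered span conditioned on both flanks.
3. **A decoder-only transformer** trained by next-token prediction.
4. **Sampling** in prompted (contextual IDR) and unprompted (free IDP)
   modes.
5. **GRPO reinforcement-learning alignment** against a pluggable scalar
   reward with quadratic shaping terms.
6. **Sequence analytics** — the metrics used to judge whether generated
   sequences look like natural disordered regions.

Everything runs from synthetic data generated inside the package; no
database downloads are required for development or testing.

## Curation model

Curation takes a per-residue pLDDT trace in \[0, 100\] and applies, in
order:

* a centered moving average of width `window` (default **15** residues);
  the window shrinks at the termini rather than inventing pad values, which
  keeps every smoothed value a true mean of observed scores;
* three-state classification: smoothed score strictly above **80** is
  folded, strictly below **70** disordered, anything between is a *gap*.
  Scores exactly equal to a threshold are gaps — the only assignment
  consistent with strict inequalities on both sides;
* run refinement: folded or disordered runs shorter than **10** residues
  are demoted to gaps; adjacent gaps merge; a gap flanked by two disordered
  runs, or terminal next to a disordered run, becomes disordered; all other
  gaps become folded. The pass is applied once, in that order, and is a
  fixed point: re-running it changes nothing (a property the test suite
  asserts). A gap between one disordered and one folded run goes to folded
  under the "all other gaps" reading.
* record filtering: IDRs shorter than **30** residues are dropped, and
  whole proteins are skipped when longer than **512** residues, entirely
  disordered, or containing non-canonical letters (X, B, Z, U, O, J — the
  27-token alphabet has no representation for them).

Coordinates are kept 0-based half-open internally and serialized 1-based
inclusive, following UniProt convention.

## Tokenization and the FIM transformation

The alphabet has exactly 27 tokens: the 20 canonical amino acids, the
sentinels `<N>`, `<C>`, `<I>` marking the N-context, C-context and IDR
span, and the controls `<bos>`, `<eos>`, `<pad>`, `<mask>`. A record is
rearranged as

```
<N> n-context <C> c-context <I> idr
```

so the disordered span comes last and a causal model learns
`p(idr | both flanks)`. Duplicating every record with its contexts deleted
(the IDP augmentation) teaches unconditional generation through the same
interface; the prompt degenerates to `<N><C><I>`.

One bookkeeping decision deserves note: a 512-residue protein plus
`<bos>`, `<eos>` and three sentinels tokenizes to 517 tokens, which
exceeds the 512-token context. Truncation would destroy the `<I>` span, so
over-length records are dropped at encoding (the effective residue budget
is 507). `<mask>` is reserved — present in the alphabet, never emitted —
and masked out of every loss.

## Architecture and training

The language model is a decoder-only transformer with pre-LayerNorm,
SwiGLU feedforward blocks, rotary position embeddings (base 10 000, applied
to the full head dimension), no biases on projections, and an untied output
head. The full-scale configuration is 12 layers, 14 heads, width 896, FFN
expansion 8/3, context 512.

The SwiGLU hidden width is `8/3 × 896` rounded to the nearest multiple of
64, i.e. 2368, and SwiGLU is counted as three matrices (gate, up, down).
Under these standard conventions the exact trainable-parameter count is
**115,010,560 (~115.0M)**, which `count_parameters()` reports and
`parameter_breakdown()` itemizes. The count printed for the original
full-scale model is 122M; no rounding convention we are aware of reproduces
that figure exactly from the stated hyperparameters, and we deliberately do
not tune hidden widths to chase it — the discrepancy (~5.7%) is documented
here and the acceptance comparison carries the stated ±6% band.

Pre-training is AdamW (no weight decay, no gradient clipping), linear
warmup from 0 over 3,000 steps to a peak learning rate of 4.0e-4, cosine
decay to 4.0e-5 at 250,000 steps, 99/0.5/0.5 train/validation/test splits,
and pad/mask-excluded cross-entropy. Sentinel and context tokens *do*
contribute to the loss — training is plain next-token prediction over the
whole transformed sequence.

Desk-scale work uses a named profile (`desk_train_config()`,
`desk_grpo_config()`): 2 layers, width 64, batch 16–32, a few hundred
steps, peak learning rate 3e-3. The schedule shape is identical; only the
sizes change. The test-suite and acceptance-script problem sizes (corpora
of ~1,500 sequences with median length 60, 300 pre-training steps, 150–400
GRPO steps, 200–500 evaluation samples) are the package's chosen
desk-scale conditions.

Forward, backward and decoding have two numerically equivalent backends: a
compiled (RcppArmadillo) implementation used by default, and a plain-R
reference implementation. The contract is the math, not the kernel; the
test suite checks the two agree to ~1e-10 and validates the analytic
gradients against central finite differences.

## Sampling

Decoding samples from the full categorical `softmax(z/T)` at fixed
temperature `T = 1` by default, stopping at `<eos>` or when the total token
count (prompt included) reaches 512. Sentinels and controls other than
`<eos>` are masked to −∞ during decoding: the original description does not
say how mid-stream structural tokens are handled, and masking is the only
choice that guarantees parseable pure-residue outputs. Because the masked
distribution is the sampling policy, the RL aligner uses the *same* masking
when it recomputes log-probabilities, keeping importance ratios exactly 1
at the moment of sampling.

## GRPO alignment

Post-training uses Group Relative Policy Optimization: for each prompt the
policy samples a group of G = 8 completions; each completion's reward is
reduced to a group-relative advantage `(r − mean)/(sd + 1e-8)` (population
sd; an all-equal group yields zero advantages, never NaN). The loss is the
PPO-clipped surrogate (ε = 0.2) on completion tokens only — prompt tokens
are masked — plus a KL penalty to the frozen pre-trained reference with
weight β = 0.02, in the direction KL(reference ‖ policy) as the original
objective prints it (a switch provides the conventional direction).

The composite reward is a sum of quadratic penalties around three targets:
a score-model output of 0.9, a length of 100 residues, and a per-sequence
composition entropy of 2.7 nats. The penalty weights and the length
normalization are not stated in the source description; we use unit weights
with lengths divided by 100 so the three terms share a comparable scale —
an unnormalized `(L−100)²` would dwarf the others. All are configurable.

Implementation decisions that were genuinely open:

* **KL estimator.** With a 27-symbol vocabulary the exact per-position KL
  over the whole alphabet costs the same as a sampled estimator and has
  zero variance, so the exact form is the default and drives the penalty
  gradient; the k3 sampled estimator is available as an option and the two
  agree in expectation (tested).
* **DAPO aggregation.** The "decoupled" modification is implemented as
  token-level loss normalization — dividing by the total completion-token
  count across the batch rather than per sequence — the most commonly
  cited reading; per-sequence aggregation is switchable.
* **Old-policy log-probabilities** are captured at sampling time and a
  single optimizer step is taken per batch of rollouts, so ratios start at
  1 and the clip guards pathological updates.
* **Desk-scale learning rate.** The full-scale recipe uses 5e-6 for a
  ~1e8-parameter policy; desk-scale models here have ~1e5 parameters, and
  Adam step sizes do not transfer across three orders of magnitude of
  scale. The desk profile uses 1e-3, at which the length-targeted and
  entropy-targeted rewards converge within a few hundred steps while the
  per-step KL stays well below 0.4.
* **Score model.** The neural localization predictor used at full scale is
  out of scope; the package ships `toy_localization_reward()`, a fixed
  logistic over interpretable composition features (K+R fraction, glycine
  fraction, RGG-tract count), explicitly a synthetic stand-in, plus
  `command_score_model()` so any external predictor speaking a
  line protocol can be plugged in unchanged.

## Sequence analytics

Charge assignment is the Das–Pappu convention at pH 7: K/R = +1, D/E = −1,
histidine and cysteine neutral (configurable).

* **FCR** — fraction of D, E, K, R.
* **NCPR profile** — sliding-window mean charge, truncated windows at the
  termini.
* **κ (kappa)** — for blob sizes 5 and 6, the mean squared deviation of
  windowed charge asymmetry `σ = (f⁺−f⁻)²/(f⁺+f⁻)` from the whole-sequence
  value, normalized by the same quantity for the maximally segregated
  arrangement of the identical composition, averaged over blob sizes.
  Finding that arrangement needed care: the textbook construction —
  (+ block)(neutrals)(− block) at the sequence ends — is *not* maximal for
  sparsely charged sequences, because an interior charge block overlaps
  more windows than one flush against a terminus, so normalizing by the
  ends-only construction can push κ above 1. The true maximizer keeps each
  charge type contiguous with neutral buffers, `0^a (+)^p 0^b (−)^m 0^c`,
  and only buffer widths up to g−1 change the window-overlap profile, so
  the implementation enumerates that small family exactly (the ends
  construction is its a = c = 0 member). The fully charge-segregated
  50-mer still scores exactly 1, exhaustive enumeration of all charge
  placements at n ≤ 12 confirms maximality, and κ stays in \[0, 1\]
  wherever defined. Sequences with no charges, or where δ_max is zero,
  return `NA` (undefined) rather than a misleading number.
* **SHD** — `(1/N) Σ_{i<j} (h_i+h_j)/(j−i)` with Kyte–Doolittle
  hydropathies rescaled to \[0, 1\]; the scale is a named, swappable table.
* **SEG-style complexity** — mean windowed Shannon entropy (window 12,
  base 2), the "average compositional entropy over a sliding window"
  reading rather than the full Wootton–Federhen trimming algorithm.
* **Normalized Wasserstein-1** — the area between empirical CDFs divided
  by a normalizer. What normalizer the original figures used is unstated;
  the default here is the standard deviation of the reference sample,
  exposed as an argument.
* **Motif scanning** — regex patterns shipped as an editable TSV
  (`inst/extdata/motif_patterns.tsv`): classic monopartite/bipartite NLS
  patterns, a documented subset of PTM (MOD-class) site patterns, and
  RG/RGG, \[FY\]GG, SYG RNA-interaction elements. These defaults are
  approximate stand-ins for the full ELM resource lists, which are data,
  not code. Overlapping matches are counted by scanning from every
  position, since PTM sites can overlap; co-occurrence uses start-position
  distance against a 30-residue span.

## What the synthetic generators emulate — and what they do not

`synth_protein_with_plddt()` produces segment-structured traces (folded
92 ± 3, disordered 55 ± 6, 4-residue linear boundary ramps, Gaussian noise
clipped to \[0, 100\]) with ground truth, so curation can be tested as a
recovery problem. It does not emulate the long-range autocorrelation of
real AlphaFold confidence traces, nor realistic folded-domain sequence
statistics.

`synth_idr_corpus()` draws lengths log-normal (median 80 by default,
clipped to \[30, 300\], matching the bulk-below-100-with-a-tail shape of
natural IDR lengths) and residues i.i.d. from a disorder-biased
composition that encodes the direction of known biases (P, S, G, E, K up;
L, I, V, F, W, Y down) without claiming their magnitudes. A blockiness
parameter `b ∈ [0, 1]` interpolates charge placement between strictly
alternating and fully segregated, giving the metrics suite a controllable
κ dial. A deliberately skewed `low_entropy_composition()` (~2.2 nats mean
composition entropy) supports entropy-targeted RL experiments. Because
residues are i.i.d. within a sequence, these corpora contain no motif
grammar or positional structure: passing tests demonstrate the machinery
is correct at desk scale, not that a tiny model trained on them captures
real IDR biology.

## Numerical choices and degenerate inputs

* Losses are in nats; SEG complexity in bits; entropies of sequences in
  nats over the 20 canonical residues.
* LayerNorm ε = 1e-5; AdamW (β₁, β₂, ε) = (0.9, 0.999, 1e-8).
* Warmup starts at learning rate 0 (the most common convention; the origin
  is unstated in the source description).
* κ windows shorter than the sequence raise an error; empty sequences are
  rejected by every metric; an empty completion (immediate `<eos>`) is
  scored with entropy 0 in the composite reward.
* Ties in sampling cumulative sums fall back to the modal token; the
  probability of hitting this float edge is negligible but the guard keeps
  the sampler total.
* All generators and training loops consume explicitly passed seeds; mixed
  seeds stay below 2³¹.

## Known limitations

* The parameter count of the full-scale architecture is reproduced under
  documented conventions but does not equal the printed 122M (see above).
* Sequence-identity clustering (MMseqs2) and structure prediction of
  generated sequences are out of scope; the external MMseqs2 commands are
  documented in the README.
* The shipped motif patterns approximate, but are not, the ELM lists.
* Desk-scale RL runs demonstrate convergence of the shaping terms (length,
  entropy); they say nothing about the biology of any particular reward
  model.
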