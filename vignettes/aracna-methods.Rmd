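---
title: "Copy number calling with a simulation-trained sequence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number calling with a simulation-trained sequence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model the package implements, the assumptions
behind its simulator, the tunable parameters and the numerical choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The generative model

A tumour sample is a mixture of tumour cells (purity $\rho \in [0,1]$) and
normal cells assumed diploid at every locus; germline copy number variants
in the normal compartment are ignored as negligible against somatic
alterations. With per-copy read yield $r_d$, parental copy numbers
$(C_{P,i}, C_{M,i})$ and B-allele indicators $(s_{p,i}, s_{m,i})$, the
observed per-SNP read depth and B-allele frequency (BAF) have expectations

$$C^s_{T,i} = \rho C_{T,i} + 2(1-\rho), \qquad
  C^s_{B,i} = s_{p,i}\left[(1-\rho) + \rho C_{P,i}\right] +
              s_{m,i}\left[(1-\rho) + \rho C_{M,i}\right],$$
$$\mathbb E[R_i] = r_d\, C^s_{T,i}, \qquad
  \mathbb E[B_i] = C^s_{B,i} / C^s_{T,i}.$$

Swapping the parental assignment leaves both observables unchanged, so only
the major/minor pair $(A_M, A_m)$ is identifiable, and the caller's label
space is the catalogue of pairs with $A_M \ge A_m \ge 0$,
$A_M + A_m \le T_\max$ (`enumerate_profiles()`), ordered by ascending total
then ascending minor copy number so that class indices are stable across
checkpoints. Where $C^s_T = 0$ (homozygous deletion in a pure sample) the
expected BAF is emitted as missing: zero reads carry no allelic signal, and
downstream metrics skip missing loci.

A deeper degeneracy remains: at $\rho = 1$, doubling every copy number
while halving $r_d$ reproduces the data exactly, and a genome that is
(1,1) everywhere carries *no* purity information at all (depth is
$2 r_d$ and het BAF is $1/2$ for every $\rho$). Both facts shape the
simulator bias and the interpretation of purity errors below.

## The simulator

Training genomes are drawn per the generative procedure: a segment count
from a mixture (probability $q_s = 0.3$ of a uniform draw on
$\{1..N\}$, $N = 250$; otherwise a Poisson with rate 15 truncated to the
same support, oversampling the few-segment genomes whose global parameters
are hardest to infer); breakpoints uniform on the genome, deduplicated,
with segments shorter than $L_\min = 25$ loci merged into their left
neighbour; segment profiles drawn with weight
$\exp(-\alpha [|A_M - 1| + |A_m - 1|])$, $\alpha = 1.5/(1 + N_s/20)$, which
realises the low-ploidy preference that resolves non-identifiable genomes;
haplotype indicators as fair coins, with runs of homozygosity (IBD regions,
probability 0.2 per genome, up to 3 regions) forcing $s_p = s_m$; purity
uniform on $(0.5, 1)$ and $r_d$ uniform on $(5, 70)$.

Observation noise: reads are Poisson with a per-locus lognormal rate
modulation ($\sigma \sim U(0, 0.15)$ per genome), matching the
overdispersion of WGS coverage; BAF is a binomial draw of B-allele reads
out of the sampled total plus Gaussian jitter ($\sigma \sim U(0, 0.02)$),
clipped to $[0,1]$. The exact noise law of real pipelines is not public, so
these forms and ranges are this package's surrogate, exposed in
`noise_config()`. Constants never stated for the procedure ($N$, $q_s$,
the Poisson rate, $L_\min$, the IBD geometry) are package defaults chosen
at realistic magnitudes and are all configurable; the IBD length range
defaults to $U(\min(500, 0.01L), 0.05L)$ loci so it degrades gracefully at
desk-scale $L$.

What the simulator does *not* emulate: GC/mappability waves, FFPE
artefacts, subclonal mixtures, sex chromosomes, and real SNP spacing.
Passing tests on simulations therefore demonstrate correct inversion of
the stated generative model, not performance on real tumours.

## The sequence model

The caller $f_\theta(\{R_i, B_i\}) \to (\{p_{k,i}\}, \hat\rho)$ is a
sequence-labelling network:

* **Inputs.** Depth channel $\log(1+R_i)/4$ (or the log ratio $l_r$ in the
  logR variant), BAF with missing values imputed at $1/2$ plus an explicit
  missing indicator, and a folded-BAF channel $|B_i - 1/2|$ — the
  heterozygous band offset, which carries the purity signal directly. A
  global placeholder element with all-zero features and token flag 1 is
  appended; the purity estimate is read off its final hidden state.
* **Encoder.** Two-layer perceptron (ReLU) into dimension $d$, summed with
  a learned two-entry token embedding.
* **Backbone.** $n$ bidirectional blocks. Each block layer-normalises,
  projects, and runs a causal multi-scale gated linear recurrence
  $s_t = a \odot s_{t-1} + (1-a) \odot u_t$ (a diagonal state-space
  operator; decay logits initialised from $-1$ to $8$ so channels span
  local to near-global time scales) forward, and a second one over the
  reversed sequence; the two output projections are combined by elementwise
  sum with a residual connection, followed by a positionwise feed-forward
  sublayer. Every output position depends on every input position and
  compute is linear in $L$. The operator interface is pluggable
  (`register_backbone()`) so selective-state-space or implicit-convolution
  kernels can stand behind the same contract; the shipped reference
  operator is what a single CPU trains in minutes.
* **Decoder.** Positionwise MLP + softmax over the $J$ classes at the data
  positions; MLP + sigmoid at the global position for $\hat\rho$.

Training minimises
$\mathcal L = \mathcal L_{ss} + \lambda_r |r_d - \hat r_d| +
\lambda_\rho |\rho - \hat\rho|$, where $\mathcal L_{ss}$ is the mean
cross entropy and $\hat r_d = \mu_{\text{robust}}(R)/\hat\Phi^s$ with
$\hat\Phi^s$ the expected sample ploidy under the output distribution —
probability-weighted during training so the estimator is differentiable
through both $p$ and $\hat\rho$; at inference the smoothed hard states are
used instead. The logR variant replaces the $r_d$ term with
$|\Phi^s - \hat\Phi^s|$, which ties the purity estimate to the output copy
numbers when no absolute read scale exists. Log probabilities are clamped
at $10^{-12}$.

All gradients are hand-derived reverse-mode expressions (the recurrence
adjoint runs the decay backwards), verified against central finite
differences to $10^{-4}$ relative error in the test suite. The reported
loss keeps the reference weights $\lambda_r = \lambda_\rho = 1$; the
*optimiser* defaults to $\lambda_r = 0.1$ because the absolute depth error
is on the scale of tens of reads and otherwise swamps the cross entropy at
desk scale (the desk recipe also uses $\lambda_\rho = 2$). Optimisation is
Adam (learning rate $10^{-3}$, linear decay to 10%, global gradient-norm
clip 1.0), streaming freshly simulated genomes so no fixed dataset is ever
reused, with early stopping on 8 fixed held-out genomes (improvement
$< 10^{-3}$ for 10 evaluations, evaluated every 40 steps) and
best-checkpoint return.

## Curriculum

Training starts on an easy sub-distribution and complexity is staged, so
each stage warm-starts in a basin the previous one found: (1) pure ($\rho = 1$), noiseless,
$T_\max = 2$ — the four classes $(0,0), (1,0), (1,1), (2,0)$; (2) purity
and noise sampling switched on; (3) $T_\max$ raised stepwise to 8;
(4) length raised by doubling to 650{,}000. That is the full-scale
schedule (`default_curriculum(desk_scale = FALSE)`); the desk-scale
schedule keeps the same shape with $L: 2000 \to 8000$ and
$T_\max: 2 \to 4$, which is what the tests and the acceptance script train
(stages 1–2, 400 and 600 steps, batch 4, $d = 32$, 2 blocks — a few
minutes each on one CPU). Each stage warm-starts from the previous best
parameters; `fine_tune_logr()` continues from a reads-mode checkpoint with
the depth channel swapped for $l_{r,i} = \log(t_{r,i}/\mu_{\text{robust}}(t_r))$,
$t_{r,i} = R_i/(2 r_d^n)$, with 5% two-sided trimming.

## Smoothing

Given output probabilities, the called sequence minimises
$-\sum_i \log p_{S_i,i} + \lambda_t \#\{i : S_i \ne S_{i+1}\}$ by forward
dynamic programming with backtracking (exact, verified against exhaustive
enumeration on small problems). Ties break toward the lowest state index,
consistent with the low-ploidy bias. Smoothing runs per chromosome —
segments cannot biologically span chromosome boundaries. $\lambda_t = 500$
is the full-scale default (~650k loci). The penalty buys constancy against
accumulated per-locus evidence, which scales with the loci per segment, so
a genome at desk length $L$ warrants $\lambda_t = 500\,L/650000$
(`desk_lambda_t()`; $\approx 1.5$ at $L = 2000$) — using 500 at desk scale
erases real short segments.

## Numerical and degenerate-input choices

* Trimming drops $\lfloor f n \rfloor$ values per tail (reproducible
  integer rule; no interpolation).
* BAF at zero sample copy number is missing end to end (simulator, model
  features via the missing channel, metrics).
* A genome drawing the (0,0) profile for *every* segment is redrawn —
  fully deleted genomes are impossible and break logR normalisation.
* The BAF reconstruction error selects the haplotype *minimising the
  residual* $|B_i - \hat B_i|$ over $(s_1, s_2) \in \{0,1\}^2$ — the most
  probable haplotype — not the smallest reconstructed value.
* The multiclonal (Battenberg-style) reconstruction mixes both clones'
  copy numbers with the clonal fraction $\tau$ symmetrically in both
  haplotype terms, so $\tau \equiv 1$ collapses bitwise to the
  single-clone formulas.
* The whole-genome duplication flag is `major CN >= 2 over > 50% of loci`
  (configurable); the output is standard but no printed definition exists,
  so common practice is followed.
* Encoder bias initialised at 0.01 so the all-zero global-token features
  do not sit exactly on the ReLU kink.

## Known limitations

Desk-scale models ($T_\max \le 4$, $L \le 8000$) are demonstrations of the
method, not production callers: they have not seen high-amplification
states, real noise structure, or genome-scale context. Purity has an
irreducible error component on near-diploid genomes where it is
structurally non-identifiable; aggregate purity error over random
simulated genomes includes those cases. The logR variant assumes the
upstream pipeline has already corrected GC and mappability. Sex
chromosomes and subclonal calling are out of scope; subclones appear only
in the evaluation module's reconstruction of external multiclonal calls.
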