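---
title: "Phenotypic plasticity of digital organisms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic plasticity of digital organisms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiplast)
```

## The system

A digital organism is a self-replicating program: a circular genome of
instructions over a 26-letter alphabet, executed by a virtual CPU with three
32-bit registers (AX, BX, CX), two stacks, two input buffers, and four heads
(instruction pointer, read, write, flow) addressing memory modularly. To
reproduce, the organism must allocate an offspring region, copy its genome
instruction by instruction (`h-copy`), and divide off the copied region
(`h-divide`). The *transcriptome* of one gestation is the ordered sequence of
(position, instruction) pairs actually executed between birth and successful
division.

The *phenotype* is the subset of nine Boolean logic operations (NOT, NAND,
AND, OR_N, OR, AND_N, NOR, XOR, EQU) the organism performs on
environment-supplied 32-bit words. Every `input-output` execution emits the
BX register and the emitted word is compared — bit-for-bit over the full
32-bit width — against each operation applied to the two words currently held
in the input buffers (NOT against each buffer individually; the asymmetric
OR_N and AND_N in either argument orientation). With nine operations there
are $2^9 = 512$ possible phenotypes, encoded as a 9-bit integer (bit order
NOT=0 … EQU=8).

An *environment* is a deterministic stream of uniformly distributed 32-bit
words, keyed by `(master_seed, env_id)` through a counter-based splitmix64
construction: the $n$-th word is addressable directly and streams are
identical across platforms and runs. Identical genomes in identical
environments always produce bitwise-identical gestations.

## Two mechanisms for plasticity

A genome may encode different phenotypes in different environments through
two routes:

* **Non-genetic**: the executed instruction sequence is identical in every
  environment, but the input words differ, so the emitted words — and hence
  the matched operations — differ. This corresponds to a *robust*
  transcriptome.
* **Genetic-based**: four *regulatory* instructions (`if-less`, `if-n-equ`,
  `jump-head`, `set-flow`) make control flow depend on register contents and
  therefore on the environment. When one of them executes, different
  environments may execute different instruction sequences — a *sensitive*
  transcriptome — which can change the phenotype, lengthen the gestation, or
  trap the organism in an endless loop (a viability cost).

This dichotomy is exact in the implementation: control flow depends on
register contents only through those four instructions, so a gestation whose
trace contains none of them executes the identical step sequence in every
environment, with identical viability (the robustness property, tested over
100 environments).

Profiling a genome across an environment set counts, over the environments
where it is viable, the distinct phenotypes ($>1$: *plastic*) and distinct
transcriptomes ($>1$: *sensitive*), giving the four quadrants
non-plastic/robust, non-plastic/sensitive (canalization through changed
transcription), plastic/robust (non-genetic mechanism) and plastic/sensitive
(genetic mechanism). *Phenotypic uncertainty* is the mean over the nine
operations of the binary Shannon entropy of the per-operation frequency
across viable environments; it lies in $[0,1]$, with 0 for a constant
phenotype. This aggregation (mean of per-operation binary entropies) is one
admissible reading of an entropy on the phenotype repertoire; the
quasi-binomial model downstream only requires a response in $[0,1]$.

## Execution semantics that had to be pinned

The alphabet is the canonical 26-instruction "heads" set
(`instruction_set()`). Choices the genome-level descriptions leave open are
fixed as follows; each is a deliberate, documented decision:

* **Words and arithmetic.** All values are unsigned 32-bit; `add`, `sub`,
  `inc`, `dec` wrap modulo $2^{32}$; shifts fill with zero; comparisons
  (`if-less`) are two's-complement signed; `nand` is bitwise on raw bits.
* **Nop modifiers.** A nop immediately following an instruction selects its
  register operand (nop-A→AX, nop-B→BX, nop-C→CX) or head operand
  (nop-A→IP, nop-B→read, nop-C→write); the default operand is BX (IP for
  head operations); the complement register of AX/BX/CX is BX/CX/AX. Modifier
  nops are consumed: they cost no cycle and do not appear in the trace, so
  exactly one instruction effect is applied per cycle.
* **Control flow.** `if-less`/`if-n-equ` execute the next instruction iff
  the condition holds, else skip it (skipping costs no cycle). `jump-head`
  moves the instruction pointer by the value of CX (mod memory length) and
  the normal post-instruction advance still applies. `mov-head` places the
  addressed head at the flow-head; when that head is the instruction
  pointer, the post-advance is suppressed so execution resumes exactly at
  the flow-head (this is what makes compact copy loops work). `h-search`
  with no nop label sets the flow-head to the next position and BX=CX=0;
  with a label it finds the complement label and sets the flow-head just
  past it, BX to the distance, CX to the label length. `if-label` compares
  the most recently copied instructions against the complement of its label.
* **Memory.** `h-alloc` extends memory once by the parent genome length,
  filled with nop-A; registers are untouched. `h-divide` succeeds only if at
  least one `h-copy` has executed, the offspring region (read-head to
  write-head, circular) is at least `min_offspring_length` (default 10)
  long, and at least `require_copied_fraction` (default 0.5) of its
  positions were written by `h-copy`. A successful divide ends the
  gestation.
* **Initial state.** All heads at position 0; AX = CX = 0; BX, input-1 and
  input-2 pre-loaded with words 0, 1, 2 of the environment stream (so
  two-input operations are checkable from the first `input-output`); the
  next consumed word is word 3.
* **Budget.** `max_cycles` defaults to 20000 for 100-instruction genomes —
  an order of magnitude above typical gestation lengths — so truncation only
  catches genuine endless loops. Viability requires producing an offspring
  able to self-replicate: the offspring must equal the parent
  (short-circuit) or itself divide in one further gestation; recursion stops
  there.

Two structural consequences are worth noting. First, a genome rotation
relabels absolute positions, so trace isomorphism under rotation holds
exactly for the instruction subset that never moves absolute positions
through registers (everything except `get-head`, `set-flow`, `h-alloc`);
the property test uses exactly that subset, with a `start` offset standing
in for the rotation. Second, because modifier nops are consumed, a nop
*after* a payload block would silently re-target the block's last
instruction — the generator guards blocks with a neutral `swap-stk`.

## The synthetic genome generator

The original study profiled 512,000 genomes sampled from genotype space
stratified by all 512 phenotypes; reproducing that database is out of scope
here. The generator instead emulates its *structural* properties: viable
100-instruction self-replicators whose payload composition controls which
plasticity mechanisms are present.

Every genome carries a fixed copy scaffold — allocate, label search,
`mov-head` to position the write-head at the offspring region, an `h-copy`
loop with a label-terminated exit, divide — verified viable at construction
time in the reference environment. Payload is inserted in the padding
region (executed once per gestation) or inside the copy loop (executed once
per copied instruction). Payload is drawn as *motifs*, not isolated
letters: a regulatory instruction acting on constant registers is
deterministic, so environmental sensitivity requires first coupling a fresh
input word into the compared or jumped-by register (`y e`, `y d`, and the
strong form `y r h`, which jumps by an environment word and is the main
source of environment-dependent viability failure). The default mix
(`io = 2, math = 2, regulatory = 1`, 2–10 motifs, io-in-loop probability
0.25) yields populations spanning all four quadrants with a minority of
sensitive and cost-bearing genomes, qualitatively matching a system where
most sampled replicators are environmentally robust.

What the generator does *not* emulate: phenotype-stratified sampling (the
mix controls mechanisms, not phenotype identity), mutational variation
(copying is faithful), and the genotype-space frequencies behind the
original study's population percentages. Passing tests therefore
demonstrate the correctness of the machinery — semantics, tracing,
classification, costs, models — on populations with the right mechanism
spectrum, not the original database's headline proportions. One quadrant
deserves a caveat: plastic/robust phenotypes arise from rare coincidences
(e.g. an echoed word equals OR of the buffer pair only when one word's bits
subsume the other, probability $(3/4)^{32} \approx 10^{-4}$ per io
execution), so they need many io executions — io inside the copy loop — and
enough environments to be observed; exemplar fixtures record seeds where
this occurs.

## Statistical models

The per-genome and per-record tables feed the model suite
(`plasticity_models()`):

* binomial-logit for plasticity ~ transcriptome sensitivity;
* binomial-logit for viability-in-all-environments ~ plasticity, among
  sensitive-transcriptome genomes;
* zero-truncated negative binomial (log link) for the number of distinct
  phenotypes, against sensitivity and against the scaled-log number of
  distinct transcriptomes crossed with the binary viability-cost flag;
* a linear model for transcriptome length ~ plasticity × sensitivity on
  genome × environment records;
* poisson-log for `input-output` executions inside tandem repeats;
* quasi-binomial-logit for phenotypic uncertainty ~ sensitivity.

Binomial, poisson and quasi-binomial fits use `stats::glm` (iteratively
reweighted least squares, convergence `1e-8`, 100 iterations);
non-convergence and boundary fits are flagged, never silently returned.
Reference levels are robust transcriptome, single phenotype, and no cost, so
coefficient signs are directly comparable across fits. The scaled-log
covariate is `log` then z-scoring with the sample standard deviation, so the
output has mean 0 and s.d. 1 exactly.

The zero-truncated negative binomial is fitted in the package: the NB
likelihood with untruncated mean $\mu = e^{X\beta}$ and size $\theta$ is
renormalized by $1 - P(0)$, $P(0) = (\theta/(\theta+\mu))^\theta$, and the
exact truncated log-likelihood is maximized jointly over
$(\beta, \log\theta)$ by BFGS with analytic gradients, initialized from a
Poisson fit. Wald covariance comes from the observed information of the
joint problem. A fit with all counts equal to 1 sits on the boundary
($\theta$ unidentified) and is diagnosed rather than returned as converged.
In the $\theta \to \infty$ limit the fit approaches a zero-truncated
Poisson, and on simulated data the estimates agree with an independent
truncated-NB implementation to four decimals; both are exercised in the
test suite.

Coefficients live on the link scale; results are reported on the natural
scale via the inverse links $1/(1+e^{-\beta})$ and $e^{\beta}$
(`inverse_logit`, `inverse_log`). The package ships the link-scale
coefficient table of a published large-scale analysis
(`reference_estimates()`) and recomputes its back-transformed summary
quantities analytically (`reference_quantities()`); `scripts/acceptance.R`
writes these alongside summaries of a fresh pipeline run.

## Tandem repeats

A finite execution loop leaves a periodic run in the executed-position
sequence. The detector reports maximal leftmost runs of at least two full
copies of a period-$p$ block, non-overlapping, choosing at each start the
run with the largest full-period coverage and breaking ties by the smallest
period (making the output unique); partial trailing periods are not
counted. `io_in_repeats` counts `input-output` steps inside reported runs;
it is computed for viable gestations (truncated endless-loop traces are
never used downstream). The detector is verified against a brute-force
block-comparison scan on traces up to 200 steps.

## Problem sizes and numerical choices in the tests

The suite and the acceptance script run at desk scale, chosen so the whole
battery completes in well under a minute: populations of 15–120 genomes,
environment sets of 10–100, the robustness property over 100 environments,
oracle checks over $10^4$ random word pairs per operation, logistic
recovery at $n = 20{,}000$ and zero-truncated NB recovery at $n = 10{,}000$
(both within 3 standard errors under fixed seeds), and a full pipeline run
of 120 genomes × 40 environments. Determinism is asserted byte-for-byte on
the pipeline artifacts.

## Known limitations

* No population dynamics: no scheduler, merit, mutation, births/deaths, or
  selection — single-gestation analysis only, by design.
* Operation checking uses the two current buffer words; implementations
  that credit operations computed against a deeper input history would
  classify a few more outputs as operations.
* The generator's quadrant frequencies are properties of its motif mix, not
  estimates of any natural genotype space; population-level percentages
  from the original database are not reproduced and not targeted.
* The execution budget, divide-validity thresholds and initial-state
  conventions are explicit knobs; alternative conventions would change
  individual traces while preserving the mechanism dichotomy the analysis
  rests on.
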