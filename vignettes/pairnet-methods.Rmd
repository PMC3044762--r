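---
title: "Stimulus-pair selectivity in plastic spiking networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-pair selectivity in plastic spiking networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pairnet)
```

# The problem

In a biconditional (XOR) discrimination, two of four stimuli (A, B, C,
D) are shown together and the required response depends on the specific
pairing: A+B and C+D demand one response (Release), A+D and C+B the
other (Hold). No single-stimulus response can solve this task — a cell
firing at rate $r_A$ whenever A is present responds equally strongly to
the A+B and A+D pairings. Solving the task requires neurons selective
for *conjunctions* of stimuli, and `pairnet` asks which synaptic
plasticity rules can carve such stimulus-pair selectivity out of an
initially random recurrent network, and whether the resulting code
suffices to drive a rewarded winner-take-all (WTA) decision.

# The network model

## Associative layer

The associative layer is a random recurrent network of 400 leaky
integrate-and-fire neurons (320 excitatory, 80 inhibitory). Membrane
parameters are heterogeneous, drawn per cell from uniform distributions:
leak reversal $V_L = -70 \pm 2.5$ mV, membrane time constant
$\tau_m = 10 \pm 0.75$ ms, leak conductance $g_L = 35 \pm 1$ µS (40 or
50 µS in the high-threshold regimes), firing threshold
$V_{th} = -50 \pm 2$ mV, refractory time constant $2 \pm 0.25$ ms
(excitatory) or $1 \pm 0.25$ ms (inhibitory).

Connectivity is random and fixed throughout training:

* excitatory→excitatory: sparse random, probability 10%;
* inhibitory→excitatory: random, probability 25%;
* inhibitory→inhibitory: all-to-all;
* excitatory→inhibitory: absent (inhibition is feedforward only),
  except in the recurrent-inhibition regime (probability 25%, fixed
  strength).

Initial weights are uniform within ±50% of the mean $W_0 = 0.05$, and
the effective mean scales as $W_0 \cdot 400/n$ so that total recurrent
drive is invariant when the network is scaled down.

Synapses are conductance-based: AMPA (reversal 0 mV, decay 2 ms), NMDA
(0 mV, 100 ms) with the standard magnesium gate
$s(V) = 1/(1 + [\mathrm{Mg}]e^{-0.062V}/3.57)$, $[\mathrm{Mg}] = 1$ mM,
and GABA$_A$ (−70 mV, 10 ms). There is no hard voltage reset: each
spike increments a refractory conductance (reversal −70 mV) that
repolarizes the cell, and the spike threshold is dynamic — it jumps per
spike and relaxes exponentially to its base, with a hard ceiling at
150 mV. A configurable hard-reset mode exists and is used by the
analytic interspike-interval tests.

## Inputs

Each stimulus is represented by $G \in \{2, 4, 6, 10, 20\}$ independent
Poisson input groups firing at $480/G$ Hz, so an active stimulus always
delivers 480 Hz in total; fewer groups mean more strongly correlated
input. Each group projects independently to excitatory and inhibitory
cells with probability
$p \in \{1/2, 1/3, 1/5, 1/10, 1/20\}$. The 5 × 5 product of these two
axes defines the 25-network grid explored per regime
(`grid_configs()`). A trial is 500 ms of relaxation with inputs off
followed by a 1 s cue.

## Conductance scale and noise (calibrated constants)

The printed parameter set is not dimensionally closed: a synaptic
weight jump of $W_0 = 0.05$ µS against a 35 µS leak could never drive
spiking, and the printed per-spike refractory increment (0.002 µS)
could never repolarize a cell without a hard reset. The package
therefore separates *weights* (kept in the printed $W_0$ units, with
all printed bounds applied to them) from *conductance*, through two
gain constants in `kinetics_config()`:

* `g_unit = 220` µS of conductance per unit weight, and
* `gref_gain = 5e5` multiplying the printed refractory increment
  (effective jump 1000 µS, decaying with the per-cell refractory time
  constant).

Two further constants close the model: `nmda_frac = 0.15` (the NMDA
jump relative to the AMPA jump — with equal jumps the 100 ms NMDA tail
makes recurrent activity bistable rather than graded) and the
dynamic-threshold setting (+10 mV per spike, relaxing with
$\tau = 200$ ms). With purely feedforward inhibition the recurrent
excitatory loop has gain above one, and this slow threshold adaptation
is the mechanism that bounds network rates; the chosen values place the
dense standard network (6 groups, $p = 1/3$) in the high
initial-activity regime (tens of hertz, asserted by the test suite)
while the sparsest networks ($p = 1/20$) stay below 3 Hz (recomputed by
the acceptance script).

Noise enters as (i) Gaussian voltage noise (amplitude 0.5 mV·ms^−1/2^,
Euler–Maruyama $\sqrt{dt}$ scaling) in the associative layer and (ii)
uniform $[0,1]$ conductance noise (amplitude 1 µS) added to the AMPA
and GABA$_A$ conductances each step. The decision layer receives
conductance noise only. All four amplitudes are free parameters of the
model (the source text gives no numbers for them); they were fixed once
against the activity-regime targets above and are exposed in
`noise_config()`.

# Plasticity rules

All rules share the printed bounds: per-trial changes capped at ±50% of
the trial-start weight, global bounds $[0, 20W_0]$, enforced at every
update (`enforce_bounds()`).

**Pair STDP** (`pair_stdp_config()`): all-to-all exponential windows,
$\Delta W = dW \cdot A^+ e^{-\Delta t/\tau^+}$ for post-after-pre and
$-dW \cdot A^- e^{-|\Delta t|/\tau^-}$ for post-before-pre, with
$A^+ = 1.20$, $A^- = 0.80$, $\tau^+ = 16$ ms, $\tau^- = 25$ ms,
$dW = 0.005$. Simultaneous spikes produce no change. The per-event
scale $dW$ multiplies the windowed amplitudes, keeping $A^\pm$
meaningful as the LTP/LTD asymmetry.

**Triplet STDP** (`triplet_stdp_config()`): the all-to-all trace
formulation with fast pairing traces
($\tau_{2+} = 16.68$, $\tau_{2-} = 33.7$ ms) and slow triplet traces
($\tau_x = 101$, $\tau_y = 125$ ms); amplitudes are the full-model
all-to-all cortical set ($A_{2+} = 5\times10^{-10}$,
$A_{2-} = 7\times10^{-3}$, $A_{3+} = 6.2\times10^{-3}$,
$A_{3-} = 2.3\times10^{-4}$), scaled by $dW = 0.005$. For independent
Poisson trains at matched rate $r$ the expected drift is

$$\dot W = dW\, r^2\left[\tau_{2+}(A_{2+} + A_{3+} r \tau_y)
  - \tau_{2-}(A_{2-} + A_{3-} r \tau_x)\right],$$

which changes sign at 19.4 Hz with these constants
(`triplet_crossover_rate()`), matching the printed 20 Hz LTD→LTP
threshold. `simulate_triplet_drift()` is the event-driven Monte-Carlo
counterpart used as an independent cross-check.

**LTPi** (`ltpi_config()`): each inhibitory spike potentiates the
inhibitory→excitatory synapse by $idW = 0.005$ *unless* the
postsynaptic excitatory cell spikes within ±20 ms (the veto) or its
voltage at the inhibitory spike time is at or below the depolarization
threshold (−65 mV by default; sweepable including no threshold). The
rule never depresses. The veto uses the instantaneous voltage at the
inhibitory spike time, and spikes during the relaxation window can veto
cue-edge events. The hard upper bound equals the global $20W_0$ bound.

**Homeostasis** (`homeostasis_config()`): once per trial,
multiplicative postsynaptic scaling pushes each excitatory cell's
cue-window rate toward its goal rate: excitatory synapses scale by
$1 + \epsilon(r_{goal} - r)$ with $\epsilon = 10^{-4}$, inhibitory
synapses onto the cell by $1 + \epsilon(r - r_{goal})$ with
$\epsilon = 10^{-2}$. Goal rates are 8 Hz (4 Hz in the low-goal
regime) with a +5 Hz uniform per-cell spread. Inhibitory→inhibitory
synapses are not plastic and receive no scaling; the printed
inhibitory goal rate is retained for diagnostics only.

# Decision layer

Two pools (Release, Hold) of 200 excitatory + 50 inhibitory cells with
homogeneous parameters. Within-pool E→E, E→I and I→I connections are
all-to-all at $W_0 = 0.25$; inhibition onto excitatory cells is purely
cross-pool (each inhibitory pool projects to the opposing excitatory
pool), which is what generates the winner-take-all competition. All
associative excitatory cells project all-to-all to both excitatory
pools at $DW_0 = 0.075$ (0.125 when testing untrained networks at the
sparse probabilities 1/10 and 1/20). A linear urgency conductance ramps
from 0 at cue onset to 5 µS at cue end on all excitatory cells,
guaranteeing a decision every trial.

The decision layer runs on its own conductance scale
(`decision_opts()`): `g_unit = 1.2`, NMDA fraction 1.5 (slow
recurrence, so the pools integrate evidence before committing), a
weaker refractory gain (5 × 10^4^) and milder threshold adaptation
(+2 mV, 50 ms) than the associative layer — strong per-cell adaptation
was found to stabilize the symmetric co-active state and abolish the
competition. The winner is the pool with the higher mean excitatory
rate over the final 100 ms of the cue (exact ties resolved at random);
winning-pool rates saturate high and only the readout sign is used.

**Reward rule** (`reward_rule_config()`): after each trial, afferents
from coactive associative cells (cue rate ≥ 1 Hz) onto the *winning*
pool change by $\eta \cdot DA \cdot r_j$, with $DA = +1$ on rewarded
(correct) and $-1$ on unrewarded trials; losing-pool afferents are
untouched and weights stay in $[0, 20DW_0]$. The default learning rate
is $\eta = 5\times10^{-4}$: with rate-proportional eligibility at
~20 Hz presynaptic rates, larger values saturate the afferents within
tens of trials after which discrimination degrades, while $5\times
10^{-4}$ converges to ceiling and stays there in the surrogate-input
harness. Rate-proportional eligibility is the default; a binary
variant is available.

# Protocol

`train_network()` interleaves, per trial: input generation → the
associative trial with the condition's hooks (plasticity during the
cue only) → the decision trial on the associative spikes → the reward
update → homeostasis → bound enforcement → logging. The six conditions
are `initial` (no associative plasticity), `pair_stdp`,
`triplet_stdp`, `ltpi`, and the two LTPi combinations; homeostasis is
on during training and off in the `initial` condition. When untrained
("initial") decision performance is measured, reward plasticity on the
afferents remains active while associative weights are frozen — that
is how a random network's decision capacity is assessed.

Trial order is balanced pseudorandom blocks of four (one trial per
pair per block, shuffled), preventing long runs of one pair from
biasing homeostasis. Selectivity is probed with frozen-plasticity
blocks (5 trials per pair by default) before training, every 40 trials
(configurable; `probe_every = NA` probes only at the start and end),
and after the last trial; the trial-resolved selectivity curve uses
these probe blocks rather than running averages.

# Metrics

For per-cell cue rates $r_{i,1..4}$ over the four pairs, stimulus-pair
selectivity is $s_i = (\max_k r_{ik} - \bar r_i)/\bar r_i \in [0, 3]$
(0 for uniform responders, 1 for linear single-stimulus cells, 3 for
single-pair responders); silent cells score 0, consistent with
all-cell network means being lower in sparse networks. The network
value is the mean over all excitatory cells; the active-only variant
(mean rate ≥ 0.5 Hz, configurable) reproduces the alternative reported
summary. Decision performance is binned in 40-trial blocks and
classified reliable (≥ 85%), borderline (76–84%) or unreliable
(≤ 75%); selectivity changes beyond ±5% of the initial value classify
a network as improved/worsened. `group_weight_matrix()` averages
weight changes between groups of cells labelled by their post-training
preferred pair (argmax, ties to the lowest index) and exposes
cross-inhibition in its diagonal-subtracted form.
`cross_correlogram()` uses 2 ms bins over a ±50 ms window by default
(a figure-level choice). The selectivity–performance relation is
summarized by nonlinear least squares on
$y = 50 + 50/(1 + e^{-(x - x_0)/\delta})$.

# Numerics and problem sizes

Integration is Euler–Maruyama; the full-scale step is $dt = 0.02$ ms.
The desk-scale defaults used by the test-suite and the acceptance
script are 200-neuron networks (400 for the initial-rate checks),
$dt = 0.05$ ms, and 200-trial training runs — a halving-dt check keeps
noise-free spike counts within one spike per neuron, and weights scale
by $400/n$. The trial loop is compiled (Rcpp) with an internal
xoroshiro128+ generator seeded from the R-level seed; one master seed
derives independent child seeds per randomness source
(`child_seed()`), so structure, parameters, inputs and noise are each
reproducible in isolation. Spike propagation has zero delay
(same-step delivery). Full-paper scale — 25-network grids × 6
conditions × 800 trials × ≥4 instantiations — is reachable through
`run_condition_grid()` but is a cluster-scale computation and is not
run by the desk-scale suite; the suite substitutes the module-level
property and oracle-equivalence checks.

# What the generator does and does not emulate

The synthetic networks reproduce the stated connectivity statistics,
parameter heterogeneity, Poisson input statistics and the grid of
sparseness/correlation conditions. They do not emulate structured
(small-world or motif-based) connectivity, synaptic transmission
delays, short-term plasticity, or inhibitory long-term depression —
all outside the model. Passing tests therefore show that the
*mechanisms* (veto-gated LTPi producing cross-inhibition, the
rate-dependence of the triplet rule, reward-gated afferent learning)
behave as specified in this model class; they are not evidence about
biological cortex beyond it.

# Known limitations

* The conductance scale and noise amplitudes are calibrated constants,
  not printed values; other calibrations meeting the same activity
  targets may shift quantitative outcomes (not the rule-ordering
  properties, which are tested across seeds).
* Winning decision pools saturate at biologically high rates; the
  readout uses only the rate ordering.
* Desk-scale training runs (200 trials, reduced networks) demonstrate
  the direction and ordering of effects; full-scale grid statistics
  (e.g. counts of reliable networks) require the paper-scale runs.
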