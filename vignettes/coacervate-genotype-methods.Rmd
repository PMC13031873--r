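---
title: "Models and methods behind coacervgeno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coacervgeno}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coacervgeno)
```

# The system and the questions

Fuel-driven complex-coacervate droplets — formed from a cationic
arginine-rich peptide and poly-U RNA, sustained by an EDC reaction cycle —
can carry short single-stranded DNA 30-mers as a rudimentary genotype. Two
questions organize the analysis this package implements:

1. **Which sequences partition into the droplets?** Droplet and supernatant
   phases are separated, their DNA is sequenced, and the two pools are
   compared: base composition per position, homopolymer-run frequencies,
   and run-motif enrichment under exact tests.
2. **What do those sequences do to the droplet phenotype?** Turbidity
   traces give lifetimes, titrations give critical salt and fuel
   concentrations, FRAP gives component diffusivity, and supernatant
   depletion gives partition coefficients.

Because the deposited reads are not required for any computation here, a
first-class synthetic-data layer generates every input with known ground
truth, and all statistical machinery is validated against it.

# The per-position categorical library model

A library is a `base_profile`: an $L \times 4$ matrix of per-position
probabilities over $\{A, C, G, T\}$, each position drawn independently.
Two designs matter: the unbiased library (25% per base) and biased
libraries in which one base has probability 0.76 and the other three 0.08
each. Rows must sum to 1 within $10^{-12}$; `generate_library()` samples by
per-column inverse-CDF lookup so a seed fixes the output exactly.

# Exact homopolymer-run probabilities

The design-rule analysis needs exact probabilities of events like "a run of
at least 7 consecutive A whose maximal run starts within one base of the 5'
end or ends within one base of the 3' end, OR a run of at least 20 A
anywhere". `exact_probability()` computes these with a transfer
(automaton) dynamic program over positions. The state is:

* the base of the currently open run (restricted to bases that appear in
  some condition; everything else collapses to "other");
* the open run's length, capped at the largest `min_len` needed for that
  base (longer runs are equivalent);
* the open run's start position, capped at $d_{\max} + 2$ (only "did the
  run start within $d + 1$ of the 5' end" is ever asked);
* one satisfaction bit per condition (OR is the only combiner, so any set
  bit at the end counts).

Unanchored and start-anchored satisfaction is credited while the run is
open; end-anchored satisfaction is resolved when the maximal run closes
(the following base differs) or at the sequence end, where the run's end
position is known. *Maximal*-run semantics — a run bounded by a different
base or the sequence boundary — are used everywhere, including the pool
scanners (`count_in_pool()`, `run_frequency()`), so Monte Carlo, observed
pools and the DP judge precisely the same event. The state space is a few
hundred states, so a 30-mer evaluation takes milliseconds.

Two phrasings of "within one base of either end" are supported. The
default (`anchor_mode = "maximal"`) anchors the maximal run's own
start/end positions; the alternative (`anchor_mode = "window"`) asks for a
`min_len`-long stretch inside the terminal `min_len + d` window. For
contiguous homopolymer runs the two are in fact equivalent (a sub-run of
length `min_len` inside the terminal window forces the maximal run's start
or end into the anchor region, and conversely), and a test asserts that
equivalence on the DP; the option exists so the definition in use is
explicit rather than implicit. The default reading reproduces the printed
compliance percentages (1.4%, roughly one-third, 0.02%) analytically.
Whether the unbiased-library OR-condition also counts G runs is not
specified anywhere; the A-only reading is the default since it reproduces
the printed 0.02%.

The DP is verified against probability-weighted exhaustive enumeration of
all $4^L$ sequences for $L \in \{3, 5, 8\}$ across uniform, biased and
degenerate profiles, to $10^{-12}$. $L = 8$ (65,536 sequences) is the
largest enumeration size used; larger $L$ adds runtime but no new
structural case, since every state-machine feature (cap, start flag,
closure, OR) is already exercised at $L = 8$.

# The synthetic recruitment model

The study observes enrichments but no generative law, so the generator
adopts the minimal model that reproduces the observed signatures: each
sequence enters the droplet pool by an independent Bernoulli draw with

$$\Pr(\text{droplet}) = \operatorname{logit}^{-1}\!\big(\beta_0 +
\beta_G\, g_{\text{term}} + \beta_A\, a_{\max} + \beta_S\, s\big),$$

where $g_{\text{term}}$ is the summed 5' and 3' maximal G-run length,
$a_{\max}$ the longest A run, and $s$ the structure proxy. Positive
$\beta_G$ concentrates G excess at the termini; positive $\beta_A$ elevates
long-A-run frequencies in the droplet pool; negative $\beta_S$ depletes
self-structured sequences. With all coefficients zero the pools are
exchangeable — the basis for all type-I-error calibration. The
coefficients are free parameters of the generator, not estimates of the
physical system; the analysis stage never sees them. The default study
conditions use $n = 50{,}000$ unbiased 30-mers and
$(\beta_0, \beta_G, \beta_A) = (-4, 1, 1)$, chosen once so that the
planted signatures are unambiguous at that pool size (terminal-G excess of
tens of percentage points; A-run enrichment e-values far below the 0.05
cutoff) without being degenerate.

The structure proxy is the longest reverse-complement stem: the largest
$k$ such that some $k$-mer substring equals the reverse complement of a
disjoint substring, computed by a pairing recurrence
$H_{ij} = [\,s_i \text{ pairs } s_j\,](1 + H_{i+1,j-1})$ with the
non-crossing bound $k \le \lfloor (j - i + 1)/2 \rfloor$; values below 2
report 0. It is monotone with hairpin-forming ability and dependency-free,
but its absolute values are not comparable to thermodynamic
minimum-free-energy predictions; it stands in for folding propensity only
qualitatively, and an MFE-based score can be substituted wherever a
structure covariate enters.

# Read cleaning

`process_reads()` fixes the stage order: 3' adapter trim (first occurrence,
substitution-only matching, default one mismatch, deleting the adapter and
everything downstream; an optional anchored 5' constant region is removed
first), then polyG-tail removal, then the exact-length filter (30 nt), which
also discards reads still containing N. The composed pipeline is idempotent
and is always applied with identical parameters to both pools, so any
processing bias cancels in the comparison.

One interaction deserves care. The polyG artifact of two-color chemistry
arises *downstream* of the 3' adapter (dark cycles read as G once the
template is exhausted), so a read whose adapter was found and removed
cannot still carry a chemistry tail — but roughly one in a thousand
uniform 30-mer inserts genuinely ends in five or more G. `process_reads()`
therefore exempts adapter-trimmed reads from the polyG stage; only reads
whose adapter was *not* located (e.g. corrupted by the artifact itself) are
polyG-trimmed. This keeps the emit-then-process round trip an exact
multiset identity. Standalone `trim_polyg()` trims unconditionally.

# Enrichment statistics

Composition tables are plain counts; positional differences are reported in
percentage points. Run-motif enrichment replaces de-novo PWM discovery with
an explicit catalog of run conditions (runs of 5/7/9 of each base,
unanchored, plus terminal-anchored A and G runs of 5 and 7). For each
condition the $2 \times 2$ table (has-run × pool) gets a one-sided exact
p-value for droplet enrichment (hypergeometric tail, computed by
`stats::fisher.test`; tests verify it against a direct tail summation) and
an e-value $p \times (\text{number of conditions})$ — a Bonferroni-style
correction matching the e-value convention used with the 0.05 cutoff. The
sample odds ratio uses the Haldane–Anscombe 0.5 correction when any cell
is zero. Calibration: over 500 null-recruitment replicates the e-value
false-hit rate at 0.05 stays below $0.05 + 2\,\mathrm{SE}$ (it is far
below, as Bonferroni is conservative).

# Partitioning algebra

With total concentration $C$ and volume $V$, mean supernatant
concentration $\bar c$ and mean droplet volume $\bar v$, the amount in
droplets is $CV - \bar c\,(V - \bar v)$ (the supernatant volume is taken as
$V - \bar v$; at volume fractions near 0.5% the distinction from $V$ is
negligible but the convention is fixed), the droplet concentration follows,
and $K_P = c_{\text{drop}} / \bar c$. The standard deviation is first-order
delta-method propagation from the replicate standard deviations of
$\bar c$ and $\bar v$ with zero covariance — the two stated error sources.
A supernatant amount at or above the total flags the result and clamps
$K_P$ to 0 rather than returning a negative coefficient. Droplet volumes
come from segmented areas under a sphere assumption
($r = \sqrt{A/\pi}$, $v = \tfrac43 \pi r^3$), summed and normalized by the
spherical microreactor volume. The share of DNA in droplets is
$f = K_P\varphi / (K_P\varphi + 1 - \varphi)$; at $K_P = 11$ and $f = 5\%$
the implied $\varphi$ is $1/210 \approx 0.476\%$, and a 20-fold larger
$K_P$ at that $\varphi$ yields $f \approx 51\%$.

# Turbidity and titration analysis

Lifetime and longevity are the times at which OD600 falls below 0.12 and
0.2 after the trace maximum. Because real traces are noisy near the
threshold, the *last* downward crossing after the global maximum is used
(configurable to the first), with linear interpolation between the 30-s
samples — so recovery is accurate to well under one sampling interval on
synthetic traces. The synthetic trace model is a smooth rise–plateau–decay,
$\mathrm{OD}(t) = A\,(1 - e^{-t/\tau_r})\,\sigma((t_d - t)/w)$ with
$\sigma$ the logistic function: the observed trace shape is never
parameterized by the study, so this is a generator choice whose only role
is to provide threshold crossings with known ground truth.

Critical salt: per replicate, OLS on the titration points with OD600 >
0.12, crossing extrapolated to 0.1, averaged over replicates. Non-linear
dissolution (hard-to-dissolve aggregates) is detected by a non-negative
fitted slope *or* a measured OD600 already below 0.1 at a concentration
smaller than the extrapolated crossing (with a small relative tolerance
against floating-point grid effects); such replicates use the first
measured sub-0.1 concentration instead. The source protocol text assigns
one sentence of the salt procedure to "critical fuel"; that is treated as
a typo — the linear-fit rule belongs to salt, and critical fuel is simply
the first tabulated concentration whose turbidity exceeds 0.1 on fuel
titration. Volumetric dilution during titration is ignored, as in the
protocol.

Significance testing is the two-sided Welch's t-test for independent
samples with Welch–Satterthwaite degrees of freedom (`stats::t.test`,
`var.equal = FALSE`; tests verify against the textbook formulas). The
type-I calibration uses $10^4$ null draws of two normal samples of 10; at
very small samples ($n = 5$) the Welch approximation itself is measurably
conservative (empirical rate ≈ 0.041), which is a property of the test,
not of the implementation.

# FRAP

Double normalization
$F(t) = \frac{I_t - B_t}{N_t - B_t}\cdot\frac{N_0 - B_0}{I_0 - B_0}$
uses pre-bleach averages over all frames before the bleach frame; any frame
with reference at or below background is a hard error naming the frame.
The recovery fit is $F(t) = a(1 - e^{-bt}) + c$ by Levenberg–Marquardt
nonlinear least squares (`minpack.lm::nlsLM`) over post-bleach frames with
time re-zeroed at the first post-bleach frame (the time origin is not
specified by the protocol; this convention is fixed here). Starting values:
$c_0$ = first post-bleach value, $a_0$ = last value minus $c_0$, $b_0$
from the time to the halfway level; bounds $a, c \in [0, 1.5]$, $b > 0$.
Non-convergence returns a flagged fit with diagnostics. Then
$t_{1/2} = \ln 2 / b$ and the Soumpasis diffusion coefficient
$D = 0.224\, r^2 / t_{1/2}$ with the corrected post-bleach-frame radius
$r$ accepted as an input number (how the correction is performed upstream
of the tables is an imaging detail outside this package). The mobile
fraction is reported as $a / (1 - c)$ with plain $a$ also available.
Replicates aggregate by mean and sample standard deviation. On noiseless
synthetic traces the fit residual RMS is below $10^{-8}$ and
$(a, b, c)$ are recovered to six digits; at assay-like noise
(sd 0.02 on the normalized scale) $b$ is recovered within 10% across a
rate grid $b \in [0.05, 5]\ \mathrm{s^{-1}}$ (slow recoveries use longer
synthetic acquisitions so the plateau is observed, mirroring the longer
real acquisition used for slow species).

# Orchestration and reproducibility

`run_all()` drives generate → recruit → FASTQ → clean → enrich → run
probabilities → assays → FRAP → partition from one validated YAML
configuration (unknown keys rejected, defaults applied and echoed), writes
TSV outputs with header rows, and emits a manifest with every consumed
parameter and an md5 checksum per output. One global seed is expanded into
per-stage child seeds as $\mathrm{seed} + 104729k \bmod (2^{31}-1)$, so
any stage can be reproduced in isolation and identical configurations give
identical checksums. The numbered scripts under `analysis/` run the same
computations as a readable narrative at study scale ($n = 50{,}000$ reads;
triplicate assays); the default demo configuration uses $n = 10{,}000$ and
finishes in well under a minute.

# What the synthetic study does and does not show

The generator emulates: per-position categorical libraries, logistic
recruitment on run/structure features, adapter-flanked reads with polyG
artifacts, and noisy assay traces with known parameters. It does not
emulate sequencing errors or quality scores, amplification bias, droplet
coalescence kinetics, the EDC reaction cycle, or any sequence-dependent
physics beyond the logistic features. Passing tests therefore demonstrate
that the *analysis* is correct and calibrated — exact where exactness is
claimed, within stated tolerances where estimation is involved — not that
the recruitment model is the physical law of the real droplets. Real-read
results (overall G percentages, motif tables) require the deposited
sequencing data and are deliberately out of scope.

# Known limitations

* The structure proxy ranks hairpin propensity but is not an energy; scores
  are small integers and ties are common.
* Anchored-run semantics follow the maximal-run reading; pools scored under
  the window reading can differ for runs far longer than `min_len`.
* The enrichment catalog is fixed and run-shaped; it cannot discover motifs
  that are not homopolymer runs.
* Delta-method error propagation is first-order and assumes independent
  replicate errors; strongly skewed replicate distributions would call for
  resampling instead (the tests include such a resampling cross-check).
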