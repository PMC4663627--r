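---
title: "Discovering small-RNA duplexes enriched by p19 capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering small-RNA duplexes enriched by p19 capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaduplex)
```

## The problem

Plant cells process pre-miRNA hairpins into short duplexes: a guide strand
(the miRNA) paired with its passenger strand (the miRNA*), roughly 21 nt
each, with 2-nt overhangs at both 3′ termini. In vivo the passenger strand
is degraded quickly, so bulk small-RNA sequencing sees mostly single
strands. The tombusviral silencing-suppressor protein p19 binds double-strand
small RNA duplexes with 2-nt 3′ overhangs, size-selectively and largely
sequence-independently, which makes it a molecular hook for pulling intact
miRNA/miRNA* duplexes out of a total-RNA mixture before they decay.

`srnaduplex` implements the computational side of such an experiment:

1. collapse sequenced reads into a species/count table,
2. call candidate duplex pairs with four pairing criteria,
3. test whether a called pair sits on opposite arms of one pre-miRNA
   hairpin stem in a reference genome,
4. quantify library-level enrichment (count spectra, strand balance), and
5. estimate binding affinities (Langmuir $K_d$) and the electrolyte
   screening length that constrains field-effect sensing of the complexes.

A seeded simulator generates the whole experiment — hairpins, libraries,
capture — so each stage is testable end to end without external downloads.

## The duplex model

A duplex here is a *gapless antiparallel register* of two equal-length
strands (both written 5′→3′): position $i$ of strand A faces position
$L - v + 1 - i$ of strand B over $i = 1 \dots L - v$, where $L$ is the
strand length and $v$ the 3′-overhang length. Each facing pair is classified
Watson–Crick (A:U, G:C), wobble (G:U) or mismatch; wobble counts as
*paired*. Overhang bases are never counted as mismatches. Strands of
unequal length are rejected outright rather than aligned: the model scores
mismatches only, never insertions, because a bulged structure no longer has
the fixed geometry that p19 recognises.

The four criteria for calling a pair from a count table are:

1. read count strictly greater than 30 on **both** strands (a count of 31
   passes, 30 does not — a literal reading of "more than 30");
2. exactly 2 unpaired nt at each 3′ terminus (the register above with
   $v = 2$);
3. at most 3 mismatches ("fewer than four");
4. G:U wobble allowed as a paired state.

Positions are 1-based; mismatch positions are reported in strand-A
coordinates of the lexicographically smaller strand so output is canonical
and byte-reproducible. Self-pairing of near-palindromic species is permitted
(and flagged) by default; note a strand can never pair with itself
perfectly, because the centre position of the paired region would have to
pair with itself.

### Finding pairs without scanning all pairs

Every paired position joins a purine with a pyrimidine. Collapsing each
sequence to its R/Y skeleton, the partner of a given strand must match a
predicted R/Y pattern everywhere except at its $\le 3$ mismatch positions.
Splitting the pattern into `max_mismatches + 1` contiguous blocks therefore
guarantees (pigeonhole) that a true partner matches at least one block
exactly, so candidates come from hash lookups on block keys and are then
verified positionally. The brute-force all-pairs scan remains available
(`strategy = "brute"`) and serves as the oracle in the test suite; the two
strategies are asserted to produce identical call sets.

## Hairpin support

A called pair is biologically plausible as a miRNA/miRNA* duplex when both
reads derive from one pre-miRNA. Operationally, `hairpin_support()` requires
that some contig carries both reads on the same strand within 300 nt
(plant pre-miRNA scale), and that in the folded region spanning both reads
(plus 10-nt flanks):

* at least 60% of each read's bases are paired, and
* at least 50% of those partners fall inside the other read's interval.

The numeric thresholds are declared package defaults, not values inherited
from any reference analysis; they are configurable. Folding uses a
wobble-aware Nussinov base-pair maximisation with a minimum hairpin loop of
3 nt and a deterministic traceback (whenever pairing the 5′-most open base
attains the optimum it is paired, with its 5′-most partner). Base-pair
maximisation finds stems reliably but ignores stacking energetics, so users
can supply externally computed dot-bracket structures instead
(`read_structure_file()`); the internal folder keeps the package
self-contained and exhaustively testable (its pair counts are checked
against complete enumeration for short sequences).

Reference cleaning (`filter_by_reference()`) keeps a read only if it, or its
reverse complement, occurs *exactly* in some contig — the package's reading
of "filtering sequencing errors through the genome". Mismatched mapping is
deliberately not offered: an error-tolerant filter would defeat its purpose.

## Binding analytics

The sensor response at duplex concentration $C$ follows the Langmuir
adsorption isotherm

$$\Delta G(C) \;=\; \Delta G_{\max}\,\frac{C}{K_d + C},$$

fitted by Levenberg–Marquardt least squares with $K_d$ parameterised on the
log scale (positivity for free; standard errors mapped back by the delta
method). Two modes:

* **fixed** (default): $\Delta G_{\max}$ pinned to the mean observed
  response at $C \ge 200$ nM, the saturation convention for tight binders;
* **free**: both parameters fitted. The fit falls back to this mode
  automatically when no observation reaches the saturation threshold, and it
  is the right choice whenever $K_d$ is comparable to or larger than the
  largest design concentration (at $K_d \sim 1\,\mu M$ a 200 nM "plateau"
  is nowhere near saturation and pinning to it would bias $K_d$ low).

Starting values are deterministic — $\Delta G_{\max}$ at the maximum
response, $K_d$ at the concentration closest to half of it — so fits are
reproducible. Degenerate inputs (all-zero responses) return a diagnosable
failure object rather than an error. `relative_kd()` normalises a set of
fitted constants to a reference duplex ($K_{rel} = K_d / K_d^{ref}$).

Buffer electrostatics: `ionic_strength()` computes
$I = \tfrac12 \sum_i c_i z_i^2$ over *explicitly listed* ionic species —
speciation is not derived from pH, the user states the ions (the shipped
0.1× phosphate solution lists Na⁺ 1.76 mM, H₂PO₄⁻ 0.24 mM, HPO₄²⁻ 0.76 mM).
`debye_length()` then evaluates
$\lambda_D = \sqrt{\varepsilon_r \varepsilon_0 k_B T / (2 N_A e^2 I)}$
at 298.15 K and $\varepsilon_r = 78.5$ by default:

```{r}
I <- ionic_strength(phosphate_solution_0.1x())
c(I_mol_per_L = I, lambda_nm = debye_length(I))
```

About 6.1 nm — long enough to cover a protein–duplex complex on a nanowire
surface, whereas full-strength PBS screens below 1 nm.

## The simulator

`sim_params()` fixes the study conditions; all randomness flows from its
single seed (stage offsets 0/1/2 for hairpins, library, capture), so
identical parameters give byte-identical libraries.

* **Hairpins.** Each planted pre-miRNA is `guide + loop + star` embedded in
  a random 500-nt contig; the star arm is the reverse complement of the
  guide's first 19 nt (hence 2-nt 3′ overhangs by construction) with 0–3
  mismatch substitutions drawn from `mismatch_spectrum` (default uniform),
  and an 8–15 nt loop.
* **Input library.** Guide counts uniform on 31–500 (above the count
  criterion); star counts binomial at 5% survival — the strand asymmetry of
  in vivo degradation, under which most planted stars legitimately fall
  below the count threshold in the input. The background holds 1000
  non-pairing species (rejection-sampled against pairing with planted
  reads), 80% singletons, the remainder geometric-tailed — the shape of a
  deeply sequenced small-RNA library dominated by one-off species.
* **Capture.** p19 binds the *duplex*: the paired copies
  $\min(\text{count}_{guide}, \text{count}_{star})$ are captured with the
  Langmuir occupancy $P/(P + K_d(\text{class}))$ at an effective p19
  concentration $P = 100$ nM, with the class ladder
  $K_d = 16, 55, 227, 1138$ nM for 0–3 mismatches. Captured guide and star
  copies move together, so their captured counts are exactly equal.
  Leftover single strands and background are retained with a 1%
  non-specific probability.
* **Sequencing depth.** The eluted pool is then re-scaled deterministically
  to its own sequencing depth (default: the input library's total reads).
  This mirrors real paired-library designs, where the eluted sample is an
  independently sequenced library, not a subsample of the input reads — a
  captured star strand can carry a *higher* count in the eluted library
  than in the input. The uniform rounding preserves the exact guide/star
  balance of captured duplexes. Setting `eluted_total_reads = NA` disables
  re-scaling and leaves pure binomial thinning.

What the simulator does **not** emulate: sequencing errors and adapter
artefacts, PCR amplification bias, length heterogeneity of true Dicer
products beyond 20–24 nt, isomiR end-variability, or genomic repeats
placing one read at many loci. Passing tests on simulated data therefore
demonstrate the pipeline's correctness under ideal reads, not robustness to
platform noise — the reference-cleaning stage is where real-data noise
would be absorbed or lost.

## Numerical and design choices

* Count threshold strict (`> 30`), mismatch bound inclusive (`<= 3`).
* "Two nucleotides at the overhang" is modelled at the 3′ termini only,
  consistent with how p19 engages duplex ends; overhang length is a
  parameter of every geometry function but the four-criterion scan defaults
  to 2.
* All inputs are treated as 5′→3′; the package never auto-detects
  orientation. The shipped two-strand fixture stores the negative strand
  re-oriented to 5′→3′ alongside its printed 3′→5′ form for reference.
* Ties in the fold traceback break toward the 5′-most pairing; calls are
  canonicalised (lexicographic) so every pipeline run is byte-reproducible
  and the manifest records parameters, seed and input checksums.
* Test problem sizes: oracle-equivalence scans use 50 random tables of up
  to 200 species; fold enumeration up to length 14; Langmuir recovery uses
  200 noisy replicates per $K_d$ level; the end-to-end simulation uses 5
  hairpins over 1000 background species and 20 seeds for the enrichment
  property. These sizes make the suite exhaustive where enumeration is
  feasible and statistically stable where it is not, while keeping a full
  run in the low minutes.

## Limitations

* The scan considers equal-length strands only; duplexes between species of
  different lengths (asymmetric Dicer products) are out of scope.
* Base-pair maximisation can recruit loop or flank bases into optimal
  structures that thermodynamic folding would reject; the stem thresholds
  (0.6/0.5) absorb this in practice, and external structures are the
  escape hatch.
* The published full-scale pair counts depend on deposited libraries, a
  reference genome, and cleaning details not fully specified; the package
  ships `full_scale_recipe()` — the documented commands to reproduce that
  analysis — rather than asserting its numbers.
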