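---
title: "Methods: germline-anchored UCA inference and quantitative variant profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline-anchored UCA inference and quantitative variant profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `ablineage`. The package analyzes a single, well-characterized
antibody lineage — the Phl p 5-specific human antibody 212579, its
inferred unmutated common ancestor (UCA) and the reversion/allele-swap
variants between them — and ships synthetic-data generators so the whole
chain is testable without external downloads.

## IMGT numbering

Variable domains are numbered on the IMGT unique scheme: positions 1–128
with fixed region boundaries (FR1 1–26, CDR1 27–38, FR2 39–55, CDR2
56–65, FR3 66–104, CDR3 105–117, FR4 118–128). Numbering is *propagated*
from IMGT-gapped germline V references rather than recomputed from a
profile HMM: each codon of a rearranged sequence inherits the position of
the germline codon it aligns to, and germline gap positions are simply
absent from the product. This is the right model for the 212579 clonotype,
which carries no insertions or deletions; inputs that cannot be aligned
without indels raise an explicit error rather than being silently
repaired, because a silent repair would corrupt every downstream UCA
claim. Both `.` and `-` are accepted as gap characters (dots are the
AIRR germline-set convention, dashes appear in printed alignments) and
normalized to `.` internally.

CDR3 loops longer than the canonical 13 residues gain decimal insertion
positions between 111 and 112, added alternately starting on the 112 side
(112.1, then 111.1, then 112.2, ...), so that a 19-residue loop carries
111.1–111.3 and 112.3–112.1 in that sequential order. The total order is
… 111 < 111.1 < 111.2 < … < 112.2 < 112.1 < 112 …, implemented by mapping
111.k to 111 + k/100 and 112.k to 112 − k/100. Loops shorter than 13
remove apex positions starting on the 112 side (112, then 111, then
alternating 113, 110, 114, 109, …); this convention is declared here
because the lineage itself never exercises it. With insertion indices
capped at 13 per side, the longest representable loop is 39 residues; a
requested length of 40 is rejected as out of range.

## Germline assignment and UCA construction

Assignments are deliberately simple and fully deterministic:

- **V**: gap-free alignment anchored at the read 5′ end, allowing 3′
  germline trimming (up to 30 nt). Alleles are scored by
  `matches − 4 × mismatches` (the penalty ratio used by standard
  immunogenetics aligners); co-optimal alleles are reported as ties and
  the lexicographically smallest name is used for reconstruction, so
  ambiguity is recorded rather than hidden. An assignment whose best
  overlap still mismatches more than 20% is refused — generous for
  somatic hypermutation, but a guard against nonsense input.
- **J**: the same, anchored at the read 3′ end with 5′ trimming (up to
  15 nt).
- **D**: exact-substring search of the junction window between the V end
  and the J start, forward orientation only. The longest exact run wins if
  it reaches `min_len = 5` nt; all alleles achieving the maximal run are
  returned, because short D matches genuinely tie (the lineage itself has
  two co-reported D alleles). No mismatches are allowed inside a D match:
  mismatched short matches are statistically unreliable, and exact runs
  naturally produce the observed ties.

Every read base inside a segment alignment is *templated* (V/D/J); every
other base is *non-templated* (N). P-nucleotides are not modeled
separately — the accounting is the same two-way split used when asking
which junction bases are "not covered by the germline genes". Overlapping
segment claims are resolved V > J > D with a warning.

The UCA then follows from one assumption, stated by the lineage analysis
itself: **non-templated bases carry no mutation**. Templated positions are
reverted to germline; N positions are copied from the observed read.
Substitutions are the translated differences between the mature domain and
the UCA, expressed as `<UCA residue><IMGT position>_<chain>_<mature
residue>`. The assumption has an asymmetric consequence that the tests
assert rather than hide: a somatic mutation that lands in an N region is
invisible to the method by construction, and a mutation within the
aligners' trim reach of a segment boundary (or inside a D segment, whose
assignment is exact-match) may be reclassified as junction material. These
are intrinsic identifiability limits of junction analysis, not defects of
a particular aligner; the planted-mutation recovery experiments therefore
place mutations at templated positions beyond those zones (31 nt from any
block boundary, outside D, and away from allele-distinguishing positions),
where recovery must be — and is — exact.

Internally all coordinates are 0-based half-open; IMGT positions appear
only at the reporting boundary.

## Variant panel and mutagenesis primers

The 13-member study panel is generated from its experimental design graph:
heavy-chain reversions as singles and cumulative combinations in position
order, the three light-chain reversions moving as one block, the block
additionally combined with each of the first two heavy singles, the full
set defining the UCA, and the two allele-swap substitutions as singles
plus their pair. Enumeration is deterministic and independent of input
order.

Codon edits use a "minimal nucleotide edit, then fixed preference table"
policy. The expression constructs are codon-optimized and the true policy
is unstated, so the preference table is seeded with the codons visible in
the published primers (AAC for Asn, TCG/TCT for Ser, GTC for Val, GCA for
Ala, GGG for Gly, TAC for Tyr); with that seeding the printed pairs
validate against the package's own checks. Designed pairs follow the
overlapping complementary style: the forward primer spans 14 nt on each
side of the mutated codon, the reverse is the reverse complement of the
same window shifted by up to 3 nt (the printed pairs differ in register by
about 2 nt), and validation checks (a) mutual complementarity over the
overlap, (b) template match outside the intended codon, (c) presence of
the intended codon, and (d) an informational GC-rule melting-temperature
estimate (no Tm criterion is imposed — none is stated for the original
design). One printed row covers two light-chain substitutions jointly and
no dedicated pairing for the third is resolvable from the published
layout, so each printed pair is validated independently per substitution.

## Binding kinetics

Sensorgrams follow the plain 1:1 Langmuir model — association
$R(t) = R_\mathrm{eq}\,(1 - e^{-(k_a C + k_d)t})$ with
$R_\mathrm{eq} = R_\mathrm{max} C/(C + K_D)$, exponential dissociation at
rate $k_d$, and $K_D \equiv k_d/k_a$ stored exactly as that ratio.
Mass-transport limitation is not modeled, matching the model used for the
reported fits. Fitting is global (shared $k_a$, $k_d$, $R_\mathrm{max}$
across the concentration series, standard practice for this instrument
class) by Levenberg–Marquardt on log-scale parameters from a fixed 3×3
log-spaced start grid over $(k_a, k_d)$, so convergence behavior is
deterministic; the 0 nM blank is subtracted point-wise when present.
Approximate 95% confidence half-widths come from the Gauss–Newton
covariance; a relative half-width above 50% flags a parameter as poorly
constrained. At the study design (120 s association, 1360 s dissociation,
0.5 RU noise, 2 s sampling) that flag engages for dissociation rates
around $10^{-6}\,\mathrm{s^{-1}}$ and below, where the 1360 s window
simply contains too little decay.

Fold changes use half-away-from-zero rounding (so a 19.5-fold ratio
reports as 20-fold). The rate-constant table reports
$|K_D^\mathrm{reported} - k_d/k_a|/K_D^\mathrm{reported}$ as an
internal-consistency column: one published row (ka 26×10⁵, kd 1.4×10⁻⁴,
KD 0.56 nM) is arithmetically inconsistent (kd/ka = 0.054 nM) and is
flagged as such; the package deliberately does not choose a correction.

## Thermostability

Melt curves are simulated from the two-state van 't Hoff model,
$f_u(T) = 1/(1 + e^{\Delta H/R\,(1/T - 1/T_m)})$, mixed between linear
native and unfolded baselines per fluorescence channel; defaults are
$\Delta H = 400$ kJ/mol (a typical IgG-domain transition steepness), a
25–95 °C scan sampled at 0.1 °C (equivalent to 6 s sampling at the
1 °C/min scan rate), and 0.2% multiplicative channel noise. The default
baselines let the 350 nm channel carry most of the unfolding signal with
only a modest 330 nm change — note that whenever the 330 nm denominator
changes across the transition, the derivative-of-ratio peak shifts
slightly away from the thermodynamic midpoint; this is a property of the
ratio method itself, kept small here by the baseline choice.

Extraction computes the 350/330 ratio and its first derivative with a
Savitzky–Golay differentiation filter. The smoothing window is 51 points
(5.1 °C) with a quadratic peak fit over ±1.5 °C around the grid maximum:
a narrow window with 3-point interpolation leaves the peak position far
too noise-sensitive at 0.1 °C sampling (triplicate scatter near half a
degree), while the wide window plus local parabola keeps the triplicate
mean comfortably inside the 0.2 °C recovery tolerance the tests assert. Curves
whose derivative has no interior maximum standing at least five robust
SDs above the median — flat or transition-free traces — raise an
extraction error.

## Hydrodynamic radius

A taylorgram is modeled as a Gaussian of temporal variance
$\sigma^2 = r_c^2\, t_R/(24 D)$ (Taylor–Aris) around the residence time
$t_R$; the hydrodynamic radius follows from Stokes–Einstein,
$R_h = k_B T/(6\pi\eta D)$. Instrument constants are unpublished, so they
are explicit configuration with defaults $r_c = 37.5\,\mu$m,
$t_R = 200$ s, and water viscosities 8.9×10⁻⁴ Pa·s at 25 °C and
6.9×10⁻⁴ Pa·s at 37 °C (a Vogel-type fit supplies other temperatures;
the buffer is treated as aqueous). Polydispersity detection uses the
*structured* part of the single-Gaussian residuals — a 21-point moving
average suppresses white detector noise but retains model misfit — with a
threshold of 0.12% of the peak amplitude, above which a dual-species model
(two Gaussians sharing $t_R$) is fitted and the sample flagged. Raw
residual RMS cannot separate a subtle mixture from ordinary noise at
realistic noise levels; the smoothed metric separates the two regimes by
several-fold in both directions.

## Exact Mann–Whitney test

$U$ counts pairs in which the first group's value exceeds the second's,
with 0.5 credit for ties. The exact two-sided p-value enumerates the
rank-sum distribution over all $\binom{n_a+n_b}{n_a}$ labelings —
implemented as a subset-sum recursion over doubled midranks, which is
arithmetically identical to full enumeration and exact under ties — and
doubles the smaller tail, capped at 1. The package's test suite checks
this against literal brute-force enumeration and against
`stats::wilcox.test` on untied samples. On the published 25 °C radius
groups the exact test gives $U = 33$ of 35 and $p = 8/792 \approx 0.0101$,
which does not reproduce the previously reported $p = 0.015$ (the variant
behind that figure — normal approximation, continuity correction, or a
different grouping — is not stated); the report carries the exact value
and an explicit discrepancy note rather than adopting the printed one.

Group summaries are arithmetic means with $n-1$ sample SDs, rounded to two
decimals half-away-from-zero for table reporting; both reported group
summaries (6.16 ± 0.13 nm and 6.46 ± 0.15 nm) follow from the published
per-variant values under exactly these conventions.

## What the synthetic generators emulate — and what they do not

The fixture germline set reproduces the *structure* that the analysis
depends on: a heavy V gene with four alleles differing at CDR positions
38/62 (the *03-vs-*01 analogue), a framework position 96 (the *02
analogue) and a synonymous-only allele; D alleles of realistic lengths; J
alleles with annotated FR4 offsets; and a light V/J pair. Gap placement in
the fixtures is plausible rather than authoritative — the true IMGT gap
pattern of IGHV3-48 is only available from a licensed germline download,
which is also why the six-substitution and CDR3-coverage checks on the
deposited GenBank sequences are integration tests that skip when those
files are absent.

Two stylizations matter when interpreting passing tests. First, gapped V
fixtures end at IMGT codon 104, so unlike real IGHV/IGKV genes they do not
template the first CDR3 codons; to preserve the lineage's signature
junction economics (a light junction with only two untemplated bases, a
heavy CDR3 with J-templated positions deep enough to carry a recoverable
mutation at position 113), the synthetic J alleles carry long CDR3-encoded
heads (27 nt heavy, 25 nt light). Second, somatic hypermutation is uniform
per base with no hotspot bias — inference never uses mutability, and
hotspot-aware simulation is deliberately out of scope (a pluggable
mutability hook exists). Trimming and N-addition lengths are geometric
with caps (12 nt for V/J trims, 4 nt for D ends), which produces
junction structures of the right shape without claiming to match any
repertoire-scale distribution. Passing recovery tests therefore
demonstrate correctness of the inference machinery under the stated
assumptions, not robustness to indels, hotspot-clustered mutation, or
misannotated germline sets.

All generators are pure functions of their seed: a private RNG scope is
used throughout, so identical seeds give byte-identical outputs and no
global RNG state leaks.

## Problem sizes

The shipped experiments use sizes chosen to characterize each estimator
well while staying lightweight: 20 seeds for the KD-recovery experiment
(six concentrations plus blank, 741 points per curve at 2 s sampling),
triplicates for Tm extraction (701 points per curve), single taylorgrams
of 801 points per radius, and 200 planted rearrangements (alternating
heavy/light, 1–3 mutations each) for UCA recovery. The packaged end-to-end
demonstration (`simulate_study()`) runs in about a second.

## Known limitations

- No indel support anywhere (explicit error): correct for this clonotype,
  wrong for lineages with insertions/deletions.
- D assignment by exact runs cannot see mutated D bases; the affected
  positions degrade to N, which biases the UCA toward the observed read
  at those positions.
- The Tm reported is the derivative-peak midpoint of the 350/330 ratio,
  which tracks but does not exactly equal the thermodynamic $T_m$ when
  both channels' baselines change across the transition.
- The dual-species taylorgram fit resolves two well-separated radii at
  low noise; it is a dispersity flag, not a full size-distribution
  deconvolution.
- The exact Mann–Whitney enumeration is limited to 12 values per group.
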