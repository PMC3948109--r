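---
title: "Elucidating short-chain triacylglyceride structures from CID and OzID spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elucidating short-chain triacylglyceride structures from CID and OzID spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagelucidator)
```

## The problem

Males of several desert *Drosophila* species carry sexually dimorphic
triacylglycerides (TAGs) on the anogenital cuticle and transfer them to
females during mating, where they act as anti-aphrodisiacs. These TAGs have
an unusual motif: one long-chain fatty acyl (16–18 carbons, 0–2 double
bonds) plus two short-chain acyls (2–5 carbons, 0–1 double bonds), with the
branched 5:1 tiglate ubiquitous among them. Elucidating such a structure
from mass spectra requires answering four nested questions: elemental
composition, acyl-chain composition, backbone (*sn*) positions, and
double-bond positions/geometry. This package implements that staged
inference, the downstream quantification, and the mate-choice statistics,
together with a ground-truth spectrum simulator.

## The model, stage by stage

**Mass arithmetic.** All m/z values derive from one fixed monoisotopic
table (`ATOMIC_MASS`, CODATA-derived, ≥ 7 significant decimals; electron
mass 0.00054858 Da). A TAG with acyl chains $(n_i{:}d_i)$ has neutral
formula

$$\mathrm{C_3H_8O_3} + \sum_{i=1}^{3} \mathrm{C}_{n_i}\mathrm{H}_{2n_i-2d_i}\mathrm{O}_2 - 3\,\mathrm{H_2O},$$

and a singly charged adduct has $m/z = M + m(\mathrm{X}) - m(e^-)$ for
cation X. Both reporting conventions in the source literature are
supported: `report_mz(mode = "table")` (2 decimals) and `mode = "text"`
(nearest integer). The electron-mass subtraction is invisible at either
reporting scale but fixed as the internal convention.

**Composition search.** `search_formulas()` enumerates a CHO(N) bound box
exhaustively (H solved analytically per C/O/N cell, so the default box is
milliseconds); `enumerate_acyl_compositions()` enumerates the
one-long-two-short constraint box. Both filter at a signed ppm tolerance
and report double-bond equivalents. Sorting is fully deterministic:
$|\mathrm{ppm}|$, then fewer total double bonds, then lexicographic label —
so ties cannot reorder between runs.

**CID.** Each acyl is lost through two channels from the metal adduct:
the free acid ($\mathrm{precursor} - m(\mathrm{RCOOH})$) and the metal
carboxylate ($\mathrm{precursor} - m(\mathrm{RCOOH}) + m(\mathrm{H}) -
m(\mathrm{X})$, atom masses — the surviving fragment is protonated). A
candidate's score averages per-acyl channel evidence (both channels 1.0,
one 0.5), because the *pair* of losses is the diagnostic signature; a
composition whose acid masses merely graze stray peaks scores visibly
lower. Isobaric co-candidates at the same score are flagged, never merged.

**sn inference.** Losses of the *sn*-2 substituent are less abundant than
losses from the outer positions. The qualitative rule is made operational
as: the distinct acyl with minimal mean relative loss abundance is proposed
for *sn*-2 when that abundance is below `sn_ratio` (default 0.5) times the
minimum of the other acyls'. No quantitative threshold exists in the
literature; 0.5 is this package's choice, configurable, and echoed in every
report (`decision_ratio`). *sn*-1 vs *sn*-3 is structurally indistinguishable
by this evidence and never claimed.

**OzID.** A double bond at n-*x* yields an aldehyde ion at
$\mathrm{precursor} - 14.01565\,x + 15.99491$ and a Criegee ion
+15.99491 Da above it. For the branched tiglate's n-2 bond the neutral loss
is modeled as C2H4 (the branch methyl stays on the charged fragment), which
is numerically identical to the generic shift and reproduces the printed
m/z 531 product. "Supported" (aldehyde only) is distinguished from
"confirmed" (pair) because lone aldehyde matches are far more susceptible
to chance peaks.

**Position attribution.** A localized position is attributed to the top
candidate's acyls by feasibility ($d \ge 1$ and $2 \le x \le n-1$), with
the *shortest* feasible chain claiming the position — a short chain's
double bond has very few places to be, so e.g. n-2 goes to the 5:1 tiglate
rather than the 18:1 chain even though both could host it. An acyl claiming
more positions than it has double bonds marks a positional isomer mixture
(the n-7/n-9 situation); a position feasible for no acyl raises a conflict
flag. Attribution affects flags and reporting only, never candidate rank.

**Geometry.** cis and trans alkenes differ in ozone reactivity and in the
aldehyde:Criegee partition. The package compares the observed ratio against
reference ratios within a relative tolerance (default ±50 %). No published
numbers exist for these references — the original work calibrated against
synthetic standards — so `geometry_references` defaults to `NULL` and
geometry is `"undetermined"` until the user supplies calibration. The
synthetic world uses cis = 2, trans = 8, which are well separated under the
±50 % bands (cis matches in [1,3], trans in [4,12]).

**Ranking and monotone evidence.** Candidates are ranked by CID score,
then $|\mathrm{ppm}|$, then fewer double bonds. OzID evidence decorates the
report but does not enter the rank key, so adding an OzID spectrum can
never demote a candidate — a deliberate conservatism: double-bond evidence
pertains to positions within a composition, not to choosing between
compositions, and conflicts are surfaced as flags instead.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `tol_ppm` | 20 | ppm | stated accuracy of the accurate-mass survey instrument class |
| `tol_mz` | 0.3 | Da | unit-resolution ion trap for CID/OzID product ions |
| `sn_ratio` | 0.5 | — | operationalizes the qualitative sn-2 suppression rule |
| `geometry_references` | NULL | ratio | must be calibrated; no literature value |
| `geometry_rel_tol` | 0.5 | relative | generous band; references are order-of-magnitude calibrations |
| `candidate_positions` | 2:16 | n-x | covers all double-bond positions reachable in ≤ 18-carbon chains |
| constraint box | 16–18 C / 0–2 db long; 2–5 C / 0–1 db short | — | the observed structural motif |

All of these layer as defaults < config file < explicit arguments
(`te_config()`), and every report embeds an FNV-1a hash of the resolved
configuration.

One reading-convention note: published peak *labels* are integer-rounded,
so when re-analyzing printed peak lists (as opposed to instrument output)
the match window must be at least 0.5 Da; the worked-example tests pass
`tol_mz = 0.5` explicitly for exactly this reason.

## The synthetic world

`simulation_config()` states the world the pipeline is validated in:

* structures uniform over the constraint box; long-chain monoenes at
  n-7/n-9 (palmitoleoyl/oleoyl, 50/50), dienes at n-6,9 (linoleoyl);
  short-chain double bonds at n-2 (the tiglate motif; 5:1 chains are marked
  branched); long-chain bonds cis with probability 0.9, tiglate bonds
  trans;
* the long chain sits at *sn*-2 with probability 0.2 — outer positions
  dominate among the characterized TAGs;
* CID channel intensities: metalated loss 1.0 (the major peak), neutral
  acid loss 0.4; the *sn*-2 acyl's losses scaled by 0.3 (the literature
  says only "less abundant"; 0.3 is this package's stated value);
* OzID aldehyde intensity fixed, Criegee = aldehyde / geometry ratio
  (cis 2, trans 8);
* noise: 5 spurious peaks per product-ion scan, uniform m/z, log-normal
  intensities capped below the median true-peak intensity; product-ion m/z
  jittered uniformly within ±0.05 Da (well under half the 0.3 Da match
  window); the precursor instead carries a ±5 ppm error, reflecting that
  survey and fragmentation data come from different instrument classes;
  intensities carry 10 % log-normal noise.

The suppression factor is applied at the level of the *distinct acyl*
occupying *sn*-2 (both copies of a duplicated acyl), not per backbone slot.
This is a simplification — a real spectrum of TG(18:1/5:1/5:1) sums a
suppressed and an unsuppressed tiglate loss — but it reproduces the
observed contrast (long-chain losses dominant when the long chain is
outer), which is exactly the signal the inference rule consumes.

What the generator does **not** emulate: isotope envelopes, profile-mode
line shapes, collision-energy dependence, ozonolysis kinetics, in-source
fragmentation, and intensity effects of chain length on ionization. A green
round-trip therefore establishes the *logic* of the pipeline (arithmetic,
matching, ranking, rule application) — not instrument-level robustness.

```{r roundtrip}
cfg <- simulation_config(seed = 7)
set.seed(7)
tg <- parse_lipid_shorthand(
  "TG(18:1(n-9,cis)/5:1(n-2,trans,Me)/5:1(n-2,trans,Me))")
b <- simulate_spectra(tg, "Na", cfg)
elucidate(b$precursor$peaks$mz[1], "Na", b$cid, b$ozid,
          te_config(geometry_references = c(cis = 2, trans = 8)))
```

## Statistics

The mate-choice preference score is $(A - B)/(A + B)$ over trials with a
choice; no-choice trials are excluded from the denominator because the
scored event is which female the male courts *first*. The primary test is
the exact two-sided binomial test of the choosers against $p_0 = 1/2$,
computed by summing all outcome probabilities not exceeding the observed
one — the published analyses cite Fisher's exact test for these one-sample
choice data without printing the underlying tables, so those p-values are
not reconstructable and the package instead guarantees exactness against a
full-enumeration oracle (tested to $n = 20$). A 2×2 Fisher test
(`choice_fisher_test()`) is provided for between-condition comparisons.

Normalization is a plain ratio to a reference peak (the C35:2 hydrocarbon,
[M+K]+ 527.5, present on both sexes) or to a TLC control band; both are
scale-invariant by construction, which the tests assert as a property.

## Numerical choices and degenerate inputs

* Peak matching takes the most intense peak in the window, breaking ties
  toward the smaller m/z offset.
* An empty CID spectrum scores all candidates 0 and flags "no evidence";
  an empty OzID spectrum yields an undetermined localization, not an error.
* Zero Criegee intensity makes the geometry ratio undefined →
  undetermined with a reason, never ±Inf.
* Zero choosers make the preference score undefined (NA), reported as
  such.
* A precursor with no in-tolerance composition yields an empty ranking and
  the nearest-miss ppm, so near-tolerance cases are visible.
* Bound boxes above 10^7 combinations are refused with guidance rather
  than silently churning.

## Known limitations

* Composition search covers CHO (plus N for ammoniated species) only; no
  S/P chemistry.
* CID modeling stops at the two acyl-loss channels; diacyl-level and
  lower fragments are out of scope.
* Branched vs linear isomeric acyls are mass-identical everywhere in the
  pipeline; branching claims require orthogonal evidence (GC-MS) supplied
  as annotation, not inferred.
* Geometry calls are only as good as the supplied reference ratios.
* sn inference presumes the suppression contrast survives co-elution of
  duplicated acyls at both inner and outer positions; with two copies of
  the same short chain this is the resolution limit of the evidence, and
  the package reports at the coarse granularity
  (long-chain-at-sn-1/3 / at-sn-2 / unresolved) only.
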