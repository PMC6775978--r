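---
title: "Methods: catabolic energetics and genome profiling for crustal-fluid archaea"
author: "crustalbio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catabolic energetics and genome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crustalbio)
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
defaults are field-constrained versus placeholder, and what the synthetic
data can and cannot tell you about real genomes.

## The scientific setting

Ridge-flank crustal aquifers such as the Juan de Fuca Ridge (JdFR) flank
carry warm (about 64 °C), anoxic, sulfate-rich (~18 mM) fluids through
fractured basalt. Uncultivated archaea recovered from these fluids as
single-amplified genomes (SAGs) and metagenome-assembled genomes (MAGs)
carry genes for sulfate reduction and for carbon monoxide oxidation
(carboxydotrophy). Three quantitative questions follow, and the package
answers each with a dedicated module:

1. Is CO oxidation coupled to sulfate reduction energetically competitive
   with other electron donors under in situ chemistry? (energetics)
2. Which pathways are encoded, individually and collectively, by a set of
   partial genomes? (marker profiling)
3. Are motility genes enriched in crustal-fluid organisms relative to
   other marine environments, and how large are the genomes really?
   (motility comparison; assembly statistics)

## The energetic model

For a reaction with signed stoichiometric coefficients $\nu_i$,

$$\Delta G_r = \Delta G^\circ_r(T) + RT \ln Q, \qquad
  \ln Q = \sum_i \nu_i \ln a_i,$$

with $R = 8.314462618\times10^{-3}$ kJ mol$^{-1}$ K$^{-1}$. Yields are
reported per mole of electrons transferred, $\Delta G_r / n_e$, in
kJ (mol e$^-$)$^{-1}$, which is the scale on which catabolisms with
different stoichiometries are comparable.

**Temperature correction.** Standard formation properties are tabulated
at 298.15 K; the standard reaction energy at in situ temperature uses the
Gibbs–Helmholtz (van 't Hoff) relation with constant reaction enthalpy,

$$\Delta G^\circ_r(T) = \frac{T}{T_{\mathrm{ref}}}\,
  \Delta G^\circ_r(T_{\mathrm{ref}})
  + \Bigl(1 - \frac{T}{T_{\mathrm{ref}}}\Bigr)\,
  \Delta H^\circ_r(T_{\mathrm{ref}}).$$

This is standard practice for temperatures up to roughly 70 °C and is
fully reproducible from the shipped $\Delta G^\circ_f/\Delta H^\circ_f$
table. It deliberately stops short of revised-HKF equation-of-state
property calculation (SUPCRT-style), speciation solving, and pressure
corrections, which are out of scope; pressure is treated as metadata only.

**Activities.** The default activity model is ideal ($\gamma = 1$),
because published in situ energy estimates for this setting do not state
their activity treatment and the ideal model is the transparent baseline.
The Davies equation is available as an option:
$\log_{10}\gamma = -A z^2 (\sqrt{I}/(1+\sqrt{I}) - 0.3 I)$ with
$A = 0.509$. $A$ is held constant at its 298.15 K value rather than
interpolated from a temperature table; between 25 and 64 °C, $A$ varies
by only a few percent, well below the uncertainty introduced by the
placeholder analyte concentrations below. Water has unit activity and
$a(\mathrm{H^+}) = 10^{-\mathrm{pH}}$.

**Shipped reactions.** The four sulfate-reduction couples are written per
mole of sulfate ($n_e = 8$), with bicarbonate (not CO$_2$) as the carbon
product — the appropriate carbonate species at circumneutral pH:

```{r reactions}
for (r in shipped_reactions()) print(r)
```

Every reaction is element- and charge-balanced against the species table;
`validate_reaction()` enforces this and is itself tested against hand
tallies.

**Formation properties.** `species_table()` ships
$\Delta G^\circ_f/\Delta H^\circ_f$ values at 298.15 K for the nine
participating species, transcribed from the standard aqueous-geochemistry
compilations named per-row in its `source` column, with *aqueous*
standard states for the dissolved gases (CO, H$_2$, CH$_4$). The table is
data, not code: a user file with the same columns replaces it wholesale.

**The `jdfr` profile.** Temperature (337.15 K) and sulfate molality
(0.018 mol kg$^{-1}$) are field-constrained. The remaining entries — pH
7.5, ionic strength 0.7 mol kg$^{-1}$, HS$^-$ 10 µM, HCO$_3^-$ 2 mM, and
1 µM each for the four electron donors — are documented placeholders of
seawater-derived anoxic crustal fluid, chosen once and exposed in the
profile file rather than hard-coded; every field can be overridden
(`fluid_profile("jdfr", pH = 7)`), and conclusions that depend on them
(the absolute per-electron yields) should be read as scenario values. The
donor *ranking* — CO most exergonic per electron — is robust across the
entire 10 nM–100 µM matched-donor sweep under these defaults.

**Donor sweeps.** Because only the donor's activity term varies, the
per-electron yield changes by exactly
$\nu_d R T \ln(r) / n_e$ over a concentration ratio $r$; for the CO
reaction ($\nu_d = -4$, $n_e = 8$) at 337.15 K the decrement over
$r = 10^4$ (10 nM to 100 µM) is $-12.909$ kJ (mol e$^-$)$^{-1}$. This
closed form doubles as an acceptance oracle. Whether in situ donor
concentrations or the sweep should be used is configurable: both are
supported, since measured CO and acetate concentrations are unavailable
for this setting.

## Marker profiling

A marker is present in a genome when at least one annotation matches its
gene symbol (case-insensitive) or its KO identifier (exact); symbol
matching takes precedence because IMG/M-style exports report symbols most
reliably. Grouped subunit names (e.g. fwdABCDEFG) are pre-expanded to
individual members so pathway completeness has per-subunit resolution.
Rules per set are `any`, `all`, or `fraction >= theta`; the
expected-absent methanogenesis set (mcrA) contributes to rule
satisfaction — absence is an assertion about the lineage — but not to
completeness fractions, which are defined only over expected-present
members. The marker definitions are an editable TSV, not code, so the
inventory can be revised without touching the scorer. The shipped default
encodes the collectively-present/absent gene lists for the
Hydrothermarchaeota lineage; per-genome splits beyond that are the user's
data.

The lineage summary is a union over genomes: with partial genomes
(22–97% complete), per-genome absence is weak evidence, and collective
presence is the robust statement.

## Motility comparison

The statistic is the relative abundance of COG functional category N:
`counts["N"] / total_annotated`, with the denominator fixed to genes
carrying at least one COG category (configurable in principle; the
alternative "all predicted genes" denominator would shift all values down
by the unannotated fraction). Multi-letter category strings increment
each listed category and count once in the denominator, so categories are
not silently undercounted. Genomes are filtered at an inclusive
completeness threshold (default 10%); metagenomes pass the filter by
definition. Group summaries use Tukey's five-number summary (`fivenum`),
the inclusive-median quartile convention — fixed so that identical inputs
give byte-identical outputs. An experimental completeness-normalized
column (abundance divided by fractional completeness) is reported
alongside the raw fraction, since raw fractions from partial genomes are
noisy at low completeness.

## Assembly statistics

Contig filtering is strict (`> 2000` bp by default), matching the
screening convention for single-cell assemblies. N50 uses the
descending-cumulative convention: the smallest length $L$ such that
contigs $\ge L$ hold at least half the assembly; the published per-genome
values are not recomputable (contig lists are unpublished), so the
convention is fixed here by documentation and by a brute-force oracle
test over random instances. GC content excludes ambiguous bases from the
denominator. Complete-genome-size extrapolation divides assembly size by
fractional completeness; across the five reference SAGs the per-genome
estimates range 1.50–2.13 Mbp and their *mean* is 1.82 Mbp, reported to
two significant figures as 1.8 Mbp. Mean rather than median is the
aggregation (the median, 1.81 Mbp, agrees to the reported precision);
both are returned.

```{r extrapolation}
extrapolate_genome_size(table1_genomes(), type = "SAG")$per_genome
```

## Synthetic data: what it does and does not emulate

The generator produces IMG/M-like annotation tables with (i) planted
marker inventories — every expected-present member of each listed set,
exactly once, carrying symbol and KO — and (ii) a
Binomial($n$, $p_{\mathrm{env}}$) draw of motility (category N) genes
among $n$ background genes. Planted marker genes carry no COG category,
so the COG-annotated denominator is exactly $n$ and the motility
estimator is an unadulterated binomial proportion — which is what makes
the recovery property (mean estimate within $3\sqrt{p(1-p)/n}$ of $p$
across seeds) well-defined. Default cohort sizes follow the comparison
the package targets: 30 genomes per environment, 1000 annotated genes per
genome, $p = 0.03$ (crustal aquifer) versus $p = 0.005$ (sediment);
contig sets use a log-normal length law (meanlog 8.5, sdlog 1 — median
~5 kbp, SAG-like) and i.i.d. bases at a 50% GC target, matching the
reference genomes' ≈50% GC.

Per-genome randomness is derived by hashing the genome id into a sub-seed
of the root seed, so adding or removing genomes never perturbs the other
genomes' draws, and all generators are pure functions of (spec, seed).

What the synthetic data does **not** emulate: annotation error and
missingness (symbols are planted verbatim; real pipelines mislabel and
truncate), correlated gene content, genome-size variation, amplification
bias, assembly chimerism, or phylogenetic signal. Passing the recovery
tests therefore demonstrates that the *scoring and estimation machinery*
is correct, not that real annotations are this clean; on real exports the
symbol/KO matching is only as good as the upstream annotation.

## Numerical choices and degenerate inputs

- Balance checks use a $10^{-9}$ tolerance on element and charge sums;
  energetic identities (equilibrium zero, scaling invariance, additivity)
  hold to the same tolerance.
- Concentrations must be strictly positive (logarithms are taken);
  missing concentrations, formation properties, or species raise errors
  naming the offender.
- Reported percentages round half away from zero (base `round()` is
  half-to-even, which would report 42.5% as 42).
- Empty inputs: an empty donor grid, an empty length list, an
  all-ambiguous sequence, and a zero-annotation sample are errors; an
  annotation-free *genome* in a scored cohort is a legitimate all-absent
  row with zero completeness.
- Ranking ties break lexicographically by reaction id, fixing the order
  of identical-energy couples.
- Problem sizes in the shipped tests and acceptance script — 20 seeds for
  recovery, 30 genomes per cohort, 1000-instance N50 oracle sweeps,
  25-point donor grids — were chosen as the smallest sizes at which the
  binomial standard-error bounds and quartile contrasts are meaningful.

## Known limitations

- The van 't Hoff correction ignores the temperature dependence of
  $\Delta H^\circ_r$ (constant heat capacity zero); above ~70 °C a full
  equation-of-state treatment should replace it.
- The Davies model is a single-parameter approximation valid to roughly
  $I \le 0.5$–0.7 mol kg$^{-1}$; the default seawater-like ionic strength
  sits at the edge of that range, one more reason ideal activities are
  the default.
- Placeholder analyte concentrations shift absolute yields; only the
  donor ranking and the closed-form sweep structure are robust
  conclusions under the defaults.
- Completeness-based size extrapolation inherits CheckM-style marker-set
  bias: lineages missing "universal" markers systematically inflate the
  estimate.
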