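---
title: "Models and methods behind gquadms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gquadms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gquadms)
```

`gquadms` analyses native electrospray mass spectra, CAD breakdown curves,
and UV melting traces of tetramolecular RNA G-quadruplexes. This vignette
explains the models it fits, the conventions it adopts where several were
defensible, and what its synthetic-data generators do and do not emulate.

## Mass and m/z bookkeeping

All mass arithmetic is built on an elemental-composition algebra over
C, H, N, O, P, K, Na with NIST monoisotopic atomic masses to at least six
decimals. An unmodified L-mer RNA strand with 5′-OH/3′-OH termini is the
sum of its L nucleoside compositions (U: C9H12N2O6, A: C10H13N5O4,
G: C10H13N5O5, C: C9H13N3O5) plus (L − 1) internal phosphodiester
linkages, each contributing HPO3 and removing H2O. Because composition is
a function of the residue *multiset*, sequence isomers such as UAGGGU and
UUAGGG share composition (C58H71N24O41P5) and monoisotopic mass
(1914.290 Da).

Ion m/z follows

$$ m/z = \frac{a\,M + x\,m(\mathrm{Cat}^+) - h\,m(\mathrm{H}^+) - k\,m(\mathrm{NH_3})}{n}, $$

with strand count $a$, cation count $x$, deprotonation count $h$, NH3-loss
count $k$, and net negative charge $n = h - x$ (charge balance, enforced).
Cation and proton masses are electron-corrected
($m(\mathrm{K}^+) = m(\mathrm{K}) - m_e$, proton 1.0072765 Da,
electron 0.0005486 Da); at four to eight charges on a ~7.7 kDa assembly the
electron correction is what keeps computed m/z within the 0.002 Th
agreement the package asserts against printed three-decimal values.

Isotope patterns are isotopologue distributions aggregated by nucleon
number (unit-mass bins): per element the single-atom isotope vector is
raised to the atom count by square-and-multiply convolution, element
distributions are convolved, and each bin reports its abundance-weighted
centroid mass. Unit-mass aggregation matches how Orbitrap-resolved
envelopes of intact multimers are read; isotope fine structure is
deliberately not resolved.

## Fragment chemistry and cleavage regions

CAD backbone products use the standard McLuckey oligonucleotide
nomenclature, with neutral fragments defined purely by composition
arithmetic for a 5′-OH strand: the 5′ prefix of $i$ residues defines
$b_i$; $c_i = b_i + \mathrm{HPO_3}$, $a_i = b_i - \mathrm{H_2O}$; the 3′
suffix of $j$ residues defines $y_j$, and $w_j = y_j + \mathrm{HPO_3}$.
Two invariants follow and are tested: $m(c_i) + m(y_{L-i}) - M$ is the
mass of one water independent of $i$, and $m(a_i) + m(w_{L-i}) = M$
exactly. Only a/c/w/y are enumerated — the series observed for RNA CAD —
and $y_1$ (a neutral nucleoside for 3′-OH RNA) is enumerated but flagged
MS-silent and excluded from detectable tallies rather than omitted.

Cleavage site $k$ (between residues $k$ and $k+1$) is labelled *overhang*
iff at least one flanking residue lies outside the annotated tetrad core,
else *inter-tetrad*. For UAGGGU with tetrads at positions 3–6 this puts
sites 1–2 in the overhang and 3–5 between tetrads, i.e. a 40%/60% split of
the five sites — the random-cleavage expectation against which observed
c/y region shares are compared. The boundary site (U–A|G) is classified
overhang because one of its flanking residues is unstructured; this is
the convention that makes $c_2$ an overhang product.

Two pairs of fragments of this sequence are strictly mass-degenerate
($c_1$/$w_1$ and $c_5$/$w_5$, equal residue multisets with equal terminal
adjustments). No m/z-based assignment can separate them; region analyses
should therefore restrict the candidate set to the c/y series (as the
stacked-share analysis here does), and the assignment tie-break (below)
makes the choice deterministic rather than jitter-dependent.

## Peak assignment and species percentages

Peaks match the nearest theoretical candidate within a ppm tolerance
(default 10 ppm, the accuracy class of an Orbitrap on these species;
configurable). Ambiguities resolve to the smallest ppm error; ties —
which arise exactly for mass-degenerate species, e.g. a dimer at 4−
versus a monomer at 2− — resolve to the lower charge state. Ties are
detected within 1e-4 ppm, far below any real mass accuracy, so that
floating-point noise cannot flip a degenerate assignment. Unassigned
peaks are retained and reported, never silently dropped.

Species quantification sums intensity over all charge states, adduct
counts, and satellites of a species under the native-MS interpretation
rules for these assemblies: tetramers with extra cations (adducts on
deprotonated phosphates) remain quadruplex; ammonium tetramers short of
their full cation count are quadruplexes that lost NH3; covalent products
(backbone fragments and base losses) pool into one class. Peak heights
(centroid intensities) are used, and response factors are assumed equal
across species and charge states — the percentages are raw signal shares,
which is also how the quantities this package reproduces were defined.
Molecule percentages weight species shares by strand stoichiometry
(1/2/3/4), which is why a spectrum with 62% quadruplex signal contains
84% of its RNA molecules in the quadruplex.

## Breakdown curves and E50

The laboratory-frame energy of a CAD point is collision voltage times
absolute net charge (eV). Quadruplex survival versus energy is fitted
with a three-parameter logistic
$Q(E) = P_0 / (1 + \exp((E - E_{mid})/w))$ via Levenberg–Marquardt
(minpack.lm); linear interpolation between the bracketing points is
always computed as the reference and is the fallback if the fit fails.

E50 is defined on the *absolute* convention — the energy where fitted Q
equals 50% of all detected species — giving
$E_{50} = E_{mid} + w\,\ln(P_0/50 - 1)$. Note the sign: for a precursor
entering pre-depleted ($P_0 < 100$%, from unintended activation during
isolation of highly charged ions) the absolute crossing comes *before*
the midpoint ($P_0 = 80$, $E_{mid} = 150$, $w = 10$ gives
$E_{50} = 144.9$ eV, not 155.1). Because the absolute convention
understates the stability of pre-depleted precursors, the fit also
reports the energy at which half of the *initial* quadruplexes survive
whenever $P_0 < 99.5$%; comparisons should use matching conventions.

Stability comparisons report pairwise E50 ratios and percent differences,
plus a monotonicity flag of E50 versus net charge (the Coulombic
destabilisation signature). No absolute internal-energy calibration is
attempted — lab-frame eV are comparable only within one instrument and
collision regime.

## The topology model

The quadruplex is modelled combinatorially: four strands forming a
4-cycle in every tetrad plane, a 5′→3′ stack of G/U tetrads with 2
hydrogen bonds per G–G Hoogsteen edge and 1 per U–U edge (the only
per-edge counts consistent with 4 broken bonds per G-tetrad and 2 per
U-tetrad under any 3+1 or adjacent 2+2 split), and channel cations in
inter-tetrad slots, each contacting all 8 bases of its two flanking
tetrads (the only contact set reproducing the 12/9/6
intact/asymmetric/symmetric sequence of the three-G-tetrad, two-cation
assembly). Pathways are ranked by retained cation–base contacts
(descending), then broken H-bonds (ascending): any model with at least
one cation ranks asymmetric 3+1 dissociation first, because the cations
can follow the trimer and keep 3 of 4 bases per flanking tetrad. The
diagonal 2+2 split (opposite strands) is computed for completeness but
flagged non-physical — each product would retain no tetrad edge. Cations
follow the larger part by convention; for 2+2 ties both retained counts
are reported.

## UV melting

Heating curves are fitted with
$A(T) = c_0 + c_1 T + \sum_k a_k/(1 + \exp(-(T - T_{mid,k})/w_k))$,
$k \le 2$, signed amplitudes. $T_m$ is the sigmoid midpoint (equal to the
dA/dT extremum of that term), and the transition width is reported as the
10–90% amplitude span $2\ln(9)\,w$ — a defined quantity standing in for
the loosely-stated "transition range". Initialisation is noise-robust by
design: baseline and total amplitude from the smoothed end segments,
midpoints from level crossings of the smoothed curve (50%, or 30%/80% for
two sigmoids), width from the 25–75% crossing span ($= 2\ln 3\,w$); all
starting points are tried and the best residual sum of squares wins.
Model order is chosen by small-sample-corrected AIC, and a selected
transition is flagged *degenerate* when its amplitude is under 3 residual
SDs, its midpoint leaves the data range, or its 10–90% span exceeds the
scanned range (a sigmoid that wide is indistinguishable from baseline).
Cooling branches are accepted in the data model but never fitted for
$T_m$: at micromolar strand concentrations tetramolecular association is
far slower than dissociation, so cooling curves are hysteretic and carry
no equilibrium midpoint. Thermodynamic quantities (ΔH, ΔG, van 't Hoff
analysis) are out of scope for the same reason.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the analyses consume, from the same
models the analyses assume, under a single integer seed (identical seeds
give byte-identical output):

* **ESI spectra** — species in configurable true proportions (default
  Q 62% / M 28% / D 10%, the potassium study conditions; trimers absent),
  per-species charge-state distributions (quadruplex 4−…8−), channel
  cations with optional extra adducts (10%) or, for ammonium, NH3-loss
  satellites, isotope envelopes, 2 ppm Gaussian m/z jitter, and 2%
  log-normal intensity noise. Default charge states avoid strictly
  mass-degenerate species pairs (dimer 4− vs monomer 2−), which no
  assignment could separate — real spectra containing such overlaps
  carry an irreducible ambiguity the round-trip tests deliberately
  exclude.
* **CAD series** — phenomenological logistic trajectories (no kinetic
  modelling, since the analysis fits none): quadruplex survival with
  configurable midpoint/width/initial depletion, trimer + monomer as the
  low-energy channel (dimer + monomer for net charges ≥ 7), dimers capped
  at 2%, covalent products ramping to ~11%, ammonium satellites appearing
  below the dissociation regime, and overhang-biased c/y cleavage
  (~80% at low energy) decaying exponentially to the random 40%. Shares
  are renormalised to close exactly and a 0.01% detection floor removes
  unobservably weak species.
* **Melting traces** — the fit model plus additive Gaussian noise
  (default SD 0.002 AU on ~0.08 AU amplitudes, a realistic photometric
  noise-to-signal ratio), with an optional hysteretic cooling branch
  shifted to lower temperature.

Passing round-trip tests on these data shows the estimators are correct
and unbiased *under the assumed models and noise structure*. It does not
validate peak picking (inputs are already centroided), response-factor
equality, isotope-envelope interference between species, baseline drift
or wavelength-dependent artefacts in melting data, or kinetic shifts in
CAD thresholds.

## Problem sizes and numerical choices

The test suite and examples use the 6-mer study system: 30-species m/z
grids, 14–19-point energy series, 161-point melting curves, and spectra
of a few hundred centroids — each analysis runs in seconds on one CPU.
Key defaults: 10 ppm matching tolerance; isotope patterns truncated to
the requested number of unit-mass bins and renormalised; logistic and
melting fits via `minpack.lm::nlsLM` with bounded parameters
($P_0 \ge 1$, $w > 0$) and multiple starts; composition subtraction
below zero is an error (a fragment cannot contain atoms its parent
lacks); uncharged species have no m/z and say so.

## Interfaces

This is an analysis package for R users: the exported functions, this
vignette, and `scripts/acceptance.R` are the interface; no shell
subcommand layer is shipped. Peak lists interchange as CSV
(`mz,intensity`; bit-exact for tests), mzML is read-only via Bioconductor
mzR when installed, energy series are described by a CSV manifest
(`voltage,file`), and fragment tables, breakdown tables and fit reports
export as CSV/JSON.
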