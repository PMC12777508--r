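# gquadms

Native electrospray mass spectrometry (ESI-MS) can transfer intact,
noncovalent RNA assemblies into the gas phase, where their stability can be
probed by collisionally activated dissociation (CAD). `gquadms` implements
the complete computational workflow for such experiments on tetramolecular
RNA G-quadruplexes — four short strands stacked into guanine (and uridine)
tetrads around monovalent channel cations (K⁺ or NH₄⁺):

* **Mass bookkeeping** — elemental-composition algebra, monoisotopic masses
  and isotope patterns, and the m/z of arbitrary
  (a·RNA + x·Cat⁺ − h·H⁺)ⁿ⁻ species, with electron-corrected ion masses and
  the charge-balance constraint n = h − x.
* **Fragment chemistry** — the a/c/w/y backbone series of oligonucleotide
  CAD under McLuckey nomenclature, nucleobase and NH₃ neutral losses, and
  classification of each backbone cleavage site as *overhang* versus
  *inter-tetrad*.
* **Species quantification** — ppm-tolerance peak assignment, aggregation
  over charge states, adducts and NH₃-loss satellites, and conversion of
  species percentages into strand-weighted *molecule* percentages:
  molecule%(s) = order(s)·species%(s) / Σ order(s′)·species%(s′), with
  order 1/2/3/4 for monomer/dimer/trimer/tetramer.
* **Breakdown curves** — species trajectories versus laboratory-frame
  energy (collision voltage × net charge, eV), logistic survival fits
  Q(E) = P₀ / (1 + exp((E − E_mid)/w)), and the energy of 50% quadruplex
  dissociation E50 = E_mid + w·ln(P₀/50 − 1).
* **Topology model** — a combinatorial quadruplex (4-cycle of strands ×
  stacked tetrads, 2 H-bonds per G–G edge, 1 per U–U edge, cations
  contacting the 8 bases of their flanking tetrads) that scores every
  strand-separation pathway by retained cation–base contacts and broken
  hydrogen bonds, rationalising why asymmetric 3+1 dissociation
  (quadruplex → trimer + monomer) beats symmetric 2+2.
* **UV melting** — fits A(T) = c₀ + c₁T + Σ aₖ/(1 + exp(−(T − T_mid,k)/wₖ))
  with one or two sigmoids, analytic dA/dT profiles, and AICc-based model
  selection; only heating branches are fitted (tetramolecular
  re-association is hysteretic).
* **Synthetic data** — seeded generators for ESI spectra, CAD energy
  series, and melting traces with the statistical structure the analyses
  assume, for validation and power analysis.

Functions are tibble-first and pipe-friendly; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(gquadms)

s <- rna_strand("UAGGGU")
s
#> <RNA strand> 5'-UAGGGU-3' (6 nt, 5'-OH/3'-OH)
#>   composition C58H71N24O41P5, monoisotopic mass 1914.2897 Da

# m/z grid of the tetrameric quadruplex with three channel K+
species_table(s, order = 4, cation = "K", x = 3, n = 4:8)
#>   label    class    order cation     x     h     n   nh3    mz
#> 1 (Q+3K)4- assembly     4 K          3     7     4     0 1942.
#> 2 (Q+3K)5- assembly     4 K          3     8     5     0 1553.
#> 3 (Q+3K)6- assembly     4 K          3     9     6     0 1294.
#> 4 (Q+3K)7- assembly     4 K          3    10     7     0 1109.
#> 5 (Q+3K)8- assembly     4 K          3    11     8     0  970.

# simulate a CAD series of (Q+3K)5- and extract E50
an  <- tetrad_annotation(6, 3:6, c("G", "G", "G", "U"))
sim <- simulate_cad_series(e_mid = 150, width = 15, seed = 11)
fit <- sim$series |> build_breakdown(s, an) |> fit_e50()
fit
#> <E50 fit> E50 = 150.6 eV (logistic_fit; interpolation 151.3 eV)
#>   logistic: P0 = 99.9%, midpoint = 150.6 eV, width = 15.1 eV
```

The fitted E50 (150.6 eV) recovers the generating midpoint (150 eV): the
energy at which half of all detected species are still intact quadruplex.

```r
# species and molecule percentages from a simulated ESI spectrum
esi <- simulate_esi_spectrum(seed = 7)   # true shares Q 62, M 28, D 10
esi$peaks |>
  assign_peaks(expand_isotopes(esi$candidates, s, 5)) |>
  species_percentages() |>
  molecule_percentages()
#>   species intensity species_pct molecule_pct
#> 1 Q         621236.       61.9         83.8
#> 2 D          99003.        9.87         6.68
#> 3 M         283222.       28.2         9.55
```

Although only 62% of the ion *signal* is quadruplex, each quadruplex
carries four strands, so 84% of the RNA *molecules* reside in it.

```r
# UV melting: Tm and 10-90% transition width
fit_melting(simulate_melting(seed = 2)$curve, 1)
#> <melting fit> linear baseline + 1 sigmoid(s), residual SD 0.0022 AU
#>   transition 1: Tm = 60.1 degC, amplitude +0.0814 AU, 10-90% width 15.0 degC
```

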