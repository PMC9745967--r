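# glucanSim

Mechanistic, fully discrete simulation of the antagonistic enzyme pair that
remodels 1,3-beta-glucan — the structural polysaccharide of fungal cell
walls and of algal laminarin — for glycobiologists and CAZyme researchers
who want to check branching/degradation stoichiometries *in silico*.

Two activities are modelled as rewrite rules on rooted glycan trees:

* **Exo-1,3-beta-glucanase** — removes one glucose (Glc) per step from a
  non-reducing terminus, but only when the terminus heads a run of at least
  three consecutive 1,3-linked glucosyl residues (the run is cut short by a
  glucitol, a 1,6 bond, or a 1,6-substituted residue). Linear
  laminarioligomers therefore digest as
  `LAMn -> (n-2) Glc + LAM2`, reduced chains as
  `LAMnol -> (n-3) Glc + LAM3ol`.
* **1,3-beta-transglucanase** — cleaves a linear donor (DP >= 5) after the
  second glucosyl from its reducing end, releases laminaribiose (LAM2), and
  transfers the DP−2 remainder onto an acceptor through a new 1,6-beta
  bond: `2 x LAM5 -> LAM2 + H8`, then iteratively
  `H8 -> H11 -> H14` (+DP3 series). Because the exo enzyme cannot pass a
  1,6 branch, branching *protects* the glucan: pretreating LAM5 with the
  transglucanase drops the exo digestion ratio Glc:LAM2 from 3:1 to 1.5:1
  (a 45 % cut in released glucose in the measured tables).

Around the engines the package provides canonical parsing/serialization of
condensed glycan strings (`Glc(b1-3)Glc(b1-3)[Glc(b1-6)...]Glc`, aliases
`LAM2..LAM20`, `LAMnol`, `H8..H16`), additive mass arithmetic
(average/monoisotopic/integer conventions; `[M+Na]+` prediction), +DP3
arithmetic-series detection in peak lists, the microgram/nanomole
difference-formula accounting layer, and seeded synthetic-data generators
(contaminated substrate pools, laminarin-like ensembles, noisy
quantification tables and peak lists).

## Worked example

```r
library(glucanSim)

rep <- runAntagonismExperiment(glycanPool(c(LAM5 = 2)), mode = "scheme")
rep
#> Two-enzyme antagonism experiment (scheme mode)
#>   transfer events: 1
#>   Glc:LAM2  untreated 3.00, treated 1.50
#>   Glc released reduced by 50%
```

Untreated, two LAM5 digest to 6 Glc + 2 LAM2 (ratio 3). After one
transglycosylation (LAM2 + a DP-8 hybrid), digestion yields 3 Glc + 2 LAM2
+ one exo-resistant branched trisaccharide ("by-product X"), ratio 1.5 —
the branching cut glucose release by half (per-molecule counts; the
measured micrograms give 45 %).

```r
rep$treatedTable
#>   species dp count nmol mass_ug
#> 1    LAM2  2     2    2   0.684
#> 2     Glc  1     3    3   0.540
#> 3       X  3     1    1   0.504

pk <- predictPeaks(glycanPool(c(LAM5 = 8, H8 = 4, H11 = 2, H14 = 1)))
detectDP3Series(pk)[, 1:3]
#>   start_dp n_members  spacing
#> 1        5         4 486.1584
```

The four predicted sodiated centroids (851.26, 1337.42, 1823.58, 2309.74)
form one arithmetic ladder spaced by three anhydroglucose units — the
mass-spectrometric signature of iterative trisaccharide transfer; the
octamer peak matches the integer mass convention `molarMass(parseGlycan("H8"),
"paper_integer") = 1315` g/mol.

See `vignettes/glucan-remodelling.Rmd` for the model's assumptions, the
positional-isomer question for the 1,6 branch, and the scheme-versus-rules
distinction for hybrid digestion.

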