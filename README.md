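# acdfret

Spectral FRET analysis for membrane proteins labeled with the fluorescent
noncanonical amino acid acridon-2-ylalanine (Acd).

## The problem

Acd can be installed at single sites of a purified protein by amber-codon
suppression and acts as a FRET acceptor for the protein's intrinsic
tryptophan (Trp) and tyrosine (Tyr) residues, with short Förster radii
(R0 = 23.5 Å for Trp→Acd, 20.9 Å for Tyr→Acd). Because 280 nm light
excites Acd directly as well as through energy transfer, raw emission
spectra mix donor emission, sensitized acceptor emission, and
direct-excitation acceptor emission. The **Ratio A** method unmixes them
using only ratios of steady-state spectra:

1. Scale a donor-only control spectrum (`F280,NoTAG`) onto the sample
   spectrum `F280` over the donor band (300–360 nm) and subtract it,
   leaving the extracted Acd spectrum.
2. Divide pointwise by the directly excited Acd spectrum `F370` and
   average over 410–480 nm:
   `Ratio A = F280 / F370 = F280_direct/F370 + F280_FRET/F370`.
3. Measure the direct-excitation component on free Acd (`Ratio A0`).
   Then `Ratio A − Ratio A0 = F280_FRET / F370` is directly proportional
   to the FRET efficiency, independent of detector transfer function,
   acceptor quantum yield, and protein concentration.

The package implements this pipeline together with the companion analyses
of a typical Acd-labeling study of a dimeric channel:

- **Structure-based prediction**: simplified rotamer ensembles for
  Trp/Tyr/Acd sites on a dimeric model (PDB/mmCIF), donor–acceptor
  distance distributions, multi-acceptor efficiencies
  `E = Σk/(1+Σk)` with `k = (R0/r)^6`, all-donor vs intrasubunit modes,
  and the through-origin fit `measured = m · predicted`.
- **Condition comparisons**: paired per-replicate Zn²⁺ / EDTA relative
  FRET changes with reversibility.
- **TCSPC lifetimes**: multiexponential reconvolution fitting with a
  measured instrument response.
- **ACMA proton-flux traces**: `(F(t) − Fmin)/(Fmax − Fmin)`
  normalization and quench extent/rate.
- **Synthetic data**: seed-deterministic generators for every input class,
  each carrying its ground truth, so every stage has a parameter-recovery
  test with no external downloads.

## Worked example

```r
library(acdfret)

# a synthetic sample with true FRET efficiency 0.3 and
# relative-FRET/efficiency proportionality m = 0.8
ds <- make_fret_dataset(spectra_scenario(true_efficiency = 0.3))
a0 <- ratio_a0(ds$free_f280, ds$free_f370)
res <- spectral_fret_analysis(ds$f280, ds$f370, ds$f280_notag, a0)
res
#> <ratio_a_result> Ratio A = 0.7400 over 410-480 nm (flatness 2.77e-16);
#> Ratio A0 = 0.5000; Ratio A - Ratio A0 = 0.2400
```

Ratio A is 0.74: 0.50 from direct excitation (Ratio A0) plus
0.8 × 0.3 = 0.24 from FRET. The flatness (coefficient of variation of the
per-wavelength ratio) near machine precision says the unmixing left no
wavelength-dependent residual.

```r
# structure-based prediction on a C2-symmetric toy dimer with one Trp
# per chain and an Acd site at residue 15
tb <- make_helix_bundle(toy_structure_scenario(
  n_chains = 2, n_res = 20,
  chain_offsets = list(c(0, 0, 0), c(25, 0, 0)),
  chain_rotations = list(diag(3), diag(c(-1, -1, 1))),
  sites = data.frame(chain = c(1, 2), resid = c(5, 5),
                     resname = c("TRP", "TRP"))))
construct_prediction(tb$model, 15, mode = "all_donors", seed = 1)
#> <fret_prediction> 15Acd (all_donors): E = 0.8699 over 2 donors
construct_prediction(tb$model, 15, mode = "intrasubunit", seed = 1)
#> <fret_prediction> 15Acd (intrasubunit): E = 0.8661 over 2 donors
```

Letting each donor see both acceptor copies of the dimer can only raise
the efficiency, so `all_donors >= intrasubunit` always holds; the gap
carries information about subunit organization.

```r
# TCSPC: recover a two-component decay through IRF reconvolution
d <- make_decay(c(3, 16), c(0.4, 0.6), irf_sigma = 0.2,
                n_photons = 1e6, seed = 42)
fit_decay(d, 2)
#> <decay_fit> 3.04 ns (39.8%), 15.9 ns (60.2%); mean 10.8 ns; chi2_red 1.040
```

## Command line

```sh
Rscript -e 'acdfret::acd_cli()' fret-ratio --manifest manifest.tsv --out results.tsv
Rscript -e 'acdfret::acd_cli()' predict --structure model.pdb --sites 18,56,169 --mode both --seed 1
Rscript -e 'acdfret::acd_cli()' lifetime --in decay.csv --irf irf.csv --components 2
Rscript -e 'acdfret::acd_cli()' flux --in flux.csv --events flux_events.csv
Rscript -e 'acdfret::acd_cli()' simulate --what fret --dir sim --seed 7
```

Subcommands exit 0 on success, 1 on input errors, 2 on computation
errors. `inst/scripts/acdfret` is a ready-made wrapper.

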