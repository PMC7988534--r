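# pepdmd

Event-driven square-well dynamics and cross-linking mass-spectrometry
tools for amyloid peptide self-assembly.

## What this package is for

Short amyloidogenic peptides such as Aβ16-22 (Ac-Lys-Leu-Val-Phe-Phe-
Ala-Glu-NH₂, the central fibril-forming fragment of the Alzheimer's Aβ
peptide) assemble into cross-β fibrils in which strands pack
antiparallel and in register.  Resolving *how* they get there — which
strand orientations and registries transient oligomers sample — needs
two complementary instruments: coarse-grained simulation of the assembly
itself, and photo-induced cross-linking (PIC) mass spectrometry that
covalently traps strand-to-strand contacts for sequencing.  `pepdmd`
implements both arms in one package, for structural-biophysics users who
want to regenerate and stress-test this kind of analysis at desk scale:

* a **discontinuous molecular dynamics (DMD) engine** for a PRIME20-style
  square-well peptide model — 3 backbone beads + 1 sidechain bead per
  residue, hard-walled bonds (±2%), square-well sidechain interactions,
  a directional square-well backbone hydrogen bond
  (ε_HB = 12.47 kJ/mol defines the energy unit; T* = k_BT/ε_HB the
  temperature), an Andersen thermostat, cell lists and an event calendar
  with exact ballistic flight between events;
* the **trajectory observables** used to characterise assembly:
  hydrogen-bond maps, β-sheet residue percentage over time, strand-pair
  orientation/registry classification, oligomer clustering with sheet
  layer counting, nearest interpeptide sidechain contacts (the F19/F20
  contact statistics);
* ideal **β-sheet lattice fixtures** in the four canonical arrangements
  with construction-time ground truth (the oracle for every analysis);
* the **PIC/MS interpretation layer**: exact masses for TFMD-diazirine
  modified peptides and cross-linked dimers (one N₂ lost per link), b/y
  fragment enumeration with cross-link bookkeeping, cross-link site
  localization against peak lists, and traveling-wave ion-mobility CCS
  calibration Ω = A·t_D^B·z·√(1/m_ion + 1/m_gas).

## Worked example

The quantitative anchors, straight from the package:

```r
library(pepdmd)

concentration_of(192, 321.0)           # 192 chains in a 321.0 A box
#> [1] 9.64                            # i.e. 10 mM at quoted precision

mz_to_neutral_mass(988.58, 2)          # the cross-linked dimer peak (2+)
#> [1] 1975.15                         # Da

ch <- peptide_chain("KLVFFAE",
                    modifications = list(list(position = 5, id = "TFMD")))
dimer <- crosslinked_dimer(ch, ch, 5, 1)   # F20 -> K16 link, 2x monomer - N2
dimer$mono_mass
#> [1] 1974.983

fr <- fragment_ions(dimer, max_charge = 1, include_double = TRUE)
# b ion from loss of F*-Ala-Glu, y ion from loss of Ac-Lys-Leu:
min(abs(fr$mz[fr$series == "b"] - 1503.82))   # 0.002 Da from the annotation
min(abs(fr$mz[fr$series == "y"] - 1692.95))   # 0.149 Da (within the 0.2 Da
                                              # documented convention window)
```

An ideal antiparallel in-register sheet, and what the analyses say:

```r
fx <- build_sheet_fixture("antiparallel_in_register", n_strands = 8)
head(classify_all_pairs(fx$state), 3)
#>   chain_i chain_j  orientation registry_offset n_hbonds
#> 1       1       2 antiparallel               0        8
#> 2       2       3 antiparallel               0        6
#> 3       3       4 antiparallel               0        8
beta_sheet_fraction(fx$state)
#> [1] 100
nearest_sidechain_contacts(fx$state, "F20")
#> V18
#>   8            # every F20 faces a V18 on the adjacent strand
```

A desk-scale self-assembly run (24 chains, 10 mM, T* = 0.193; a few
minutes of CPU):

```r
traj <- simulate_assembly(assembly_proxy_config(seed = 1))
ts <- energy_and_beta_timeseries(traj)
check_monotone_rise(ts)       # beta % climbs from ~0 to a plateau
check_two_phase_decay(ts)     # fast collapse, then slow ordering
```

A shell front-end is available for simulation runs:

```sh
Rscript scripts/simulate.R --config my.cfg --seed 3 --out run3/
```

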