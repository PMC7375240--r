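# cyslock

Covalent virtual screening anchored at a nucleophilic cysteine, with the
supporting computations used to find and validate such a site: trajectory
clustering for pocket discovery, a cysteine-conservation screen, covalent-adduct
mass validation, and NMR chemical-shift-perturbation (CSP) mapping.

## The problem

Small GTPases such as RhoA lack deep, druggable pockets in their crystal
structures, but molecular-dynamics ensembles expose cryptic grooves near
surface cysteines. A Michael-acceptor "warhead" (acrylamide, enone, vinyl
sulfone, vinyl sulfonate, acrylate ester) can alkylate such a cysteine's
thiol, tethering the ligand covalently and making even a shallow groove
tractable. `cyslock` implements the in-silico side of this strategy for
structural bioinformaticians and chemical biologists:

1. **Pocket discovery support** — cluster trajectory frames on pairwise
   superposed C&alpha; RMSD with k-medoids (PAM), reporting per-cluster
   occupancies and medoid representative structures; screen a superfamily
   alignment for columns where only one family carries a cysteine.
2. **Covalent docking** — detect the warhead, apply the Michael-addition
   transform (C=C &rarr; C–C, the thiol hydrogen added at C&alpha;, an open
   valence at C&beta; for the S&gamma; link), build the attachment geometry,
   and *exhaustively* enumerate conformers by driving every rotatable bond in
   constant increments. Each pose is scored against the pocket with

   E = w_es &Sigma; 332.0637 q_i q_j / (&epsilon;_r r_ij)
     + w_vdw &Sigma; 4&epsilon;&#772; [ (&sigma;&#772;/r)&sup1;&sup2; − (&sigma;&#772;/r)&#8310; ]

   (kcal/mol; Lorentz–Berthelot combining, distance-independent dielectric).
   Clashed poses come out strongly positive through the r&supmin;&sup1;&sup2;
   repulsion; favorable electrostatic and dispersion contacts drive scores
   negative. Each compound keeps its best-scoring conformer and the library
   ranking's top fraction (default 10 %) is selected.
3. **Validation** — monoisotopic/average masses of elemental formulas,
   in-silico tryptic digestion (cleave after K/R, not before P), adduct
   matching at ppm tolerance, and CSP classification
   (&radic;(&Delta;&delta;H&sup2; + (0.2 &Delta;&delta;N)&sup2;), perturbed
   when CSP &gt; 0.05 or the resonance is attenuated) with contiguous-segment
   summaries.

Everything is deterministic: the same inputs and configuration reproduce the
same ranking byte for byte, and all synthetic generators are pure functions of
their seed.

## Worked example

```r
library(cyslock)

# a synthetic pocket: one cysteine anchor ringed by small residues
s      <- readStructure(makeToyPocket(1))
anchor <- findAnchor(s, "A", 107)
pocket <- parameterizePocket(extractPocket(s, anchor, radius = 10))

# dock one acrylamide covalently
lig   <- parseLigand("C=CC(=O)N", "acrylamide")
match <- detectWarheads(lig)          # pattern_id=acrylamide, beta_c=1
adduct <- applyMichaelAddition(lig, match[1, ])
massDelta(adduct)                     # 71.03711 -- the whole parent adds on
pose  <- placeAnchor(adduct, pocket)  # S-C bond 1.81 A, anti to S-CB
set   <- pruneInternalClashes(enumerateConformers(pose, incrementDeg = 30,
                                                  cap = 1000))
bestScore(set, pocket)
#>     electrostatic       vdw     total conformer_index
#> 378     -0.676223 -3.271721 -3.947944             378
```

The best pose binds at −3.95 kcal/mol (in this simplified force field's
scale), dominated by dispersion; conformer 378 of the 30°-increment torsion
scan over the three rotatable bonds. A full library screen is one call:

```r
lib <- makeLigandLibrary(1, n = 120, warheadFraction = 1.0)
res <- runScreen(lib, pocket, incrementDeg = 30, cap = 1000, fraction = 0.10)
res
#> ScreenResult: 120 compounds (120 scored, 0 no_warhead, 0 failed); top 10% = 12 selected
```

Trajectory clustering and CSP work the same way (`makeTrajectory`,
`clusterFrames`, `makePeakLists`, `computeCSP`, `classifyPerturbations`); see
the methods vignette in `vignettes/` for the models, parameters and their
defaults. A thin CLI wraps the same functions:

```sh
inst/scripts/cyslock mass C12H10SO4
inst/scripts/cyslock screen --receptor pocket.pdb --anchor A:107 \
    --library lib.smi --out results.tsv
```

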