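# exitvector

Computational design of three-dimensional fragment elaborations around
bifunctional cyclopropane building blocks, for medicinal and computational
chemists planning fragment-growth campaigns.

The scaffolds in scope pair a small cyclic amine (azetidine, pyrrolidine,
piperidine) with a fused or spirocyclic cyclopropane. Each scaffold carries
two variation points: a cyclopropane carbon **C1** that receives an aryl
fragment (the design-phase surrogate of a Suzuki–Miyaura coupling of a
boron handle) and the ring nitrogen **N2** that receives a capping group
(sulfonamide, amide, alkyl or aryl). The 3D display of the two substituents
is summarized by the exit-vector pair

- **r** — the through-space distance C1⋯N2 (Å), measured on the
  lowest-energy conformer, and
- **θ** — the dihedral between the plane spanned by the N2 exit vector and
  the C1–N2 axis and the plane spanned by the C1 exit vector and that
  axis; computed as the four-point torsion *red–orange–green–blue*
  (cap atom, N2, C1, fragment atom) and reported unsigned in [0°, 180°].

A scatter of r vs θ — the exit-vector plot — shows how much of 3D space a
scaffold collection can reach. The package enumerates the full theoretical
scaffold set, virtually elaborates it, generates conformers, measures
(r, θ), profiles lead-likeness (Rule-of-Two: MW < 200 and clogP < 2 for
scaffolds; lead-like: 200 ≤ MW ≤ 350 and −1 < clogP < 3 for products,
plus Fsp3), and picks maximin-diverse subsets.

## Worked example

Enumerate the theoretical scaffold set, identify the nine packaged
building blocks (`1a`–`1i`), elaborate them into the pyrimidine
methanesulfonamide series, and measure the exit vectors:

```r
library(exitvector)

sc <- augment_with_tropane(enumerate_scaffolds())
nrow(sc)
#> [1] 27        # 26 enumerated combinations + the tropane augmentation

m <- match_named_blocks(sc, load_registry("building_blocks"))
length(m$virtual_only)
#> [1] 18        # scaffolds not realized by a packaged block

nine <- sc[match(m$matches$scaffold_id, sc$id), ]
nine$id <- m$matches$block_id
caps <- load_registry("caps")
lib <- enumerate_library(nine, load_registry("fragments"),
                         caps[caps$id == "methanesulfonyl", ])
ens <- setNames(lapply(seq_len(nrow(lib)),
                       function(i) embed_and_minimize(lib[i, ])),
                lib$product_id)
tab <- vectors_for_library(lib, ens)
data.frame(block = tab$scaffold_id, r = round(tab$r_angstrom, 2),
           theta = round(tab$theta_degrees, 1))
#>   block    r theta
#> 1    1a 1.51  81.4
#> 2    1b 4.40 104.5
#> 3    1c 3.35 124.3
#> 4    1d 2.68 117.0
#> 5    1e 2.63  89.3
#> 6    1f 4.37  82.5
#> 7    1g 3.29  59.5
#> 8    1h 3.20 179.1
#> 9    1i 2.58  20.8
```

The nine sulfonamides span r from 1.51 Å (in the `1a` derivative C1 and
N2 are directly bonded, so the minimum is a C–N bond length) to 4.40 Å,
with θ covering 21°–179°: each building block presents its substituents
along a distinct 3D vector. All nine products profile as lead-like:

```r
pp <- profile_properties(lib)
c(leadlike = sum(pp$leadlike_pass), mean_fsp3 = round(mean(pp$fsp3), 2))
#> leadlike mean_fsp3
#>        9      0.64

diversity_select(tab, 4)
#> [1] "1a.pyrimidin-5-yl.methanesulfonyl" "1b.pyrimidin-5-yl.methanesulfonyl"
#> [3] "1h.pyrimidin-5-yl.methanesulfonyl" "1i.pyrimidin-5-yl.methanesulfonyl"
```

The full design grid (27 scaffolds × pyrimidin-5-yl × 4 caps) is one call:
`enumerate_library(sc, load_registry("fragments"), load_registry("caps"))`
gives 108 distinct virtual products; `run_pipeline(ev_config())` runs the
whole chain end-to-end and writes CSV tables, an SDF of lowest-energy
conformers and a JSON manifest. A thin command-line front end lives at
`inst/cli/exitvector.R`.

Crystallographic (or any externally determined) 3D coordinates can be fed
into the same analysis with `load_coordinates()`; multi-model files
contribute every model to the plot table.

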