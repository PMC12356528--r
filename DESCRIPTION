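Package: exitvector
Title: Exit-Vector Design of Bifunctional Cyclopropane Building Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational design pipeline for fragment elaboration in three
    dimensions. Enumerates the bifunctional scaffolds that combine an
    azetidine, pyrrolidine or piperidine with a fused or spirocyclic
    cyclopropane, virtually elaborates them with an aryl fragment at the
    cyclopropane variation point and a capping group on the ring nitrogen,
    generates lowest-energy conformers with a molecular-mechanics force
    field, and measures the exit-vector parameters r (through-space distance
    between the two variation points) and theta (dihedral between the two
    substituent planes). Includes lead-likeness profiling (Rule-of-Two and
    lead-like filters, Fsp3) and a greedy maximin selector for picking
    geometrically diverse scaffold subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
SystemRequirements: OpenBabel >= 3.0 (obabel and obenergy on the PATH)
Config/testthat/edition: 3
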