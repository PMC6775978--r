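Package: crustalbio
Title: Catabolic Energetics and Genome Profiling for Subseafloor
    Crustal-Fluid Archaea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting the metabolic potential of uncultivated
    archaea from warm, anoxic crustal aquifers such as the Juan de Fuca
    Ridge flank. Computes standard and in situ Gibbs energies of catabolic
    reactions (sulfate reduction coupled to carbon monoxide, hydrogen,
    methane, or acetate oxidation), normalized per mole of electrons
    transferred, with donor-concentration sweeps and donor ranking; scores
    per-genome gene-annotation tables against named metabolic marker sets
    to produce presence/absence matrices and pathway-completeness
    fractions; compares the relative abundance of COG category N (motility)
    genes across environments with quartile summaries; and provides
    assembly statistics (contig filtering, N50, GC content) and
    completeness-based complete-genome-size extrapolation. A synthetic-data
    generator produces annotation tables, contig sets, and fluid-chemistry
    profiles with known ground truth so every stage can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
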