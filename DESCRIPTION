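Package: paleomaize
Title: Damage-Aware Population Genomics for Ancient Maize
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for low-coverage ancient maize genomes against a
    structured modern reference panel. Classifies SNPs by substitution type and
    applies deamination-aware (molecular damage) and transversion-only filters
    with exact accounting; estimates positional C-to-T / G-to-A
    misincorporation profiles; computes ABBA-BABA D-statistics under two
    quartet designs with block-jackknife uncertainty; scans for
    elevation-adaptive alleles by Hudson F_ST and tests allelic similarity of
    an ancient individual to highland and lowland populations by resampling
    nulls; and places the ancient sample among panel populations with
    identity-by-state distances and neighbor joining. A Balding-Nichols
    synthetic-data generator emulates a maize/teosinte panel with admixture and
    an ancient sample observed through short, terminally deaminated fragments,
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
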