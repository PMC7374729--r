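Package: stabscan
Title: Protein Folding Stability Analysis of Androgen Receptor Missense Variants
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating missense-variant pathogenicity to protein
    folding stability, developed around the androgen receptor (AR)
    ligand-binding domain. Implements the two-state linear extrapolation
    method (LEM) for guanidine-hydrochloride chemical denaturation curves
    measured by circular dichroism, yielding the folding free energy at zero
    denaturant, the m value, the transition midpoint and mutant-versus-wild-type
    experimental ddG. Also provides a variant catalog layer (domain assignment
    on the 920-residue AR reference, phenotype normalisation, per-domain
    mutation statistics, three-way dataset overlap counts), a parser for
    FoldX "Dif" stability predictions, class-wise ddG group comparisons, a
    synthetic-data generator for denaturation curves and variant catalogs,
    and a configurable end-to-end pipeline with reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
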