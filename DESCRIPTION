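Package: nucdeam
Title: Deamination Kinetics and Mutagenic Potential of UV Photoproducts in
    Nucleosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how nucleosome rotational positioning
    modulates the formation and deamination of cyclobutane pyrimidine dimers
    (CPDs) at methylated CpG sites. Fits first-order deamination rate
    constants, half-lives and photoproduct yields from gel band-intensity
    time courses; converts rate and yield ratios into transition-state
    free-energy differences; scores the C-to-T mutagenic potential of each
    rotational position as the product of relative photoproduct formation
    and relative deamination rate; fits the ~10-11 bp periodicity of
    hydroxyl-radical cleavage profiles and classifies backbone orientation;
    and computes per-nucleotide geometry (mean temperature factors, base
    orientation angles relative to the histone surface, photodimer interbond
    distance and improper torsion) from nucleosome coordinate files. A
    synthetic-data module generates gel time courses, cleavage profiles and
    idealized DNA-on-superhelix coordinates with the statistical structure
    the analysis assumes, and a packaged reference table of site yields and
    half-lives supports end-to-end reproduction of the derived quantities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
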