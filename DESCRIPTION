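Package: mutcloud
Title: Mutant-Cloud Analytics for Serial-Transfer Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Mutcloud", "Developers", email = "mutcloud@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for serial-dilution laboratory
    evolution of asexual microbes, with an emphasis on mutator strains.
    Provides pooled population-sequencing diversity metrics (cloud spread,
    consensus distance, nucleotide site diversity, high-frequency derived
    alleles, folded mutational spectra), a replicate-convergence test for
    putatively beneficial genes, nominal effective population size from
    growth-dilution census ladders, Luria-Delbruck fluctuation-assay
    mutation-rate estimation with Drake-style genomic conversion, logistic
    growth-curve fitness and endpoint stress-phenotype scoring, and a
    haplotype-based serial-transfer Wright-Fisher simulator that generates
    every input format the analysis stages consume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
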