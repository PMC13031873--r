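Package: coacervgeno
Title: Genotype-Phenotype Analysis for Fuel-Driven Coacervate Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studies that couple short DNA
    "genotypes" to the phenotype of fuel-driven complex-coacervate droplets.
    Provides seeded generators for biased 30-mer oligonucleotide libraries and
    droplet/supernatant read pools with planted recruitment signal; FASTQ read
    cleaning (adapter trimming, polyG-tail removal, exact-length filtering);
    droplet-versus-supernatant composition and homopolymer-run enrichment
    statistics with exact tests and e-value correction; an exact transfer
    dynamic program for homopolymer-run probabilities under per-position
    categorical base models; partition-coefficient estimation with error
    propagation; turbidity-trace lifetime and critical salt/fuel titration
    analysis with Welch tests; and FRAP recovery fitting with the Soumpasis
    diffusion coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
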