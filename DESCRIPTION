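Package: amplipop
Title: Candidate-Gene Amplicon Population Genetics and Association Mapping
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of candidate-gene amplicon resequencing data
    from a mass-cross aquaculture population: amplicon coverage and
    sensitivity modelling (two-way ANOVA and a Boltzmann depth-sensitivity
    curve), SNP quality filtering, nucleotide diversity and neutrality
    statistics (pi, Watterson's theta, Tajima's D, Fu's Fs, Nei-Gojobori
    dN/dS), linkage-disequilibrium decay regression under a
    mutation-recombination drift model, EM haplotype estimation with
    haplotype trend regression, and structure-aware mixed-linear-model
    association with gene-action classification. Includes a synthetic
    mass-cross data generator so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
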