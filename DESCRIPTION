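Package: cfconcord
Title: Concordance Analysis of Tumor and Circulating Cell-Free DNA Variant Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nucleotide-resolution matching of somatic variant profiles across
    multiple tumor lesions and plasma cell-free DNA (cfDNA) from the same
    patient. Provides germline subtraction, confidence and functional
    filtering, tumor/cfDNA overlap (Venn) counts and detection rates,
    truncal/shared/individual mutation classification with class-stratified
    cfDNA detection statistics, variant-allele-frequency (VAF) stratification
    of detected versus undetected tumor variants, longitudinal cfDNA set
    dynamics between diagnosis and death, and identification of
    metastasis-presaging variants. A clonal-evolution and cfDNA-shedding
    simulator with known ground truth makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
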