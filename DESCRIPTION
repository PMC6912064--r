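Package: ctdnaclone
Title: Serial ctDNA Clonal Evolution Monitoring for Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal circulating tumor DNA (ctDNA)
    panel sequencing of patients on immune checkpoint therapy. Starting from
    per-sample somatic variant calls (VCF with allelic depths), the package
    applies a four-step germline/artifact filter cascade using population
    allele-frequency databases and matched white-blood-cell evidence, computes
    per-sample burden statistics (maximum somatic allele frequency and blood
    tumor mutational burden), deconvolutes mutations into clones across serial
    samples with a Dirichlet-process binomial mixture Gibbs sampler,
    reconstructs clonal evolution trees under the crossing rule, detects clone
    emergence and its lead time over radiological progression, and runs the
    associated outcome statistics (rank tests, Kaplan-Meier and log-rank by
    median biomarker split). A synthetic-cohort simulator with full ground
    truth makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    survival,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
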