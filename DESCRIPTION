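Package: gsurvey
Title: Genome Survey Sequencing Analysis with Contaminant Screening
Version: 0.1.0
Authors@R:
    person("Survey", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for desk-scale genome survey sequencing analysis of
    short-read data: paired-end FASTQ quality filtering, 17-mer spectrum
    estimation of genome size, heterozygosity and repetitive rate, a
    minimal de Bruijn unitig assembler with contig statistics, GC-depth
    profiling with stray-region extraction and k-mer based read
    decontamination, perfect microsatellite (SSR) detection with
    MISA-style thresholds, and a ground-truthed simulator of contaminated
    diploid samples for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
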