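Package: triptofunnel
Title: Gene-to-Metabolite Networks, CYP Candidate Funnels and
    Whole-Genome-Multiplication Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to nominate biosynthetic cytochrome P450 candidates from
    matched transcriptome and metabolome profiles, as applied to diterpenoid
    (triptolide-type) pathways. Implements LC-MS peak-table filtering (mass
    window, ANOVA responsiveness, fragment presence), RPKM and time-course
    differential expression, Pearson gene-to-metabolite correlation networks,
    percent-identity based species-specific CYP classification and
    near-duplicate collapse, a staged candidate-prioritization funnel, and
    paralog-divergence statistics for whole-genome-duplication dating (4DTv,
    Nei-Gojobori Ks with Jukes-Cantor correction, molecular-clock conversion,
    kernel-density peak detection, collinearity blocks and syntenic depth).
    A synthetic multi-omics generator with planted ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
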