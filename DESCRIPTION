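Package: refstab
Title: Reference Gene Stability Evaluation for RT-qPCR
Version: 0.1.0
Authors@R:
    person("refstab", "developers", email = "refstab@example.org", role = c("aut", "cre"))
Description: Evaluates candidate reference (housekeeping) genes for RT-qPCR
    normalization from tables of cycle-threshold (Ct) values. Implements
    standard-curve amplification-efficiency estimation, four stability
    statistics (the comparative delta-Ct method, geNorm M-values with
    pairwise variation V, the NormFinder intra/inter-group variance model,
    and BestKeeper descriptive dispersion), a geometric-mean-of-ranks
    consensus ordering with a recommended reference pair, and target-gene
    validation by 2^-ddCt relative quantification against an aggregated
    multi-gene reference set with one-way ANOVA group comparison. A
    synthetic Ct generator with known ground-truth stability supports
    end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
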