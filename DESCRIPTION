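Package: bucketeval
Title: Batch-Effect-Robust Similarity for Chemogenomic Profiles via
    Bucket Evaluations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements Bucket Evaluations (BE), a non-parametric,
    levelled-rank similarity score for genome-wide fitness-defect and
    expression profiles.  Each profile is ranked and partitioned into
    significance-weighted buckets (small early buckets hold the most
    sensitive strains); pairs of experiments are scored by a levelled
    scoring matrix that rewards co-occurrence of genes in low, nearby
    buckets, which makes the score robust to batch effects such as
    experiment date.  Includes Pearson/Spearman/Kendall baseline
    comparators, a Wilcoxon rank-sum assessment of score batching by
    metadata factors, average-linkage clustering of experiments, a
    synthetic chemogenomic-profile generator with known compound
    structure and date-linked nuisance shifts, TSV readers/writers,
    log2-ratio fitness-defect computation from barcode counts, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
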