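Package: facstress
Title: Factorial Multiple-Stressor Transcriptomic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing factorial multiple-stressor RNA-seq
    experiments: transcript-to-gene summarisation with abundance-weighted
    effective lengths, median-of-ratios normalisation, per-gene
    negative-binomial generalised linear models over a full-factorial
    design with Wald tests and Benjamini-Hochberg adjustment, adaptive
    (mixture-of-normals) log-fold-change shrinkage, surrogate-variable
    estimation for latent batch effects, classification of significant
    stressor interactions into synergistic and antagonistic categories,
    expression-profile clustering, exclusive set intersections, and
    DAG-aware (elim) gene-ontology-style enrichment.  A seeded synthetic
    data generator produces negative-binomial counts with known effects
    for benchmarking the full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    DESeq2,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
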