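Package: ehrlatent
Title: Denoising-Autoencoder Latent Representations for Chronic-Patient
    Phenotyping from Binary Diagnosis and Drug Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning low-dimensional latent representations of
    patients from binary ICD9-CM diagnosis and ATC drug code vectors with a
    denoising autoencoder, clustering the representations (k-means and
    Ward-linkage agglomerative clustering) with cluster-validity-index based
    selection of the number of clusters, characterizing clusters through
    presence-rate profiles, Pearson profile correlations, cross-tabulations
    against clinical risk groups and age summaries, and mapping simple and
    complex synthetic-patient health-status trajectories in a two-dimensional
    t-SNE embedding. Includes a synthetic-cohort generator emulating
    CRG-structured populations so the full workflow runs without access to
    protected hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    mclust,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
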