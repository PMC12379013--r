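Package: senoscreen
Title: Subtype-Specific Drug Vulnerability and Senescence Phenotype Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of drug sensitivity screens in neuroblastoma
    cell-line cohorts spanning the mesenchymal-to-adrenergic identity spectrum.
    Fits five-parameter asymmetric dose-response curves and computes normalized
    drug sensitivity scores (DSS), calls cohort quantile-rank hits, scores
    single-sample gene-set enrichment (ssGSEA) signatures including
    mesenchymal/adrenergic identity and MAPK pathway activity, quantifies
    lysosomal puncta from high-content images to derive basal and
    treatment-adaptation lysosomal scores, analyses combination screens with
    the zero-interaction-potency (ZIP) model on full and diagonal reduced
    designs with combination sensitivity scores (CSS), and classifies
    zebrafish xenograft responses with RECIST-style volume-change criteria.
    Includes a synthetic-cohort generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    EBImage,
    fgsea,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
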