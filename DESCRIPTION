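Package: xsubtype
Title: Cross-Species Mapping of Mouse Intestinal Tumor Signatures onto
    Human Colorectal Cancer Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for projecting genetically engineered mouse model (GEMM)
    intestinal-tumor expression signatures onto human colorectal cancer
    molecular subtypes (CMS and CRIS).  Builds top-N differential-expression
    signatures and subtype weight templates, maps genes across species by a
    highest-homology orthology rule, scores patient samples with z-sum gene
    panels (NOTCH, WNT, custom) and signature-correlation scores, stratifies
    recurrence-free survival with Kaplan-Meier curves and log-rank tests,
    compares correlations with the Fisher r-to-z transform, summarises
    metastasis incidence, computes marker-based immune infiltration scores,
    and scans promoter sequences for IUPAC consensus motifs such as the RBPJ
    core site.  A synthetic-data module generates human-like cohorts with
    subtype expression blocks, batch effects and score-linked censored
    survival, plus mouse-model profiles and orthology tables, so the whole
    pipeline is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    survival,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
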