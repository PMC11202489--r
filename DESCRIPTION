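Package: cernet
Title: Back-Splice Junction Detection, Differential Expression and
    ceRNA Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reconstruction of circRNA-miRNA-mRNA competing endogenous RNA
    (ceRNA) networks from RNA-seq derived expression data, modelled on the
    analysis chain used in eggshell-colour transcriptomics of blue-egg
    layer hens. Provides anchor-based back-splice junction calling with
    GT/AG splice-site validation and unique-read support filtering,
    TPM/FPKM/RPM expression metrics and the 2^-ddCt qPCR statistic, an
    exact negative-binomial test for differential expression with
    Benjamini-Hochberg adjustment, canonical miRNA seed-match target
    prediction, Spearman-correlation screening with a shared-miRNA
    hypergeometric test and connectivity ranking, hypergeometric
    over-representation analysis, and synthetic-data generators with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
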