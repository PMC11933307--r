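Package: iuorfscan
Title: Detection of Internal Upstream Open Reading Frames Repressing
    Truncated Proteoforms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans mRNA sequences for short internal out-of-frame open
    reading frames (iuORFs) positioned immediately upstream of, or
    overlapping, internal in-frame translation initiation sites that
    drive N-terminally truncated proteoforms. Provides Kozak-context
    classification of start codons, cross-species conservation analysis
    of the cis-element features (contexts, ORF length, intercistronic
    spacer), plate-screen Z-score hit calling with a Shapiro-Wilk
    normality gate and Benjamini-Hochberg FDR, a delta-delta-Ct
    translation-initiation index for harringtonine ribosome-protection
    qPCR readouts, and a certified synthetic-data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
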