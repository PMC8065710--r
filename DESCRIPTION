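Package: gtais
Title: A Goedel-Turing-Post Model of the Adaptive Immune System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An executable recursion-theoretic model of adaptive immunity.
    Gene codes are programs in a small concatenative stack language with a
    bijective Goedel numbering; online self-assembly is self-application
    (Diag), the thymic mirror is the s-m-n meta-index sigma(g,g), V(D)J
    receptor motifs are two-place sigma indices filtered by positive and
    negative selection, and detection of a novel negator antigen is a
    synchronized fixed-point ("Goedel sentence") match between a released
    receptor motif and the peripheral MHC meta-index. Includes knockout
    scenarios (interferon-gamma, AIRE), a dovetailed bounded enumeration of
    listable code sets, productive-function antibody construction, and a
    reproducible scenario runner with JSON/JSONL/TSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
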