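Package: asmforge
Title: Reference-Assisted Genome Assembly Curation, Synteny Analysis and
    Consensus Positive-Selection Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating draft genome assemblies with long-read and
    mate-pair evidence and for downstream comparative analyses. Implements
    in-silico size selection of gel-free mate-pair libraries, junction
    validation by spanning long-read support with splitting of unsupported
    joins, contig-end link-graph scaffolding with a reference-synteny guard,
    detection and merging of large end overlaps between neighboring contigs,
    synteny-block chaining with chromosome anchoring and rearrangement
    counting, assembly quality control (telomeric repeat detection, N50
    statistics, linkage-map concordance), and a consensus caller for
    positively selected genes over four branch-site tests with
    hypergeometric gene-set enrichment. A synthetic-data module generates
    every input with planted truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
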