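Package: DenovoAnnotate
Title: Annotation and Quality Control of De Novo Transcriptome Assemblies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-assembly annotation and quality-control toolkit for de novo
    transcriptome assemblies of the 454/Newbler kind (isotigs, isogroups,
    singletons). Provides redundancy removal of contained assembly products,
    reciprocal-best-BLAST-hit orthology assignment with region-aware
    multi-assignment and isoform/paralog classification, ortholog-hit-ratio
    completeness analysis, gene-discovery saturation curves, category and
    protein-domain composition analyses, assembly summary statistics
    (N50, coverage, length distributions) and Welch's t-test comparisons.
    A synthetic ground-truth generator with planted homology, isogroup
    structure, duplicates and emulated BLAST tabular hit tables makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
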