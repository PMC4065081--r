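Package: venomics
Title: Venom-Gland Transcriptome Annotation and Toxin Evolution Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing venom-gland cDNA sequence data from disulfide-rich
    peptide toxins, modelled on tarantula (huwentoxin, HWTX) transcriptomes. Provides
    a ground-truthed synthetic read simulator, a high-stringency exact-overlap read
    assembler, similarity-based five-category transcript classification, toxin
    precursor segmentation (signal peptide, propeptide, mature peptide) driven by a
    bundled signal-peptide catalog and the processing quadruplet motif, cysteine
    framework extraction and pattern classification, superfamily/family/subfamily
    taxonomy by nested sequence-identity clustering, mutational variant-event calling
    and expression tiers, Nei-Gojobori dN/dS with Jukes-Cantor correction and
    Fisher exact tests for positive selection, neighbor-joining trees with bootstrap
    support, and an end-to-end resumable pipeline with a reporting layer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
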