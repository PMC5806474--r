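Package: varseg
Title: Pedigree-Aware Variant Annotation and Inheritance-Model Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained exome/genome variant prioritisation pipeline for
    family studies. Reads one VCF per individual together with a PED pedigree,
    annotates every variant in-line with gene context (exon, intron, essential
    splice site, UTR, promoter), codon-level functional consequence, and
    base-count zygosity while preserving the VCF format at every stage; offers
    a chainable battery of single- and multi-file filters (physical location,
    read depth, call quality, mutation type, population allele frequency,
    novelty, same-variant, same-gene); and screens surviving variants under
    five trait-penetrance models (autosomal dominant incl. de novo, autosomal
    recessive with compound-heterozygote detection, X-linked dominant and
    recessive with hemizygous-male handling, and mosaicism by allele-fraction
    window). A resumable, provenance-hashed pipeline engine chains the stages
    and renders an HTML/TSV report; a deterministic simulator generates toy
    genomes, gene maps and pedigree-linked family VCFs with planted causal
    variants for every inheritance model so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    IRanges,
    methods,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
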