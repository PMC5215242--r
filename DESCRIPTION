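Package: octadRecomb
Title: Meiotic Recombination Event Inference from Octad Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genome-wide meiotic recombination events from octad
    sequencing of polymorphic hybrid yeast meioses, in which the two daughter
    cells of each of the four spores are sequenced so that all eight DNA
    strands of one meiosis are recovered. Converts per-SNP read counts into
    strand genotype calls with read-count validity thresholds, segments the
    eight-strand genotype matrix into crossover and noncrossover events,
    classifies retained heteroduplex DNA tracts (full conversion, SDSA-like,
    trans and symmetric heteroduplex), measures gene-conversion tract lengths
    under several conventions, and estimates crossover interference by
    maximum-likelihood fitting of a gamma model to inter-crossover distances.
    A strand-resolved meiosis simulator with known ground truth makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    VariantAnnotation,
    SummarizedExperiment
biocViews: Genetics, SNP, Sequencing, Coverage, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluate.R'
    'genotyping.R'
    'inference.R'
    'io.R'
    'octadRecomb-package.R'
    'pipeline.R'
    'stats-interference.R'
    'stats-tests.R'
    'summarize.R'
    'synthetic.R'
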