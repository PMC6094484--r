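Package: lncrnakit
Title: Long Noncoding RNA Discovery and Characterization from Stranded RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and characterizes long noncoding RNAs (lncRNAs) from
    assembled stranded RNA-seq transcript models in compact fungal genomes.
    Implements novel-transcript class-code assignment against a reference
    annotation, a trainable coding-potential model (longest ORF, Fickett
    TESTCODE statistic, hexamer usage bias combined by logistic regression
    with a two-graph ROC decision threshold), stage-wise expression
    statistics (TMM-normalized CPM/RPKM, moderated differential expression,
    stage-specificity ratios, coexpression modules with soft thresholding),
    antisense/neighbor genomic context analysis, small-RNA cluster calling
    from 5'-U reads, and detection of Xrn1-sensitive unstable transcripts
    from wild-type versus exonuclease-deletion experiments. A synthetic-data
    module generates genomes, annotations, count matrices and small-RNA
    alignments with planted ground truth so that every stage of the pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
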