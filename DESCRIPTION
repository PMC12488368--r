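Package: dyadtrack
Title: Mother-Infant Gut Microbiome Vertical Transmission Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis of 16S rRNA amplicon sequence variant (ASV)
    count tables from mother-infant dyad cohorts with gestational diabetes
    mellitus (GDM) and control groups. Provides readers and validators for
    ASV tables (TSV and BIOM-style JSON), taxonomy and dyad metadata;
    alpha/beta diversity, ordination (PCoA, NMDS) and pairwise PERMANOVA on
    Bray-Curtis dissimilarity; negative-binomial Wald differential abundance
    with a log2-fold-change/FDR marker selection rule; core-microbiome
    identification and tracking; per-dyad vertical-transmission bookkeeping
    (shared, unique, retained and contributed ASVs); expectation-maximization
    microbial source tracking with an unknown source; and a Dirichlet-
    multinomial synthetic dyad-cohort generator with ground truth for
    end-to-end validation. A config-driven pipeline runner produces a
    reproducible report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
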