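Package: cisdtools
Title: Sequence and Structure Analysis of CDGSH Iron-Sulfur Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection, classification, phylogenetic profiling and structural
    comparison of CDGSH iron-sulfur domains (CISDs), the small protein domains
    that bind a [2Fe-2S] cluster through a 17-residue CDGSH motif with an
    atypical 3-Cys/1-His ligation. Provides a degeneracy-aware scanner for the
    consensus motif and the lid-proline (P) motif, a rule-based classifier for
    the seven CISD types and the DUF1271-fusion subtypes, species-deduplicated
    phylogenetic distribution tables with a within-genus gene-loss statistic,
    and structural geometry: [2Fe-2S] cluster detection and ligand assignment,
    iron-sulfur binding module extraction, Kabsch superposition, inter-cluster
    distances and module shift angles, Shrake-Rupley solvent-accessible surface
    areas and buried interfaces, hydrogen bonds, close contacts and pseudo-dyad
    symmetry. A synthetic-data generator plants motifs, domain architectures
    and dimeric coordinate sets with known ground truth so the whole pipeline
    is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
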