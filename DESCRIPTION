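Package: myoevo
Title: Evolution of the Eukaryotic Myosin Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of the myosin gene family
    across eukaryotic genomes: parsing of protein domain annotations and
    selection of motor-domain proteins, canonicalisation and comparison of
    domain architectures, clade-based assignment of sequences to myosin
    classes on support-annotated gene trees, presence/absence matrices at
    class, subclass and type granularity, Dollo (single-gain, minimal-loss)
    reconstruction of ancestral myosin repertoires on a rooted species tree
    with named ancestors and alternative rootings, concurrent-domain
    diversity summaries and Venn partitions, detection of convergent
    domain-architecture acquisition, and a seeded simulator of gain/loss
    histories, evolving architectures and gene trees for end-to-end
    validation. Ships a curated census of 31 myosin classes across 62
    eukaryotic genomes in 14 lineage groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
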