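# myoevo

Comparative-genomic analysis of the **myosin** gene family — the
actin-based motor proteins of eukaryotes — from raw domain annotations to
ancestral repertoires.

Myosin paralog families ("classes", e.g. myosin II, myosin V) are defined
by phylogenetic affinity: clades in a gene tree of the shared motor domain
(Pfam PF00063). Their presence and absence across genomes, mapped onto a
rooted species tree under **Dollo parsimony** (each family gained once,
lost freely afterwards), reconstructs the myosin complement of key
ancestors — LECA (the last eukaryotic common ancestor), LBikCA, LACA, LOCA
and LHolCA. For a family observed in leaf set *P*, the gain sits on the
branch above MRCA(*P*), every maximal empty subtree below the MRCA takes
one loss, and that loss set is the provable minimum for the pattern.

The package provides, for users studying gene-family evolution across
genomes:

* parsing of domain-scan tables (`pfamscan15` and `simple6` dialects),
  motor-protein extraction, clan-overlap resolution, and canonical domain
  architectures with repeat-insensitive comparison
  (`read_domain_annotations()`, `extract_target_proteins()`,
  `resolve_overlaps()`, `canonical_architecture()`);
* clade-based class assignment on support-annotated gene trees and
  presence/absence matrices at class/subclass/type granularity
  (`assign_by_clade()`, `build_presence_matrix()`,
  `aggregate_granularity()`);
* Dollo reconstruction with named ancestors and alternative rootings
  (`dollo_reconstruct()`, `ancestor_complement()`, `gains_losses_table()`,
  `compare_rootings()`);
* concurrent-domain diversity, Venn partitions, and detection of
  convergently acquired architecture signatures (`concurrent_domains()`,
  `diversity_summary()`, `venn_partition()`,
  `detect_convergent_architectures()`);
* a seeded simulator of gain/loss histories, evolving architectures and
  gene trees for end-to-end validation (`simulate_repertoire()`,
  `simulate_architectures()`, `simulate_gene_tree()`), with a closed-form
  recovery calibration (`expected_gain_recovery()`);
* a packaged census of 31 myosin classes across 62 eukaryotic genomes in
  14 lineage groups, with species tree and rootings
  (`myoevo_fixture()`), and a one-call orchestration of all stages
  (`run_pipeline()`).

## Worked example: the ancestral myosin toolkit

```r
library(myoevo)

rec <- fixture_reconstruction(granularity = "type")
rec
#> Dollo reconstruction: 14 units on 19 leaves
#>   gains: 14 (one per observed unit), losses: 52
#>   root complement: I, If, II, IV, V-like, VI

ancestor_complement(rec, "LACA")
#> [1] "I"          "If"         "II"         "IV"         "MyTH4-FERM"
#> [6] "V-like"     "VI"

head(summary(rec), 4)
#>         unit gain_branch n_losses n_present_leaves
#> 1          I        ROOT        8                9
#> 2         If        ROOT        9                6
#> 3         II        ROOT        5                8
#> 4 MyTH4-FERM        LACA        1                8
```

Reading: at the type granularity the census resolves into 14 ancestral
paralog types. Six of them — myosin I, If, II, IV, the V-like progenitor
and myosin VI — are present on both sides of the unikont–bikont root, so
their single Dollo gain lands on the root: **the last eukaryotic common
ancestor already carried six myosin types**, each with a distinct domain
architecture. The amorphean ancestor (LACA) adds the MyTH4-FERM type
(`gain_branch = "LACA"`), whose single loss reflects lineages that
discarded it. The 52 losses across 14 units quantify how much of myosin
evolution is secondary reduction — including the complete toolkit losses
in metamonads and rhodophytes.

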