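# rmcensus

Census, classification and persistence analysis of restriction–modification
(RM) systems across completely sequenced prokaryotic genomes, with a focus
on archaea.

RM systems pair a restriction endonuclease (REase) with a DNA
methyltransferase (MTase) writing m6A, m4C or m5C marks. Surveying them
across a genome collection answers two kinds of question. First, the
census: how many genes of each functional category (Type I M/R/S, Type II
MTase and REase, fused Type IIG, Type III Mod/Res, methyl-directed Type IV,
BREX-associated MTases, control proteins, Vsr nucleases) does an average
genome of each taxon carry, and do observed methylome motifs reconcile with
the predicted MTase genes? Second, persistence: which MTase families break
the usual pattern of horizontally scattered, rapidly gained-and-lost
defence genes and are instead conserved vertically — present in at least
75% of the members of a taxon with at least five sequenced genomes —
suggesting an epigenetic, regulatory role rather than a defensive one?

The package implements the full pipeline as composable functions with an
analysis workflow on top:

- **`genome_select`** — completeness filtering of a strain manifest
  (`filter_complete()`): keep `complete_genome`-flagged records, drop WGS
  assemblies, sequences under 500 kb and unfinished projects, in that order.
- **`cluster`** — exact greedy centroid clustering of protein sequences at a
  fractional-identity threshold (`greedy_cluster()`, `pairwise_identity()`
  under global BLOSUM62 alignment; identity = identical pairs / alignment
  columns).
- **`classify`** — position-specific profile models built from training
  alignments (`build_profile()`), ungapped best-window log-odds scoring
  (`score_profile()`), top-hit classification with a null-calibrated bit
  threshold (`classify_gene()`, `calibrate_threshold()`), methylation-type
  assignment (`assign_meth_type()`) and fused-domain detection
  (`detect_fused_domains()`).
- **`census`** — locus typing from gene adjacency (`type_loci()`),
  per-taxon mean-genes-per-genome tables (`census_by_taxon()`,
  `census_total()`), methylation-type gene/motif censuses with
  reconciliation flags (`meth_census()`) and the m6A:m4C:m5C ratio
  (`meth_ratio()`).
- **`persistence`** — presence/absence matrices over the taxonomy
  (`presence_matrix()`), the 75%/5-genome rule (`persistent_at()`),
  neighbor-joining homologous-group refinement with monophyly reassortment
  (`nj_tree()`, `refine_hgs()`) and most-inclusive-taxon reporting
  (`persistence_report()`, `persistence_evaluate()`).
- **`rims_motif`** — m5C site calling from paired-read C>T deamination
  counts (`call_m5c_sites()`; one-sided Fisher's exact test of read1 vs
  read2 rates with BH control) and exhaustive C-anchored k-mer motif
  discovery with IUPAC consolidation (`find_motifs()`), which recovers
  CCWGG from a simulated heterologous-host validation.
- **`synthetic_data`** — a generator for taxonomies, gene families,
  sequences, methylomes and deamination tables with complete ground truth
  (`generate_taxonomy()`, `plant_families()`, `emit_family_sequences()`,
  `emit_methylome()`, `emit_rims_counts()`), so every stage is testable
  without external databases.

Three plain-text reference tables with the published per-taxon summaries
for the 519 complete archaeal genomes in REBASE ship under `inst/extdata/`
(`read_survey_table()`).

## Worked example

Aggregate the published phylum rows of the archaeal methylation census into
the overall per-genome MTase gene means and ratio:

```r
library(rmcensus)
t2 <- read_survey_table("meth_census")
phyla <- t2[t2$rank == "phylum", ]
tot <- census_total(data.frame(n_genomes = phyla$n_genomes,
                               m6A = phyla$genes_m6A,
                               m4C = phyla$genes_m4C,
                               m5C = phyla$genes_m5C))
round(tot, 3)
#>   n_genomes   m6A   m4C   m5C
#> 1       519 2.707 1.347 0.665
format_ratio(meth_ratio(tot))
#> [1] "4:2:1"
```

An average archaeal genome carries 2.7 m6A, 1.3 m4C and 0.7 m5C MTase
genes — the 4:2:1 ratio — and the weighted aggregation reproduces the
published TOTAL row exactly.

Simulate an m5C clone validation and recover the motif from deamination
counts alone:

```r
sim <- emit_rims_counts(genome_length = 60000, motif = "CCWGG",
                        methylated_offset = 1, methylation_fraction = 1,
                        background_rate = 0.005, m5c_rate = 0.1,
                        coverage = 100, seed = 88)
sites <- call_m5c_sites(sim$table, min_coverage = 10, fdr = 0.05)
nrow(sites)
#> [1] 263
find_motifs(sites, sim$genome)[1, ]
#>   motif offset support n_sites fold_enrichment p q
#> 1 CCWGG      1     130     256             112 0 0
```

263 cytosines show significantly elevated read1 deamination; the motif scan
reports CCWGG with the methylated C at offset 1 (the second C), supported by
130 duplex sites at ~112-fold enrichment — the Dcm-like signature.

## The analysis workflow

`analysis/01_simulate_world.R` … `07_rims_motif.R` run the whole pipeline
on a 120-strain synthetic community (six unevenly sized classes, six
planted persistent MTase families, eighteen sporadic families, 10%
methylome availability) and write their tables under `results/`:
completeness filtering (01–02), clustering at 30% identity (03, recovers
the 24 planted families exactly), profile classification (04, category and
methylation-type accuracy 1.000 against ground truth), the per-taxon
censuses with reconciliation (05), persistence detection (06, reports the
six planted persistent families at their home classes and nothing else)
and the CCWGG recovery above at 200 kb (07). Each script is a thin driver
over the package functions and states what it found on stderr.

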