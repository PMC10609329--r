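---
title: "Methods: surveying restriction-modification systems across genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying restriction-modification systems across genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmcensus)
```

# The problem

Restriction-modification (RM) systems are the classic prokaryotic defence
against foreign DNA: a restriction endonuclease (REase) cleaves unmodified
recognition sites and a cognate DNA methyltransferase (MTase) protects the
host's own sites with N6-methyladenine (m6A), N4-methylcytosine (m4C) or
C5-methylcytosine (m5C). A census of RM genes across a set of completely
sequenced genomes — how many genes of each functional category per genome,
in which taxa, with which observed methylome motifs — reveals both the
churn of horizontally transferred defence systems and the quieter signal of
*persistent* orphan MTases: families conserved vertically within a taxon,
which usually indicates an epigenetic role beyond defence (the textbook
examples are Dam/GATC and CcrM in proteobacteria, and CTAG methylation in
Halobacteria).

`rmcensus` implements that census as a tested pipeline: completeness
filtering of a strain manifest, greedy centroid clustering of RM-gene
proteins, profile-based functional classification, per-taxon census tables
with gene/motif reconciliation, persistence detection with
neighbor-joining refinement of homologous groups, and m5C motif discovery
from RIMS-seq-style paired-read deamination counts. Because the underlying
gene databases cannot be redistributed, the package also contains a
synthetic community generator with full ground truth; every downstream
stage is tested against worlds whose right answers are known by
construction. Three small reference tables with the published per-taxon
summaries for the 519 complete archaeal genomes in REBASE ship with the
package (`read_survey_table()`), and the aggregation arithmetic is checked
against them.

# The synthetic community generator

The generator defines the study conditions for every test; its defaults are
chosen once, on first principles, and the tests inherit them.

**Taxonomy** (`taxonomy_spec()`, `generate_taxonomy()`). Strains sit in a
ranked taxonomy (phylum, class, order by default). Clade sizes may be
uneven, which matters: real collections of complete genomes are dominated by
a few heavily sequenced classes (six classes cover 92.5% of the archaeal
set), and the persistence rule's 5-genome floor makes the census sensitive
to exactly this unevenness. The workflow's default world has 120 strains in
6 classes with order sizes from 4 to 20 and 10% methylome availability
(close to the 49/519 seen in archaea).

**Gene families** (`family_spec()`, `plant_families()`). A family is either
*persistent* — present in each strain of one home taxon independently with
probability equal to its presence rate — or *sporadic* — present in any
strain of the manifest at a (low) rate, emulating the patchy distribution
left by horizontal transfer and loss. Presence is sampled independently per
strain rather than by gain/loss on a tree: the persistence statistic only
consumes incidence fractions, so the simpler model exercises the same code
with analytically checkable binomial behaviour. This is a stand-in, not an
inference claim about real gain/loss dynamics.

**Sequences** (`emit_family_sequences()`). Each family has a
uniform-random ancestor (default 300 residues); members substitute each
position independently with probability *d* (the divergence), replacing the
residue uniformly among the 19 alternatives. Two members then agree at a
position with probability $(1-d)^2 + d^2/19$, which the tests verify at
*d* = 0.2 over 200 replicate pairs. No indels are emitted by default, so
the trivial columnwise alignment is exact and identity expectations stay
closed-form; an indel-emitting extension would trade that away for realism.

**Methylomes** (`emit_methylome()`). Every active MTase gene contributes
its family motif to its strain's observed-motif list unless silenced
(default silencing 10% in the workflow), and m5C motifs are additionally
dropped at one minus the m5C detection rate (default 30% detected,
reflecting how poorly SMRT kinetics detect m5C). An `extra_motifs` hook
injects motifs with no gene behind them — the "missing plasmid" scenario —
so the reconciliation stage has something to flag.

**Deamination tables** (`emit_rims_counts()`). For an m5C clone validation,
every cytosine on both strands of a random genome receives binomial
read1/read2 C>T counts at a background deamination rate (default 0.5%),
except read1 at methylated motif cytosines, which uses the elevated m5C
rate (default 10%). Methylation is sampled per duplex instance, so both
strands of a palindromic site are methylated together, and a palindromic
site counts once per duplex in motif support. Defaults (200 kb genome,
100x per-strand coverage) are the scale of the packaged workflow and of the
acceptance run.

# Design choices in the analysis stages

**Completeness filter.** Records flagged `complete_genome` are always
kept. Among the rest the rules fire in a fixed order — whole-genome
shotgun, then longest sequence < 500 kb (500,000 bp exactly is kept, a
literal reading of "less than 500 kb"), then project status — so each
rejection has a single deterministic primary reason. The source procedure
does not state a precedence; fixing one is a repository decision.

**Clustering.** `pairwise_identity()` is exact global Needleman-Wunsch
under BLOSUM62 with gap open 11 / extend 1; identity is identical aligned
pairs over all alignment columns, gap columns included — one of several
defensible identity definitions, chosen because it is symmetric and easy to
oracle-check. `greedy_cluster()` replays length-sorted greedy centroid
clustering (the cluster_fast strategy) with fixed tie-breaks (length
descending, then id), making results deterministic; a brute-force replay of
the definition serves as the oracle for inputs up to 12 sequences. No
k-mer prefiltering is attempted — exactness at desk scale beats speed, and
results on real data would differ slightly from heuristic tools.

**Classification.** A full profile HMM (insert/delete states, forward
algorithm) is deliberately replaced by an ungapped best-window log-odds
score over the alignment's match columns (those with at most 50% gaps,
+1 pseudocount emissions against a uniform background). This is
deterministic, enumerable by a brute-force oracle, and sufficient for
well-separated families; the operation signature would admit a drop-in
full-HMM scorer. The call threshold is not hand-picked: it is the 99.9th
percentile of best-hit scores over a seeded null of 1000 random sequences
(`calibrate_threshold()`). Cluster centroids are classified and calls
propagate to members. Fused double-MTase genes are found as disjoint
above-threshold windows (`detect_fused_domains()`). The default shipped
library is synthetic (random ancestors) and is for pipeline testing only;
it bakes in the conventional typing of the ambiguous families (`b1a`,
`lmoa118-like`, `nru-like` as m6A; `b3` as m4C).

**Census.** Means are exact ratios (total genes / genomes), with rounding
left to presentation; aggregation must satisfy, and is tested to satisfy,
the weighted-mean identity between child and parent rows. Motif means are
computed only over genomes with methylome data, and taxa with no such
genomes get blank (NA) cells rather than zeros — an important distinction
when flagging taxa where motifs exceed genes, which is only meaningful
within the methylome subset. The m6A:m4C:m5C ratio normalizes to m5C = 1
(falling back to m4C with a warning when the m5C mean is zero, the
convention used for bacterial sets where m5C outnumbers m4C).

**Persistence.** The rule is strict: a family is persistent in a taxon of
at least 5 genomes when present in at least 75% of them. Survey practice
admits "nearly so" members; rather than silently loosening the rule, a
separate near-persistent tier reports families within 10 percentage points
below the threshold in an evaluable taxon, and enumerations of
persistent systems include both tiers. Records are reported at the most
inclusive passing taxon with descendants suppressed, which is what keeps a
phylum-wide family from being re-reported in every child order.
Homologous-group refinement merges clusters that share a best-hit profile
at centroid identity >= 0.20 (plus an explicit override list, standing in
for manual curation), builds a neighbor-joining tree on p-distances
(1 - identity), and reassorts members into maximal label-homogeneous
split sides with at least two leaves; singleton homogeneous leaves — for
example one horizontally transferred migrant inside a foreign clade — go
to the residual subgroup rather than becoming one-member "clades".
Neighbor-joining is the standard agglomeration (via `ape`), validated
against exact recovery of additive metrics.

**m5C site calling.** Per cytosine, a one-sided Fisher's exact test asks
whether the read1 C>T rate exceeds the read2 rate, with Benjamini-Hochberg
control across positions. The reference arm of the 2x2 table is, by
default, the read2 counts pooled across all eligible positions: read2
never carries the methylation signal, so the genome-wide read2 pool
estimates the shared background rate with high precision. This choice is
what gives the test per-position power — at 100x coverage a local
10-versus-0 table is barely significant on its own, while 10 of 100
against a pooled 0.5% background is decisive (measured sensitivity ~0.97
at the default simulation parameters, with false positives well under 1%
of background cytosines). `background = "local"` restores the literal
per-position comparison for users who want the fully unpooled test. The
exact test is computed as a vectorized hypergeometric tail, identical to
`fisher.test(alternative = "greater")` (cross-checked in the tests).

**Motif discovery.** An exhaustive C-anchored k-mer scan (k = 3..8 by
default) counts each context k-mer over called sites against its
genome-wide frequency among cytosines (one-sided binomial). The
multiple-testing family is every C-anchored k-mer present in the genome —
not merely the k-mers observed at sites, which would be a selection bias
that inflates false motifs on null data. Significant k-mers differing at
one non-anchor position with comparable support consolidate into IUPAC
degenerate motifs (CCAGG + CCTGG into CCWGG), fully degenerate ends are
trimmed, and near-redundant motifs (>= 80% of their sites covered by a
stronger motif) are dropped. Motifs rank by support times information
content, which is what puts the maximally specific full-support motif
first. Thresholds (FDR 0.05, minimum 3 supporting sites, k range) are
repository defaults; the source procedure names none.

# Numerical and degenerate-input conventions

Coordinates in deamination tables are 1-based with explicit strand; the
BED export is 0-based half-open. Motif offsets are 0-based indices into
the motif written on its own strand. Ties in classification break
lexicographically by profile name; ties in clustering by gene id; NJ uses
`ape`'s deterministic agglomeration, and the two-taxon case returns the
unique two-leaf tree. Zero-coverage positions are skipped with a message;
empty cluster input yields an empty partition; a single-sequence
"alignment" is rejected when building profiles. All simulator functions
take explicit seeds and restore the RNG state (`withr::with_seed`), so
identical seeds give byte-identical outputs.

# Problem sizes used by the tests and the acceptance script

The suite runs desk-scale versions of every property: clustering oracle
equivalence on seeded inputs of up to 12 sequences; classification
recovery with 8 families at divergence 0.3 (160-625 held-out genes)
against a 1000-sequence calibrated null; NJ recovery for 4-8 taxa;
persistence sensitivity/false-flag rates over 50 worlds of 80 strains with
5 persistent (rate 0.9) and 20 sporadic (rate 0.2) families; m5C calling
and CCWGG recovery on 60-200 kb genomes at 100x; and census conservation
on 100 random worlds. These sizes were chosen as the smallest that make
the binomial tolerances tight enough to be meaningful.

# What passing tests do and do not show

The synthetic worlds have no indels, no gene fragments or pseudogenes, no
compositional bias, no correlated presence between families, and
classification families are mutually unrelated random ancestors — far
better separated than real MTase subfamilies, some of which differ in
methylation type at high sequence similarity. Recovery rates here
therefore validate the *machinery* (the statistics, the bookkeeping, the
rule logic), not the expected accuracy on real REBASE-scale data, where
alignment heuristics, under-annotated REase families and HMM library
curation dominate the error budget. The same caveat applies in reverse to
the shipped survey tables: the package reproduces their internal
arithmetic (weighted totals, ratios, rule counts) exactly, but does not —
and cannot, offline — re-derive them from primary sequence data.

# Known limitations

Greedy clustering is quadratic in the worst case and meant for thousands,
not millions, of sequences. The ungapped window score degrades for
families with long indels. Taxon labels are matched by name within a rank,
so two different clades must not share a name at the same rank (generated
manifests guarantee this by construction; externally supplied manifests
should too, or "unclassified" groups will merge). The motif consolidator
only merges same-length, same-offset k-mers, so gapped or bipartite motifs
(Type I-style `GCANNNNNNTGC`) are reported as their significant half-sites
rather than as one spaced motif.
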