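# tcscensus

Census and classification of two-component signal transduction (TCS)
systems in archaeal genomes.

Two-component systems pair a sensor **histidine kinase** (HK) — a
HisKA/DHp dimerization domain plus a GHKL-superfamily ATPase domain
(HATPase_c) — with a **response regulator** (RR) carrying a phosphoacceptor
**receiver (REC)** domain, usually fused to an output module. Archaeal TCS
repertoires differ sharply from bacterial ones: stand-alone REC proteins and
REC–PAS/GAF fusions dominate, classical DNA-binding outputs are rare, and
several output domains are lineage-specific and previously undescribed.
`tcscensus` is for comparative genomicists who have per-protein domain hits
(HMMER3 `--domtblout` or a simple TSV), protein FASTA and GFF3 gene models,
and want a reproducible census: per-protein classification, candidate novel
output domains, REC active-site conservation, chemotaxis/neighborhood
context, and per-taxon summary tables.

## What it computes

* **Architecture resolution** — overlapping domain hits are reduced to a
  linear architecture by greedy e-value-ordered acceptance (a hit is kept
  iff it overlaps every kept hit by ≤ 30% of the shorter segment), with
  explicit unassigned gaps and canonical strings like
  `REC-(PAS)2-HisKA-HATPase`.
* **Classification** — the census counting rules: HisKA+HATPase → HK;
  HisKA alone → kinase-dead "HisKA, no HATPase"; HATPase+Hpt/CheW → CheA-like
  HK; REC before the kinase core → RR (`REC_HisK`), REC after it →
  hybrid HK (counted among HKs); REC without HK domains → RR subclassed by a
  fixed output priority (CheB > HTH > HalX > enzymatic > novel output >
  PAS/GAF > REC-only > other). Divergent or truncated receivers (< 80 aa or
  < 60% reference coverage) keep their call but are excluded from totals.
* **Novel output domains** — unassigned regions ≥ 70 aa are harvested and
  clustered by pairwise alignment identity (≥ 30% over ≥ 70% of the shorter
  region, single linkage) into candidate families with contexts and
  taxon distributions.
* **REC active sites** — each receiver is aligned to the packaged 129-aa
  *E. coli* CheY reference; residues at positions 12, 13, 57, 87, 109 are
  reported and a phosphorylatability verdict applied (D57 plus ≥ 3 of the
  four auxiliary sites). Sequence-logo matrices give per-column frequencies
  and information `R = log2(20) − H` bits.
* **Census & neighborhoods** — per-taxon tables with HK/RR counts, REC-only
  percentages (rounded half away from zero) and totals; per-genome RR/HK
  ratios and ORF fractions; Kyte–Doolittle TM prediction (window 19,
  cutoff 1.6) and cytoplasmic-HK fractions; operon and divergent-pair calls
  from strand geometry and intergenic distance; chemotaxis association of
  REC-only RRs near CheA-like or CheB genes.
* **Synthetic genomes** — `generate_genomes()` produces
  haloarchaea-/methanogen-/thaumarchaea-like genomes with complete ground
  truth (categories, subclasses, phosphorylatability, chemotaxis flags,
  membrane status, planted novel-domain families), so the whole pipeline is
  testable without downloads.

## Worked example

Simulate two haloarchaea-like genomes, classify, and build the census:

```r
library(tcscensus)

sim   <- generate_genomes(builtin_profile("haloarchaea", n_genomes = 2, seed = 7))
archs <- resolve_architectures(sim$hits, sim$proteins)
calls <- classify_all(archs, proteins = sim$proteins)
calls <- find_neighbors(sim$features, calls)$calls

taxonomy <- data.frame(genome_id = unique(sim$proteins$genome_id),
                       taxon = "Halobacteria-like")
format_census(build_census(calls, sim$proteins, taxonomy))
```

```
             taxon n_genomes n_proteins n_HK n_HisKA_no_HATPase n_RR n_REC_only n_HTH pct_REC_only
 Halobacteria-like         2        156   17                  1   49          9    12           18
             Total         2        156   17                  1   49          9    12           18
```

156 proteins yield 17 HKs (hybrid HKs included), one kinase-dead HisKA-only
protein, and 49 RRs, of which 9 are stand-alone receivers (18%) and 12 carry
DNA-binding HTH outputs — the haloarchaeal pattern of few REC-only but many
Bat-type regulators. The RR subclass breakdown and HK sensor statistics:

```r
table(calls$rr_subclass[calls$category == "RR"])
#>  CheB  REC_HalX  REC_HisK  REC_novel_OD  REC_only  REC_PAS_GAF  transcriptional_HTH
#>     1         6         7            13         9            1                   12

st <- sensor_tally(calls, archs)
sprintf("HKs with PAS and/or GAF: %.0f%%; cytoplasmic HKs: %.0f%%",
        st$pct_PAS_or_GAF, membrane_fraction(calls)$pct_cytoplasmic)
#> "HKs with PAS and/or GAF: 65%; cytoplasmic HKs: 76%"
```

Single architectures classify directly:

```r
classify_architecture(architecture_from_string("REC-PAS-GAF-BAT-HTH_10"))[, 1:3]
#>  protein_id category         rr_subclass
#>          p1       RR transcriptional_HTH
```

A command-line front-end (`inst/scripts/tcscensus.R`) exposes the stages as
subcommands (`classify`, `census`, `novel-domains`, `rec-sites`,
`neighborhoods`, `simulate`) over a YAML config, writing TSV outputs plus a
JSON run manifest.

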