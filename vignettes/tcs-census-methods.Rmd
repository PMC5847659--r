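---
title: "Methods: censusing archaeal two-component systems from domain evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing archaeal two-component systems from domain evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcscensus)
```

## The problem

Two-component signal transduction (TCS) systems couple a sensor histidine
kinase (HK) — a dimerization/phosphoacceptor domain (HisKA/DHp) plus a GHKL
ATPase domain (HATPase_c) — to a response regulator (RR) carrying a
phosphoacceptor receiver (REC) domain, usually fused to an output module.
In archaea these systems are unevenly distributed across lineages and their
output domains differ sharply from the familiar bacterial repertoire: most
archaeal RRs are either stand-alone REC domains or REC fused to PAS/GAF
ligand-binding domains, while classical DNA-binding outputs are rare and
several outputs are lineage-specific and previously undescribed.

`tcscensus` turns the census methodology for this setting into a tested
pipeline: starting from per-protein domain hits (HMMER3 `--domtblout` or a
TSV dialect), protein FASTA and GFF3 gene models, it

1. resolves overlapping hits into a linear domain architecture,
2. classifies each protein into HK / hybrid HK / kinase-dead
   (HisKA, no HATPase) / RR classes and RR output subclasses,
3. harvests long unassigned regions and clusters them into candidate novel
   output-domain families,
4. scores REC active-site conservation against a CheY reference and builds
   sequence-logo matrices,
5. aggregates per-genome and per-taxon census tables and analyses gene
   neighborhoods, chemotaxis operons and membrane localization.

A synthetic-genome generator with complete ground truth validates every
stage end to end.

## Architecture resolution

Raw hits for one protein may overlap (the same region matched by related
models from different databases). `resolve_hits()` accepts hits greedily in
order of ascending e-value (ties: descending bit score, then ascending
start); a hit is accepted iff it overlaps every previously accepted hit by
at most 30% of the shorter of the two. Segments are never trimmed —
within-tolerance overlaps are kept as reported — and the final order is by
start coordinate. The 30% tolerance mirrors common Pfam-clan practice for
near-duplicate hits; it is a package convention (exposed as `overlap_tol`)
because the original census resolved such cases by manual curation. Envelope
coordinates are used because they bound the region that must be masked when
hunting for novel domains. For eight or fewer hits the greedy result is
provably identical to a brute-force application of the acceptance rule
(enumerating maximal compatible subsets and taking the priority-minimal
one), and the test suite asserts this equivalence on randomized cases.

Unassigned gaps are the complement of the accepted segments within
`[1, length]`. Architecture strings join segment names with dashes;
consecutive repeats collapse to `(NAME)k`, and gaps of at least 70 aa can be
rendered as `X` placeholders.

## Classification rules

The cascade in `classify_architecture()` applies the census counting
conventions:

* **No REC, no HK domains** — not a TCS protein.
* **HK domains without REC** — HisKA + HATPase is an HK; HisKA alone is the
  kinase-dead *HisKA, no HATPase* class (dimerization domain with the
  conserved His but no ATPase); HATPase with Hpt and/or CheW but no HisKA is
  a CheA-type chemotaxis kinase (flag `cheA_like`). A lone GHKL ATPase
  without any of these is treated as non-TCS, since isolated GHKL matches
  are typically gyrase/topoisomerase/MutL-like proteins.
* **REC together with HK domains** — position decides: a REC starting before
  the first kinase-core segment makes the protein an RR (subclass
  `REC_HisK`); a REC starting after the last core segment makes it a hybrid
  HK, which the census counts among HKs. "N-terminal" and "C-terminal" are
  thus defined relative to the kinase core, not by absolute residue
  position, which matches every architecture in the source tables without an
  arbitrary length cutoff. RECs flanking the core on both sides, or a REC
  strictly inside the core, are resolved with a warning (RR and hybrid HK
  respectively) because the original counting rule does not cover them.
* **REC without HK domains** — an RR, with subclass decided by a fixed
  priority over the non-REC segments: CheB methylesterase > DNA-binding HTH
  (BAT, HTH_10, wHTH, HxlR, ...) > HalX > enzymatic output (KaiC-like
  ATPase, BcsA glycosyltransferase, GGDEF, EAL, ...) > novel/unknown output >
  PAS/GAF-only > REC-only > other. The priority is fixed so the subclasses
  partition the RRs.

One deliberate extension: an RR whose architecture contains an unassigned
region of at least 70 aa (`novel_gap_min`) is assigned `REC_novel_OD` even
when no unknown segment is present, because the delineation procedure marks
exactly those regions as putative novel output domains. `REC_only`
therefore means a stand-alone receiver with at most short gaps.

The domain-role dictionary ships as an editable TSV covering the archaeal
TCS vocabulary. Its role set refines the coarse grouping of
"other outputs" into `output_halx`, `output_novel` (the provisional
HalOD/MetOD/NitrOD/TackOD/AcidOD families) and `output_other`
(MCPsignal, TPR-like, ...), because the classifier must distinguish these
subclasses. Unknown names map to role `unknown` rather than erroring, so
unannotated domains flow through to the novel-domain stage.

### Divergent receiver domains

Census totals exclude proteins whose REC domains are too degraded to count:
a REC segment shorter than 80 aa, or aligning to less than 60% of the
reference receiver, is flagged `excluded_divergent` (thresholds
`min_rec_len`, `min_rec_coverage`). The flag preserves the classification;
only the census aggregation omits the protein. The numeric thresholds are
package conventions — the original census excluded "highly divergent,
truncated and/or frameshifted" RECs without stating numbers.

## Novel output-domain delineation

`extract_unassigned()` harvests all maximal gaps of ≥ 70 aa (the one
threshold fixed by the method), annotated with flanking segment names; a
protein with no assigned domains at all contributes its whole chain, so
stand-alone members of unrecognized families stay eligible.
`cluster_regions()` computes pairwise end-gap-free (overlap) alignments with
BLOSUM62 and affine gaps (open 10, extend 0.5); two regions are linked iff
identity ≥ 30% over ≥ 70% of the shorter region, and families are the
connected components (single linkage), singletons included. The 30%/70%
thresholds are conventional remote-homology screen settings, exposed as
config, since the original clustering method is unstated; whether clustering
should be per-lineage or global is likewise unstated, and the package
clusters globally (per-lineage behaviour is obtained by subsetting the
input). Family reports give member counts, median lengths, the architecture
contexts with the family inserted (e.g. a family seen both stand-alone and
as a REC fusion lists both), and genome/taxon distributions.

## REC active-site conservation

`map_rec_positions()` aligns a receiver sequence globally
(Needleman–Wunsch, BLOSUM62, affine gaps) to the packaged reference — the
129-aa *E. coli* CheY (UniProt P0AE67), numbered with the initiator Met so
the canonical positions are Asp12, Asp13, Asp57, Thr87, Lys109 — and reports
the query residue aligned to each position, with `-` for unaligned.
Reported residues always come from the query, never the reference
(query-anchored convention). Alignments below 20% identity are treated as
non-alignable: coverage 0, all positions gapped.

The `phosphorylatable` verdict — Asp at position 57 plus at least 3 of the
4 auxiliary sites (12 ∈ {D,E}, 13 = D, 87 ∈ {T,S}, 109 = K) — is a package
rule, exposed as config (`min_auxiliary`), chosen as the simplest rule under
which the phosphoacceptor is strictly required while single auxiliary
losses, consistent with observed divergence of a substantial minority of
receiver domains, are tolerated.

`logo_matrix()` computes per-column residue frequencies over the 20 amino
acids with gaps excluded from the denominator (WebLogo's default behaviour)
and information `R = log2(20) − H` bits without small-sample correction.
An anchor row drops the columns where the anchor is gapped, reproducing
"query-anchored with letters for identities" trimming. All-gap columns get
information 0 with a warning. Closed forms pin the arithmetic: a pure
column gives log2(20) ≈ 4.322 bits, a uniform 20-residue column 0, a 50/50
two-residue column log2(20) − 1 ≈ 3.322.

## Census, membrane localization, neighborhoods

`build_census()` aggregates calls per taxon: HK counts include hybrid HKs
(the footnote convention), kinase-dead HisKA-only proteins are tallied in
their own column rather than among HKs (the original table does not state
where they were counted, so both tallies are reported), and REC-only
percentages are rounded to the nearest integer, half away from zero. A
totals row is the column-wise sum; zero counts render as dashes. The
printed per-taxon fixture (`fixture_table1()`) reproduces the published
totals — 2,139 HKs, 1,875 RRs, 740 REC-only, 116 HTH over 511,588 proteins —
and the four printed REC-only percentages (76, 23, 43, 77) under this
rounding. The printed genome counts themselves sum to 219 against a printed
total of 218 (the euryarchaeal rows sum to 150 against a printed 149); the
package reports the computed sum, keeping the conservation invariant, and
the acceptance checks assert the protein and TCS count columns, which are
internally consistent.

`predict_tm()` is a Kyte–Doolittle sliding-window predictor (window 19,
mean hydropathy > 1.6, overlapping windows merged) used as the fallback when
no precomputed TM table is supplied; `membrane_fraction()` reports the
percentage of HKs with no predicted TM segment, with HisKA-only proteins
excluded from the denominator and reported separately.

`find_neighbors()` replaces external operon databases with the standard
heuristic: adjacent co-oriented genes at intergenic distance
`start(downstream) − end(upstream) − 1 ≤ 200 nt` form operon links; adjacent
head-to-head genes (strands −,+ in coordinate order) are divergent pairs. A
REC-only RR within 5 genes of a CheA-like HK or a CheB RR inside one
co-oriented run is flagged `chemotaxis_associated`, operationalizing the
observation that chemotaxis receivers sit in che operons next to CheA/CheB.

## The synthetic generator

`generate_genomes()` draws each protein's architecture from a lineage
profile's frequency table and realizes it as sequence (10-aa hydrophilic
linkers between domain bodies), domain hits (clean emission: exactly one hit
per planted domain, none for planted novel regions), and gene models on one
contig per genome. The built-in profiles encode the lineage contrasts the
census describes: a haloarchaea-like profile rich in REC-HalX and Bat-type
REC-PAS-GAF-BAT-HTH_10 regulators with stand-alone HalOD1-like proteins and
membrane HisKA_7TM sensors; a methanogen-like profile with REC-(PAS)n
combinations, hybrid HKs, MEDS sensors and enzymatic outputs; and a
thaumarchaea-like profile in which 77% of RR-generating architectures are
stand-alone REC, matching the published REC-only share of that lineage.
Across profiles roughly 72% of HK architectures carry PAS and/or GAF.
TCS architectures are about half of each roster, so TCS genes are a few
percent of ORFs, as in TCS-rich archaeal genomes; non-TCS filler proteins
exercise the `not_TCS` path.

Design choices that make ground truth exact rather than probabilistic:

* REC bodies derive from the packaged CheY reference with 10% per-site
  substitution, the five active-site positions protected; deliberate
  D57N knockouts (rate `rec_site_knockout_rate`) are the only way a
  planted receiver becomes non-phosphorylatable, so phosphorylatability
  recovery is exact.
* All random residues (linkers, domain bodies, novel-domain plants) are
  drawn from a hydrophobe-poor alphabet, so the only sequences that can
  trigger the TM predictor are the deliberately planted hydrophobic
  stretches of the membrane sensor domains.
* Gene strands alternate except inside planted blocks: chemotaxis operons
  are co-oriented triples (CheA-like HK, CheB RR, REC-only RR) flanked by
  opposite-strand genes, and divergent pairs are planted head-to-head. This
  makes chemotaxis association deterministic, so flag recovery can be
  asserted at 100%.
* Tandem duplicates are adjacent same-strand copies of the preceding
  protein; REC truncation plants (45-aa receiver fragments) are recorded in
  the truth table and must be excluded by the divergent-REC rule in exact
  numbers.
* Everything flows from a single seed; the same seed reproduces the
  simulation byte for byte. Per-domain consensus sequences come from a
  private RNG stream keyed by the domain name, so they are stable across
  profiles and runs.

What the generator does not emulate — realistic codon usage or GC content,
phylogenetic correlation between genomes, noisy or missing domain hits,
frameshifts — bounds what the passing tests show: they validate the
pipeline's logic under clean evidence, not its robustness to annotation
noise, which in the original census was handled by manual curation.

## Problem sizes and numerical conventions

The test suite and the acceptance script run the full pipeline on roughly a
thousand synthetic proteins across the three lineage profiles (14 genomes of
60–80 proteins), a size at which every stage, including the quadratic
region-clustering step, completes in seconds while the binomial checks on
lineage fractions retain useful power (3σ on the REC-only share of ~70 RRs
is about ±15 percentage points). Alignment parameters are BLOSUM62 with gap
open 10 / extend 0.5 throughout; ties in hit resolution break by descending
score then ascending start for determinism; family ids are assigned in
protein-id order so clustering output is independent of input order;
percentages round half away from zero. Degenerate inputs are defined
throughout: empty hit files give empty tables, a taxon with no RRs renders a
dash rather than dividing by zero, all-gap logo columns report zero
information with a warning, and proteins lacking both TM data and sequence
are dropped from membrane denominators with a warning.

## Limitations

The package classifies from domain-hit evidence; it does not search
databases, build HMM profiles, or make remote-homology calls, so a protein
whose domains are absent from the hit table is invisible to it. Operon
calls use a distance/strand heuristic, not transcription data. The
genome-size correlation is validated only on synthetic profiles, and the
published whole-census figures that require the original 218 genomes are
represented by the packaged per-taxon fixture rather than recomputed from
sequence.
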