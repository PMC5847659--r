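# the synthetic-genome generator: determinism, ground-truth bookkeeping,
# planted truncations, and the census fixture

test_that("a pure REC profile yields only REC-only response regulators", {
  prof <- lineage_profile("pure_rec", n_genomes = 1,
                          proteins_per_genome = c(10L, 10L),
                          arch_freq = c(REC = 1),
                          tandem_duplication_rate = 0,
                          chemotaxis_operon_rate = 0,
                          rec_site_knockout_rate = 0, seed = 2)
  sim <- generate_genomes(prof)
  expect_equal(nrow(sim$truth), 10)
  expect_true(all(sim$truth$category == "RR"))
  expect_true(all(sim$truth$rr_subclass == "REC_only"))
  expect_true(all(sim$truth$phosphorylatable))
})

test_that("the same seed reproduces the simulation exactly", {
  s1 <- generate_genomes(builtin_profile("haloarchaea", seed = 99))
  s2 <- generate_genomes(builtin_profile("haloarchaea", seed = 99))
  expect_identical(s1, s2)
  s3 <- generate_genomes(builtin_profile("haloarchaea", seed = 100))
  expect_false(identical(s1$proteins, s3$proteins))
})

test_that("architecture frequencies must sum to one", {
  expect_error(lineage_profile("bad", arch_freq = c(REC = 0.5, PAS = 0.4)),
               "sum to 1")
  expect_error(lineage_profile("bad2", arch_freq = c(REC = 1),
                               mutation_rate = 1.5), "rates")
})

test_that("planted REC truncations are excluded in exact numbers", {
  prof <- lineage_profile("trunc", n_genomes = 2,
                          proteins_per_genome = c(40L, 40L),
                          arch_freq = c(REC = 1),
                          tandem_duplication_rate = 0,
                          chemotaxis_operon_rate = 0,
                          rec_truncation_rate = 0.25, seed = 7)
  sim <- generate_genomes(prof)
  res <- pipeline_calls(sim)
  expect_gt(sum(sim$truth$excluded_divergent), 0)
  expect_equal(sum(res$calls$excluded_divergent),
               sum(sim$truth$excluded_divergent))
  expect_equal(res$calls$excluded_divergent,
               sim$truth$excluded_divergent)
  # excluded proteins drop out of census totals
  taxonomy <- data.frame(genome_id = unique(sim$proteins$genome_id),
                         taxon = "trunc")
  cen <- build_census(res$calls, sim$proteins, taxonomy)
  expect_equal(cen$n_RR[cen$taxon == "Total"],
               sum(!sim$truth$excluded_divergent))
})

test_that("generated gene models are internally consistent", {
  sim <- generate_genomes(builtin_profile("methanogen", n_genomes = 2,
                                          seed = 12))
  expect_setequal(sim$features$protein_id, sim$proteins$protein_id)
  expect_equal(nchar(sim$proteins$sequence), sim$proteins$length)
  # gene length encodes the protein plus a stop codon
  m <- match(sim$features$protein_id, sim$proteins$protein_id)
  expect_equal(sim$features$end - sim$features$start + 1L,
               3L * (sim$proteins$length[m] + 1L))
  # hits never extend past their protein
  hm <- match(sim$hits$protein_id, sim$proteins$protein_id)
  expect_true(all(sim$hits$end <= sim$proteins$length[hm]))
  expect_true(all(sim$hits$start >= 1))
})

test_that("the packaged per-taxon census fixture sums to the printed totals", {
  fx <- fixture_table1()
  expect_equal(sum(fx$n_proteins), 511588)
  expect_equal(sum(fx$n_HK), 2139)
  expect_equal(sum(fx$n_RR), 1875)
  expect_equal(sum(fx$n_REC_only), 740)
  expect_equal(sum(fx$n_HTH), 116)
})

test_that("simulation files round-trip through FASTA/GFF3/TSV", {
  sim <- generate_genomes(builtin_profile("thaumarchaea", n_genomes = 1,
                                          proteins_per_genome = c(20L, 20L),
                                          seed = 8))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  gid <- unique(sim$proteins$genome_id)
  prot <- read_protein_fasta(file.path(dir, paste0(gid, ".faa")),
                             genome_id = gid)
  expect_equal(prot$sequence,
               sim$proteins$sequence[match(prot$protein_id,
                                           sim$proteins$protein_id)])
  hits <- read_domain_hits(file.path(dir, paste0(gid, ".hits.tsv")))
  expect_equal(nrow(hits), nrow(sim$hits))
  feats <- read_gene_features(file.path(dir, paste0(gid, ".gff3")),
                              genome_id = gid)
  expect_equal(feats$strand,
               sim$features$strand[match(feats$protein_id,
                                         sim$features$protein_id)])
})
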