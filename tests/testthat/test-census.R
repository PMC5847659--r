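# census aggregation, genome statistics, TM prediction, sensor tallies,
# and gene neighborhoods

test_that("percentages round half away from zero", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_away(76.19), 76)
  expect_equal(round_half_away(76.79), 77)
})

test_that("a taxon with no RRs renders a dash, not a division error", {
  rows <- data.frame(taxon = c("A", "B"), n_genomes = c(1L, 1L),
                     n_proteins = c(1000L, 900L), n_HK = c(3L, 0L),
                     n_RR = c(0L, 4L), n_REC_only = c(0L, 2L),
                     n_HTH = c(0L, 1L))
  cen <- census_with_totals(rows)
  expect_true(is.na(cen$pct_REC_only[cen$taxon == "A"]))
  expect_equal(cen$pct_REC_only[cen$taxon == "B"], 50)
  fmt <- format_census(cen)
  expect_equal(fmt$pct_REC_only[fmt$taxon == "A"], "-")
})

test_that("census counts are conserved across taxa and categories", {
  sims <- list(generate_genomes(builtin_profile("haloarchaea",
                                                n_genomes = 2, seed = 31)),
               generate_genomes(builtin_profile("thaumarchaea",
                                                n_genomes = 2, seed = 32)))
  proteins <- rbind(sims[[1]]$proteins, sims[[2]]$proteins)
  hits <- rbind(sims[[1]]$hits, sims[[2]]$hits)
  archs <- resolve_architectures(hits, proteins)
  calls <- classify_all(archs, proteins = proteins)
  taxonomy <- data.frame(genome_id = unique(proteins$genome_id),
                         stringsAsFactors = FALSE)
  taxonomy$taxon <- sub("_g[0-9]+$", "", taxonomy$genome_id)
  cen <- build_census(calls, proteins, taxonomy)
  body <- cen[cen$taxon != "Total", ]
  tot <- cen[cen$taxon == "Total", ]
  for (cn in c("n_genomes", "n_proteins", "n_HK", "n_RR", "n_REC_only",
               "n_HTH")) {
    expect_equal(sum(body[[cn]]), tot[[cn]])
  }
  # per genome: every protein lands in exactly one category
  for (g in unique(proteins$genome_id)) {
    sub <- calls[calls$genome_id == g, ]
    expect_equal(nrow(sub), sum(proteins$genome_id == g))
    expect_equal(sum(table(sub$category)), nrow(sub))
  }
})

test_that("genomes missing from the taxonomy group under unclassified", {
  sim <- generate_genomes(builtin_profile("thaumarchaea", n_genomes = 2,
                                          seed = 33))
  archs <- resolve_architectures(sim$hits, sim$proteins)
  calls <- classify_all(archs, proteins = sim$proteins)
  gids <- unique(sim$proteins$genome_id)
  taxonomy <- data.frame(genome_id = gids[1], taxon = "Thaumarchaeota")
  expect_warning(cen <- build_census(calls, sim$proteins, taxonomy),
                 "unclassified")
  expect_true("unclassified" %in% cen$taxon)
})

test_that("genome statistics report ratios, ORF fractions and correlations", {
  calls <- data.frame(
    protein_id = sprintf("p%02d", 1:15),
    genome_id = "g1",
    category = c(rep("HK", 4), "hybrid_HK", rep("RR", 10)),
    rr_subclass = c(rep("n/a", 5), rep("REC_only", 10)),
    excluded_divergent = FALSE, stringsAsFactors = FALSE)
  proteins <- data.frame(protein_id = sprintf("q%04d", 1:1000),
                         genome_id = "g1", length = 300L,
                         sequence = NA_character_)
  gs <- genome_stats(calls, proteins)
  expect_equal(gs$n_HK, 5L)           # hybrid HKs count as HKs
  expect_equal(gs$rr_hk_ratio, 2.0)
  expect_equal(gs$pct_of_orfs, 1.5)   # 15 TCS proteins in 1,000 ORFs
  # 14 TCS proteins among 1,000 ORFs is 1.4%
  gs2 <- genome_stats(calls[-1, ], proteins)
  expect_equal(gs2$pct_of_orfs, 1.4)
})

test_that("TCS counts independent of genome size give |r| < 0.3", {
  set.seed(50)
  n_genomes <- 50
  sizes <- sample(500:4000, n_genomes)
  rows <- lapply(seq_len(n_genomes), function(i) {
    n_tcs <- rpois(1, 10)
    data.frame(
      protein_id = sprintf("g%02d_p%03d", i, seq_len(n_tcs)),
      genome_id = sprintf("g%02d", i),
      category = sample(c("HK", "RR"), n_tcs, replace = TRUE),
      rr_subclass = "n/a", excluded_divergent = FALSE,
      stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  proteins <- do.call(rbind, lapply(seq_len(n_genomes), function(i) {
    data.frame(protein_id = sprintf("g%02d_q%04d", i, seq_len(sizes[i])),
               genome_id = sprintf("g%02d", i), length = 300L,
               sequence = NA_character_, stringsAsFactors = FALSE)
  }))
  gs <- genome_stats(calls, proteins)
  expect_lt(abs(attr(gs, "pearson")), 0.3)
  expect_lt(abs(attr(gs, "spearman")), 0.3)
})

test_that("hydropathy windows find planted TM helices and nothing else", {
  hydrophilic <- strrep("DQESKNRT", 20)
  island <- paste0(substr(hydrophilic, 1, 60), strrep("L", 25),
                   substr(hydrophilic, 61, 160))
  tm <- predict_tm(island)
  expect_equal(nrow(tm), 1)
  # the 25-aa poly-Leu island sits at 61..85; merged windows cover it
  expect_lte(tm$tm_start, 61)
  expect_gte(tm$tm_end, 85 - 18)
  expect_equal(nrow(predict_tm(strrep("D", 200))), 0)
  expect_equal(nrow(predict_tm(hydrophilic)), 0)
})

test_that("membrane fraction counts HKs without TM segments", {
  calls <- data.frame(
    protein_id = sprintf("p%02d", 1:12),
    category = c(rep("HK", 10), "RR", "HisKA_no_HATPase"),
    rr_subclass = c(rep("n/a", 10), "REC_only", "n/a"),
    membrane_bound = c(rep(FALSE, 6), rep(TRUE, 4), FALSE, TRUE),
    stringsAsFactors = FALSE)
  mf <- membrane_fraction(calls)
  expect_equal(mf$pct_cytoplasmic, 60)
  expect_equal(mf$n_HK, 10L)
  expect_equal(mf$n_hiska_only, 1L)    # reported separately
})

test_that("sensor tally flags PAS/GAF combinations and named sensors", {
  archs <- list(
    h1 = architecture_from_string("PAS-GAF-HisKA-HATPase", "h1"),
    h2 = architecture_from_string("MEDS-HisKA-HATPase", "h2"),
    h3 = architecture_from_string("HisKA-HATPase", "h3"))
  calls <- do.call(rbind, lapply(archs, classify_architecture))
  st <- sensor_tally(calls, archs)
  expect_true(st$per_hk$has_both[st$per_hk$protein_id == "h1"])
  expect_equal(unname(st$named_counts["MEDS"]), 1L)
  expect_equal(st$pct_PAS_or_GAF, 100 / 3)
})

test_that("neighborhood relations follow strand geometry and distance", {
  features <- data.frame(
    genome_id = "g1", contig = "c1",
    protein_id = c("A", "B", "C", "D"),
    start = c(100L, 1100L, 2500L, 4000L),
    end = c(1000L, 2000L, 3600L, 5000L),
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  calls <- data.frame(protein_id = c("A", "B", "C", "D"),
                      category = "RR", rr_subclass = "REC_only",
                      cheA_like = FALSE, chemotaxis_associated = FALSE,
                      stringsAsFactors = FALSE)
  nb <- find_neighbors(features, calls, max_gap = 200L)
  expect_equal(nb$neighbors$relation[1], "same_operon_adjacent")
  expect_equal(nb$neighbors$intergenic_distance[1], 99L)   # 1100 - 1000 - 1
  # C(-) then D(+): head-to-head, transcribed divergently
  cd <- nb$neighbors[nb$neighbors$protein_id_1 == "C", ]
  expect_equal(cd$relation, "divergent")
  # B(+) then C(-): convergent, no relation
  expect_false(any(nb$neighbors$protein_id_1 == "B"))
})

test_that("neighborhood relations are symmetric in the gene pair", {
  features <- data.frame(
    genome_id = "g1", contig = "c1", protein_id = c("A", "B"),
    start = c(100L, 1100L), end = c(1000L, 2000L),
    strand = c("-", "+"), stringsAsFactors = FALSE)
  calls <- data.frame(protein_id = c("A", "B"), category = "not_TCS",
                      rr_subclass = "n/a", cheA_like = FALSE,
                      chemotaxis_associated = FALSE, stringsAsFactors = FALSE)
  r1 <- find_neighbors(features, calls)$neighbors
  # feeding the rows in reverse order must give the same unordered relation
  r2 <- find_neighbors(features[2:1, ], calls)$neighbors
  expect_equal(r1$relation, r2$relation)
  expect_equal(sort(c(r1$protein_id_1, r1$protein_id_2)),
               sort(c(r2$protein_id_1, r2$protein_id_2)))
  expect_equal(r1$intergenic_distance, r2$intergenic_distance)
})

test_that("REC-only RRs near CheA-like kinases gain the chemotaxis flag", {
  sim <- generate_genomes(builtin_profile("thaumarchaea", n_genomes = 6,
                                          seed = 60,
                                          chemotaxis_operon_rate = 1))
  res <- pipeline_calls(sim)
  m <- seq_len(nrow(sim$truth))
  expect_true(any(sim$truth$chemotaxis_associated))
  expect_equal(res$calls$chemotaxis_associated[m],
               sim$truth$chemotaxis_associated)
})
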