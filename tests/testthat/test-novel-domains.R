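# unassigned-region harvesting and single-linkage family clustering

test_that("unassigned regions are the long gaps, with flank context", {
  hits <- make_hit("p1", "REC", 1, 120)
  a <- resolve_hits(hits, make_protein("p1", 300))
  r <- extract_unassigned(a)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end, r$length), c(121, 300, 180))
  expect_equal(r$flank_left, "REC")
  expect_equal(r$flank_right, "C-terminus")
  # independent oracle: complement of the single segment
  expect_equal(complement_oracle(1, 120, 300),
               data.frame(start = 121L, end = 300L))
})

test_that("fully tiled proteins yield no regions", {
  hits <- rbind(make_hit("p1", "REC", 1, 120),
                make_hit("p1", "PAS", 121, 300, evalue = 1e-10))
  a <- resolve_hits(hits, make_protein("p1", 300))
  expect_equal(nrow(extract_unassigned(a)), 0)
})

test_that("the length threshold is inclusive at exactly 70 aa", {
  # gap of 69: rejected; gap of 70: accepted
  for (gap in c(69L, 70L)) {
    hits <- rbind(make_hit("p1", "REC", 1, 120),
                  make_hit("p1", "PAS", 121 + gap, 250 + gap,
                           evalue = 1e-10))
    a <- resolve_hits(hits, make_protein("p1", 250 + gap))
    r <- extract_unassigned(a, min_len = 70L)
    expect_equal(nrow(r), as.integer(gap >= 70L))
    if (gap == 70L) expect_equal(r$length, 70L)
  }
})

test_that("raising min_len never increases the number of regions", {
  sim <- generate_genomes(builtin_profile("haloarchaea", n_genomes = 1,
                                          seed = 3))
  archs <- resolve_architectures(sim$hits, sim$proteins)
  counts <- vapply(c(50L, 70L, 90L, 150L), function(ml) {
    sum(vapply(archs, function(a) nrow(extract_unassigned(a, ml)),
               integer(1)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical regions cluster together, unrelated ones stay apart", {
  seqA <- random_aa(80, seed = 1)
  seqB <- random_aa(100, seed = 2)
  seqC <- random_aa(100, seed = 3)
  proteins <- rbind(
    make_protein("a1", 80, sequence = seqA),
    make_protein("a2", 80, sequence = seqA),
    make_protein("a3", 80, sequence = seqA),
    make_protein("b1", 100, sequence = seqB),
    make_protein("c1", 100, sequence = seqC))
  regions <- data.frame(
    protein_id = proteins$protein_id,
    start = 1L, end = proteins$length, length = proteins$length,
    flank_left = "N-terminus", flank_right = "C-terminus",
    stringsAsFactors = FALSE)
  cl <- cluster_regions(regions, proteins)
  fam_a <- unique(cl$family_id[cl$protein_id %in% c("a1", "a2", "a3")])
  expect_length(fam_a, 1)                      # identical triple: one family
  expect_length(unique(cl$family_id), 3)       # plus two singletons
  expect_false(cl$family_id[cl$protein_id == "b1"] ==
                 cl$family_id[cl$protein_id == "c1"])
  rep_fams <- family_report(cl, archs = list(), proteins = proteins)
  expect_equal(rep_fams$median_length[rep_fams$family_id == fam_a], 80)
  # partition: every region in exactly one family
  expect_equal(sum(rep_fams$n_members), nrow(cl))
})

test_that("clustering is invariant to input order", {
  sim <- generate_genomes(builtin_profile("haloarchaea", n_genomes = 1,
                                          seed = 8))
  archs <- resolve_architectures(sim$hits, sim$proteins)
  regions <- do.call(rbind, lapply(archs, extract_unassigned))
  rownames(regions) <- NULL
  cl1 <- cluster_regions(regions, sim$proteins)
  set.seed(1)
  perm <- sample(nrow(regions))
  cl2 <- cluster_regions(regions[perm, ], sim$proteins)
  key <- function(cl) {
    split(paste(cl$protein_id, cl$start), cl$family_id) |>
      lapply(sort) |> unname() |> (\(x) x[order(vapply(x, `[`, "", 1))])()
  }
  expect_equal(key(cl1), key(cl2))
})

test_that("planted family is recovered with both of its contexts", {
  sim <- generate_genomes(builtin_profile("haloarchaea", n_genomes = 2,
                                          seed = 14))
  archs <- resolve_architectures(sim$hits, sim$proteins)
  regions <- do.call(rbind, lapply(archs, extract_unassigned))
  cl <- cluster_regions(regions, sim$proteins)
  rep_fams <- family_report(cl, archs, sim$proteins)
  planted <- sim$truth$protein_id[sim$truth$novel_family != ""]
  got <- cl[cl$protein_id %in% planted, ]
  expect_equal(length(unique(got$family_id)), 1)   # one recovered family
  expect_equal(nrow(got), length(planted))         # all copies found
  fam <- rep_fams[rep_fams$family_id == got$family_id[1], ]
  ctx <- strsplit(fam$contexts, "; ")[[1]]
  expect_length(ctx, 2)                            # stand-alone and REC fusion
  expect_true(any(grepl("^REC-", ctx)))
  # median length close to the planted 80 aa (regions include short linkers)
  expect_true(abs(fam$median_length - 80) <= 25)
})
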