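# fixtures and independent oracles shared across the test files

make_hit <- function(protein_id, domain_name, start, end,
                     score = 50, evalue = 1e-20, accession = "") {
  data.frame(protein_id = protein_id, domain_name = domain_name,
             accession = accession, start = as.integer(start),
             end = as.integer(end), score = score, evalue = evalue,
             stringsAsFactors = FALSE)
}

make_protein <- function(protein_id, length, genome_id = "g1",
                         sequence = NA_character_) {
  data.frame(protein_id = protein_id, genome_id = genome_id,
             length = as.integer(length), sequence = sequence,
             stringsAsFactors = FALSE)
}

# independent interval-complement oracle: positions of [1, len] not covered
# by any segment, grouped into maximal runs
complement_oracle <- function(starts, ends, len) {
  covered <- rep(FALSE, len)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  free <- which(!covered)
  if (!length(free)) return(data.frame(start = integer(), end = integer()))
  brk <- c(0, which(diff(free) > 1), length(free))
  data.frame(start = free[head(brk, -1) + 1], end = free[brk[-1]])
}

# brute-force oracle for hit resolution: enumerate all subsets, keep those
# pairwise compatible under the overlap rule and maximal (no further hit can
# be added), then pick the one that is lexicographically smallest in the
# (e-value, -score, start) priority ranking -- which is what sequential
# greedy acceptance must produce
resolve_oracle <- function(hits, tol = 0.30) {
  n <- nrow(hits)
  if (n == 0) return(integer(0))
  prio <- order(hits$evalue, -hits$score, hits$start)
  rank <- match(seq_len(n), prio)
  compat <- function(i, j) {
    ov <- max(0L, min(hits$end[i], hits$end[j]) -
                max(hits$start[i], hits$start[j]) + 1L)
    ov <= tol * min(hits$end[i] - hits$start[i] + 1L,
                    hits$end[j] - hits$start[j] + 1L)
  }
  best <- NULL
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    ok <- TRUE
    for (a in idx) for (b in idx) if (a < b && !compat(a, b)) ok <- FALSE
    if (!ok) next
    # maximality: no hit outside idx compatible with all of idx
    addable <- setdiff(seq_len(n), idx)
    maximal <- !any(vapply(addable, function(h)
      all(vapply(idx, function(a) compat(h, a), logical(1))), logical(1)))
    if (!maximal) next
    key <- sort(rank[idx])
    if (is.null(best) || lex_less(key, best$key)) {
      best <- list(key = key, idx = idx)
    }
  }
  sort(best$idx)
}

lex_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# all "Typical domain architecture" strings of the REC-associated-domain
# tables, with the category / subclass each table section implies (repeat
# counts instantiated at n = 2; evident table typos corrected)
worked_examples <- function() {
  rows <- list(
    # previously described REC-associated domains
    list("CheB",                        "not_TCS",   "n/a"),
    list("REC-CheB",                    "RR",        "CheB"),
    list("REC-PAS",                     "RR",        "REC_PAS_GAF"),
    list("REC-PAS-PAS",                 "RR",        "REC_PAS_GAF"),
    list("REC-PAS-GAF",                 "RR",        "REC_PAS_GAF"),
    list("REC-GAF",                     "RR",        "REC_PAS_GAF"),
    list("REC-(PAS)2-HisKA",            "RR",        "REC_HisK"),
    list("REC-(PAS)2-HisKA-HATPase",    "RR",        "REC_HisK"),
    list("REC-PAS-GAF-BAT-HTH_10",      "RR",        "transcriptional_HTH"),
    list("HalX",                        "not_TCS",   "n/a"),
    list("REC-HalX",                    "RR",        "REC_HalX"),
    list("HxlR-REC-HalX",               "RR",        "transcriptional_HTH"),
    list("REC-BcsA",                    "RR",        "REC_enzymatic"),
    list("REC-REC-BcsA",                "RR",        "REC_enzymatic"),
    list("iKaiC-REC",                   "RR",        "REC_enzymatic"),
    list("REC-DUF835",                  "RR",        "REC_enzymatic"),
    list("REC-PAS-PAS-DUF835",          "RR",        "REC_enzymatic"),
    list("REC-PAS-PAS-HAMP-MCPsignal",  "RR",        "other"),
    list("MEDS",                        "not_TCS",   "n/a"),
    list("MEDS-REC",                    "RR",        "other"),
    list("REC-MEDS",                    "RR",        "other"),
    list("REC-PAS-TPR",                 "RR",        "other"),
    list("TPR-TPR-TPR-REC",             "RR",        "other"),
    # counting-rule footnote: C-terminal REC on a kinase core
    list("HisKA-HATPase-REC",           "hybrid_HK", "n/a"),
    list("REC",                         "RR",        "REC_only"),
    # novel lineage-specific output domains
    list("REC-AcidOD1",                 "RR",        "REC_novel_OD"),
    list("REC-HalOD1",                  "RR",        "REC_novel_OD"),
    list("HalOD1",                      "not_TCS",   "n/a"),
    list("HalOD1-PAS",                  "not_TCS",   "n/a"),
    list("HalOD1-iKaiC",                "not_TCS",   "n/a"),
    list("REC-HalOD2",                  "RR",        "REC_novel_OD"),
    list("MetOD1",                      "not_TCS",   "n/a"),
    list("REC-MetOD1",                  "RR",        "REC_novel_OD"),
    list("REC-PAS-MetOD1",              "RR",        "REC_novel_OD"),
    list("REC-MetOD2",                  "RR",        "REC_novel_OD"),
    list("MetOD3-REC-MetOD2",           "RR",        "REC_novel_OD"),
    list("MetOD4",                      "not_TCS",   "n/a"),
    list("REC-MetOD4",                  "RR",        "REC_novel_OD"),
    list("MetOD5",                      "not_TCS",   "n/a"),
    list("MetOD5-REC",                  "RR",        "REC_novel_OD"),
    list("NitrOD1",                     "not_TCS",   "n/a"),
    list("REC-NitrOD1",                 "RR",        "REC_novel_OD"),
    list("NitrOD2",                     "not_TCS",   "n/a"),
    list("NitrOD2-REC",                 "RR",        "REC_novel_OD"),
    list("NitrOD3-REC",                 "RR",        "REC_novel_OD"),
    list("NitrOD4",                     "not_TCS",   "n/a"),
    list("NitrOD4-REC",                 "RR",        "REC_novel_OD"),
    list("NitrOD5",                     "not_TCS",   "n/a"),
    list("REC-NitrOD5",                 "RR",        "REC_novel_OD"),
    list("TackOD1",                     "not_TCS",   "n/a"),
    list("REC-TackOD1",                 "RR",        "REC_novel_OD"),
    list("REC-wHTH-TackOD1",            "RR",        "transcriptional_HTH"))
  data.frame(
    architecture = vapply(rows, `[[`, character(1), 1),
    category = vapply(rows, `[[`, character(1), 2),
    rr_subclass = vapply(rows, `[[`, character(1), 3),
    stringsAsFactors = FALSE)
}

# run the full pipeline on a simulation and return calls aligned to truth
pipeline_calls <- function(sim) {
  archs <- resolve_architectures(sim$hits, sim$proteins)
  calls <- classify_all(archs, proteins = sim$proteins)
  calls <- find_neighbors(sim$features, calls)$calls
  calls <- mark_divergent_rec(calls, archs, proteins = sim$proteins)
  list(archs = archs, calls = calls[match(sim$truth$protein_id,
                                          calls$protein_id), ])
}

random_aa <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}
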