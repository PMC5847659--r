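# synthetic genome generator with known ground truth. Emulates the
# statistical structure the census assumes -- lineage-biased architecture
# frequencies (haloarchaea-, methanogen- and thaumarchaea-like), chemotaxis
# operons, tandem duplicates, divergent gene pairs, membrane-bound sensor
# kinases, and planted novel-output-domain families -- so every pipeline
# stage can be validated without any genome downloads.

# residues biased away from strong hydrophobics, so that random linkers and
# domain bodies never mimic a transmembrane helix
HYDROPHILIC_AA <- c("D","E","G","K","N","P","Q","R","S","T","H","A","Y")

# run expr with a private RNG stream, leaving the caller's stream untouched
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic per-domain consensus sequence; the REC consensus is the
# packaged CheY reference so alignment-based stages stay meaningful
domain_consensus <- function(name) {
  if (toupper(name) == "REC") return(rec_reference())
  len <- domain_typical_length(name)
  key <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 100000L
  body <- with_local_seed(7241L + key, {
    paste(sample(HYDROPHILIC_AA, len, replace = TRUE), collapse = "")
  })
  if (toupper(name) %in% c("HISKA_7TM", "HISKA_4TM")) {
    # membrane sensor: plant two 25-aa hydrophobic stretches
    tm <- paste(rep(c("L", "I", "L", "V", "L"), 5), collapse = "")
    substr(body, 11, 10 + nchar(tm)) <- tm
    substr(body, 61, 60 + nchar(tm)) <- tm
  }
  body
}

mutate_seq <- function(s, rate, protect = integer(0)) {
  aa <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(aa)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    aa[i] <- sample(setdiff(HYDROPHILIC_AA, aa[i]), 1)
  }
  paste(aa, collapse = "")
}

random_linker <- function(n) {
  paste(sample(HYDROPHILIC_AA, n, replace = TRUE), collapse = "")
}

#' Define a lineage profile for the synthetic generator
#'
#' A profile fixes the per-protein architecture frequency table (the empty
#' string is a plain non-TCS protein), the rates of tandem duplication,
#' chemotaxis operons, divergent REC/HTH gene pairs, deliberate
#' phosphosite knockouts and REC truncations, and the novel-domain families
#' to plant. Frequencies must sum to 1.
#'
#' @param name profile name
#' @param n_genomes number of genomes to generate
#' @param proteins_per_genome integer range `c(lo, hi)`
#' @param arch_freq named numeric vector: architecture string -> frequency
#' @param tandem_duplication_rate per-protein probability of an adjacent
#'   tandem duplicate
#' @param chemotaxis_operon_rate per-genome probability of one planted
#'   chemotaxis operon (CheA-like HK, CheB RR, CheY-like REC-only RR)
#' @param divergent_pair_rate per-genome probability of one planted
#'   head-to-head REC-only / HTH gene pair
#' @param rec_site_knockout_rate probability that a REC domain carries a
#'   D57N phosphoacceptor knockout
#' @param rec_truncation_rate probability that a plain REC-only protein is
#'   emitted with a truncated (45-aa) receiver domain
#' @param mutation_rate per-site substitution rate applied to every domain
#'   copy (active-site positions are protected)
#' @param novel_domain_plants list of plants, each
#'   `list(name=, length=, n_fused=, n_standalone=, identity=)`
#' @param seed integer seed; all generator randomness flows from it
#' @return object of class `lineage_profile`
#' @export
lineage_profile <- function(name, n_genomes = 3L,
                            proteins_per_genome = c(60L, 80L),
                            arch_freq,
                            tandem_duplication_rate = 0.02,
                            chemotaxis_operon_rate = 0.5,
                            divergent_pair_rate = 0,
                            rec_site_knockout_rate = 0.1,
                            rec_truncation_rate = 0,
                            mutation_rate = 0.10,
                            novel_domain_plants = list(),
                            seed = 1L) {
  if (abs(sum(arch_freq) - 1) > 1e-8) {
    abort("lineage_profile: architecture frequencies must sum to 1 (got ",
          format(sum(arch_freq)), ")")
  }
  rates <- c(tandem_duplication_rate, chemotaxis_operon_rate,
             divergent_pair_rate, rec_site_knockout_rate,
             rec_truncation_rate, mutation_rate)
  if (any(rates < 0 | rates > 1)) abort("lineage_profile: rates must be in [0,1]")
  structure(list(
    name = name, n_genomes = as.integer(n_genomes),
    proteins_per_genome = as.integer(proteins_per_genome),
    arch_freq = arch_freq,
    tandem_duplication_rate = tandem_duplication_rate,
    chemotaxis_operon_rate = chemotaxis_operon_rate,
    divergent_pair_rate = divergent_pair_rate,
    rec_site_knockout_rate = rec_site_knockout_rate,
    rec_truncation_rate = rec_truncation_rate,
    mutation_rate = mutation_rate,
    novel_domain_plants = novel_domain_plants,
    seed = as.integer(seed)), class = "lineage_profile")
}

#' Built-in lineage profiles
#'
#' Three profiles emulating the lineage contrasts of the archaeal census:
#' `"haloarchaea"` (abundant REC-HalX and Bat-type REC-PAS-GAF-BAT-HTH_10
#' regulators, stand-alone HalOD1-like proteins, membrane HisKA_7TM sensors),
#' `"methanogen"` (REC-(PAS)n combinations, hybrid HKs, MEDS sensors,
#' enzymatic outputs), and `"thaumarchaea"` (77% of RRs are stand-alone REC,
#' divergent REC/HTH gene pairs). Across profiles the HK sensor complement
#' is tuned so roughly 72% of HKs carry PAS and/or GAF.
#'
#' @param name one of `"haloarchaea"`, `"methanogen"`, `"thaumarchaea"`
#' @param ... overrides passed to [lineage_profile()]
#' @return a `lineage_profile`
#' @export
builtin_profile <- function(name = c("haloarchaea", "methanogen",
                                     "thaumarchaea"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    haloarchaea = list(
      arch_freq = setNames(
        c(0.50,
          0.05, 0.03, 0.02, 0.02, 0.01,
          0.06, 0.08, 0.05, 0.02, 0.01, 0.02,
          0.01, 0.06, 0.01, 0.05),
        c("",
          "PAS-PAS-HisKA-HATPase", "GAF-HisKA-HATPase",
          "HisKA_7TM-HisKA-HATPase", "PAS-GAF-HisKA-HATPase",
          "HATPase-Hpt-CheW",
          "REC", "REC-HalX", "REC-PAS-GAF-BAT-HTH_10",
          "REC-HalOD1", "REC-CheB", "REC-PAS",
          "HisKA-HATPase-REC", "HalOD1", "PAS-HisKA",
          "REC-PAS-PAS-HisKA-HATPase")),
      chemotaxis_operon_rate = 0.5,
      novel_domain_plants = list(
        list(name = "HalODX", length = 80L, n_fused = 6L,
             n_standalone = 4L, identity = 0.90))),
    methanogen = list(
      arch_freq = setNames(
        c(0.53,
          0.04, 0.05, 0.03, 0.01, 0.04,
          0.07, 0.04, 0.02, 0.02, 0.02, 0.01, 0.01, 0.01,
          0.06, 0.02, 0.02),
        c("",
          "MEDS-HisKA-HATPase", "PAS-HisKA-HATPase",
          "PAS-PAS-HisKA-HATPase", "HATPase-Hpt-CheW",
          "PAS-HisKA-HATPase-REC",
          "REC", "REC-PAS", "REC-PAS-PAS", "REC-PAS-GAF", "REC-MetOD1",
          "REC-DUF835", "REC-CheB", "REC-BcsA",
          "REC-PAS-PAS-HisKA-HATPase", "PAS-GAF-HisKA", "MetOD1")),
      chemotaxis_operon_rate = 0.5,
      tandem_duplication_rate = 0.04),
    thaumarchaea = list(
      arch_freq = setNames(
        c(0.55,
          0.05, 0.04, 0.025, 0.035, 0.01,
          0.2002, 0.02, 0.01, 0.01, 0.01, 0.0098,
          0.01, 0.02),
        c("",
          "PAS-HisKA-HATPase", "GAF-HisKA-HATPase",
          "PAS-GAF-HisKA-HATPase", "HisKA-HATPase", "HATPase-Hpt-CheW",
          "REC", "REC-NitrOD1", "NitrOD2-REC",
          "REC-TackOD1", "REC-PAS", "REC-CheB",
          "PAS-HisKA", "NitrOD1")),
      chemotaxis_operon_rate = 0.3,
      divergent_pair_rate = 0.6))
  args <- utils::modifyList(c(list(name = name), spec), list(...))
  do.call(lineage_profile, args)
}

# realize one architecture string as sequence + hits; returns list with
# sequence, hits (data.frame), per-REC phosphorylatable plan
realize_protein <- function(arch_names, pid, profile, roles) {
  linker <- 10L
  seq_parts <- list(random_linker(linker))
  pos <- linker
  hits <- list()
  rec_ok <- logical(0)
  for (nm in arch_names) {
    cons <- domain_consensus(nm)
    if (toupper(nm) == "REC") {
      knock <- stats::runif(1) < profile$rec_site_knockout_rate
      s <- mutate_seq(cons, profile$mutation_rate,
                      protect = REC_SITE_POSITIONS)
      if (knock) substr(s, 57, 57) <- "N"
      rec_ok <- c(rec_ok, !knock)
    } else {
      protect <- if (toupper(nm) %in% c("HISKA_7TM", "HISKA_4TM"))
        seq_len(nchar(cons)) else integer(0)
      s <- mutate_seq(cons, profile$mutation_rate, protect = protect)
    }
    start <- pos + 1L
    end <- pos + nchar(s)
    acc <- roles$accession[match(tolower(nm), tolower(roles$domain_name))]
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = pid, domain_name = nm,
      accession = if (is.na(acc)) "" else acc,
      start = start, end = end,
      score = round(nchar(s) * 1.2, 1),
      evalue = 10^(-stats::runif(1, 10, 40)),
      stringsAsFactors = FALSE)
    seq_parts[[length(seq_parts) + 1L]] <- s
    seq_parts[[length(seq_parts) + 1L]] <- random_linker(linker)
    pos <- end + linker
  }
  list(sequence = paste(unlist(seq_parts), collapse = ""),
       hits = if (length(hits)) do.call(rbind, hits) else empty_hits(),
       rec_ok = rec_ok)
}

#' Generate synthetic genomes with ground truth
#'
#' Realizes each genome of the profile as a protein FASTA-able table, a
#' domain-hit table (clean emission: one hit per planted domain instance,
#' none for planted novel regions), gene features with operon / divergent /
#' tandem structure on one contig per genome, and a truth table recording
#' the expected classification of every protein.
#'
#' @param profile a [lineage_profile()]
#' @param seed overrides the profile seed when given
#' @return list of class `tcs_simulation`: `hits`, `proteins`, `features`,
#'   `truth`, `profile`
#' @export
generate_genomes <- function(profile, seed = NULL) {
  set.seed(seed %||% profile$seed)
  roles <- domain_roles()
  hits <- list(); prot <- list(); feat <- list(); truth <- list()
  for (g in seq_len(profile$n_genomes)) {
    gid <- sprintf("%s_g%02d", profile$name, g)
    rng <- profile$proteins_per_genome
    n <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
    # plan the protein roster: ordinary draws, then planted blocks
    plan <- list()
    for (i in seq_len(n)) {
      arch <- sample(names(profile$arch_freq), 1, prob = profile$arch_freq)
      plan[[length(plan) + 1L]] <- list(arch = arch, block = NA_character_)
      if (stats::runif(1) < profile$tandem_duplication_rate && nzchar(arch)) {
        plan[[length(plan) + 1L]] <- list(arch = arch, block = "tandem")
      }
    }
    if (stats::runif(1) < profile$chemotaxis_operon_rate) {
      plan <- append(plan, list(
        list(arch = "HATPase-Hpt-CheW", block = "che"),
        list(arch = "REC-CheB", block = "che"),
        list(arch = "REC", block = "che")),
        after = sample(length(plan), 1))
    }
    if (stats::runif(1) < profile$divergent_pair_rate) {
      # never split the chemotaxis block: only insert at block boundaries
      is_che <- vapply(plan, function(e) identical(e$block, "che"), logical(1))
      ok <- which(!(is_che & c(is_che[-1], FALSE)))
      plan <- append(plan, list(
        list(arch = "REC", block = "div1"),
        list(arch = "HTH_20", block = "div2")),
        after = ok[sample(length(ok), 1)])
    }
    for (p in profile$novel_domain_plants) {
      blocks <- c(rep("novel_fused", p$n_fused),
                  rep("novel_standalone", p$n_standalone))
      for (b in blocks) {
        plan[[length(plan) + 1L]] <- list(arch = b, block = p$name)
      }
    }
    # realize the roster
    pos <- 1L
    last_strand <- "-"
    k <- 0L
    i <- 1L
    while (i <= length(plan)) {
      entry <- plan[[i]]
      block_len <- 1L
      strand <- if (last_strand == "+") "-" else "+"
      if (identical(entry$block, "che")) block_len <- 3L
      if (identical(entry$block, "div1")) {
        block_len <- 2L
        strand <- "-"      # head-to-head: upstream gene on "-", next on "+"
      }
      if (identical(entry$block, "tandem")) strand <- last_strand
      for (j in seq_len(block_len)) {
        entry <- plan[[i + j - 1L]]
        k <- k + 1L
        pid <- sprintf("%s_p%04d", gid, k)
        out <- realize_one(entry, pid, profile, roles)
        hits[[length(hits) + 1L]] <- out$hits
        prot[[length(prot) + 1L]] <- data.frame(
          protein_id = pid, genome_id = gid, length = nchar(out$sequence),
          sequence = out$sequence, stringsAsFactors = FALSE)
        gene_len <- 3L * (nchar(out$sequence) + 1L)
        this_strand <- if (identical(entry$block, "div2")) "+" else strand
        feat[[length(feat) + 1L]] <- data.frame(
          genome_id = gid, contig = paste0(gid, "_c1"), protein_id = pid,
          start = pos, end = pos + gene_len - 1L, strand = this_strand,
          stringsAsFactors = FALSE)
        gap <- if (j < block_len) sample(20:100, 1) else sample(250:600, 1)
        pos <- pos + gene_len - 1L + gap + 1L
        out$truth$genome_id <- gid
        out$truth$chemotaxis_associated <-
          identical(entry$block, "che") && entry$arch == "REC"
        truth[[length(truth) + 1L]] <- out$truth
        last_strand <- this_strand
      }
      i <- i + block_len
    }
  }
  structure(list(
    hits = do.call(rbind, hits),
    proteins = do.call(rbind, prot),
    features = do.call(rbind, feat),
    truth = {
      t <- do.call(rbind, truth); rownames(t) <- NULL; t
    },
    profile = profile), class = "tcs_simulation")
}

# realize one roster entry: ordinary architecture, truncated REC,
# or a novel-domain plant
realize_one <- function(entry, pid, profile, roles) {
  arch <- entry$arch
  novel_family <- ""
  if (identical(entry$arch, "novel_fused") ||
      identical(entry$arch, "novel_standalone")) {
    p <- profile$novel_domain_plants[[
      which(vapply(profile$novel_domain_plants, `[[`, character(1), "name")
            == entry$block)[1]]]
    novel_family <- p$name
    arch_names <- if (entry$arch == "novel_fused") c("REC", p$name)
                  else p$name
    # plant consensus: deterministic for the family, length p$length
    plant_cons <- with_local_seed(
      5077L + sum(utf8ToInt(p$name)),
      paste(sample(HYDROPHILIC_AA, p$length, replace = TRUE), collapse = ""))
    out <- realize_plant(arch_names, pid, profile, roles, plant_cons,
                         1 - p$identity)
    expected <- if (entry$arch == "novel_fused") {
      c("RR", "REC_novel_OD")
    } else {
      c("not_TCS", "n/a")
    }
    visible <- if (entry$arch == "novel_fused") "REC" else ""
    truth <- data.frame(
      protein_id = pid, category = expected[1], rr_subclass = expected[2],
      phosphorylatable = if (length(out$rec_ok)) out$rec_ok[1] else NA,
      membrane_bound = FALSE, excluded_divergent = FALSE,
      architecture_string = visible, novel_family = novel_family,
      stringsAsFactors = FALSE)
    return(list(sequence = out$sequence, hits = out$hits, truth = truth))
  }
  arch_names <- if (nzchar(arch)) expand_arch_string(arch) else character(0)
  truncate <- nzchar(arch) && identical(arch, "REC") &&
    stats::runif(1) < profile$rec_truncation_rate
  if (truncate) {
    out <- realize_truncated_rec(pid, profile, roles)
  } else {
    out <- realize_protein(arch_names, pid, profile, roles)
  }
  expected <- expected_call(arch_names)
  truth <- data.frame(
    protein_id = pid, category = expected[1], rr_subclass = expected[2],
    phosphorylatable = if (length(out$rec_ok)) out$rec_ok[1] else NA,
    membrane_bound = any(toupper(arch_names) %in%
                           c("HISKA_7TM", "HISKA_4TM")),
    excluded_divergent = truncate,
    architecture_string = if (nzchar(arch)) collapse_arch_names(arch_names)
                          else "",
    novel_family = novel_family, stringsAsFactors = FALSE)
  list(sequence = out$sequence, hits = out$hits, truth = truth)
}

realize_truncated_rec <- function(pid, profile, roles) {
  cons <- substr(rec_reference(), 1, 45)
  s <- mutate_seq(cons, profile$mutation_rate, protect = c(12L, 13L))
  linker <- 10L
  sequence <- paste0(random_linker(linker), s, random_linker(linker))
  acc <- roles$accession[match("rec", tolower(roles$domain_name))]
  hits <- data.frame(
    protein_id = pid, domain_name = "REC", accession = acc,
    start = linker + 1L, end = linker + nchar(s),
    score = 30.0, evalue = 1e-8, stringsAsFactors = FALSE)
  list(sequence = sequence, hits = hits, rec_ok = NA)
}

realize_plant <- function(arch_names, pid, profile, roles, plant_cons,
                          plant_rate) {
  linker <- 10L
  seq_parts <- list(random_linker(linker))
  pos <- linker
  hits <- list()
  rec_ok <- logical(0)
  for (nm in arch_names) {
    if (toupper(nm) == "REC") {
      knock <- stats::runif(1) < profile$rec_site_knockout_rate
      s <- mutate_seq(rec_reference(), profile$mutation_rate,
                      protect = REC_SITE_POSITIONS)
      if (knock) substr(s, 57, 57) <- "N"
      rec_ok <- c(rec_ok, !knock)
      acc <- roles$accession[match("rec", tolower(roles$domain_name))]
      hits[[length(hits) + 1L]] <- data.frame(
        protein_id = pid, domain_name = "REC", accession = acc,
        start = pos + 1L, end = pos + nchar(s),
        score = round(nchar(s) * 1.2, 1),
        evalue = 10^(-stats::runif(1, 10, 40)), stringsAsFactors = FALSE)
    } else {
      s <- mutate_seq(plant_cons, plant_rate)   # hidden novel region
    }
    seq_parts[[length(seq_parts) + 1L]] <- s
    seq_parts[[length(seq_parts) + 1L]] <- random_linker(linker)
    pos <- pos + nchar(s) + linker
  }
  list(sequence = paste(unlist(seq_parts), collapse = ""),
       hits = if (length(hits)) do.call(rbind, hits) else empty_hits(),
       rec_ok = rec_ok)
}

expand_arch_string <- function(string) {
  out <- character(0)
  for (tok in strsplit(string, "-", fixed = TRUE)[[1]]) {
    m <- regmatches(tok, regexec("^\\((.+)\\)(\\d+)$", tok))[[1]]
    if (length(m) == 3) out <- c(out, rep(m[2], as.integer(m[3])))
    else out <- c(out, tok)
  }
  out
}

collapse_arch_names <- function(names) {
  r <- rle(names)
  paste(ifelse(r$lengths >= 2, sprintf("(%s)%d", r$values, r$lengths),
               r$values), collapse = "-")
}

# ground-truth classification of an architecture name vector, written
# independently of the classifier (simple positional rules over the
# generator's own vocabulary)
expected_call <- function(arch_names) {
  if (!length(arch_names)) return(c("not_TCS", "n/a"))
  up <- toupper(arch_names)
  rec <- which(up == "REC")
  dim_pos <- which(up %in% c("HISKA"))
  atp_pos <- which(up %in% c("HATPASE", "HATPASE_C"))
  core <- c(dim_pos, atp_pos)
  if (length(rec) && length(core)) {
    if (min(rec) < min(core)) return(c("RR", "REC_HisK"))
    return(c("hybrid_HK", "n/a"))
  }
  if (length(core)) {
    if (length(dim_pos) && length(atp_pos)) return(c("HK", "n/a"))
    if (length(dim_pos)) return(c("HisKA_no_HATPase", "n/a"))
    if (any(up %in% c("HPT", "CHEW"))) return(c("HK", "n/a"))
    return(c("not_TCS", "n/a"))
  }
  if (!length(rec)) return(c("not_TCS", "n/a"))
  others <- up[up != "REC"]
  if ("CHEB" %in% others) return(c("RR", "CheB"))
  if (any(others %in% c("BAT", "HTH_10", "HTH", "WHTH", "HXLR", "HTH_20"))) {
    return(c("RR", "transcriptional_HTH"))
  }
  if ("HALX" %in% others) return(c("RR", "REC_HalX"))
  if (any(others %in% c("DUF835", "BCSA", "IKAIC", "KAIC",
                        "GLYCO_TRANSF_2_3"))) {
    return(c("RR", "REC_enzymatic"))
  }
  if (any(grepl("OD\\d$", others))) return(c("RR", "REC_novel_OD"))
  if (length(others) && all(grepl("^(PAS|GAF)", others))) {
    return(c("RR", "REC_PAS_GAF"))
  }
  if (!length(others)) return(c("RR", "REC_only"))
  c("RR", "other")
}

#' Write a simulation to disk
#'
#' One FASTA, one GFF3 and one hits TSV per genome plus a combined truth
#' table, in the layout the command-line interface consumes.
#'
#' @param sim a `tcs_simulation` from [generate_genomes()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gid in unique(sim$proteins$genome_id)) {
    p <- sim$proteins[sim$proteins$genome_id == gid, , drop = FALSE]
    write_protein_fasta(p, file.path(dir, paste0(gid, ".faa")))
    write_gene_features(sim$features[sim$features$genome_id == gid, ,
                                     drop = FALSE],
                        file.path(dir, paste0(gid, ".gff3")))
    h <- sim$hits[sim$hits$protein_id %in% p$protein_id, , drop = FALSE]
    write_tcs_table(h, file.path(dir, paste0(gid, ".hits.tsv")))
  }
  write_tcs_table(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Printed per-taxon census rows as a machine-readable fixture
#'
#' The leaf rows of the published per-taxon census table (counts only; the
#' em dashes of the printed table are zeros). Column sums reproduce the
#' printed totals for proteins, HKs, RRs, REC-only and HTH counts.
#'
#' @return data.frame: `taxon`, `n_genomes`, `n_proteins`, `n_HK`, `n_RR`,
#'   `n_REC_only`, `n_HTH`
#' @export
fixture_table1 <- function() {
  rows <- list(
    list("Ca. Micrarchaeota",          1,    952,   1,   1,   0,   1),
    list("Ca. Nanohaloarchaeota",      1,   1183,   0,   0,   0,   0),
    list("Nanoarchaeota",              2,   1122,   0,   0,   0,   0),
    list("Archaeoglobi",               7,  15162,  37,  42,  32,   0),
    list("Halobacteria",              35, 123786, 745, 695, 163,  93),
    list("Methanobacteria",           17,  33023, 140, 150,  35,   0),
    list("Methanococci",              12,  19966,  19,  23,  15,   0),
    list("Methanomicrobia",           39, 108246, 998, 697, 300,  20),
    list("Methanopyri",                1,   1687,   0,   0,   0,   0),
    list("Thermococci",               25,  51618,  17,  31,  17,   0),
    list("Thermoplasmata",            11,  18221,   3,   4,   0,   1),
    list("Unclassified euryarchaea",   3,   4814,   4,   8,   6,   0),
    list("Thaumarchaeota",            16,  36321, 175, 224, 172,   1),
    list("Crenarchaeota",             44,  88281,   0,   0,   0,   0),
    list("Korarchaeota",               1,   1602,   0,   0,   0,   0),
    list("Unclassified archaea",       4,   5604,   0,   0,   0,   0))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(taxon = r[[1]], n_genomes = r[[2]], n_proteins = r[[3]],
               n_HK = r[[4]], n_RR = r[[5]], n_REC_only = r[[6]],
               n_HTH = r[[7]], stringsAsFactors = FALSE)
  }))
  out
}
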