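# per-genome and per-taxon aggregation of classification calls (census
# tables), genome statistics, membrane localization, sensor tallies, and
# gene-neighborhood analysis.

counts_for <- function(calls) {
  c(n_HK = sum(calls$category %in% c("HK", "hybrid_HK")),
    n_HisKA_no_HATPase = sum(calls$category == "HisKA_no_HATPase"),
    n_RR = sum(calls$category == "RR"),
    n_REC_only = sum(calls$category == "RR" & calls$rr_subclass == "REC_only"),
    n_HTH = sum(calls$category == "RR" &
                  calls$rr_subclass == "transcriptional_HTH"))
}

#' Per-taxon census with a totals row
#'
#' Aggregates classification calls into per-taxon rows (HK count including
#' hybrid HKs; RR count; REC-only and DNA-binding-HTH subclass counts with the
#' REC-only percentage of all RRs) plus a column-wise totals row. Proteins
#' flagged `excluded_divergent` are omitted from all counts. HisKA-only
#' kinase-dead proteins are tallied in their own column, not within `n_HK`.
#'
#' @param calls calls table from [classify_all()] (needs `genome_id`)
#' @param proteins protein table (total protein counts per genome)
#' @param taxonomy data.frame `genome_id`, `taxon`; genomes missing from it
#'   are grouped under `"unclassified"` with a warning
#' @return data.frame of class `tcs_census`: `taxon`, `n_genomes`,
#'   `n_proteins`, `n_HK`, `n_HisKA_no_HATPase`, `n_RR`, `n_REC_only`,
#'   `pct_REC_only`, `n_HTH`; last row `Total`
#' @export
build_census <- function(calls, proteins, taxonomy) {
  stopifnot("genome_id" %in% names(calls))
  tax <- taxonomy$taxon[match(calls$genome_id, taxonomy$genome_id)]
  if (anyNA(tax)) {
    warning("genome(s) missing from taxonomy, grouped as 'unclassified': ",
            paste(unique(calls$genome_id[is.na(tax)]), collapse = ", "))
    tax[is.na(tax)] <- "unclassified"
  }
  ptax <- taxonomy$taxon[match(proteins$genome_id, taxonomy$genome_id)]
  ptax[is.na(ptax)] <- "unclassified"
  keep <- !calls$excluded_divergent
  rows <- lapply(unique(tax), function(t) {
    sub <- calls[keep & tax == t, , drop = FALSE]
    psub <- proteins[ptax == t, , drop = FALSE]
    cbind(data.frame(taxon = t,
                     n_genomes = length(unique(psub$genome_id)),
                     n_proteins = nrow(psub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(counts_for(sub))))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  census_with_totals(out)
}

#' Append a totals row and REC-only percentages to census rows
#'
#' The totals row is the column-wise sum of the taxon rows. The REC-only
#' percentage is `100 * n_REC_only / n_RR` rounded to the nearest integer,
#' half away from zero, and `NA` where a taxon has no RRs.
#'
#' @param rows per-taxon count rows (`taxon`, `n_genomes`, `n_proteins`,
#'   `n_HK`, `n_RR`, `n_REC_only`, `n_HTH`, optionally
#'   `n_HisKA_no_HATPase`)
#' @return data.frame of class `tcs_census` with `pct_REC_only` and a
#'   final `Total` row
#' @export
census_with_totals <- function(rows) {
  numcols <- setdiff(names(rows), "taxon")
  tot <- rows[1, , drop = FALSE]
  tot$taxon <- "Total"
  for (cn in numcols) tot[[cn]] <- sum(rows[[cn]], na.rm = TRUE)
  out <- rbind(rows, tot)
  out$pct_REC_only <- ifelse(out$n_RR > 0,
                             round_half_away(100 * out$n_REC_only / out$n_RR),
                             NA_real_)
  class(out) <- c("tcs_census", "data.frame")
  out
}

#' Format a census table for printing
#'
#' Zero counts and undefined percentages are rendered as an em dash,
#' mirroring the printed-table convention.
#'
#' @param census a `tcs_census` table
#' @param dash the placeholder string (default `"-"`)
#' @return data.frame of characters
#' @export
format_census <- function(census, dash = "-") {
  out <- as.data.frame(lapply(census, function(col) {
    if (is.numeric(col)) ifelse(is.na(col) | col == 0, dash,
                                format(col, trim = TRUE, big.mark = ","))
    else as.character(col)
  }), stringsAsFactors = FALSE)
  names(out) <- names(census)
  out
}

#' Per-genome TCS statistics
#'
#' For each genome: HK count (hybrid HKs included), RR count, RR/HK ratio
#' (`NA` when there are no HKs), and the TCS fraction of ORFs in percent.
#' Also returns the Pearson and Spearman correlations of the per-genome TCS
#' total with the genome protein count, as attributes `pearson` and
#' `spearman` (NA with fewer than 3 genomes).
#'
#' @param calls calls table with `genome_id`
#' @param proteins protein table (denominator of the ORF fraction)
#' @return data.frame `genome_id`, `n_proteins`, `n_HK`, `n_RR`,
#'   `rr_hk_ratio`, `pct_of_orfs`, with correlation attributes
#' @export
genome_stats <- function(calls, proteins) {
  keep <- !calls$excluded_divergent
  genomes <- unique(proteins$genome_id)
  rows <- lapply(genomes, function(g) {
    sub <- calls[keep & calls$genome_id == g, , drop = FALSE]
    n_hk <- sum(sub$category %in% c("HK", "hybrid_HK"))
    n_rr <- sum(sub$category == "RR")
    n_orf <- sum(proteins$genome_id == g)
    data.frame(genome_id = g, n_proteins = n_orf, n_HK = n_hk, n_RR = n_rr,
               rr_hk_ratio = if (n_hk > 0) n_rr / n_hk else NA_real_,
               pct_of_orfs = if (n_orf > 0) 100 * (n_hk + n_rr) / n_orf
                             else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tcs <- out$n_HK + out$n_RR
  if (nrow(out) >= 3 && stats::sd(tcs) > 0 && stats::sd(out$n_proteins) > 0) {
    attr(out, "pearson") <- cor(tcs, out$n_proteins, method = "pearson")
    attr(out, "spearman") <- cor(tcs, out$n_proteins, method = "spearman")
  } else {
    attr(out, "pearson") <- NA_real_
    attr(out, "spearman") <- NA_real_
  }
  out
}

#' Predict transmembrane segments by hydropathy
#'
#' Kyte-Doolittle sliding-window predictor: every window of `window` residues
#' whose mean hydropathy exceeds `cutoff` marks a candidate transmembrane
#' window; overlapping windows are merged into segments. A standard stand-in
#' for an external TM predictor when no precomputed segment table is given.
#'
#' @param sequence amino-acid string
#' @param window window width (default 19)
#' @param cutoff mean-hydropathy threshold (default 1.6)
#' @return data.frame `tm_start`, `tm_end` (1-based inclusive), possibly
#'   zero rows
#' @export
predict_tm <- function(sequence, window = 19L, cutoff = 1.6) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  h <- unname(KD_SCALE[aa])
  h[is.na(h)] <- 0
  n <- length(h)
  if (n < window) return(data.frame(tm_start = integer(), tm_end = integer()))
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hit <- which(means > cutoff)
  if (!length(hit)) {
    return(data.frame(tm_start = integer(), tm_end = integer()))
  }
  starts <- hit
  ends <- hit + window - 1L
  # merge overlapping / adjacent windows
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(tm_start = out_s, tm_end = out_e)
}

#' Fraction of histidine kinases without transmembrane segments
#'
#' Uses the `membrane_bound` flag of the calls (from a TM table or the
#' fallback [predict_tm()] predictor). HisKA-only kinase-dead proteins are
#' excluded from the denominator and reported separately.
#'
#' @param calls calls table with `membrane_bound` filled
#' @return list: `pct_cytoplasmic` (percent of HKs with no TM segments),
#'   `n_HK` (denominator), `n_no_tm`, and the same three for the
#'   HisKA-only class (`pct_cytoplasmic_hiska_only`, ...)
#' @export
membrane_fraction <- function(calls) {
  frac <- function(sub) {
    known <- sub[!is.na(sub$membrane_bound), , drop = FALSE]
    dropped <- nrow(sub) - nrow(known)
    if (dropped > 0) {
      warning(dropped, " protein(s) without TM data excluded from the ",
              "membrane denominator")
    }
    n <- nrow(known)
    n_no <- sum(!known$membrane_bound)
    list(pct = if (n > 0) 100 * n_no / n else NA_real_, n = n, n_no = n_no)
  }
  hk <- frac(calls[calls$category %in% c("HK", "hybrid_HK"), , drop = FALSE])
  hd <- frac(calls[calls$category == "HisKA_no_HATPase", , drop = FALSE])
  list(pct_cytoplasmic = hk$pct, n_HK = hk$n, n_no_tm = hk$n_no,
       pct_cytoplasmic_hiska_only = hd$pct, n_hiska_only = hd$n,
       n_hiska_only_no_tm = hd$n_no)
}

#' Sensor-domain tally over histidine kinases
#'
#' Per HK (hybrid HKs included; HisKA-only proteins excluded): whether the
#' architecture carries PAS, GAF, or both, plus counts of the named archaeal
#' sensor domains.
#'
#' @param calls calls table
#' @param archs architectures for the called proteins
#' @param named_sensors sensor names counted individually
#' @return list: `per_hk` (data.frame `protein_id`, `has_PAS`, `has_GAF`,
#'   `has_both`), `pct_PAS_or_GAF`, `pct_both`, `named_counts`
#' @export
sensor_tally <- function(calls, archs,
                         named_sensors = c("MEDS", "PocR", "Cache",
                                           "HisKA_7TM", "HisKA_4TM")) {
  hk_ids <- calls$protein_id[calls$category %in% c("HK", "hybrid_HK")]
  per <- lapply(hk_ids, function(pid) {
    a <- archs[[pid]]
    nm <- tolower(a$segments$domain_name)
    has_pas <- any(grepl("^pas", nm))
    has_gaf <- any(grepl("^gaf", nm))
    data.frame(protein_id = pid, has_PAS = has_pas, has_GAF = has_gaf,
               has_both = has_pas && has_gaf, stringsAsFactors = FALSE)
  })
  per_hk <- if (length(per)) do.call(rbind, per) else
    data.frame(protein_id = character(), has_PAS = logical(),
               has_GAF = logical(), has_both = logical())
  named_counts <- vapply(named_sensors, function(s) {
    sum(vapply(hk_ids, function(pid) {
      any(tolower(archs[[pid]]$segments$domain_name) == tolower(s))
    }, logical(1)))
  }, integer(1))
  n <- nrow(per_hk)
  list(per_hk = per_hk,
       pct_PAS_or_GAF = if (n > 0)
         100 * sum(per_hk$has_PAS | per_hk$has_GAF) / n else NA_real_,
       pct_both = if (n > 0) 100 * sum(per_hk$has_both) / n else NA_real_,
       named_counts = named_counts)
}

#' Gene-neighborhood analysis
#'
#' Walks each contig in coordinate order. Adjacent co-oriented genes with an
#' intergenic distance of at most `max_gap` nucleotides are called
#' `same_operon_adjacent`; adjacent head-to-head genes (strands `-`,`+` in
#' coordinate order, i.e. transcribed divergently) are called `divergent`.
#' Intergenic distance is `start(downstream) - end(upstream) - 1`, clamped at
#' zero for overlapping genes. A REC-only RR within `window` genes of a
#' CheA-like HK or a CheB RR inside one co-oriented operon run gets the
#' `chemotaxis_associated` flag.
#'
#' @param features gene features ([read_gene_features()])
#' @param calls calls table (updated flags are returned alongside)
#' @param max_gap operon distance threshold in nt (default 200)
#' @param window gene-count window for chemotaxis association (default 5)
#' @return list: `neighbors` (data.frame `protein_id_1`, `protein_id_2`,
#'   `relation`, `intergenic_distance`) and `calls` with
#'   `chemotaxis_associated` updated
#' @export
find_neighbors <- function(features, calls, max_gap = 200L, window = 5L) {
  rel_rows <- list()
  chem <- setNames(rep(FALSE, nrow(calls)), calls$protein_id)
  cat_of <- setNames(calls$category, calls$protein_id)
  sub_of <- setNames(calls$rr_subclass, calls$protein_id)
  chea_of <- setNames(calls$cheA_like, calls$protein_id)
  for (key in unique(paste(features$genome_id, features$contig, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    f <- features[features$genome_id == parts[1] &
                    features$contig == parts[2], , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    n <- nrow(f)
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        d <- max(0L, f$start[i + 1] - f$end[i] - 1L)
        rel <- if (f$strand[i] == f$strand[i + 1] && d <= max_gap) {
          "same_operon_adjacent"
        } else if (f$strand[i] == "-" && f$strand[i + 1] == "+") {
          "divergent"
        } else {
          NA_character_
        }
        if (!is.na(rel)) {
          rel_rows[[length(rel_rows) + 1L]] <- data.frame(
            protein_id_1 = f$protein_id[i], protein_id_2 = f$protein_id[i + 1],
            relation = rel, intergenic_distance = d,
            stringsAsFactors = FALSE)
        }
      }
    }
    # co-oriented runs for the chemotaxis flag
    run_id <- cumsum(c(1L, as.integer(f$strand[-1] != f$strand[-n])))
    for (r in unique(run_id)) {
      ids <- f$protein_id[run_id == r]
      idx_rec <- which(sub_of[ids] == "REC_only" & !is.na(sub_of[ids]))
      idx_anchor <- which((chea_of[ids] %in% TRUE) |
                            (sub_of[ids] %in% "CheB"))
      if (length(idx_rec) && length(idx_anchor)) {
        for (i in idx_rec) {
          if (any(abs(idx_anchor - i) <= window)) {
            chem[ids[i]] <- TRUE
          }
        }
      }
    }
  }
  neighbors <- if (length(rel_rows)) do.call(rbind, rel_rows) else
    data.frame(protein_id_1 = character(), protein_id_2 = character(),
               relation = character(), intergenic_distance = integer())
  calls$chemotaxis_associated <- calls$chemotaxis_associated |
    unname(chem[calls$protein_id])
  list(neighbors = neighbors, calls = calls)
}
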