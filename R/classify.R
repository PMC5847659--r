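# classification of resolved architectures into histidine-kinase and
# response-regulator categories and RR subclasses.
#
# counting conventions: a protein combining REC with HK domains is a
# response regulator when the REC domain precedes the kinase core (REC-HisK)
# and a hybrid histidine kinase (counted with the HKs) when the REC domain
# follows it. HisKA-like proteins lacking the ATPase domain are tallied as
# their own kinase-dead class.

HK_DIM <- "phosphotransfer_dimerization"
HK_ATP <- "phosphotransfer_atpase"

#' Classify one architecture
#'
#' Decision cascade over segment roles:
#' 1. no REC and no HK domain: `not_TCS`;
#' 2. HK domains without REC: HisKA + HATPase gives `HK`; HisKA alone gives
#'    `HisKA_no_HATPase`; HATPase with Hpt and/or CheW but no HisKA gives
#'    `HK` flagged `cheA_like` (CheA-type chemotaxis kinase); a lone HATPase
#'    is `not_TCS` (GHKL ATPases outside the TCS);
#' 3. REC together with HK domains: a REC starting before the first HK-core
#'    segment makes the protein an RR of subclass `REC_HisK`; a REC starting
#'    after the last HK-core segment makes it a `hybrid_HK`; a REC strictly
#'    inside the kinase core (or RECs on both sides) is resolved with a
#'    warning;
#' 4. REC without HK domains: RR, subclass by fixed output priority
#'    CheB > DNA-binding HTH > HalX > enzymatic > novel/unknown output >
#'    PAS/GAF-only > REC-only > other. An unassigned region of at least
#'    `novel_gap_min` residues counts as a putative novel output domain
#'    (subclass `REC_novel_OD`), mirroring the delineation rule for
#'    unassigned regions of >= 70 aa; `REC_only` therefore means a
#'    stand-alone receiver with at most short gaps.
#'
#' @param arch a `tcs_architecture` from [resolve_hits()]
#' @param novel_gap_min unassigned-gap length treated as a putative novel
#'   output domain (default 70 aa)
#' @return one-row data.frame (class `tcs_call`): `protein_id`, `category`,
#'   `rr_subclass`, logical flags `cheA_like`, `chemotaxis_associated`,
#'   `membrane_bound`, `excluded_divergent`, and `architecture_string`
#' @export
classify_architecture <- function(arch, novel_gap_min = 70L) {
  seg <- arch$segments
  role <- seg$role
  nm <- tolower(seg$domain_name)
  has_rec <- any(role == "receiver")
  has_dim <- any(role == HK_DIM)
  has_atp <- any(role == HK_ATP)
  has_hpt <- any(role == "hpt")
  has_chew <- any(role == "chew")
  category <- "not_TCS"
  subclass <- "n/a"
  cheA <- FALSE

  if (!has_rec && (has_dim || has_atp)) {
    if (has_dim && has_atp) {
      category <- "HK"
    } else if (has_dim) {
      category <- "HisKA_no_HATPase"
    } else if (has_atp && (has_hpt || has_chew)) {
      category <- "HK"
      cheA <- TRUE
    }                                     # lone HATPase stays not_TCS
  } else if (has_rec && (has_dim || has_atp)) {
    core <- role %in% c(HK_DIM, HK_ATP)
    core_first <- min(seg$start[core])
    core_last <- max(seg$start[core])
    rec_start <- seg$start[role == "receiver"]
    n_term <- any(rec_start < core_first)
    c_term <- any(rec_start > core_last)
    if (n_term && !c_term) {
      category <- "RR"; subclass <- "REC_HisK"
    } else if (c_term && !n_term) {
      category <- "hybrid_HK"
    } else if (n_term && c_term) {
      warning(arch$protein_id,
              ": REC domains flank the kinase core on both sides; ",
              "counted as RR (REC_HisK)")
      category <- "RR"; subclass <- "REC_HisK"
    } else {
      warning(arch$protein_id,
              ": REC domain inside the kinase core; counted as hybrid_HK")
      category <- "hybrid_HK"
    }
  } else if (has_rec) {
    category <- "RR"
    other <- which(role != "receiver")
    orole <- role[other]; onm <- nm[other]
    long_gap <- nrow(arch$gaps) > 0 &&
      any(arch$gaps$end - arch$gaps$start + 1L >= novel_gap_min)
    subclass <- if (any(onm %in% c("cheb", "cheb_methylest"))) {
      "CheB"
    } else if (any(orole == "output_dna_binding")) {
      "transcriptional_HTH"
    } else if (any(orole == "output_halx")) {
      "REC_HalX"
    } else if (any(orole == "output_enzymatic")) {
      "REC_enzymatic"
    } else if (any(orole %in% c("output_novel", "unknown")) || long_gap) {
      "REC_novel_OD"
    } else if (length(other) &&
               all(orole == "sensor") && all(grepl("^(pas|gaf)", onm))) {
      "REC_PAS_GAF"
    } else if (!length(other)) {
      "REC_only"
    } else {
      "other"
    }
  }

  out <- data.frame(
    protein_id = arch$protein_id,
    category = category,
    rr_subclass = subclass,
    cheA_like = cheA,
    chemotaxis_associated = FALSE,
    membrane_bound = NA,
    excluded_divergent = FALSE,
    architecture_string = architecture_string(arch, collapse_repeats = TRUE),
    stringsAsFactors = FALSE)
  class(out) <- c("tcs_call", "data.frame")
  out
}

#' Classify a set of architectures
#'
#' Runs [classify_architecture()] on every architecture and, when protein
#' or TM information is supplied, fills the `membrane_bound` flag (a protein
#' is membrane-bound iff it has at least one transmembrane segment).
#'
#' @param archs named list of `tcs_architecture`
#' @param proteins optional protein table with sequences (fallback TM
#'   prediction via [predict_tm()])
#' @param tm optional TM-segment table ([read_tm_table()]); takes precedence
#'   over prediction
#' @return data.frame of calls, one row per architecture
#' @export
classify_all <- function(archs, proteins = NULL, tm = NULL) {
  calls <- do.call(rbind, lapply(archs, classify_architecture))
  rownames(calls) <- NULL
  if (!is.null(proteins) && "genome_id" %in% names(proteins)) {
    calls$genome_id <- proteins$genome_id[match(calls$protein_id,
                                                proteins$protein_id)]
  }
  if (!is.null(tm)) {
    calls$membrane_bound <- calls$protein_id %in% tm$protein_id
  } else if (!is.null(proteins) && any(!is.na(proteins$sequence))) {
    idx <- match(calls$protein_id, proteins$protein_id)
    calls$membrane_bound <- vapply(idx, function(i) {
      if (is.na(i) || is.na(proteins$sequence[i])) return(NA)
      nrow(predict_tm(proteins$sequence[i])) > 0L
    }, logical(1))
  }
  class(calls) <- c("tcs_call", "data.frame")
  calls
}

#' Flag divergent or truncated REC domains
#'
#' Proteins whose REC domains are too short or align too poorly to the
#' packaged CheY reference are flagged `excluded_divergent`: they keep their
#' classification but are omitted from census totals, mirroring the practice
#' of excluding highly divergent, truncated or frameshifted receiver domains
#' from the count.
#'
#' @param calls calls table from [classify_all()]
#' @param archs the architectures the calls came from
#' @param proteins protein table with sequences (needed for the coverage
#'   check; without sequences only the length rule applies)
#' @param min_len minimum credible REC segment length in aa (default 80)
#' @param min_coverage minimum fraction of reference positions aligned
#'   (default 0.6)
#' @param reference reference REC sequence (default [rec_reference()])
#' @return `calls` with `excluded_divergent` updated
#' @export
mark_divergent_rec <- function(calls, archs, proteins = NULL,
                               min_len = 80L, min_coverage = 0.6,
                               reference = rec_reference()) {
  seqs <- NULL
  if (!is.null(proteins)) {
    seqs <- setNames(proteins$sequence, proteins$protein_id)
  }
  for (i in seq_len(nrow(calls))) {
    a <- archs[[calls$protein_id[i]]]
    if (is.null(a)) next
    rec <- a$segments[a$segments$role == "receiver", , drop = FALSE]
    if (!nrow(rec)) next
    lens <- rec$end - rec$start + 1L
    bad <- any(lens < min_len)
    if (!bad && !is.null(seqs)) {
      s <- seqs[[calls$protein_id[i]]]
      if (!is.null(s) && !is.na(s)) {
        for (j in seq_len(nrow(rec))) {
          recseq <- substr(s, rec$start[j], rec$end[j])
          rep <- map_rec_positions(recseq, reference)
          if (rep$reference_coverage < min_coverage) { bad <- TRUE; break }
        }
      }
    }
    calls$excluded_divergent[i] <- bad
  }
  calls
}
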