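# REC active-site conservation: map receiver domains onto CheY reference
# numbering, report the residues at the five canonical active-site positions
# (Mg2+-coordinating Asp/Glu12 and Asp13, phosphoacceptor Asp57,
# phosphoryl-interacting Thr/Ser87 and Lys109), and build sequence-logo
# matrices from query-anchored alignments.

#' The packaged CheY reference sequence
#'
#' The 129-aa Escherichia coli CheY sequence (UniProt P0AE67), numbering
#' including the initiator Met, so that the canonical active-site residues sit
#' at D12, D13, D57, T87 and K109. Any CheY-like receiver-domain sequence can
#' be substituted via the `path` argument.
#'
#' @param path optional FASTA with a single replacement reference
#' @return character scalar, the reference amino-acid sequence
#' @export
rec_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cheY_reference.fasta",
                        package = "tcscensus")
  }
  as.character(Biostrings::readAAStringSet(path))[[1]]
}

# canonical CheY active-site positions (reference numbering)
REC_SITE_POSITIONS <- c(12L, 13L, 57L, 87L, 109L)

align_global <- function(query, reference) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
}

#' Map a REC domain onto reference active-site numbering
#'
#' Globally aligns `rec_sequence` to the reference (Needleman-Wunsch, BLOSUM62,
#' affine gaps) and reports the query residue aligned to each canonical
#' position (`-` when unaligned). `reference_coverage` is the fraction of
#' reference positions aligned to a query residue. The `phosphorylatable`
#' verdict requires the phosphoacceptor Asp at position 57 plus at least
#' `min_auxiliary` of the four auxiliary sites (12 in D/E, 13 = D, 87 in T/S,
#' 109 = K). Alignments with identity below `identity_floor` are treated as
#' non-alignable: coverage 0, all positions gapped, verdict `FALSE`.
#'
#' @param rec_sequence amino-acid string of the REC segment
#' @param reference reference sequence (default [rec_reference()])
#' @param positions reference positions to report (default c(12,13,57,87,109))
#' @param min_auxiliary auxiliary sites required alongside D57 (default 3)
#' @param identity_floor minimum alignment identity for a credible REC
#'   (default 0.20)
#' @return one-row data.frame: `residue_12`, `residue_13`, `residue_57`,
#'   `residue_87`, `residue_109`, `reference_coverage`, `identity`,
#'   `phosphorylatable`
#' @export
map_rec_positions <- function(rec_sequence, reference = rec_reference(),
                              positions = REC_SITE_POSITIONS,
                              min_auxiliary = 3L, identity_floor = 0.20) {
  stopifnot(nzchar(rec_sequence), nzchar(reference))
  aln <- align_global(rec_sequence, reference)
  qa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  identity <- sum(qa == ra & ra != "-") / nchar(reference)

  res <- setNames(rep("-", length(positions)), positions)
  covered <- 0L
  if (identity >= identity_floor) {
    rpos <- cumsum(ra != "-")
    aligned <- ra != "-" & qa != "-"
    covered <- sum(aligned)
    for (k in seq_along(positions)) {
      hit <- which(aligned & rpos == positions[k])
      if (length(hit)) res[k] <- qa[hit[1]]
    }
    coverage <- covered / nchar(reference)
  } else {
    coverage <- 0
  }

  aux <- c(res[as.character(12)] %in% c("D", "E"),
           res[as.character(13)] == "D",
           res[as.character(87)] %in% c("T", "S"),
           res[as.character(109)] == "K")
  verdict <- identical(res[[as.character(57)]], "D") &&
    sum(aux) >= min_auxiliary && coverage > 0

  out <- as.data.frame(as.list(setNames(res, paste0("residue_", positions))),
                       stringsAsFactors = FALSE)
  out$reference_coverage <- coverage
  out$identity <- identity
  out$phosphorylatable <- verdict
  out
}

#' REC-site reports for classified proteins
#'
#' Extracts every receiver segment from the architectures of REC-containing
#' calls and runs [map_rec_positions()] on each.
#'
#' @param archs named list of `tcs_architecture`
#' @param proteins protein table with sequences
#' @param reference reference sequence (default [rec_reference()])
#' @param ... passed to [map_rec_positions()]
#' @return data.frame with `protein_id`, `rec_index`, the residue columns,
#'   `reference_coverage`, `identity`, `phosphorylatable`
#' @export
rec_site_reports <- function(archs, proteins, reference = rec_reference(),
                             ...) {
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  rows <- list()
  for (a in archs) {
    rec <- a$segments[a$segments$role == "receiver", , drop = FALSE]
    if (!nrow(rec)) next
    s <- seqs[[a$protein_id]]
    if (is.null(s) || is.na(s)) next
    for (j in seq_len(nrow(rec))) {
      rep <- map_rec_positions(substr(s, rec$start[j], rec$end[j]),
                               reference = reference, ...)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(protein_id = a$protein_id, rec_index = j,
                         stringsAsFactors = FALSE), rep)
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(), rec_index = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Position frequency / information matrix for a sequence logo
#'
#' Takes a list of equal-length gapped sequences. If `anchor` is given
#' (query-anchored convention), columns where the anchor row has a gap are
#' dropped before counting. Per column, residue frequencies are computed over
#' non-gap residues (gaps are excluded from the denominator) and the
#' information content is `R = log2(20) - H` with `H` the Shannon entropy in
#' bits; no small-sample correction is applied. All-gap columns get
#' information 0 with a warning.
#'
#' @param alignment character vector of aligned, equal-length sequences
#'   (gap = `-`)
#' @param anchor optional anchor (reference) row, same length
#' @return list of class `tcs_logo`: `frequencies` (20 x L matrix, rows AA20),
#'   `information` (numeric length L, bits), `n` (non-gap count per column)
#' @export
logo_matrix <- function(alignment, anchor = NULL) {
  stopifnot(length(alignment) >= 1)
  width <- unique(nchar(alignment))
  if (length(width) != 1) abort("logo_matrix: sequences differ in length")
  rows <- do.call(rbind, strsplit(toupper(alignment), ""))
  if (!is.null(anchor)) {
    if (nchar(anchor) != width) abort("logo_matrix: anchor length mismatch")
    keep <- strsplit(toupper(anchor), "")[[1]] != "-"
    rows <- rows[, keep, drop = FALSE]
  }
  L <- ncol(rows)
  freq <- matrix(0, nrow = length(AA20), ncol = L, dimnames = list(AA20, NULL))
  info <- numeric(L)
  n <- integer(L)
  for (j in seq_len(L)) {
    col <- rows[, j]
    col <- col[col %in% AA20]
    n[j] <- length(col)
    if (!n[j]) {
      warning("logo_matrix: column ", j, " contains only gaps; information 0")
      next
    }
    f <- table(factor(col, levels = AA20)) / n[j]
    freq[, j] <- as.numeric(f)
    p <- f[f > 0]
    info[j] <- log2(20) - sum(-p * log2(p))
  }
  structure(list(frequencies = freq, information = info, n = n),
            class = "tcs_logo")
}

#' @export
print.tcs_logo <- function(x, ...) {
  cat("tcs_logo:", ncol(x$frequencies), "columns; information (bits):\n")
  print(round(x$information, 3))
  invisible(x)
}
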