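# resolve raw, possibly overlapping domain hits into a linear architecture
# with explicit unassigned gaps, and render canonical architecture strings
# such as "REC-(PAS)2-HisKA-HATPase".

overlap_len <- function(s1, e1, s2, e2) {
  max(0L, min(e1, e2) - max(s1, s2) + 1L)
}

# acceptance rule shared by the greedy resolver and the brute-force oracle:
# a candidate is compatible with an accepted hit iff their overlap is
# <= tol of the shorter of the two
hits_compatible <- function(s1, e1, s2, e2, tol = 0.30) {
  ov <- overlap_len(s1, e1, s2, e2)
  shorter <- min(e1 - s1 + 1L, e2 - s2 + 1L)
  ov <= tol * shorter
}

# priority order: ascending e-value, ties by descending score then
# ascending start (fixed for determinism)
hit_priority_order <- function(hits) {
  order(hits$evalue, -hits$score, hits$start)
}

#' Resolve domain hits into a linear architecture
#'
#' Greedy selection in order of ascending e-value (ties broken by descending
#' bit score, then ascending start): a hit is accepted iff it overlaps every
#' previously accepted hit by at most `overlap_tol` of the shorter of the two
#' segments. Accepted segments are kept with their original coordinates
#' (overlaps within tolerance are not trimmed) and ordered by start. Gaps are
#' the complement of the accepted segments within `[1, length]`.
#'
#' @param hits data.frame of hits for one protein ([read_domain_hits()] rows)
#' @param protein one-row data.frame (or list) with at least `protein_id` and
#'   `length`
#' @param roles a [domain_roles()] dictionary used to annotate segment roles
#' @param overlap_tol maximum tolerated mutual overlap, as a fraction of the
#'   shorter segment (default 0.30)
#' @return object of class `tcs_architecture`: list with `protein_id`,
#'   `length`, `segments` (data.frame `domain_name`, `role`, `start`, `end`,
#'   sorted by start) and `gaps` (data.frame `start`, `end`)
#' @export
resolve_hits <- function(hits, protein, roles = domain_roles(),
                         overlap_tol = 0.30) {
  pid <- protein$protein_id[1]
  plen <- as.integer(protein$length[1])
  if (nrow(hits)) {
    if (!all(hits$protein_id == pid)) {
      abort("resolve_hits: hits reference more than one protein")
    }
    past <- hits$end > plen
    if (any(past)) {
      warning(pid, ": discarded ", sum(past),
              " hit(s) extending past protein length")
      hits <- hits[!past, , drop = FALSE]
    }
  }
  acc <- integer(0)
  if (nrow(hits)) {
    ord <- hit_priority_order(hits)
    for (i in ord) {
      ok <- all(vapply(acc, function(j) {
        hits_compatible(hits$start[i], hits$end[i],
                        hits$start[j], hits$end[j], tol = overlap_tol)
      }, logical(1)))
      if (ok) acc <- c(acc, i)
    }
  }
  seg <- hits[acc, , drop = FALSE]
  seg <- seg[order(seg$start, seg$end), , drop = FALSE]
  segments <- data.frame(
    domain_name = seg$domain_name,
    role = if (nrow(seg)) lookup_role(seg$domain_name, roles, seg$accession)
           else character(0),
    start = seg$start, end = seg$end,
    stringsAsFactors = FALSE)
  rownames(segments) <- NULL
  structure(
    list(protein_id = pid, length = plen, segments = segments,
         gaps = segment_gaps(segments, plen)),
    class = "tcs_architecture")
}

# complement of the segments within [1, length]; overlapping-in-tolerance
# segments are merged for gap purposes
segment_gaps <- function(segments, length) {
  if (!nrow(segments)) {
    if (length >= 1L) {
      return(data.frame(start = 1L, end = as.integer(length)))
    }
    return(data.frame(start = integer(), end = integer()))
  }
  s <- segments[order(segments$start, segments$end), , drop = FALSE]
  cov_s <- integer(0); cov_e <- integer(0)
  for (i in seq_len(nrow(s))) {
    if (length(cov_s) && s$start[i] <= cov_e[length(cov_e)] + 1L) {
      cov_e[length(cov_e)] <- max(cov_e[length(cov_e)], s$end[i])
    } else {
      cov_s <- c(cov_s, s$start[i]); cov_e <- c(cov_e, s$end[i])
    }
  }
  gs <- integer(0); ge <- integer(0)
  if (cov_s[1] > 1L) { gs <- 1L; ge <- cov_s[1] - 1L }
  if (length(cov_s) > 1L) {
    gs <- c(gs, cov_e[-length(cov_e)] + 1L)
    ge <- c(ge, cov_s[-1] - 1L)
  }
  if (cov_e[length(cov_e)] < length) {
    gs <- c(gs, cov_e[length(cov_e)] + 1L)
    ge <- c(ge, as.integer(length))
  }
  keep <- ge >= gs
  data.frame(start = as.integer(gs[keep]), end = as.integer(ge[keep]))
}

#' @export
print.tcs_architecture <- function(x, ...) {
  cat(x$protein_id, " (", x$length, " aa): ",
      architecture_string(x, collapse_repeats = TRUE), "\n", sep = "")
  invisible(x)
}

#' Render the canonical architecture string
#'
#' Segment names joined with `-` in N- to C-terminal order. With
#' `collapse_repeats`, runs of `k >= 2` identical names become `(NAME)k`
#' (e.g. `REC-(PAS)2-HisKA`). With `show_gaps`, unassigned gaps of at least
#' `gap_min` residues are rendered as `X` placeholders.
#'
#' @param arch a `tcs_architecture` from [resolve_hits()]
#' @param collapse_repeats collapse consecutive repeats (default `FALSE`)
#' @param show_gaps render long gaps as `X` (default `FALSE`)
#' @param gap_min minimum gap length rendered when `show_gaps` (default 70)
#' @return a character scalar; `""` for an empty architecture
#' @export
architecture_string <- function(arch, collapse_repeats = FALSE,
                                show_gaps = FALSE, gap_min = 70L) {
  seg <- arch$segments
  tokens <- character(0)
  starts <- integer(0)
  if (nrow(seg)) { tokens <- seg$domain_name; starts <- seg$start }
  if (show_gaps && nrow(arch$gaps)) {
    g <- arch$gaps
    long <- (g$end - g$start + 1L) >= gap_min
    tokens <- c(tokens, rep("X", sum(long)))
    starts <- c(starts, g$start[long])
  }
  if (!length(tokens)) return("")
  tokens <- tokens[order(starts)]
  if (collapse_repeats) {
    r <- rle(tokens)
    tokens <- ifelse(r$lengths >= 2L,
                     sprintf("(%s)%d", r$values, r$lengths),
                     r$values)
  }
  paste(tokens, collapse = "-")
}

#' Build an architecture from a dash-joined string
#'
#' Convenience constructor for worked examples and simulation: expands
#' `(NAME)k` repeats and lays the named domains along a protein with typical
#' domain lengths and short linkers. The inverse of [architecture_string()]
#' up to coordinates.
#'
#' @param string architecture string, e.g. `"REC-(PAS)2-HisKA-HATPase"`
#' @param protein_id protein identifier for the result
#' @param roles a [domain_roles()] dictionary
#' @param linker residues between consecutive domains (default 10)
#' @param lengths named integer vector of per-domain lengths overriding the
#'   built-in typical lengths
#' @return a `tcs_architecture`
#' @export
architecture_from_string <- function(string, protein_id = "p1",
                                     roles = domain_roles(), linker = 10L,
                                     lengths = NULL) {
  names_out <- character(0)
  if (nzchar(string)) {
    for (tok in strsplit(string, "-", fixed = TRUE)[[1]]) {
      m <- regmatches(tok, regexec("^\\((.+)\\)(\\d+)$", tok))[[1]]
      if (length(m) == 3) {
        names_out <- c(names_out, rep(m[2], as.integer(m[3])))
      } else {
        names_out <- c(names_out, tok)
      }
    }
  }
  len_of <- function(nm) {
    if (!is.null(lengths) && nm %in% names(lengths)) return(as.integer(lengths[[nm]]))
    as.integer(domain_typical_length(nm))
  }
  pos <- 1L + linker
  segs <- lapply(names_out, function(nm) {
    L <- len_of(nm)
    s <- pos; e <- pos + L - 1L
    pos <<- e + linker + 1L
    data.frame(domain_name = nm, start = s, end = e, stringsAsFactors = FALSE)
  })
  seg <- if (length(segs)) do.call(rbind, segs) else
    data.frame(domain_name = character(), start = integer(), end = integer())
  plen <- if (nrow(seg)) max(seg$end) + linker else 2L * linker
  segments <- data.frame(
    domain_name = seg$domain_name,
    role = if (nrow(seg)) lookup_role(seg$domain_name, roles) else character(0),
    start = seg$start, end = seg$end, stringsAsFactors = FALSE)
  structure(
    list(protein_id = protein_id, length = as.integer(plen),
         segments = segments, gaps = segment_gaps(segments, plen)),
    class = "tcs_architecture")
}

# typical domain lengths (aa) used by the string constructor and the
# synthetic generator
domain_typical_length <- function(name) {
  known <- c(REC = 120, PAS = 100, GAF = 150, HisKA = 65, HATPase = 110,
             HATPase_c = 110, Hpt = 80, CheW = 140, CheB = 180, HalX = 90,
             BAT = 130, HTH_10 = 60, wHTH = 70, HxlR = 95, MEDS = 90,
             PocR = 100, Cache = 100, HAMP = 50, MCPsignal = 180,
             TPR = 34, DUF835 = 180, iKaiC = 230, KaiC = 230,
             BcsA = 200, Glyco_transf_2_3 = 200,
             HalOD1 = 80, HalOD2 = 130, MetOD1 = 140, MetOD2 = 80,
             MetOD3 = 180, MetOD4 = 80, MetOD5 = 300, NitrOD1 = 70,
             NitrOD2 = 90, NitrOD3 = 120, NitrOD4 = 75, NitrOD5 = 100,
             TackOD1 = 200, AcidOD1 = 70, HisKA_7TM = 210, HisKA_4TM = 140)
  out <- unname(known[name])
  out[is.na(out)] <- 100
  out
}

#' Resolve architectures for a whole hit table
#'
#' @param hits hit table for many proteins ([read_domain_hits()])
#' @param proteins protein table ([read_protein_fasta()]); proteins without
#'   hits get an empty architecture
#' @param roles a [domain_roles()] dictionary
#' @param overlap_tol see [resolve_hits()]
#' @return named list of `tcs_architecture`, one per protein in `proteins`
#' @export
resolve_architectures <- function(hits, proteins, roles = domain_roles(),
                                  overlap_tol = 0.30) {
  split_hits <- split(hits, hits$protein_id)
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- proteins[i, , drop = FALSE]
    h <- split_hits[[p$protein_id]]
    if (is.null(h)) h <- empty_hits()
    resolve_hits(h, p, roles = roles, overlap_tol = overlap_tol)
  })
  names(out) <- proteins$protein_id
  out
}

#' Architecture summary table
#'
#' @param archs list of `tcs_architecture`
#' @return data.frame `protein_id`, `architecture_string`, `n_segments`,
#'   `total_gap_aa`
#' @export
architecture_table <- function(archs) {
  data.frame(
    protein_id = vapply(archs, `[[`, character(1), "protein_id"),
    architecture_string = vapply(archs, architecture_string, character(1),
                                 collapse_repeats = TRUE),
    n_segments = vapply(archs, function(a) nrow(a$segments), integer(1)),
    total_gap_aa = vapply(archs, function(a) {
      if (!nrow(a$gaps)) 0L else sum(a$gaps$end - a$gaps$start + 1L)
    }, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
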