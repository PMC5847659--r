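# delineation of candidate novel output domains: harvest unassigned regions
# of >= 70 aa from resolved architectures, cluster them by pairwise alignment
# identity into families (single linkage), and report per-family statistics
# and architecture contexts.

#' Extract long unassigned regions from an architecture
#'
#' All maximal gaps of at least `min_len` residues, annotated with the names
#' of the flanking segments (or `N-terminus` / `C-terminus`). A protein with
#' no assigned domains at all yields one whole-chain region, so stand-alone
#' members of unrecognized families remain eligible.
#'
#' @param arch a `tcs_architecture`
#' @param min_len minimum region length in aa (default 70, the delineation
#'   threshold for putative novel output domains)
#' @return data.frame `protein_id`, `start`, `end`, `length`, `flank_left`,
#'   `flank_right`
#' @export
extract_unassigned <- function(arch, min_len = 70L) {
  g <- arch$gaps
  if (!nrow(g)) {
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      flank_left = character(), flank_right = character(),
                      stringsAsFactors = FALSE))
  }
  len <- g$end - g$start + 1L
  keep <- len >= min_len
  g <- g[keep, , drop = FALSE]
  len <- len[keep]
  seg <- arch$segments
  flank <- function(pos, side) {
    if (side == "left") {
      prev <- seg$domain_name[seg$end < pos]
      if (length(prev)) tail(prev, 1) else "N-terminus"
    } else {
      nxt <- seg$domain_name[seg$start > pos]
      if (length(nxt)) nxt[1] else "C-terminus"
    }
  }
  data.frame(
    protein_id = rep(arch$protein_id, nrow(g)),
    start = g$start, end = g$end, length = len,
    flank_left = vapply(g$start, flank, character(1), side = "left"),
    flank_right = vapply(g$end, flank, character(1), side = "right"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise identity between two pre-delimited regions
#'
#' End-gap-free (overlap) alignment with BLOSUM62 and affine gaps. Identity
#' is the fraction of matching columns among aligned columns; coverage is the
#' number of aligned columns of the shorter region over its length.
#'
#' @param a,b amino-acid strings
#' @return list `identity`, `coverage`
#' @export
region_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "overlap")
  qa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  aligned <- qa != "-" & ra != "-"
  n_aln <- sum(aligned)
  if (!n_aln) return(list(identity = 0, coverage = 0))
  list(identity = sum(qa == ra & aligned) / n_aln,
       coverage = n_aln / min(nchar(a), nchar(b)))
}

#' Cluster unassigned regions into candidate novel-domain families
#'
#' Computes pairwise alignment identity for all region pairs; two regions are
#' linked iff identity >= `min_identity` over at least `min_coverage` of the
#' shorter region. Families are the connected components (single linkage);
#' singletons are reported as single-member families. The representative of a
#' family is its medoid (member with the highest summed identity to the other
#' members; ties to the first by protein id).
#'
#' @param regions data.frame from [extract_unassigned()] (rows for many
#'   proteins concatenated)
#' @param proteins protein table with sequences
#' @param min_identity identity threshold (default 0.30)
#' @param min_coverage coverage-of-shorter threshold (default 0.70)
#' @return `regions` with added columns `family_id`, `representative`
#'   (logical), and `sequence`
#' @export
cluster_regions <- function(regions, proteins, min_identity = 0.30,
                            min_coverage = 0.70) {
  if (!nrow(regions)) {
    regions$family_id <- character(0)
    regions$representative <- logical(0)
    regions$sequence <- character(0)
    return(regions)
  }
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  regions$sequence <- vapply(seq_len(nrow(regions)), function(i) {
    s <- seqs[[regions$protein_id[i]]]
    if (is.null(s) || is.na(s)) NA_character_
    else substr(s, regions$start[i], regions$end[i])
  }, character(1))
  has_seq <- !is.na(regions$sequence)
  if (any(!has_seq)) {
    warning(sum(!has_seq), " region(s) without sequence skipped")
    regions <- regions[has_seq, , drop = FALSE]
  }
  n <- nrow(regions)
  idm <- matrix(0, n, n)
  parent <- uf_new(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        r <- region_identity(regions$sequence[i], regions$sequence[j])
        idm[i, j] <- idm[j, i] <- r$identity
        if (r$identity >= min_identity && r$coverage >= min_coverage) {
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }
  comp <- uf_components(parent)
  # stable family ids: order components by their first member's protein id
  first <- vapply(unique(comp), function(k) {
    ord <- order(regions$protein_id[comp == k], regions$start[comp == k])
    which(comp == k)[ord[1]]
  }, integer(1))
  rank <- order(regions$protein_id[first], regions$start[first])
  fam_of <- match(comp, unique(comp)[rank])
  regions$family_id <- sprintf("NOD%03d", fam_of)
  regions$representative <- FALSE
  for (k in unique(fam_of)) {
    members <- which(fam_of == k)
    if (length(members) == 1) {
      regions$representative[members] <- TRUE
    } else {
      score <- rowSums(idm[members, members, drop = FALSE])
      ord <- order(-score, regions$protein_id[members], regions$start[members])
      regions$representative[members[ord[1]]] <- TRUE
    }
  }
  rownames(regions) <- NULL
  regions
}

#' Per-family report for candidate novel domains
#'
#' For each family: member count, median and range of member lengths, the
#' distinct architecture contexts in which the region occurs (the flanking
#' architecture with the family id inserted), and the genome / taxon
#' distribution when available.
#'
#' @param clustered output of [cluster_regions()]
#' @param archs architectures for the member proteins
#' @param proteins optional protein table (genome distribution)
#' @param taxonomy optional `genome_id`, `taxon` map (taxon distribution)
#' @return data.frame, one row per family: `family_id`, `n_members`,
#'   `median_length`, `min_length`, `max_length`, `representative`,
#'   `contexts`, `genomes`, `taxa`
#' @export
family_report <- function(clustered, archs, proteins = NULL,
                          taxonomy = NULL) {
  if (!nrow(clustered)) {
    return(data.frame(family_id = character(), n_members = integer(),
                      median_length = numeric(), min_length = integer(),
                      max_length = integer(), representative = character(),
                      contexts = character(), genomes = character(),
                      taxa = character(), stringsAsFactors = FALSE))
  }
  gid <- if (!is.null(proteins)) {
    setNames(proteins$genome_id, proteins$protein_id)
  } else NULL
  rows <- lapply(split(clustered, clustered$family_id), function(m) {
    ctx <- vapply(seq_len(nrow(m)), function(i) {
      a <- archs[[m$protein_id[i]]]
      context_string(a, m$start[i], m$end[i], m$family_id[i])
    }, character(1))
    genomes <- if (!is.null(gid)) sort(unique(unname(gid[m$protein_id]))) else
      character(0)
    taxa <- if (!is.null(taxonomy) && length(genomes)) {
      sort(unique(taxonomy$taxon[match(genomes, taxonomy$genome_id)]))
    } else character(0)
    rep_row <- m[m$representative, , drop = FALSE][1, ]
    data.frame(
      family_id = m$family_id[1],
      n_members = nrow(m),
      median_length = median(m$length),
      min_length = min(m$length),
      max_length = max(m$length),
      representative = sprintf("%s:%d-%d", rep_row$protein_id,
                               rep_row$start, rep_row$end),
      contexts = paste(sort(unique(ctx)), collapse = "; "),
      genomes = paste(genomes, collapse = ","),
      taxa = paste(taxa, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# architecture string with the candidate family inserted in place of its gap
context_string <- function(arch, start, end, family_id) {
  seg <- arch$segments
  tokens <- c(seg$domain_name, family_id)
  starts <- c(seg$start, start)
  paste(tokens[order(starts)], collapse = "-")
}
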