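# readers and writers for the formats the pipeline touches:
# HMMER3 domtblout / a TSV hit dialect, protein FASTA, GFF3 gene features,
# TMHMM-style segment tables, and the TSV outputs of downstream stages.

#' Load the domain-role dictionary
#'
#' Maps domain names (and optionally Pfam-style accessions) to functional
#' roles: `phosphotransfer_dimerization` (HisKA-like), `phosphotransfer_atpase`
#' (HATPase-like), `hpt`, `receiver` (REC), `sensor` (PAS, GAF, Cache, MEDS,
#' PocR, ...), `output_dna_binding` (HTH families, BAT), `output_enzymatic`
#' (CheB, KaiC-like ATPase, BcsA, GGDEF, EAL, ...), `output_halx`,
#' `output_novel` (the provisional HalOD/MetOD/NitrOD/TackOD/AcidOD families),
#' `output_other`, and `chew`. The packaged dictionary covers the archaeal
#' TCS vocabulary; it is an editable three-column TSV
#' (`domain_name`, `accession`, `role`) so users can extend it.
#'
#' @param path path to a dictionary TSV; `NULL` loads the packaged one.
#' @return data.frame of class `tcs_roles` with columns
#'   `domain_name`, `accession`, `role`.
#' @export
domain_roles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "domain_roles.tsv", package = "tcscensus")
  }
  d <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                  colClasses = "character", na.strings = NULL)
  need <- c("domain_name", "accession", "role")
  if (!all(need %in% names(d))) {
    abort("role dictionary must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(d$role), TCS_ROLES)
  if (length(bad)) abort("unknown role(s) in dictionary: ", paste(bad, collapse = ", "))
  if (anyDuplicated(tolower(d$domain_name))) {
    abort("duplicate domain names in role dictionary")
  }
  class(d) <- c("tcs_roles", "data.frame")
  d
}

#' Look up domain roles by name or accession
#'
#' Lookup is case-insensitive on the domain name and exact on the accession;
#' the accession wins when both match different entries. Names absent from the
#' dictionary get role `"unknown"` rather than an error, so novel or
#' unannotated domains flow through the pipeline.
#'
#' @param domain_name character vector of domain names
#' @param roles a [domain_roles()] dictionary
#' @param accession optional character vector of accessions, recycled rules
#'   as `domain_name`
#' @return character vector of roles
#' @export
lookup_role <- function(domain_name, roles = domain_roles(), accession = NULL) {
  out <- roles$role[match(tolower(domain_name), tolower(roles$domain_name))]
  if (!is.null(accession)) {
    acc <- as.character(accession)
    has_acc <- !is.na(acc) & nzchar(acc)
    by_acc <- roles$role[match(acc, roles$accession)]
    use <- has_acc & !is.na(by_acc)
    out[use] <- by_acc[use]
  }
  out[is.na(out)] <- "unknown"
  out
}

empty_hits <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             accession = character(), start = integer(), end = integer(),
             score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

validate_hits <- function(hits, lines = NULL, path = "<hits>") {
  bad <- which(!is.finite(hits$start) | !is.finite(hits$end) |
                 hits$start < 1L | hits$end < hits$start)
  if (length(bad)) {
    where <- if (is.null(lines)) bad[1] else lines[bad[1]]
    abort(sprintf("%s: malformed coordinates at line %d (need 1 <= start <= end)",
                  path, where))
  }
  bad_e <- which(!is.finite(hits$evalue) | hits$evalue < 0)
  if (length(bad_e)) {
    where <- if (is.null(lines)) bad_e[1] else lines[bad_e[1]]
    abort(sprintf("%s: malformed e-value at line %d", path, where))
  }
  hits
}

#' Read per-domain hits (HMMER3 domtblout or TSV dialect)
#'
#' Accepts either HMMER3 `--domtblout` output (hmmscan orientation: the target
#' is the domain model, the query is the protein; envelope coordinates and the
#' independent per-domain e-value are used) or a tab-separated dialect with
#' header `protein_id  domain_name  accession  start  end  score  evalue`.
#' The format is auto-detected from the header line. Coordinates are 1-based
#' inclusive amino-acid positions throughout.
#'
#' Duplicate or overlapping hits are retained as read; resolving them is the
#' job of [resolve_hits()].
#'
#' @param path input file path
#' @return data.frame with columns `protein_id`, `domain_name`, `accession`,
#'   `start`, `end`, `score`, `evalue`; zero rows for an empty file.
#' @export
read_domain_hits <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  if (!any(keep)) return(empty_hits())
  first <- raw[keep][1]
  if (grepl("^protein_id\t", first)) {
    read_hits_tsv(path)
  } else {
    read_domtblout(path)
  }
}

read_hits_tsv <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                  comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("protein_id", "domain_name", "accession", "start", "end",
            "score", "evalue")
  if (!all(need %in% names(d))) {
    abort(path, ": TSV hits need header columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    protein_id = d$protein_id, domain_name = d$domain_name,
    accession = d$accession,
    start = suppressWarnings(as.integer(d$start)),
    end = suppressWarnings(as.integer(d$end)),
    score = suppressWarnings(as.numeric(d$score)),
    evalue = suppressWarnings(as.numeric(d$evalue)),
    stringsAsFactors = FALSE)
  validate_hits(out, path = path)
}

read_domtblout <- function(path) {
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  raw <- raw[keep]; lineno <- lineno[keep]
  if (!length(raw)) return(empty_hits())
  fields <- strsplit(trimws(raw), "\\s+")
  nf <- lengths(fields)
  short <- which(nf < 22)
  if (length(short)) {
    abort(sprintf("%s: malformed domtblout line %d (%d fields, need >= 22)",
                  path, lineno[short[1]], nf[short[1]]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(
    protein_id  = col(4),                  # query name = protein
    domain_name = col(1),                  # target name = domain model
    accession   = sub("\\.\\d+$", "", col(2)),
    start  = suppressWarnings(as.integer(col(20))),  # env from
    end    = suppressWarnings(as.integer(col(21))),  # env to
    score  = suppressWarnings(as.numeric(col(14))),  # per-domain bit score
    evalue = suppressWarnings(as.numeric(col(13))),  # i-Evalue
    stringsAsFactors = FALSE)
  out$accession[out$accession == "-"] <- ""
  validate_hits(out, lines = lineno, path = path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences
#' @param genome_id genome identifier recorded on every record; defaults to
#'   the file name without extension
#' @param keep_sequence keep the sequence string (set `FALSE` to save memory
#'   when only lengths are needed)
#' @return data.frame with columns `protein_id`, `genome_id`, `length`,
#'   `sequence` (NA when `keep_sequence = FALSE`)
#' @export
read_protein_fasta <- function(path, genome_id = NULL, keep_sequence = TRUE) {
  gid <- genome_id %||% tools::file_path_sans_ext(basename(path))
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  data.frame(
    protein_id = ids,
    genome_id = gid,
    length = Biostrings::width(aa),
    sequence = if (keep_sequence) as.character(aa) else NA_character_,
    stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins data.frame as from [read_protein_fasta()] with sequences
#' @param path output file
#' @return `path`, invisibly
#' @export
write_protein_fasta <- function(proteins, path) {
  stopifnot(all(!is.na(proteins$sequence)))
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$protein_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Keeps only features carrying the protein-identifier attribute (default
#' `ID`); others are skipped with a warning. Strand is normalized to
#' `+` / `-`.
#'
#' @param path GFF3 file
#' @param id_attribute attribute key holding the protein identifier
#' @param genome_id genome identifier; defaults to file name sans extension
#' @param types feature types to keep (default `CDS` and `gene`)
#' @return data.frame with columns `genome_id`, `contig`, `protein_id`,
#'   `start`, `end`, `strand`
#' @export
read_gene_features <- function(path, id_attribute = "ID", genome_id = NULL,
                               types = c("CDS", "gene")) {
  gid <- genome_id %||% tools::file_path_sans_ext(basename(path))
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (!is.null(types) && "type" %in% names(g)) {
    g <- g[as.character(g$type) %in% types, , drop = FALSE]
  }
  if (!id_attribute %in% names(g)) {
    warning(path, ": no '", id_attribute, "' attribute on any feature; ",
            "returning 0 features")
    g <- g[0, , drop = FALSE]
    pid <- character()
  } else {
    pid <- as.character(g[[id_attribute]])
    miss <- is.na(pid) | !nzchar(pid)
    if (any(miss)) {
      warning(path, ": skipped ", sum(miss), " feature(s) without a '",
              id_attribute, "' attribute")
      g <- g[!miss, , drop = FALSE]
      pid <- pid[!miss]
    }
  }
  data.frame(
    genome_id = rep(gid, nrow(g)),
    contig = as.character(g$seqid),
    protein_id = pid,
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = ifelse(as.character(g$strand) == "-", "-", "+"),
    stringsAsFactors = FALSE)
}

#' Write gene features as GFF3
#'
#' @param features data.frame as from [read_gene_features()]
#' @param path output file
#' @param type feature type to write (default `CDS`)
#' @return `path`, invisibly
#' @export
write_gene_features <- function(features, path, type = "CDS") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\ttcscensus\t%s\t%d\t%d\t.\t%s\t0\tID=%s",
                     features$contig, type, features$start, features$end,
                     features$strand, features$protein_id), con)
  invisible(path)
}

#' Read a TMHMM-style transmembrane-segment table
#'
#' Tab-separated with header `protein_id  tm_start  tm_end`; one row per
#' predicted transmembrane segment.
#'
#' @param path input TSV
#' @return data.frame with columns `protein_id`, `tm_start`, `tm_end`
#' @export
read_tm_table <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "tm_start", "tm_end")
  if (!all(need %in% names(d))) {
    abort(path, ": TM table needs columns: ", paste(need, collapse = ", "))
  }
  d$tm_start <- as.integer(d$tm_start)
  d$tm_end <- as.integer(d$tm_end)
  if (any(d$tm_end < d$tm_start)) abort(path, ": tm_end < tm_start")
  d[order(d$protein_id, d$tm_start), , drop = FALSE]
}

#' Write / read pipeline tables as TSV
#'
#' Plain tab-separated tables with a header; `read_tcs_table()` round-trips
#' anything written by `write_tcs_table()` (classification calls, census
#' rows, neighborhood calls, ...).
#'
#' @param x data.frame to write
#' @param path file path
#' @return `write_tcs_table()` returns `path` invisibly; `read_tcs_table()`
#'   returns a data.frame.
#' @export
write_tcs_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_tcs_table
#' @export
read_tcs_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE, na.strings = "NA")
}
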