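# Readers/writers for the formats the pipeline touches: FASTQ (Phred+33),
# FASTA, the sample manifest, marker-gene hit tables, and the trait table.
# All tables are tab-separated with a header; missing values are written as
# "NA" and read back from "NA" or the empty string.

.normalize_dna <- function(seqs, what = "sequence") {
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    warning(sprintf("%s contains IUPAC ambiguity codes; mapped to N", what),
            call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  seqs
}

#' Read a FASTQ file
#'
#' Expects 4-line records with Phred+33 qualities.  Sequences are
#' uppercased, `U` is mapped to `T`, and IUPAC ambiguity codes other than N
#' are mapped to N with a warning.
#'
#' @param path Path to an (optionally gzipped) FASTQ file.
#' @return A `read_set`: a data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop_format("%s: FASTQ line count %d is not a multiple of 4", path, length(lines))
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(read_set(character(), character(), character()))
  at <- lines[seq(1L, by = 4L, length.out = n)]
  if (!all(startsWith(at, "@"))) {
    stop_format("%s: record header lacking '@' near record %d",
                path, which(!startsWith(at, "@"))[1])
  }
  ids <- sub("\\s.*$", "", substring(at, 2L))
  seqs <- .normalize_dna(lines[seq(2L, by = 4L, length.out = n)])
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad)) {
    stop_format("record '%s': sequence and quality lengths differ (%d vs %d)",
                ids[bad][1], nchar(seqs[bad][1]), nchar(quals[bad][1]))
  }
  qq <- utf8ToInt(paste(quals, collapse = ""))
  if (length(qq) && (min(qq) < 33L || max(qq) > 93L)) {
    stop_format("%s: quality characters outside the Phred+33 range [0, 60]", path)
  }
  read_set(ids, seqs, quals)
}

#' Construct a read set
#'
#' @param id,seq,qual Parallel character vectors: read identifiers, DNA
#'   sequences over A/C/G/T/N, and Phred+33 quality strings of matching
#'   length.
#' @return A data frame of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  structure(data.frame(id = as.character(id), seq = as.character(seq),
                       qual = as.character(qual), stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Write a read set as FASTQ (Phred+33)
#'
#' @param reads A [read_set].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a (nucleotide) FASTA file
#'
#' Parsed with Biostrings; sequences are uppercased and normalized to the
#' A/C/G/T/N alphabet (`U` to `T`, other ambiguity codes to N with a
#' warning).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- .normalize_dna(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences as FASTA, wrapped at 80 columns
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

.TREATMENTS <- c("unfertilized", "fertilized")

#' Read a sample manifest
#'
#' Tab-separated with header; required columns `sample_id`, `treatment`,
#' `reads`, `cds`, `markers`, `rrna_16s`, `trna_genes`, `bacterial_proteins`;
#' optional `pc_ratio`, `total_reads`, `retained`.  Sample ids must be
#' unique and treatments must be `fertilized` or `unfertilized`.
#'
#' @param path Path to the manifest TSV.
#' @return A data frame of class `sample_manifest`.
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  req <- c("sample_id", "treatment", "reads", "cds", "markers",
           "rrna_16s", "trna_genes", "bacterial_proteins")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_format("manifest lacks columns: %s", paste(miss, collapse = ", "))
  as_sample_manifest(df)
}

#' Validate a data frame as a sample manifest
#'
#' @param df Data frame with the manifest columns.
#' @return `df` with class `sample_manifest`; `retained` defaults to TRUE
#'   and `total_reads` must be non-negative when present.
#' @export
as_sample_manifest <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop_format("duplicate sample_id: %s", df$sample_id[duplicated(df$sample_id)][1])
  }
  bad <- !df$treatment %in% .TREATMENTS
  if (any(bad)) {
    stop_format("unknown treatment '%s' (expected %s)", df$treatment[bad][1],
                paste(.TREATMENTS, collapse = "/"))
  }
  for (col in intersect(c("rrna_16s", "trna_genes", "bacterial_proteins",
                          "total_reads"), names(df))) {
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) stop_format("negative %s", col)
  }
  if (is.null(df$retained)) df$retained <- TRUE
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Write a sample manifest
#' @param manifest A [as_sample_manifest()] data frame.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  write_tsv_precise(as.data.frame(manifest), path)
}

#' Read a single-copy marker-gene hit table
#'
#' Tab-separated with header and columns `marker_id`, `hit_count`,
#' `marker_length` (positive), optional `units` (`nt` or `aa`).  Marker ids
#' must be unique and counts non-negative.
#'
#' @param path Path to the TSV.
#' @return A data frame of class `marker_table`.
#' @export
read_marker_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  req <- c("marker_id", "hit_count", "marker_length")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_format("marker table lacks columns: %s", paste(miss, collapse = ", "))
  as_marker_table(df)
}

#' Validate a data frame as a marker hit table
#' @param df Data frame with marker table columns.
#' @return `df` with class `marker_table`.
#' @export
as_marker_table <- function(df) {
  if (anyDuplicated(df$marker_id)) {
    stop_format("duplicate marker_id: %s", df$marker_id[duplicated(df$marker_id)][1])
  }
  if (any(df$hit_count < 0)) stop_format("negative hit_count")
  if (any(df$marker_length <= 0)) stop_format("marker_length must be positive")
  if (!is.null(df$units) && !all(df$units %in% c("nt", "aa"))) {
    stop_format("units must be 'nt' or 'aa'")
  }
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Write a marker hit table
#' @param markers A [as_marker_table()] data frame.
#' @param path Output path.
#' @export
write_marker_table <- function(markers, path) {
  write_tsv_precise(as.data.frame(markers), path)
}

#' Write a trait table
#'
#' One row per retained sample, tab-separated, deterministic column order,
#' full double precision (`%.17g`), missing values as `NA`; round-trips
#' losslessly through [read_trait_table()].
#'
#' @param table A trait table (data frame).
#' @param path Output path.
#' @export
write_trait_table <- function(table, path) {
  if (!nrow(table)) stop_domain("empty trait table")
  write_tsv_precise(as.data.frame(table), path)
}

#' Read a trait table written by [write_trait_table()]
#' @param path Path to the TSV.
#' @return A data frame of class `trait_table`.
#' @export
read_trait_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  class(df) <- c("trait_table", "data.frame")
  df
}
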