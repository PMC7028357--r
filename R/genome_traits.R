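# Genome-level community traits: mean genome size via genome equivalents,
# GC content of open reading frames, per-read occurrence rates of rRNA/tRNA
# genes, and sequencing-depth residuals for count traits.

#' Genome equivalents from single-copy marker-gene hits
#'
#' The number of average genome copies sampled in a metagenome, estimated as
#' the mean length-normalized hit count over a set of universal single-copy
#' marker genes: `GE = scale * mean(hit_count / marker_length)`.  With
#' `hit_count` given as read hits, set `scale` to the read length so that a
#' single-copy genome sequenced at 1x yields GE of about 1; with hit counts
#' already expressed as aligned bases, the default `scale = 1` applies.
#'
#' @param markers A [as_marker_table()] data frame with at least one
#'   positive `hit_count`.
#' @param scale Length-units conversion factor (see above); default 1.
#' @return Positive genome-equivalents estimate.
#' @examples
#' m <- as_marker_table(data.frame(marker_id = c("m1", "m2"),
#'                                 hit_count = c(30, 30),
#'                                 marker_length = c(300, 600)))
#' genome_equivalents(m)  # mean(0.1, 0.05) = 0.075
#' @export
genome_equivalents <- function(markers, scale = 1) {
  stopifnot(scale > 0)
  if (!nrow(markers) || all(markers$hit_count == 0)) {
    stop_domain("no marker has a positive hit count")
  }
  scale * mean(markers$hit_count / markers$marker_length)
}

#' Mean genome size in genes per genome equivalent
#'
#' The total number of bacterial predicted proteins divided by the number of
#' genome equivalents: the average number of protein-coding genes per genome
#' in the community.
#'
#' @param bacterial_protein_count Positive integer count of bacterial
#'   predicted proteins in the sample.
#' @param ge Genome equivalents, from [genome_equivalents()].
#' @return Genome size in genes per genome equivalent.
#' @examples
#' mean_genome_size(7500, 2.5)  # 3000 genes/genome
#' @export
mean_genome_size <- function(bacterial_protein_count, ge) {
  if (ge <= 0) stop_domain("genome equivalents must be positive")
  bacterial_protein_count / ge
}

#' Find open reading frames in all six frames
#'
#' An ORF is a maximal stop-free codon run ending at a stop codon or at the
#' sequence end, reported without the stop, with length at least
#' `min_len_nt`.  Runs are not anchored at ATG because read fragments rarely
#' contain true gene starts.  Coordinates are 0-based half-open on the
#' forward strand; `frame` is the frame offset on the scanned strand.
#'
#' @param seq A DNA string.
#' @param min_len_nt Minimum ORF length in nt; must be a positive multiple
#'   of 3 (default 60).
#' @return Data frame with columns `start`, `end`, `strand` (`+`/`-`),
#'   `frame`.
#' @export
find_orfs <- function(seq, min_len_nt = 60L) {
  if (min_len_nt < 3L || min_len_nt %% 3L != 0L) {
    stop_domain("min_len_nt must be a positive multiple of 3, got %d", min_len_nt)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  m <- cpp_find_orfs(toupper(seq), as.integer(min_len_nt))
  data.frame(start = m[, "start"], end = m[, "end"],
             strand = ifelse(m[, "strand"] > 0, "+", "-"),
             frame = m[, "frame"], stringsAsFactors = FALSE)
}

#' Extract ORF sequences found by [find_orfs()]
#'
#' @inheritParams find_orfs
#' @return Character vector of ORF nucleotide sequences (reverse-strand ORFs
#'   are reverse-complemented to their coding orientation).
#' @export
extract_orfs <- function(seq, min_len_nt = 60L) {
  orfs <- find_orfs(seq, min_len_nt)
  if (!nrow(orfs)) return(character())
  seqs <- substring(seq, orfs$start + 1L, orfs$end)
  rev <- orfs$strand == "-"
  if (any(rev)) {
    seqs[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev])))
  }
  seqs
}

#' Pooled GC content of a set of sequences
#'
#' Length-weighted fraction of G+C over all nucleotides of the input
#' sequences (typically ORFs); N is excluded from both numerator and
#' denominator.
#'
#' @param orfs Character vector of DNA strings.
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gc_content("GATTACA")  # 2/7
#' @export
gc_content <- function(orfs) {
  cnt <- cpp_base_counts(orfs)
  tot <- sum(cnt)
  if (tot == 0) stop_domain("no usable (non-N) nucleotides")
  unname((cnt["C"] + cnt["G"]) / tot)
}

#' Pooled GC content of the six-frame ORFs of a read set
#'
#' Streaming equivalent of `gc_content(unlist(lapply(reads, extract_orfs)))`
#' that never materializes the ORF sequences; suitable for millions of
#' reads.
#'
#' @param reads A [read_set] or character vector of sequences.
#' @param min_len_nt Minimum ORF length in nt (multiple of 3).
#' @return GC fraction in `[0, 1]`.
#' @export
orf_gc_content <- function(reads, min_len_nt = 60L) {
  if (min_len_nt < 3L || min_len_nt %% 3L != 0L) {
    stop_domain("min_len_nt must be a positive multiple of 3, got %d", min_len_nt)
  }
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  acc <- cpp_orf_gc_pool(seqs, as.integer(min_len_nt))
  if (acc[2] == 0) stop_domain("no ORF nucleotides at min_len_nt = %d", min_len_nt)
  acc[1] / acc[2]
}

#' Per-read occurrence rate of a genomic feature
#'
#' @param count Non-negative feature count (e.g. tRNA genes detected).
#' @param total_reads Positive total read count of the sample.
#' @return `count / total_reads`.
#' @export
occurrence_rate <- function(count, total_reads) {
  if (any(total_reads <= 0)) stop_domain("total_reads must be positive")
  if (any(count < 0)) stop_domain("negative count")
  count / total_reads
}

#' Sequencing-depth residuals of a count trait
#'
#' Ordinary least squares of `log10(count)` on `log10(depth)` across all
#' retained samples (both treatments pooled); the residuals are a
#' depth-controlled version of the count trait.  When all depths are equal
#' the design is degenerate and the fit falls back to intercept-only
#' residuals with a warning.
#'
#' @param counts Positive per-sample counts.
#' @param depths Positive per-sample total read counts.
#' @return Per-sample residuals (sum to 0 within 1e-9).
#' @export
depth_residuals <- function(counts, depths) {
  if (length(counts) < 3L) stop_domain("need at least 3 samples")
  if (any(counts <= 0)) stop_domain("counts must be positive for the log transform")
  if (any(depths <= 0)) stop_domain("depths must be positive")
  y <- log10(counts)
  x <- log10(depths)
  if (sd(x) < 1e-12) {
    warning("all sequencing depths equal; falling back to intercept-only residuals",
            call. = FALSE)
    return(y - mean(y))
  }
  unname(resid(lm(y ~ x)))
}
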