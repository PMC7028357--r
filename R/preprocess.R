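# Read-level preprocessing: mean-quality filtering, seeded rarefaction, and
# the leave-one-out depth exclusion rule for shallow samples.

#' Filter reads by mean Phred quality
#'
#' Retains exactly the reads whose mean Phred quality is greater than or
#' equal to `q_threshold` (boundary inclusive); order is preserved.  The
#' filter is idempotent.
#'
#' @param reads A [read_set].
#' @param q_threshold Mean-quality threshold in `[0, 60]`; default 25.
#' @return The retained subset of `reads`.
#' @export
quality_filter <- function(reads, q_threshold = 25) {
  stopifnot(q_threshold >= 0, q_threshold <= 60)
  if (!nrow(reads)) return(reads)
  keep <- cpp_mean_qual(reads$qual) >= q_threshold
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rarefy a read set to a fixed depth
#'
#' Uniform random subsample without replacement of exactly `depth` reads,
#' deterministic given `seed`.  Reads are returned in their original file
#' order and are not modified.
#'
#' @param reads A [read_set].
#' @param depth Target number of reads; default 100000.
#' @param seed Integer seed (required, so runs are reproducible).
#' @return A [read_set] with `depth` rows.
#' @export
rarefy <- function(reads, depth = 100000L, seed) {
  stopifnot(depth >= 1)
  n <- nrow(reads)
  if (n < depth) {
    stop_domain(paste0("sample has %d reads, fewer than the rarefaction depth %d; ",
                       "exclude the sample rather than rarefying"), n, depth)
  }
  if (n == depth) return(reads)
  idx <- local_seed(seed, sort(sample.int(n, depth)))
  out <- reads[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag samples with anomalously low sequencing depth
#'
#' A sample is excluded when its total read count is below `fraction` times
#' the mean depth of all *other* samples (leave-one-out mean, the literal
#' reading of depth "less than 20% of the rest of the samples").  Input
#' order is preserved; only the `retained` flag is changed.
#'
#' @param manifest A [as_sample_manifest()] data frame with a `total_reads`
#'   column (at least 2 samples).
#' @param fraction Exclusion fraction; default 0.2.
#' @return The manifest with updated `retained` flags.
#' @export
exclude_low_depth <- function(manifest, fraction = 0.2) {
  d <- manifest$total_reads
  stopifnot(!is.null(d), length(d) >= 2L)
  n <- length(d)
  loo_mean <- (sum(d) - d) / (n - 1)
  manifest$retained <- d >= fraction * loo_mean
  manifest
}
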