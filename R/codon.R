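# Codon usage bias: Wright's effective number of codons (ENC) and the
# background-composition-corrected ENC'.
#
# ENC summarizes how unevenly a gene uses synonymous codons, on a scale from
# 20 (one codon used exclusively per amino acid) to 61 (all synonymous codons
# used equally likely).  Within each synonymous family the codon
# "homozygosity" F-hat estimates the probability that two randomly drawn
# codons of the family are identical; families are grouped by degeneracy
# class k in {2, 3, 4, 6} and ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, where Fk
# is the mean F-hat over usable families in class k and the leading 2
# accounts for Met and Trp.  ENC' replaces F-hat with a chi-square-corrected
# homozygosity that discounts the codon-usage unevenness expected from the
# background nucleotide composition alone, so compositional bias (e.g.
# extreme GC) is not mistaken for selected codon bias.

.build_codon_table <- function() {
  b <- c("A", "C", "G", "T")
  codon64 <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), times = 4L),
                    rep(b, times = 16L))
  gcode <- Biostrings::GENETIC_CODE
  aa64 <- unname(gcode[codon64])
  sense <- codon64[aa64 != "*"]
  aa <- aa64[aa64 != "*"]
  families <- split(sense, aa)
  fam_k <- vapply(families, length, integer(1))
  redundant <- names(fam_k)[fam_k >= 2L]
  list(
    codon64 = codon64,
    sense = sense,
    aa = aa,
    families = families,
    fam_k = fam_k,
    redundant = redundant,
    fam_rows = lapply(families[redundant], function(cd) match(cd, sense)),
    stops = codon64[aa64 == "*"]
  )
}

.CODON_TABLE <- .build_codon_table()

#' Standard genetic code structured for ENC computation
#'
#' Returns the 61 sense codons of the standard genetic code grouped into
#' synonymous families, with the degeneracy-class structure used by the ENC
#' combination formula: 9 two-fold families, 1 three-fold family (Ile),
#' 5 four-fold families, 3 six-fold families (Leu, Ser, Arg), and the two
#' single-codon amino acids Met and Trp.
#'
#' @return A list with elements `sense` (61 sense codons), `aa` (amino acid
#'   per sense codon), `families` (list of codon vectors keyed by amino
#'   acid), `fam_k` (family degeneracy), `redundant` (amino acids with
#'   `k >= 2`), and `stops` (the 3 stop codons).
#' @examples
#' table(codon_table()$fam_k)
#' @export
codon_table <- function() .CODON_TABLE

#' Count sense codons of an in-frame coding sequence
#'
#' Reads triplets in frame 0.  A trailing 1-2 nt remainder is dropped,
#' codons containing any non-ACGT base are skipped, and stop codons are
#' excluded from the returned counts.
#'
#' @param cds A DNA string (character scalar); `U` is treated as `T`.
#' @param gene_id Optional identifier stored as an attribute.
#' @return An object of class `codon_counts`: a named integer vector over
#'   the 61 sense codons.
#' @examples
#' count_codons("ATGAAATTT")
#' @export
count_codons <- function(cds, gene_id = NULL) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- chartr("Uu", "Tt", cds)
  v <- cpp_count_codons(cds)
  names(v) <- .CODON_TABLE$codon64
  out <- v[.CODON_TABLE$sense]
  class(out) <- "codon_counts"
  attr(out, "gene_id") <- gene_id
  out
}

# coerce a named count vector over (a subset of) sense codons
as_codon_counts <- function(x, gene_id = NULL) {
  if (inherits(x, "codon_counts")) return(x)
  stopifnot(!is.null(names(x)))
  bad <- setdiff(names(x), .CODON_TABLE$sense)
  if (length(bad)) stop_domain("not sense codons: %s", paste(bad, collapse = ", "))
  out <- stats::setNames(integer(61L), .CODON_TABLE$sense)
  out[names(x)] <- as.integer(x)
  class(out) <- "codon_counts"
  attr(out, "gene_id") <- gene_id
  out
}

#' @export
print.codon_counts <- function(x, ...) {
  id <- attr(x, "gene_id")
  cat("codon_counts:", sum(x), "sense codons",
      if (!is.null(id)) paste0("(", id, ")"), "\n")
  print(unclass(x)[x > 0])
  invisible(x)
}

#' Codon homozygosity of one synonymous family
#'
#' The unbiased estimator `F = (n * sum(p_i^2) - 1) / (n - 1)` of the
#' probability that two codons drawn from the family are identical, where
#' `n` is the family total and `p_i` the within-family codon proportions.
#'
#' @param family_counts Non-negative integer vector of per-codon counts for
#'   one synonymous family (length `k >= 2`).
#' @return The homozygosity estimate, or `NA` when fewer than 2 codons were
#'   observed (the family is then unusable).
#' @examples
#' family_homozygosity(c(3, 1))   # 0.5
#' family_homozygosity(c(1, 1))   # 0 (perfectly even at minimal n)
#' @export
family_homozygosity <- function(family_counts) {
  k <- length(family_counts)
  if (k < 2L) stop_domain("family must have k >= 2 codons, got %d", k)
  if (any(family_counts < 0)) stop_domain("negative codon count")
  n <- sum(family_counts)
  if (n < 2) return(NA_real_)
  p <- family_counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Background-corrected homozygosity of one synonymous family
#'
#' The chi-square-corrected estimator used by ENC':
#' `F_CF = (X2 + n - k) / (k * (n - 1))` with
#' `X2 = sum((n_i - n e_i)^2 / (n e_i))`, where `e` are the expected
#' within-family frequencies under the background composition (see
#' [expected_family_frequencies()]).  Usage that matches the background is
#' scored as unbiased; under uniform `e` the estimator reduces to
#' [family_homozygosity()] exactly.
#'
#' @inheritParams family_homozygosity
#' @param e Expected within-family frequency vector (same length).
#' @return The corrected homozygosity, or `NA` when fewer than 2 codons
#'   were observed or a zero-expectation codon was observed.
#' @examples
#' family_homozygosity_corrected(c(3, 1), c(0.75, 0.25))  # 1/3
#' family_homozygosity_corrected(c(3, 1), c(0.5, 0.5))    # 0.5
#' @export
family_homozygosity_corrected <- function(family_counts, e) {
  k <- length(family_counts)
  if (k < 2L) stop_domain("family must have k >= 2 codons, got %d", k)
  stopifnot(length(e) == k)
  n <- sum(family_counts)
  if (n < 2) return(NA_real_)
  if (any(e <= 0 & family_counts > 0)) return(NA_real_)
  pos <- e > 0
  x2 <- sum((family_counts[pos] - n * e[pos])^2 / (n * e[pos]))
  (x2 + n - k) / (k * (n - 1))
}

# Vectorized ENC / ENC' over a 61 x n_genes count matrix (rows in
# .CODON_TABLE$sense order).  This is the single implementation behind
# enc(), enc_prime() and the pipeline's per-gene tables.
#
# Class means use only usable families (finite F-hat > 0; non-positive
# estimates would blow up the reciprocal and are treated as missing).
# Fallbacks when a whole class is unusable for a gene: F3 is imputed as
# (F2 + F4)/2 when both neighbours exist; any other missing class term uses
# the mean F-hat over all usable families of all classes; with no usable
# family at all the gene's value is NA.  The combined value is clamped to
# [20, 61]: the finite-n estimator can exceed 61 under even usage and,
# rarely, undershoot 20.
.enc_many <- function(C, bg = NULL) {
  ct <- .CODON_TABLE
  n_genes <- ncol(C)
  fams <- ct$redundant
  nf <- length(fams)
  fhat <- matrix(NA_real_, nf, n_genes, dimnames = list(fams, NULL))
  e_list <- if (!is.null(bg)) {
    lapply(fams, function(a) expected_family_frequencies(bg, ct$families[[a]]))
  }
  for (i in seq_len(nf)) {
    rows <- ct$fam_rows[[i]]
    k <- length(rows)
    Cf <- C[rows, , drop = FALSE]
    n <- colSums(Cf)
    ok <- n >= 2
    f <- rep(NA_real_, n_genes)
    if (is.null(bg)) {
      sum2 <- colSums(Cf * Cf)
      f[ok] <- (sum2[ok] / n[ok] - 1) / (n[ok] - 1)
    } else {
      e <- e_list[[i]]
      pos <- e > 0
      if (!all(pos)) {
        # codons the background rules out: observing them leaves the
        # chi-square undefined for the family; unobserved ones drop out
        viol <- colSums(Cf[!pos, , drop = FALSE] != 0) > 0
        ok <- ok & !viol
        Cf <- Cf[pos, , drop = FALSE]
        e <- e[pos]
      }
      E <- outer(e, n)
      x2 <- colSums((Cf - E)^2 / E)
      f[ok] <- (x2[ok] + n[ok] - k) / (k * (n[ok] - 1))
    }
    fhat[i, ] <- f
  }
  # the tolerance keeps the ENC/ENC'-under-uniform-background identity exact
  # when a family's homozygosity sits numerically at the zero boundary
  usable <- is.finite(fhat) & fhat > 1e-12
  fh0 <- ifelse(usable, fhat, 0)
  cls <- ct$fam_k[fams]
  cls_mean <- function(k) {
    i <- cls == k
    m <- colSums(fh0[i, , drop = FALSE])
    cnt <- colSums(usable[i, , drop = FALSE])
    ifelse(cnt > 0, m / cnt, NA_real_)
  }
  f2 <- cls_mean(2L); f3 <- cls_mean(3L); f4 <- cls_mean(4L); f6 <- cls_mean(6L)
  n_usable <- colSums(usable)
  global <- ifelse(n_usable > 0, colSums(fh0) / n_usable, NA_real_)
  f3 <- ifelse(is.na(f3), ifelse(!is.na(f2) & !is.na(f4), (f2 + f4) / 2, global), f3)
  f2 <- ifelse(is.na(f2), global, f2)
  f4 <- ifelse(is.na(f4), global, f4)
  f6 <- ifelse(is.na(f6), global, f6)
  raw <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  pmin(61, pmax(20, raw))
}

# 64-row codon count matrix (cpp order) -> 61-row sense matrix
.sense_matrix <- function(C64) {
  C64[match(.CODON_TABLE$sense, .CODON_TABLE$codon64), , drop = FALSE]
}

#' Effective number of codons (ENC) of a gene
#'
#' @param counts A [count_codons()] result, or a named count vector over
#'   sense codons.
#' @return ENC in `[20, 61]`, or `NA` if no synonymous family is usable.
#' @examples
#' enc(count_codons(generate_cds(400, b = 1, seed = 1)))  # 20
#' @export
enc <- function(counts) {
  counts <- as_codon_counts(counts)
  .enc_many(matrix(unclass(counts), ncol = 1L))[1L]
}

#' Expected within-family codon frequencies under a background composition
#'
#' Each codon's weight is the product of the background frequencies of its
#' three nucleotides, normalized to sum to one within the family; these are
#' the frequencies codon usage would drift to under the background
#' composition alone.
#'
#' @param bg A [background_composition()] (or frequency 4-vector over
#'   A, C, G, T).
#' @param family Character vector of the family's codons.
#' @return Probability vector over the family's codons.
#' @examples
#' expected_family_frequencies(c(A = .25, C = .25, G = .25, T = .25),
#'                             c("AAA", "AAG"))
#' @export
expected_family_frequencies <- function(bg, family) {
  bg <- background_composition(bg)
  stopifnot(length(family) >= 1L)
  base_mat <- vapply(strsplit(family, "", fixed = TRUE), identity, character(3))
  w <- apply(base_mat, 2L, function(bases) prod(unclass(bg)[bases]))
  if (all(w == 0)) {
    stop_domain("degenerate background: zero weight for every codon of family %s",
                paste(family, collapse = "/"))
  }
  unname(w / sum(w))
}

#' Background-corrected effective number of codons (ENC')
#'
#' Same class-averaging, fallback, and clamping rules as [enc()], but each
#' family's homozygosity is replaced by the corrected estimator
#' `F_CF = (X2 + n - k) / (k * (n - 1))`, where `X2` is the chi-square
#' deviation of the observed within-family counts from the frequencies
#' expected under the background nucleotide composition.  Under a uniform
#' background, ENC' equals ENC exactly.
#'
#' @inheritParams enc
#' @param bg Background nucleotide composition; see
#'   [background_composition()].
#' @return ENC' in `[20, 61]`, or `NA` if no family is usable.
#' @export
enc_prime <- function(counts, bg) {
  counts <- as_codon_counts(counts)
  bg <- background_composition(bg)
  .enc_many(matrix(unclass(counts), ncol = 1L), bg = bg)[1L]
}

#' Background nucleotide composition
#'
#' Validates and normalizes an (A, C, G, T) frequency vector; frequencies
#' must be non-negative and sum to 1 within 1e-12 (vectors of counts are
#' accepted and normalized).
#'
#' @param x Numeric 4-vector (named, or taken in A, C, G, T order), or an
#'   existing `background_composition`.
#' @return A named frequency vector of class `background_composition`.
#' @export
background_composition <- function(x) {
  if (inherits(x, "background_composition")) return(x)
  stopifnot(is.numeric(x), length(x) == 4L)
  if (is.null(names(x))) names(x) <- c("A", "C", "G", "T")
  stopifnot(setequal(names(x), c("A", "C", "G", "T")))
  x <- x[c("A", "C", "G", "T")]
  if (any(x < 0)) stop_domain("negative nucleotide frequency")
  s <- sum(x)
  if (s <= 0) stop_domain("all nucleotide frequencies are zero")
  if (abs(s - 1) > 1e-12) x <- x / s
  class(x) <- "background_composition"
  x
}

#' Background composition averaged over samples' reads
#'
#' Computes each sample's nucleotide frequency vector from its reads
#' (ignoring N) and averages the frequency vectors unweighted across
#' samples, so deeply and shallowly sequenced samples contribute equally.
#'
#' @param readsets A list with one element per sample; each element is a
#'   [read_set] or a character vector of sequences.
#' @return A [background_composition()].
#' @export
background_from_samples <- function(readsets) {
  if (length(readsets) == 0L) stop_domain("no samples given")
  freqs <- vapply(readsets, function(rs) {
    seqs <- if (is.data.frame(rs)) rs$seq else rs
    cnt <- cpp_base_counts(seqs)
    tot <- sum(cnt)
    if (tot == 0) stop_domain("sample has no non-N nucleotides")
    cnt / tot
  }, numeric(4))
  background_composition(rowMeans(freqs))
}

# normalize gene input (character CDS vector, list of codon_counts, or a
# 61 x n matrix) to a 61 x n sense-count matrix
.gene_matrix <- function(genes) {
  if (is.matrix(genes)) {
    stopifnot(nrow(genes) == 61L)
    return(genes)
  }
  if (is.character(genes)) {
    genes <- chartr("Uu", "Tt", genes)
    return(.sense_matrix(cpp_count_codons_batch(genes)))
  }
  vapply(genes, function(g) as.double(unclass(as_codon_counts(g))), numeric(61L))
}

#' Per-sample codon-usage-bias summary
#'
#' Computes ENC and ENC' for each gene and summarizes by mean and median
#' over the genes with defined values.  Community codon usage bias is
#' reported as `1/mean(ENC)`, so that higher values indicate stronger bias.
#'
#' @param genes A character vector of CDS strings, a list of
#'   [count_codons()] objects, or a 61 x n sense-codon count matrix.
#' @param bg Background composition for ENC'.
#' @return A list of class `cub_summary` with `mean_enc`, `median_enc`,
#'   `mean_encp`, `median_encp`, `community_bias` (`1/mean_enc`), `n_genes`
#'   (genes with defined ENC), `n_undefined`, and the per-gene vectors
#'   `enc`, `encp`.
#' @export
summarize_cub <- function(genes, bg) {
  C <- .gene_matrix(genes)
  if (ncol(C) == 0L) stop_domain("no genes given")
  bg <- background_composition(bg)
  enc_v <- .enc_many(C)
  encp_v <- .enc_many(C, bg = bg)
  ok <- is.finite(enc_v)
  if (!any(ok)) stop_domain("no gene has a defined ENC")
  structure(list(
    mean_enc = mean(enc_v[ok]),
    median_enc = median(enc_v[ok]),
    mean_encp = mean(encp_v[is.finite(encp_v)]),
    median_encp = median(encp_v[is.finite(encp_v)]),
    community_bias = 1 / mean(enc_v[ok]),
    n_genes = sum(ok),
    n_undefined = sum(!ok),
    enc = enc_v,
    encp = encp_v
  ), class = "cub_summary")
}

#' @export
print.cub_summary <- function(x, ...) {
  cat(sprintf(
    paste0("codon usage bias over %d genes (%d undefined):\n",
           "  mean ENC %.2f, median ENC %.2f, mean ENC' %.2f, median ENC' %.2f\n",
           "  community bias 1/mean(ENC) = %.5f\n"),
    x$n_genes, x$n_undefined, x$mean_enc, x$median_enc,
    x$mean_encp, x$median_encp, x$community_bias))
  invisible(x)
}

#' Histogram and empirical CDF of per-gene codon usage bias
#'
#' @param values Numeric ENC or ENC' values in `[20, 61]` (undefined values
#'   are dropped), or gene input as in [summarize_cub()], in which case `bg`
#'   selects the measure: ENC when `bg` is NULL, ENC' otherwise.
#' @param bg Optional background composition (see `values`).
#' @param bin_width Histogram bin width over `[20, 61]`.
#' @return A list of class `cub_distribution` with `breaks`, `counts`,
#'   `density`, and the ECDF point set `ecdf_x`, `ecdf_p` (cumulative
#'   proportions ending at 1).
#' @export
cub_distribution <- function(values, bg = NULL, bin_width = 1) {
  stopifnot(bin_width > 0)
  if (!is.numeric(values)) {
    C <- .gene_matrix(values)
    values <- if (is.null(bg)) .enc_many(C) else {
      .enc_many(C, bg = background_composition(bg))
    }
  }
  values <- values[is.finite(values)]
  if (!length(values)) stop_domain("no defined values")
  breaks <- seq(20, 61, by = bin_width)
  if (breaks[length(breaks)] < 61) {
    breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  }
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  xs <- sort(unique(values))
  structure(list(
    breaks = breaks,
    counts = counts,
    density = counts / sum(counts) / bin_width,
    ecdf_x = xs,
    ecdf_p = cumsum(tabulate(match(sort(values), xs), nbins = length(xs))) / length(values),
    n = length(values)
  ), class = "cub_distribution")
}
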