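# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the package internals: the genetic
# code is spelled out by hand, and every statistic is computed straight from
# its textbook definition.

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Effective number of codons straight from the definition:
# Fhat = (n * sum(p^2) - 1)/(n - 1) per family, class means over families
# with n >= 2, ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 clamped to [20, 61].
# Returns NA whenever any degeneracy class lacks a usable family or any
# Fhat is non-positive, so no fallback rule is ever exercised here.
oracle_enc_from_counts <- function(counts) {
  aa_of <- ORACLE_CODE[names(counts)]
  fams <- split(unname(counts), aa_of)
  fams <- fams[!names(fams) %in% c("*", "M", "W")]
  fhat <- list()
  for (aa in names(fams)) {
    cnt <- fams[[aa]]
    n <- sum(cnt)
    if (n < 2) {
      fhat[[aa]] <- c(k = length(cnt), f = NA_real_)
    } else {
      p <- cnt / n
      fhat[[aa]] <- c(k = length(cnt), f = (n * sum(p^2) - 1) / (n - 1))
    }
  }
  m <- do.call(rbind, fhat)
  means <- numeric(0)
  for (k in c(2, 3, 4, 6)) {
    f <- m[m[, "k"] == k, "f"]
    f <- f[!is.na(f)]
    # exact zeros can land at +/-1e-16 in floating point; treat them as
    # non-positive (the gene is then skipped rather than misjudged)
    if (!length(f) || any(f <= 1e-12)) return(NA_real_)
    means[as.character(k)] <- mean(f)
  }
  raw <- 2 + 9 / means["2"] + 1 / means["3"] + 5 / means["4"] + 3 / means["6"]
  unname(min(61, max(20, raw)))
}

oracle_enc_from_cds <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds) - 2, by = 3),
                      seq(3, nchar(cds), by = 3))
  codons <- codons[!grepl("N", codons)]
  codons <- codons[ORACLE_CODE[codons] != "*"]
  counts <- table(factor(codons, levels = names(ORACLE_CODE)[ORACLE_CODE != "*"]))
  oracle_enc_from_counts(as.vector(counts) |> setNames(names(counts)))
}

# Exact binomial upper tail from factorials (no pbinom): P(X >= x | m, p)
oracle_binom_upper_tail <- function(x, m, p) {
  if (x <= 0) return(1)
  k <- x:m
  sum(choose(m, k) * p^k * (1 - p)^(m - k))
}

# Exact two-sample KS p-value by full enumeration of rank assignments
# (distinct values assumed): p = fraction of label assignments whose D is
# at least the observed D
oracle_ks_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  ks_d <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  d_obs <- ks_d(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(n + m, n)
  ds <- apply(idx, 2, function(i) ks_d(pooled[i], pooled[-i]))
  list(D = d_obs, p = mean(ds >= d_obs - 1e-12))
}

# Bonett variance test transcribed independently from the published
# procedure: trimmed-mean kurtosis pooled over groups, the (n-3)/n terms in
# the standard error, and the n/(n - 1.96) small-sample constant.
oracle_bonett <- function(x, y) {
  trim_prop <- function(n) if (n > 4) min(0.5, 1 / (2 * sqrt(n - 4))) else 0
  n1 <- length(x)
  n2 <- length(y)
  tm1 <- mean(x, trim = trim_prop(n1))
  tm2 <- mean(y, trim = trim_prop(n2))
  pooled_kurt <- (n1 + n2) *
    (sum((x - tm1)^4) + sum((y - tm2)^4)) /
    (sum((x - mean(x))^2) + sum((y - mean(y))^2))^2
  v1 <- (pooled_kurt - (n1 - 3) / n1) / (n1 - 1)
  v2 <- (pooled_kurt - (n2 - 3) / n2) / (n2 - 1)
  const <- (n1 / (n1 - 1.96)) / (n2 / (n2 - 1.96))
  z <- log(const * var(x) / var(y)) / sqrt(v1 + v2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# random codon-count table over the 61 sense codons
random_codon_counts <- function(lambda = 4) {
  sense <- codon_table()$sense
  stats::setNames(stats::rpois(61, lambda), sense)
}
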