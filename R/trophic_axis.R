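# The oligotrophy-copiotrophy axis: z-scored PCA of the five community
# genomic traits, with treatment separation along the first component.

#' Z-score the columns of a trait matrix
#'
#' Subtracts column means and divides by column standard deviations (n-1
#' denominator), giving each trait equal weight in the PCA.
#'
#' @param m Numeric matrix or data frame (samples x traits), no missing
#'   values.
#' @return Matrix with column means 0 and standard deviations 1.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop_domain("missing values in trait matrix")
  if (any(!is.finite(m))) {
    stop_domain("non-finite trait values (a log-transformed count of zero?)")
  }
  sds <- apply(m, 2L, sd)
  zero <- sds < 1e-300
  if (any(zero)) {
    stop_domain("zero-variance trait column: %s",
                paste(colnames(m)[zero] %||% which(zero), collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)
}

#' First principal component of a standardized trait matrix
#'
#' Eigen-decomposition of the covariance matrix of the (already z-scored)
#' traits.  The axis sign is oriented so that the genome-size loading (or,
#' absent that column, the first column's loading) is non-negative: higher
#' scores then indicate copiotrophy-adapted trait combinations, and the
#' ENC'-type loadings come out negative (high ENC' = weak codon bias =
#' oligotrophy).
#'
#' @param m Standardized samples-x-traits matrix (at least 3 samples, 2
#'   traits); see [zscore()].
#' @param orient_by Column name (or index) whose loading is forced
#'   non-negative; default `"genome_size"` when present, else column 1.
#' @return List with `scores`, `loadings` (unit norm), `variance_captured`
#'   (share of total variance on the first component).
#' @export
pc1 <- function(m, orient_by = "genome_size") {
  m <- as.matrix(m)
  if (nrow(m) < 3L || ncol(m) < 2L) stop_domain("need >= 3 samples and >= 2 traits")
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (sum(ev) <= 0) stop_domain("degenerate trait matrix (rank 0)")
  load1 <- pr$rotation[, 1L]
  scores <- pr$x[, 1L]
  j <- if (is.character(orient_by) && orient_by %in% colnames(m)) {
    match(orient_by, colnames(m))
  } else if (is.numeric(orient_by)) as.integer(orient_by) else 1L
  if (load1[j] < 0) {
    load1 <- -load1
    scores <- -scores
  }
  list(scores = unname(scores), loadings = load1,
       variance_captured = ev[1L] / sum(ev))
}

#' Treatment separation along an axis
#'
#' Fraction of variance in the per-sample scores explained by treatment,
#' with the F-test p-value; identical contract to [glm_r2()].
#'
#' @param scores Per-sample axis scores.
#' @param treatment Per-sample treatment labels.
#' @return List with `r2`, `p`.
#' @export
axis_separation <- function(scores, treatment) {
  glm_r2(scores, treatment)
}

#' Collapse community traits onto the oligotrophy-copiotrophy axis
#'
#' Z-scores the selected traits, extracts the first principal component, and
#' quantifies treatment separation along it.  The default trait set is mean
#' genome size, GC content, log10 tRNA count, log10 rRNA count, and median
#' ENC' (the preferred codon-usage-bias measure for the axis).
#'
#' @param traits Trait table (data frame) with the trait columns and,
#'   optionally, `treatment` and `sample_id`.
#' @param trait_cols Trait columns entering the PCA.
#' @return An object of class `trophic_axis`: list with `scores` (named by
#'   sample when available), `loadings`, `variance_captured`, `r2`, `p`,
#'   `trait_cols`, `treatment`.
#' @export
trophic_axis <- function(traits,
                         trait_cols = c("genome_size", "gc_content",
                                        "log_trna", "log_rrna", "median_encp")) {
  miss <- setdiff(trait_cols, names(traits))
  if (length(miss)) stop_domain("trait table lacks columns: %s", paste(miss, collapse = ", "))
  m <- zscore(as.data.frame(traits)[trait_cols])
  ax <- pc1(m, orient_by = if ("genome_size" %in% trait_cols) "genome_size" else 1L)
  r2 <- p <- NA_real_
  if ("treatment" %in% names(traits)) {
    sep <- axis_separation(ax$scores, traits$treatment)
    r2 <- sep$r2; p <- sep$p
  }
  if ("sample_id" %in% names(traits)) names(ax$scores) <- traits$sample_id
  structure(list(scores = ax$scores, loadings = ax$loadings,
                 variance_captured = ax$variance_captured,
                 r2 = r2, p = p, trait_cols = trait_cols,
                 treatment = traits$treatment),
            class = "trophic_axis")
}

#' @export
print.trophic_axis <- function(x, ...) {
  cat(sprintf("Oligotrophy-copiotrophy axis (PC1 of %d z-scored traits)\n",
              length(x$trait_cols)))
  cat(sprintf("  variance captured: %.1f%%\n", 100 * x$variance_captured))
  if (!is.na(x$r2)) {
    cat(sprintf("  treatment R^2 along the axis: %.1f%% (p = %.4g)\n",
                100 * x$r2, x$p))
  }
  cat("  loadings (positive = copiotrophy):\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @method plot trophic_axis
#' @export
plot.trophic_axis <- function(x, ...) {
  grp <- x$treatment %||% rep("all", length(x$scores))
  grp <- factor(grp)
  at <- as.integer(grp)
  off <- stats::ave(seq_along(at), at, FUN = function(i) {
    if (length(i) == 1L) 0 else seq(-0.15, 0.15, length.out = length(i))
  })
  graphics::plot(at + off, x$scores,
                 xlim = c(0.5, nlevels(grp) + 0.5), xaxt = "n",
                 xlab = "", ylab = "PC1 score (copiotrophy higher)",
                 pch = 19, col = at + 1L, ...)
  graphics::axis(1, at = seq_len(nlevels(grp)), labels = levels(grp))
  invisible(x)
}
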