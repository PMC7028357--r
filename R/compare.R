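# Treatment comparison of the community trait table: runs the full
# statistical battery per trait with a priori one-tailed directions.

#' Default one-tailed test directions for the trait battery
#'
#' Directions are fixed a priori from the trait predictions: under
#' fertilization all information-processing traits are higher (genome size,
#' GC content, tRNA/rRNA counts, rates and residuals, community bias 1/ENC,
#' seston P:C) while ENC and ENC' summaries are lower (lower effective
#' number of codons means stronger codon usage bias).  `tail` is the
#' alternative for fertilized relative to unfertilized.
#'
#' @return Data frame with columns `trait`, `tail`.
#' @export
trait_directions <- function() {
  data.frame(
    trait = c("genome_size", "gc_content", "log_trna", "log_rrna",
              "trna_rate", "rrna_rate", "trna_resid", "rrna_resid",
              "mean_enc", "median_enc", "mean_encp", "median_encp",
              "community_bias", "pc_ratio"),
    tail = c("greater", "greater", "greater", "greater",
             "greater", "greater", "greater", "greater",
             "less", "less", "less", "less",
             "greater", "greater"),
    stringsAsFactors = FALSE
  )
}

#' Compare community traits between treatments
#'
#' For each trait present in both `traits` and `directions`, runs the
#' one-tailed Welch t-test (fertilized vs unfertilized, direction fixed a
#' priori), the treatment R-squared from a binary-factor linear model, the
#' two-sided Bonett variance test, and the variance-change factor
#' `var(unfertilized) / var(fertilized)`.  For the tRNA/rRNA count traits it
#' additionally runs the exact Poisson rate test with treatment counts
#' summed and exposure equal to the number of samples times the mean reads
#' per metagenome.  If per-gene ENC/ENC' values are supplied,
#' Kolmogorov-Smirnov tests compare their distributions between treatments.
#' No multiple-testing correction is applied; all raw p-values and effect
#' sizes are reported.
#'
#' @param traits A trait table (data frame) with columns `treatment`,
#'   `total_reads`, and trait columns; only retained samples should be
#'   included.
#' @param gene_values Optional list with elements `enc` and/or `encp`, each
#'   itself a list with numeric vectors `fertilized` and `unfertilized` of
#'   pooled per-gene values.
#' @param directions Data frame of per-trait one-tailed directions; default
#'   [trait_directions()].
#' @return An object of class `trait_comparison`: list with the per-trait
#'   `table`, the `ks` results, and `directions`.
#' @export
compare_traits <- function(traits, gene_values = NULL,
                           directions = trait_directions()) {
  stopifnot(is.data.frame(traits), "treatment" %in% names(traits))
  fert <- traits[traits$treatment == "fertilized", , drop = FALSE]
  unf <- traits[traits$treatment == "unfertilized", , drop = FALSE]
  if (nrow(fert) < 2L || nrow(unf) < 2L) {
    stop_domain("need at least 2 retained samples per treatment (got %d fertilized, %d unfertilized)",
                nrow(fert), nrow(unf))
  }
  count_cols <- c(log_trna = "trna_count", log_rrna = "rrna_count")
  rows <- lapply(seq_len(nrow(directions)), function(i) {
    tr <- directions$trait[i]
    tail <- directions$tail[i]
    if (!tr %in% names(traits)) return(NULL)
    xf <- fert[[tr]]; xu <- unf[[tr]]
    if (anyNA(c(xf, xu))) return(NULL)
    wt <- tryCatch(welch_t(xf, xu, tail), error = function(e) NULL)
    r2 <- tryCatch(glm_r2(c(xf, xu), rep(c("f", "u"), c(length(xf), length(xu)))),
                   error = function(e) NULL)
    bv <- tryCatch(bonett_var_test(xu, xf), error = function(e) NULL)
    vf <- tryCatch(variance_change(xu, xf), error = function(e) NA_real_)
    p_pois <- NA_real_
    if (tr %in% names(count_cols) && count_cols[tr] %in% names(traits)) {
      cc <- count_cols[[tr]]
      p_pois <- poisson_rate_test(
        x1 = sum(fert[[cc]]), t1 = nrow(fert) * mean(fert$total_reads),
        x2 = sum(unf[[cc]]), t2 = nrow(unf) * mean(unf$total_reads),
        tail = tail)
    }
    mu_u <- mean(xu); mu_f <- mean(xf)
    data.frame(
      trait = tr, tail = tail,
      mean_unfert = mu_u, mean_fert = mu_f,
      pct_change = if (mu_u != 0) 100 * (mu_f - mu_u) / abs(mu_u) else NA_real_,
      t = wt$t %||% NA_real_, df = wt$df %||% NA_real_, p_t = wt$p %||% NA_real_,
      r2 = r2$r2 %||% NA_real_, p_r2 = r2$p %||% NA_real_,
      p_poisson = p_pois,
      bonett_z = bv$z %||% NA_real_, p_bonett = bv$p %||% NA_real_,
      var_factor = vf,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ks <- NULL
  if (!is.null(gene_values)) {
    ks <- lapply(gene_values, function(gv) {
      ks_two_sample(gv$fertilized, gv$unfertilized)
    })
  }
  structure(list(table = tab, ks = ks, directions = directions,
                 n_fert = nrow(fert), n_unfert = nrow(unf)),
            class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Trait comparison: %d fertilized vs %d unfertilized samples\n",
              x$n_fert, x$n_unfert))
  cat("(one-tailed Welch tests, directions fixed a priori; variance factor = var(unfert)/var(fert))\n\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.null(x$ks)) {
    cat("\nKolmogorov-Smirnov tests on per-gene distributions:\n")
    for (nm in names(x$ks)) {
      cat(sprintf("  %s: D = %.4f, p = %.4g%s\n", nm, x$ks[[nm]]$D,
                  x$ks[[nm]]$p, if (x$ks[[nm]]$exact) " (exact)" else ""))
    }
  }
  invisible(x)
}

#' @method summary trait_comparison
#' @export
summary.trait_comparison <- function(object, ...) {
  print(object, ...)
}
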