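# Pipeline orchestration: profile samples into the community trait table,
# then compare treatments and extract the trophic axis.  Samples are
# processed one at a time so deep read sets never need to be held in memory
# together.

# resolve input into (manifest, fetch(i) -> sample data, read_length or NA)
.profile_source <- function(x, seed) {
  if (inherits(x, "trait_bundle")) {
    list(manifest = x$manifest,
         fetch = function(i) x$samples[[x$manifest$sample_id[i]]],
         read_length = x$spec$read_length)
  } else if (inherits(x, "community_spec")) {
    if (is.null(seed)) stop_domain("profiling a community_spec requires a seed")
    # regenerate samples one at a time with the same seed schedule as
    # sample_dataset(), without retaining them
    plan <- list()
    k <- 0L
    for (tr in .TREATMENTS) {
      ns <- x$n_samples[[tr]]
      nlow <- x$low_depth[[tr]] %||% 0L
      for (i in seq_len(ns)) {
        k <- k + 1L
        plan[[k]] <- list(sid = sprintf("%s%d", substr(tr, 1, 4), i),
                          tr = tr, shallow = i > ns - nlow, k = k)
      }
    }
    fetch <- function(i) {
      p <- plan[[i]]
      local_seed(child_seed(seed, p$k),
                 .simulate_sample(x, p$tr, p$sid, p$shallow))
    }
    manifest <- NULL # filled during the pass
    list(manifest = NULL, plan = plan, fetch = fetch, read_length = x$read_length)
  } else if (is.character(x) && length(x) == 1L) {
    man_path <- if (dir.exists(x)) file.path(x, "manifest.tsv") else x
    base <- dirname(man_path)
    manifest <- read_manifest(man_path)
    fetch <- function(i) {
      row <- manifest[i, ]
      list(sample_id = row$sample_id, treatment = row$treatment,
           total_reads = row$total_reads,
           reads = read_fastq(file.path(base, row$reads)),
           cds = read_fasta(file.path(base, row$cds)),
           markers = read_marker_table(file.path(base, row$markers)),
           rrna_16s = row$rrna_16s, trna_genes = row$trna_genes,
           bacterial_proteins = row$bacterial_proteins)
    }
    list(manifest = manifest, fetch = fetch, read_length = NA_integer_)
  } else {
    stop_domain("cannot profile object of class %s", class(x)[1])
  }
}

#' Profile samples into the community trait table
#'
#' Runs the trait stages per sample in a fixed order: mean-quality
#' filtering (Q >= `q_threshold`), GC content of six-frame ORFs of the
#' retained reads, genome equivalents from the marker table and mean genome
#' size from the bacterial protein count, per-read occurrence rates of
#' 16S rRNA (one per rRNA operon) and tRNA genes with log10 counts and
#' sequencing-depth residuals, and ENC/ENC' summaries of the
#' ribosomal-protein CDS.  Feature counts, rates and residuals use the
#' full-depth (non-rarefied) quality-filtered libraries.  The background
#' composition for ENC' is the unweighted average of the retained samples'
#' read nucleotide frequencies (one global background).  Shallow samples
#' are dropped by the leave-one-out depth-exclusion rule before any
#' cross-sample statistic.
#'
#' @param x A `trait_bundle` from [sample_dataset()], a directory (or
#'   manifest path) written by [write_bundle()], or a [community_spec()]
#'   (with `seed`), in which case samples are generated on the fly and
#'   never held in memory together.
#' @param seed Seed, required only when `x` is a `community_spec`.
#' @param q_threshold Mean-quality filter threshold; default 25.
#' @param depth_fraction Depth-exclusion fraction; default 0.2.
#' @param min_orf_len Minimum ORF length (nt) for GC; default 60.
#' @return An object of class `trait_profile`: list with `traits` (the
#'   trait table, retained samples only), `bg` (background composition),
#'   `gene_values` (pooled per-gene ENC/ENC' by treatment, for KS tests),
#'   `manifest` (with retained flags), and `excluded` (sample ids).
#' @export
profile_samples <- function(x, seed = NULL, q_threshold = 25,
                            depth_fraction = 0.2, min_orf_len = 60L) {
  src <- .profile_source(x, seed)
  manifest_known <- !is.null(src$manifest)
  manifest <- if (manifest_known) exclude_low_depth(src$manifest, depth_fraction)
  n <- if (manifest_known) nrow(manifest) else length(src$plan)
  per <- vector("list", n)
  freqs <- matrix(NA_real_, 4L, n)
  gene_counts <- vector("list", n)
  man_rows <- vector("list", n)
  for (i in seq_len(n)) {
    # samples already known to fail the depth rule are never read
    if (manifest_known && !manifest$retained[i]) next
    s <- src$fetch(i)
    reads_hq <- quality_filter(s$reads, q_threshold)
    n_hq <- nrow(reads_hq)
    if (n_hq == 0L) stop_domain("sample %s: no reads pass the quality filter",
                                s$sample_id)
    cnt <- cpp_base_counts(reads_hq$seq)
    freqs[, i] <- cnt / sum(cnt)
    rl <- if (is.na(src$read_length)) median(nchar(reads_hq$seq)) else src$read_length
    # a sample destined for depth exclusion may have no marker hits at all;
    # keep its row NA-valued rather than aborting the run
    ge <- tryCatch(genome_equivalents(s$markers, scale = rl),
                   error = function(e) NA_real_)
    gene_counts[[i]] <- .gene_matrix(s$cds)
    per[[i]] <- data.frame(
      sample_id = s$sample_id, treatment = s$treatment,
      reads_raw = s$total_reads, total_reads = n_hq,
      ge = ge,
      genome_size = if (is.na(ge)) NA_real_ else
        mean_genome_size(s$bacterial_proteins, ge),
      gc_content = orf_gc_content(reads_hq$seq, min_orf_len),
      rrna_count = s$rrna_16s, trna_count = s$trna_genes,
      stringsAsFactors = FALSE
    )
    man_rows[[i]] <- data.frame(
      sample_id = s$sample_id, treatment = s$treatment,
      reads = NA_character_, cds = NA_character_, markers = NA_character_,
      rrna_16s = s$rrna_16s, trna_genes = s$trna_genes,
      bacterial_proteins = s$bacterial_proteins,
      total_reads = s$total_reads, stringsAsFactors = FALSE
    )
  }
  if (!manifest_known) {
    manifest <- exclude_low_depth(as_sample_manifest(do.call(rbind, man_rows)),
                                  depth_fraction)
  }
  keep <- which(manifest$retained)
  if (length(keep) < 3L) stop_domain("fewer than 3 samples retained")
  bg <- background_composition(rowMeans(freqs[, keep, drop = FALSE]))
  na_cub <- list(mean_enc = NA_real_, median_enc = NA_real_,
                 mean_encp = NA_real_, median_encp = NA_real_,
                 community_bias = NA_real_, n_genes = 0, n_undefined = 0,
                 enc = numeric(0), encp = numeric(0))
  tt <- do.call(rbind, per[keep])
  cub <- lapply(keep, function(i) {
    tryCatch(summarize_cub(gene_counts[[i]], bg), error = function(e) na_cub)
  })
  tt$log_trna <- log10(tt$trna_count)
  tt$log_rrna <- log10(tt$rrna_count)
  tt$trna_rate <- occurrence_rate(tt$trna_count, tt$total_reads)
  tt$rrna_rate <- occurrence_rate(tt$rrna_count, tt$total_reads)
  tt$trna_resid <- tryCatch(depth_residuals(tt$trna_count, tt$total_reads),
                            error = function(e) NA_real_)
  tt$rrna_resid <- tryCatch(depth_residuals(tt$rrna_count, tt$total_reads),
                            error = function(e) NA_real_)
  for (f in c("mean_enc", "median_enc", "mean_encp", "median_encp",
              "community_bias", "n_genes")) {
    tt[[f]] <- vapply(cub, `[[`, numeric(1), f)
  }
  if (!is.null(manifest$pc_ratio)) {
    # externally measured seston P:C, carried through as an optional trait
    tt$pc_ratio <- manifest$pc_ratio[keep]
  }
  rownames(tt) <- NULL
  class(tt) <- c("trait_table", "data.frame")
  gv <- list(enc = list(), encp = list())
  for (tr in .TREATMENTS) {
    j <- which(tt$treatment == tr)
    gv$enc[[tr]] <- unlist(lapply(cub[j], function(cs) cs$enc[is.finite(cs$enc)]),
                           use.names = FALSE)
    gv$encp[[tr]] <- unlist(lapply(cub[j], function(cs) cs$encp[is.finite(cs$encp)]),
                            use.names = FALSE)
  }
  structure(list(traits = tt, bg = bg, gene_values = gv,
                 manifest = manifest,
                 excluded = manifest$sample_id[!manifest$retained]),
            class = "trait_profile")
}

#' @export
print.trait_profile <- function(x, ...) {
  cat(sprintf("trait_profile: %d retained samples (%d excluded%s)\n",
              nrow(x$traits), length(x$excluded),
              if (length(x$excluded)) {
                paste0(": ", paste(x$excluded, collapse = ", "))
              } else ""))
  cat(sprintf("background composition: A %.3f C %.3f G %.3f T %.3f\n",
              x$bg[1], x$bg[2], x$bg[3], x$bg[4]))
  print(as.data.frame(x$traits)[, c("sample_id", "treatment", "total_reads",
                                    "genome_size", "gc_content", "trna_count",
                                    "rrna_count", "mean_enc", "median_encp")])
  invisible(x)
}

#' Run a complete synthetic fertilization analysis
#'
#' Simulates a fertilization experiment, profiles the samples, compares the
#' treatments, and extracts the trophic axis.
#'
#' @param seed Integer seed.
#' @param effects Target effect sizes (see [fertilization_design()]).
#' @param ... Passed to [fertilization_design()] (e.g. `depth_mean`).
#' @return List of class `metatrait_run` with `design`, `profile`,
#'   `comparison`, `axis`.
#' @export
run_experiment <- function(seed = 1L, effects = .DEFAULT_EFFECTS, ...) {
  design <- fertilization_design(effects, seed = seed, ...)
  profile <- profile_samples(design$spec, seed = child_seed(seed, 202L))
  comparison <- compare_traits(profile$traits, gene_values = list(
    enc = list(fertilized = profile$gene_values$enc$fertilized,
               unfertilized = profile$gene_values$enc$unfertilized),
    encp = list(fertilized = profile$gene_values$encp$fertilized,
                unfertilized = profile$gene_values$encp$unfertilized)))
  axis <- trophic_axis(profile$traits)
  structure(list(design = design, profile = profile,
                 comparison = comparison, axis = axis, seed = seed),
            class = "metatrait_run")
}

#' @export
print.metatrait_run <- function(x, ...) {
  print(x$profile)
  cat("\n")
  print(x$comparison)
  cat("\n")
  print(x$axis)
  invisible(x)
}

#' Write a report of a pipeline run
#'
#' Emits the machine-readable tables behind each report panel (trait table,
#' statistics table, per-treatment ENC' histogram/ECDF point sets, axis
#' scores) and, optionally, a multi-page PDF with the trait boxplots, the
#' codon-usage-bias distributions, and the trophic-axis strip chart.
#'
#' @param run A [run_experiment()] result (or a list with `profile`,
#'   `comparison`, `axis`).
#' @param dir Output directory.
#' @param pdf Whether to render `report.pdf`; default TRUE.
#' @return Invisibly, the paths written.
#' @export
report <- function(run, dir, pdf = TRUE) {
  missing <- setdiff(c("profile", "comparison", "axis"), names(run))
  if (length(missing)) stop_domain("report inputs absent: %s",
                                   paste(missing, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "traits.tsv")
  write_trait_table(run$profile$traits, p)
  paths <- c(paths, p)
  p <- file.path(dir, "comparison.tsv")
  write_tsv_precise(run$comparison$table, p)
  paths <- c(paths, p)
  for (tr in .TREATMENTS) {
    vals <- run$profile$gene_values$encp[[tr]]
    if (!length(vals)) next
    d <- cub_distribution(vals)
    p <- file.path(dir, sprintf("encp_hist_%s.tsv", tr))
    write_tsv_precise(data.frame(bin_left = d$breaks[-length(d$breaks)],
                                 bin_right = d$breaks[-1], count = d$counts), p)
    paths <- c(paths, p)
    p <- file.path(dir, sprintf("encp_ecdf_%s.tsv", tr))
    write_tsv_precise(data.frame(encp = d$ecdf_x, cum_prop = d$ecdf_p), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "axis.tsv")
  write_tsv_precise(data.frame(sample_id = names(run$axis$scores) %||%
                                 seq_along(run$axis$scores),
                               treatment = run$axis$treatment %||% NA,
                               pc1 = unname(run$axis$scores)), p)
  paths <- c(paths, p)
  if (pdf) {
    p <- file.path(dir, "report.pdf")
    grDevices::pdf(p, width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(run$profile$traits)
    plot_cub_distribution(run$profile$gene_values$encp)
    plot(run$axis)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Boxplots of the community traits by treatment
#'
#' @param x A trait table.
#' @param trait_cols Traits to draw.
#' @param ... Ignored.
#' @method plot trait_table
#' @export
plot.trait_table <- function(x, trait_cols = c("genome_size", "gc_content",
                                               "log_trna", "log_rrna",
                                               "community_bias"), ...) {
  trait_cols <- intersect(trait_cols, names(x))
  old <- graphics::par(mfrow = c(2, ceiling(length(trait_cols) / 2)),
                       mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (tc in trait_cols) {
    graphics::boxplot(x[[tc]] ~ factor(x$treatment, levels = .TREATMENTS),
                      xlab = "", ylab = tc, main = tc,
                      col = c("grey85", "indianred"))
  }
  invisible(x)
}

#' Histograms and cumulative distributions of codon usage bias by treatment
#'
#' @param gene_values Named list of numeric per-gene values (e.g. the
#'   `encp` element of a profile's `gene_values`).
#' @param bin_width Histogram bin width; default 1.
#' @export
plot_cub_distribution <- function(gene_values, bin_width = 1) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  cols <- c(unfertilized = "black", fertilized = "red")
  ds <- lapply(gene_values, cub_distribution, bin_width = bin_width)
  ymax <- max(vapply(ds, function(d) max(d$density), numeric(1)))
  graphics::plot(NULL, xlim = c(20, 61), ylim = c(0, ymax),
                 xlab = "ENC'", ylab = "density", main = "distribution")
  for (nm in names(ds)) {
    d <- ds[[nm]]
    graphics::lines(utils::head(d$breaks, -1) + bin_width / 2, d$density,
                    type = "s", col = cols[[nm]] %||% "blue")
  }
  graphics::plot(NULL, xlim = c(20, 61), ylim = c(0, 1),
                 xlab = "ENC'", ylab = "cumulative proportion",
                 main = "cumulative")
  for (nm in names(ds)) {
    d <- ds[[nm]]
    graphics::lines(d$ecdf_x, d$ecdf_p, type = "s", col = cols[[nm]] %||% "blue")
  }
  graphics::legend("bottomright", legend = names(ds),
                   col = unlist(cols[names(ds)]), lty = 1, bty = "n")
  invisible(ds)
}
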