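# the synthetic-community generator and its closed-form ground truth

test_that("generated CDS realize the preferred-codon scheme", {
  # b = 1 forces a single codon per family: the extreme-bias endpoint
  expect_equal(enc(count_codons(generate_cds(400, b = 1, seed = 1))), 20)
  # b = 0 at long length sits at the even-usage endpoint after clamping
  set.seed(31)
  vals <- vapply(1:40, function(i) enc(count_codons(generate_cds(3000, b = 0))),
                 numeric(1))
  expect_gte(mean(vals >= 58), 0.99)
  # expected family homozygosity: F = (b + (1-b)/k)^2 + (k-1)((1-b)/k)^2
  b <- 0.5
  expect_equal((b + (1 - b) / 2)^2 + ((1 - b) / 2)^2, 0.625)
  # no stops, frame intact
  cds <- generate_cds(200, b = 0.3, seed = 5)
  expect_equal(nchar(cds), 600L)
  codons <- substring(cds, seq(1, 598, 3), seq(3, 600, 3))
  expect_false(any(codons %in% codon_table()$stops))
  # determinism by seed
  expect_identical(generate_cds(50, 0.5, seed = 7), generate_cds(50, 0.5, seed = 7))
})

test_that("generate_cds mean ENC tracks the closed-form expectation", {
  set.seed(41)
  for (b in c(0.2, 0.5, 0.8)) {
    vals <- vapply(1:30, function(i) enc(count_codons(generate_cds(600, b))),
                   numeric(1))
    expect_equal(mean(vals), enc_expected(b), tolerance = 0.03 * enc_expected(b))
  }
})

test_that("expected community traits are abundance-weighted closed forms", {
  tx <- structure(data.frame(
    taxon_id = c("t1", "t2"), gradient = c(0, 1),
    genome_genes = c(2000L, 4000L), genome_bp = c(2e6, 4e6),
    gc = c(0.4, 0.6), rrna_copies = c(2L, 8L), trna_genes = c(30L, 90L),
    codon_bias_b = c(0.1, 0.6)), class = c("taxon_profiles", "data.frame"))
  spec <- community_spec(tx, list(unfertilized = c(0.5, 0.5),
                                  fertilized = c(0.2, 0.8)),
                         n_samples = c(unfertilized = 1L, fertilized = 1L),
                         low_depth = c(unfertilized = 0L, fertilized = 0L))
  gt <- expected_traits(spec)
  expect_equal(gt$unfertilized$genome_size, 3000)
  expect_equal(gt$unfertilized$gc_dna, (2e6 * .4 + 4e6 * .6) / 6e6)
  expect_equal(gt$unfertilized$rrna_rate, 1542 * (0.5 * 2 + 0.5 * 8) / 3e6)
  expect_equal(gt$unfertilized$trna_rate, 75 * (0.5 * 30 + 0.5 * 90) / 3e6)
  expect_equal(gt$unfertilized$mean_enc,
               mean(enc_expected(c(0.1, 0.6))))
  # single-taxon expectations equal that taxon's traits
  spec1 <- community_spec(tx, list(unfertilized = c(1, 0), fertilized = c(1, 0)),
                          n_samples = c(unfertilized = 1L, fertilized = 1L),
                          low_depth = c(unfertilized = 0L, fertilized = 0L))
  gt1 <- expected_traits(spec1)
  expect_equal(gt1$fertilized$genome_size, 2000)
  expect_equal(gt1$fertilized$gc_dna, 0.4)
  # equal genome_bp with gc 0.4/0.6 at 50:50 averages to 0.5
  tx2 <- transform(tx, genome_bp = c(3e6, 3e6))
  gt2 <- expected_traits(community_spec(tx2, list(unfertilized = c(.5, .5),
                                                  fertilized = c(.5, .5))))
  expect_equal(gt2$unfertilized$gc_dna, 0.5)
})

test_that("sampled datasets are reproducible and respect the spec", {
  tx <- taxon_pool(10, seed = 2)
  a <- rep(0.1, 10)
  spec <- community_spec(tx, list(unfertilized = a, fertilized = a),
                         n_samples = c(unfertilized = 2L, fertilized = 2L),
                         low_depth = c(unfertilized = 0L, fertilized = 1L),
                         depth_mean = 3000)
  b1 <- sample_dataset(spec, seed = 5)
  b2 <- sample_dataset(spec, seed = 5)
  expect_identical(b1$samples, b2$samples)
  b3 <- sample_dataset(spec, seed = 6)
  expect_false(identical(b1$samples[[1]]$reads$seq, b3$samples[[1]]$reads$seq))
  expect_equal(nrow(b1$manifest), 4L)
  s <- b1$samples[[1]]
  expect_equal(nrow(s$reads), s$total_reads)
  expect_equal(nchar(s$reads$seq[1]), spec$read_length)
  # the designated shallow sample is much shallower
  expect_lt(b1$samples[["fert2"]]$total_reads,
            0.2 * b1$samples[["fert1"]]$total_reads)
  # single-taxon sample GC lands near that taxon's composition
  tx1 <- tx[5, ]
  spec1 <- community_spec(tx1, list(unfertilized = 1, fertilized = 1),
                          n_samples = c(unfertilized = 1L, fertilized = 1L),
                          low_depth = c(unfertilized = 0L, fertilized = 0L),
                          depth_mean = 5000)
  s1 <- sample_dataset(spec1, seed = 3)$samples[[1]]
  expect_equal(gc_content(s1$reads$seq), tx1$gc, tolerance = 0.02)
})

test_that("abundance/taxa mismatches and infeasible effects are config errors", {
  tx <- taxon_pool(10, seed = 2)
  expect_error(community_spec(tx, list(unfertilized = rep(0.2, 5),
                                       fertilized = rep(0.1, 10))),
               "length", class = "metatrait_format_error")
  expect_error(community_spec(tx, list(unfertilized = rep(0.2, 10),
                                       fertilized = rep(0.1, 10))),
               "sum to 1", class = "metatrait_format_error")
  expect_error(fertilization_design(c(gc_shift = 0.6), gc_unfert = 0.49),
               "infeasible", class = "metatrait_format_error")
})

test_that("the fertilization design realizes the configured effects exactly", {
  d <- fertilization_design(seed = 1)
  expect_equal(unname(d$achieved["genome_size"]), 1.25, tolerance = 1e-6)
  expect_equal(unname(d$achieved["gc_shift"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(d$achieved["rrna_rate"]), 2.19, tolerance = 1e-6)
  expect_equal(unname(d$achieved["trna_rate"]), 1.93, tolerance = 1e-6)
  expect_equal(unname(d$achieved["mean_enc"]), 0.933, tolerance = 1e-6)
  expect_equal(d$ground_truth$unfertilized$gc_dna, 0.49, tolerance = 1e-9)
  # zero-effect config: identical ground truth across treatments
  d0 <- fertilization_design(c(genome_size = 1, gc_shift = 0, rrna_rate = 1,
                               trna_rate = 1, mean_enc = 1), seed = 1)
  expect_equal(d0$ground_truth$unfertilized, d0$ground_truth$fertilized,
               tolerance = 1e-9)
})

test_that("taxon pool traits co-vary along the gradient", {
  tx <- taxon_pool(40, seed = 1)
  expect_true(all(tx$trna_genes >= 20))
  expect_true(all(tx$rrna_copies >= 1))
  expect_true(all(tx$genome_bp / tx$genome_genes > 100 &
                  tx$genome_bp / tx$genome_genes < 10000))
  m <- cbind(tx$genome_genes, tx$gc, tx$rrna_copies, tx$trna_genes,
             tx$codon_bias_b)
  rc <- cor(m, method = "spearman")
  expect_true(all(rc[upper.tri(rc)] > 0.55))
  expect_gt(mean(rc[upper.tri(rc)]), 0.7)
})

test_that("the default experiment keeps 7 of 10 samples past depth exclusion", {
  d <- fertilization_design(seed = 3, depth_mean = 2000)
  bundle <- sample_dataset(d$spec, seed = 8)
  man <- exclude_low_depth(bundle$manifest)
  expect_equal(sum(man$retained), 7L)
  expect_equal(sum(man$retained[man$treatment == "unfertilized"]), 4L)
  expect_equal(sum(man$retained[man$treatment == "fertilized"]), 3L)
})
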