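# the treatment-comparison battery

test_that("Welch t matches hand formula and tail conventions", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4), "two_sided")
  expect_equal(w$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3), "two_sided")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  x <- c(10, 11, 12); y <- c(1, 2, 3)
  pg <- welch_t(x, y, "greater")$p
  pl <- welch_t(x, y, "less")$p
  expect_lt(pg, 0.5)
  expect_equal(pg + pl, 1)
  expect_error(welch_t(1, c(1, 2)), class = "metatrait_domain_error")
})

test_that("binary-factor R^2 is SSB/SST and equals squared point-biserial r", {
  expect_equal(glm_r2(c(1, 1, 2, 2), c("a", "a", "b", "b"))$r2, 1)
  expect_equal(glm_r2(c(1, 2, 1, 2), c("a", "a", "b", "b"))$r2, 0)
  expect_equal(glm_r2(c(1, 2, 3, 4), c("a", "a", "b", "b"))$r2, 0.8)
  set.seed(4)
  for (i in 1:25) {
    v <- rnorm(9)
    g <- rep(c("u", "f"), c(4, 5))
    expect_equal(glm_r2(v, g)$r2, cor(v, as.integer(g == "f"))^2,
                 tolerance = 1e-12)
  }
  expect_error(glm_r2(rep(1, 4), c("a", "a", "b", "b")),
               class = "metatrait_domain_error")
})

test_that("exact Poisson rate test equals the conditional binomial tail", {
  expect_equal(poisson_rate_test(10, 1, 0, 1, "greater"), 0.5^10)
  expect_gte(poisson_rate_test(7, 2, 7, 2, "greater"), 0.5)
  # only the exposure ratio matters
  expect_equal(poisson_rate_test(12, 3, 20, 9, "greater"),
               poisson_rate_test(12, 6, 20, 18, "greater"))
  # brute-force factorial oracle across many counts and exposure ratios
  for (x1 in c(0:15, 30, 50)) {
    for (ratio in c(0.5, 1, 2.4)) {
      x2 <- 17
      p <- poisson_rate_test(x1, ratio, x2, 1, "greater")
      expect_equal(p, oracle_binom_upper_tail(x1, x1 + x2, ratio / (ratio + 1)),
                   tolerance = 1e-12)
    }
  }
  expect_error(poisson_rate_test(0, 1, 0, 1), class = "metatrait_domain_error")
})

test_that("Bonett variance test matches an independent transcription and is antisymmetric", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1), sd = sample(1:4, 1))
    y <- rnorm(sample(3:9, 1), sd = sample(1:4, 1))
    got <- bonett_var_test(x, y)
    ref <- oracle_bonett(x, y)
    expect_equal(got$z, ref$z, tolerance = 1e-6)
    expect_equal(got$p, ref$p, tolerance = 1e-6)
    swapped <- bonett_var_test(y, x)
    expect_equal(swapped$z, -got$z, tolerance = 1e-12)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
  }
  # a fixed 5-point fixture with variance ratio 10
  x <- c(0, 1, 2, 3, 10); y <- x / sqrt(10)
  expect_equal(var(x) / var(y), 10)
  got <- bonett_var_test(x, y)
  ref <- oracle_bonett(x, y)
  expect_equal(got$p, ref$p, tolerance = 1e-6)
  same <- bonett_var_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  expect_error(bonett_var_test(c(1, 2), c(1, 2, 3)), class = "metatrait_domain_error")
  expect_error(bonett_var_test(c(1, 1, 1), c(1, 2, 3)), class = "metatrait_domain_error")
})

test_that("two-sample KS uses exact small-sample p-values", {
  r <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(r$D, 1)
  expect_equal(r$p, 1 / 3)  # 2 of the 6 interleavings fully separate
  same <- ks_two_sample(1:5, 1:5)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  # full-enumeration oracle for all n, m <= 5 on random samples
  set.seed(6)
  for (i in 1:15) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- round(rnorm(n), 6); y <- round(rnorm(m, 0.5), 6)
    got <- ks_two_sample(x, y)
    ref <- oracle_ks_exact(x, y)
    expect_equal(got$D, ref$D, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-9)
  }
  # invariance under strictly monotone transforms
  x <- rnorm(8); y <- rnorm(6, 1)
  expect_equal(ks_two_sample(exp(x), exp(y))$D, ks_two_sample(x, y)$D)
  expect_error(ks_two_sample(numeric(0), 1), class = "metatrait_domain_error")
})

test_that("variance-change factors follow the scaling law", {
  x <- c(0, 2)
  expect_equal(variance_change(x, x), 1)
  expect_equal(variance_change(x, 2 * x), 0.25)
  expect_equal(variance_change(c(0, 2), c(0, 4)), 0.25)
  expect_error(variance_change(c(1, 2), c(3, 3)), class = "metatrait_domain_error")
})

test_that("one-tailed Welch keeps near-nominal size at the retained design", {
  set.seed(19)
  n_sim <- 10000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rnorm(4)
    y <- rnorm(3)
    rej[i] <- welch_t(x, y, "greater")$p <= 0.05
  }
  expect_lte(mean(rej), 0.06)
})

test_that("compare_traits assembles the battery with a priori directions", {
  set.seed(23)
  tt <- data.frame(
    sample_id = paste0("s", 1:7),
    treatment = rep(c("unfertilized", "fertilized"), c(4, 3)),
    total_reads = round(runif(7, 9e4, 1.1e5)),
    genome_size = c(rnorm(4, 2000, 50), rnorm(3, 2500, 50)),
    gc_content = c(rnorm(4, .49, .005), rnorm(3, .54, .005)),
    trna_count = rpois(7, 120) + rep(c(0, 120), c(4, 3)),
    rrna_count = rpois(7, 150) + rep(c(0, 180), c(4, 3)),
    mean_enc = c(rnorm(4, 55, 0.4), rnorm(3, 51, 0.4))
  )
  tt$log_trna <- log10(tt$trna_count)
  tt$log_rrna <- log10(tt$rrna_count)
  cmp <- compare_traits(tt)
  tab <- cmp$table
  expect_true(all(c("genome_size", "gc_content", "log_trna", "log_rrna",
                    "mean_enc") %in% tab$trait))
  expect_true(all(tab$p_t[tab$trait != "mean_enc"] < 0.2))
  expect_lt(tab$p_t[tab$trait == "mean_enc"], 0.05)  # "less" direction honored
  expect_true(all(is.finite(tab$p_poisson[tab$trait %in% c("log_trna", "log_rrna")])))
  expect_true(all(is.na(tab$p_poisson[!tab$trait %in% c("log_trna", "log_rrna")])))
  # KS block appears when gene values are supplied
  gv <- list(enc = list(fertilized = rnorm(40, 50), unfertilized = rnorm(40, 55)))
  cmp <- compare_traits(tt, gene_values = gv)
  expect_true(is.finite(cmp$ks$enc$p))
  expect_error(compare_traits(tt[tt$treatment == "fertilized", ]),
               class = "metatrait_domain_error")
})
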