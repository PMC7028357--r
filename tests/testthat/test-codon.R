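# codon counting, family homozygosity, ENC and ENC'

test_that("the codon table has the canonical degeneracy-class structure", {
  ct <- codon_table()
  expect_length(ct$sense, 61L)
  expect_length(ct$stops, 3L)
  cls <- table(ct$fam_k[ct$fam_k >= 2])
  expect_equal(as.integer(cls[c("2", "3", "4", "6")]), c(9L, 1L, 5L, 3L))
  expect_equal(sort(names(ct$fam_k)[ct$fam_k == 1]), c("M", "W"))
  expect_equal(sort(names(ct$fam_k)[ct$fam_k == 6]), c("L", "R", "S"))
})

test_that("codon counting reads frame 0, drops tails, skips Ns and stops", {
  cc <- count_codons("ATGAAATTT")
  expect_equal(sum(cc), 3L)
  expect_equal(unclass(cc)[c("ATG", "AAA", "TTT")], c(ATG = 1L, AAA = 1L, TTT = 1L))
  cc <- count_codons("ATGNAAAAA")  # middle codon contains N
  expect_equal(sum(cc), 2L)
  expect_equal(unclass(cc)[["AAA"]], 1L)
  cc <- count_codons("ATGAAAT")    # trailing T dropped
  expect_equal(sum(cc), 2L)
  cc <- count_codons("ATGTAAAAA")  # stop codon TAA excluded
  expect_equal(sum(cc), 2L)
})

test_that("family homozygosity matches hand-computed values", {
  expect_equal(family_homozygosity(c(2, 0)), 1)
  expect_equal(family_homozygosity(c(1, 1)), 0)
  expect_equal(family_homozygosity(c(3, 1)), 0.5)
  expect_equal(family_homozygosity(c(4, 4, 4, 4)), 0.2)
  expect_true(is.na(family_homozygosity(c(1, 0))))
  expect_error(family_homozygosity(c(5)), class = "metatrait_domain_error")
})

test_that("ENC hits its analytic endpoints", {
  # one codon per family, every family observed at least twice
  expect_equal(enc(count_codons(generate_cds(400, b = 1, seed = 1))), 20)
  # exactly even usage within every family overshoots 61 and is clamped
  ct <- codon_table()
  fams <- ct$families[ct$fam_k >= 2]
  even <- unlist(lapply(fams, function(f) rep(12L %/% length(f), length(f))))
  names(even) <- unlist(fams)
  expect_equal(enc(even), 61)
})

test_that("ENC agrees with an independently coded evaluator on random genes", {
  set.seed(71)
  checked <- 0L
  for (i in 1:80) {
    cds <- generate_cds(120, b = runif(1, 0.1, 0.8), seed = NULL)
    v1 <- enc(count_codons(cds))
    v2 <- oracle_enc_from_cds(cds)
    if (!is.na(v2)) {
      expect_equal(v1, v2, tolerance = 1e-9)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 40L)
})

test_that("missing-class fallbacks follow the documented imputation rules", {
  ct <- codon_table()
  pick <- function(aa, counts) stats::setNames(counts, ct$families[[aa]][seq_along(counts)])
  # only k=2 families present, all Fhat = 0.5 (counts 3,1): F3 = (F2+F4)/2
  # fails (no F4), so every missing class term uses the global mean 0.5:
  # ENC = 2 + 9/.5 + 1/.5 + 5/.5 + 3/.5 = 38
  counts <- c(pick("F", c(3, 1)), pick("K", c(3, 1)))
  expect_equal(enc(counts), 2 + 18 / 0.5, tolerance = 1e-12)
  # k=2 and k=4 present: F3 imputed as (F2 + F4)/2
  counts <- c(pick("F", c(3, 1)), pick("A", c(3, 1, 0, 0)))
  f2 <- 0.5
  f4 <- family_homozygosity(c(3, 1, 0, 0))
  f3 <- (f2 + f4) / 2
  glob <- mean(c(f2, f4))
  expect_equal(enc(counts), 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / glob,
               tolerance = 1e-12)
  # nothing usable -> undefined
  expect_true(is.na(enc(pick("F", c(1, 0)))))
})

test_that("expected family frequencies follow the background product rule", {
  u <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  expect_equal(expected_family_frequencies(u, c("AAA", "AAG")), c(0.5, 0.5))
  expect_equal(expected_family_frequencies(c(A = .5, C = .5, G = 0, T = 0),
                                           c("AAA", "AAC")), c(0.5, 0.5))
  expect_error(expected_family_frequencies(c(A = 1, C = 0, G = 0, T = 0),
                                           c("GGA", "GGC")),
               "degenerate", class = "metatrait_domain_error")
})

test_that("corrected homozygosity scores background-matching usage as less biased", {
  # Lys family AAA/AAG, counts (3,1).  A background that itself expects
  # e = (0.75, 0.25) gives X2 = 0, so F_CF = (0 + 4 - 2)/(2*3) = 1/3 < 0.5,
  # while the uniform background reproduces Fhat = 0.5 exactly.
  ct <- codon_table()
  counts <- stats::setNames(c(3L, 1L), ct$families[["K"]])  # AAA, AAG
  # A:G ratio of 3 makes the family expectation e = (0.75, 0.25)
  bg3 <- c(A = 0.45, C = 0.20, G = 0.15, T = 0.20)
  e <- expected_family_frequencies(bg3, ct$families[["K"]])
  expect_equal(e, c(0.75, 0.25))
  set.seed(8)
  gene <- count_codons(generate_cds(200, b = 0.4))
  gene[ct$families[["K"]]] <- c(3L, 1L)
  encp_match <- enc_prime(gene, bg3)
  enc_plain <- enc(gene)
  expect_true(is.finite(encp_match))
  expect_false(isTRUE(all.equal(encp_match, enc_plain)))
})

test_that("ENC' equals ENC under a uniform background (algebraic identity)", {
  u <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  set.seed(5)
  for (i in 1:250) {
    cc <- random_codon_counts(lambda = stats::runif(1, 0.5, 8))
    e1 <- enc(cc)
    e2 <- enc_prime(cc, u)
    expect_equal(is.na(e1), is.na(e2))
    if (!is.na(e1)) expect_equal(e1, e2, tolerance = 1e-9)
  }
})

test_that("hand-evaluated corrected homozygosity cases hold", {
  # family k=2, counts (3,1), e = (0.75, 0.25): X2 = 0, F_CF = 1/3
  expect_equal(family_homozygosity_corrected(c(3, 1), c(0.75, 0.25)), 1 / 3)
  # uniform e = (0.5, 0.5): X2 = 1, F_CF = (1 + 2)/6 = 0.5 = Fhat
  expect_equal(family_homozygosity_corrected(c(3, 1), c(0.5, 0.5)), 0.5)
  expect_true(is.na(family_homozygosity_corrected(c(1, 0), c(0.5, 0.5))))
})

test_that("ENC and ENC' stay inside [20, 61] on random tables", {
  set.seed(13)
  bgs <- list(c(A = .25, C = .25, G = .25, T = .25),
              c(A = .1, C = .4, G = .4, T = .1),
              c(A = .4, C = .1, G = .1, T = .4))
  for (i in 1:100) {
    cc <- random_codon_counts(lambda = stats::runif(1, 0.2, 20))
    v <- enc(cc)
    if (!is.na(v)) expect_true(v >= 20 && v <= 61)
    bg <- bgs[[1 + i %% 3]]
    vp <- enc_prime(cc, bg)
    if (!is.na(vp)) expect_true(vp >= 20 && vp <= 61)
  }
})

test_that("higher bias parameters give lower expected ENC (monotone)", {
  bs <- seq(0.05, 0.9, by = 0.05)
  set.seed(77)
  mean_enc <- vapply(bs, function(b) {
    mean(vapply(1:15, function(i) enc(count_codons(generate_cds(300, b))),
                numeric(1)))
  }, numeric(1))
  expect_equal(cor(bs, mean_enc, method = "spearman"), -1)
})

test_that("background averaging over samples is unweighted and N-free", {
  rs1 <- c("AAAA", "CCCC")
  rs2 <- c("GGGGGGGG")  # deeper sample, still one vote
  bg <- background_from_samples(list(rs1, rs2))
  expect_equal(unclass(bg), c(A = 0.25, C = 0.25, G = 0.5, T = 0),
               ignore_attr = TRUE)
  bg <- background_from_samples(list(c("AANN", "NNAA")))
  expect_equal(unclass(bg)[["A"]], 1)
  expect_error(background_from_samples(list()), class = "metatrait_domain_error")
  expect_error(background_from_samples(list(c("NNNN"))),
               class = "metatrait_domain_error")
})

test_that("per-sample summaries and distributions follow their definitions", {
  u <- c(A = .25, C = .25, G = .25, T = .25)
  genes <- c(generate_cds(300, b = 0.95, seed = 2),
             generate_cds(300, b = 0.0, seed = 3),
             generate_cds(300, b = 0.5, seed = 4))
  s <- summarize_cub(genes, u)
  expect_equal(s$n_genes, 3L)
  expect_equal(s$community_bias, 1 / s$mean_enc)
  expect_equal(s$median_enc, sort(s$enc)[2])
  expect_equal(s$mean_enc, mean(s$enc))

  d <- cub_distribution(c(20, 61), bin_width = 1)
  expect_equal(d$ecdf_x, c(20, 61))
  expect_equal(d$ecdf_p, c(0.5, 1))
  expect_equal(sum(d$counts), 2L)
  d <- cub_distribution(c(61, 61))
  expect_equal(d$counts[length(d$counts)], 2L)
  expect_equal(d$ecdf_p, 1)
})
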