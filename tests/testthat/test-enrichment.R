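stat <- parse_motif("STAT", "TTCnnnGAA")
zld <- parse_motif("Zld", "CAGGTAG")
bg <- background_model(0.574)

test_that("background model splits composition evenly within base classes", {
  expect_equal(unname(bg$p), c(0.287, 0.213, 0.213, 0.287),
               tolerance = 1e-12)
  expect_equal(sum(bg$p), 1)
  expect_error(background_model(1.2), "in \\(0, 1\\)")
})

test_that("site probability is the product of per-position class probabilities", {
  p <- site_probability(stat, bg)
  expect_equal(p, 0.287^4 * 0.213^2)
  expect_equal(signif(p, 3), 3.08e-4)
  # fully degenerate position contributes factor 1
  expect_equal(site_probability(parse_motif("n", "N"), bg), 1.0)
  # CAGGTAG: 3 A/T-class, 4 G/C-class positions (hand product 4.87e-5)
  expect_equal(site_probability(zld, bg), 0.287^3 * 0.213^4)
  expect_equal(signif(site_probability(zld, bg), 3), 4.87e-5)
})

test_that("expected count is n * p_site", {
  p <- site_probability(stat, bg)
  expect_equal(round(expected_count(p, 84000), 1), 25.9)
  expect_equal(expected_count(0.3, 0), 0)
  expect_equal(expected_count(1.0, 10), 10)
  expect_error(expected_count(0.1, -1), ">= 0")
})

test_that("enrichment test satisfies its closed forms and reproduces the worked example", {
  p <- site_probability(stat, bg)
  r <- enrichment_test(43, 84000, p)
  expect_equal(r$expected, 84000 * p)
  expect_equal(round(r$expected, 1), 25.9)
  expect_equal(r$sd, sqrt(84000 * p * (1 - p)))
  expect_equal(round(r$sd, 1), 5.1)
  expect_equal(round(r$observed - r$expected, 1), 17.1)
  expect_equal(r$z, (43 - r$expected) / r$sd)
  expect_gt(abs(r$z), 3)  # beyond three standard deviations

  # depletion mirrors enrichment with negative z, same two-tailed mapping
  d <- enrichment_test(13, 84000, p)
  expect_lt(d$z, 0)
  expect_equal(d$p_normal_two_tailed, normal_two_tailed(abs(d$z)))
  expect_equal(round(d$z, 2), -2.53)
  expect_equal(round(d$p_normal_two_tailed, 3), 0.011)
})

test_that("null-centred observations give z = 0 and p = 1", {
  r <- enrichment_test(50, 100, 0.5)
  expect_equal(r$z, 0)
  expect_equal(r$p_normal_two_tailed, 1)
  expect_equal(r$p_binomial_exact, 1)
})

test_that("the Z to two-tailed-p mapping reproduces the printed pairs", {
  expect_equal(normal_two_tailed(0), 1.0)
  expect_equal(signif(normal_two_tailed(3.29), 2), 0.0010)
  expect_equal(signif(normal_two_tailed(2.48), 2), 0.013)
  expect_equal(normal_two_tailed(-2.48), normal_two_tailed(2.48))
})

test_that("exact binomial and normal p agree closely where the normal approximation operates", {
  set.seed(9)
  for (i in 1:40) {
    n <- sample(5000:100000, 1)
    p <- runif(1, 20 / n, 60 / n)   # expected in [20, 60]
    obs <- rbinom(1, n, p)
    r <- enrichment_test(obs, n, p)
    if (abs(r$z) <= 1.5 && r$p_normal_two_tailed < 0.999) {
      # within 20% relative in the body of the distribution
      expect_lt(abs(r$p_binomial_exact - r$p_normal_two_tailed) /
                  r$p_binomial_exact, 0.2)
    } else if (r$p_normal_two_tailed < 0.999) {
      # further out the uncorrected normal tail drifts, but stays within
      # a factor of two out to |z| ~ 3
      if (abs(r$z) <= 3)
        expect_lt(max(r$p_binomial_exact / r$p_normal_two_tailed,
                      r$p_normal_two_tailed / r$p_binomial_exact), 2)
    }
  }
})

test_that("validation errors fire on bad inputs", {
  expect_error(enrichment_test(5, 100, 0), "p_site")
  expect_error(enrichment_test(5, 100, 1), "p_site")
  expect_error(enrichment_test(-1, 100, 0.1), "observed")
  expect_error(enrichment_test(5, 0, 0.1), "n must")
})

test_that("set reports use the documented trial-count conventions", {
  g <- gen_background_sequences(21, 4000, seed = 12)
  rep_total <- set_enrichment_report(g$sequences, stat, bg,
                                     mode = "total_bp",
                                     cluster_gap = NULL)[[1]]
  expect_equal(rep_total$n, 84000L)
  rep_exact <- set_enrichment_report(g$sequences, stat, bg,
                                     mode = "exact_positions",
                                     cluster_gap = NULL)[[1]]
  expect_equal(rep_exact$n, 21L * 3992L)
  expect_error(set_enrichment_report(g$sequences, list(), bg), "no motifs")
})

test_that("background-only sets fall within three sigma of the binomial null", {
  inside <- 0
  for (seed in 1:40) {
    g <- gen_background_sequences(5, 2000, seed = seed)
    r <- set_enrichment_report(g$sequences, stat, bg,
                               mode = "exact_positions",
                               cluster_gap = NULL)[[1]]
    if (abs(r$observed - r$expected) <= 3 * r$sd) inside <- inside + 1
  }
  expect_gte(inside, 39)
})

test_that("planting k instances raises the mean observed count by about k", {
  k <- 2; n_seq <- 5; len <- 1000
  obs <- vapply(1:60, function(seed) {
    g <- gen_background_sequences(n_seq, len, seed = seed)
    pl <- plant_motifs(g$sequences, stat, k, seed = seed + 1000)
    nrow(scan_set(pl$sequences, stat))
  }, numeric(1))
  np <- n_seq * (len - stat$length + 1) * site_probability(stat, bg)
  expect_equal(mean(obs), k * n_seq + np, tolerance = 0.12)
})

test_that("the enrichment TSV report carries all columns and headers", {
  g <- gen_background_sequences(3, 500, seed = 2)
  res <- set_enrichment_report(g$sequences, list(stat, zld), bg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, f, header_lines = c("seed=2"))
  lines <- readLines(f)
  expect_match(lines[1], "^# seed=2")
  tab <- utils::read.delim(f, comment.char = "#")
  expect_identical(names(tab),
                   c("set", "motif", "observed", "n", "p_site", "expected",
                     "sd", "z", "p_normal", "p_exact", "n_clusters"))
  expect_equal(nrow(tab), 2L)
})
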