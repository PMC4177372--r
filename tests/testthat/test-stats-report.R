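test_that("chi-square matches the textbook 2x2 formula", {
  # identical proportions: no association at all
  r0 <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  m <- matrix(c(20, 10, 10, 20), 2, 2, byrow = TRUE)
  r <- chi_square_2x2(m)
  a <- 20; b <- 10; cc <- 10; d <- 20; n <- a + b + cc + d
  oracle <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(r$statistic, oracle)
  expect_equal(r$p, stats::pchisq(oracle, 1, lower.tail = FALSE))

  # symmetry under row and column swaps
  expect_equal(chi_square_2x2(m[2:1, ])$statistic, r$statistic)
  expect_equal(chi_square_2x2(m[, 2:1])$statistic, r$statistic)
  expect_equal(chi_square_2x2(t(m))$statistic, r$statistic)

  # the continuity correction only ever shrinks the statistic
  expect_lt(chi_square_2x2(m, yates = TRUE)$statistic, r$statistic)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("fraction reports keep precision and round only for display", {
  fr <- fraction_report(c(orphan = 133, promoter = 609), c(1131, 2955))
  expect_equal(fr$percent, c(100 * 133 / 1131, 100 * 609 / 2955))
  expect_equal(fr$display, c("12%", "21%"))
  expect_equal(fraction_report(0, 100)$display, "0%")
  expect_error(fraction_report(5, 0), "denominator")
})

test_that("hypergeometric enrichment equals the exhaustive tail sum", {
  # forced overlap: universe equal to the set makes every draw a hit
  r <- hypergeometric_enrichment(paste0("g", 1:10),
                                 list(all = paste0("g", 1:10)),
                                 paste0("g", 1:10))
  expect_equal(r$p, 1)
  # zero overlap has upper-tail probability 1
  r0 <- hypergeometric_enrichment(paste0("h", 1:50),
                                  list(s = paste0("g", 1:20)),
                                  c(paste0("h", 1:500), paste0("g", 1:20)))
  expect_equal(r0$overlap, 0)
  expect_equal(r0$p, 1)

  # 5 hits from a 20-gene set among 100 hits in a universe of 1000
  universe <- paste0("u", 1:1000)
  gset <- universe[1:20]
  hits <- c(universe[1:5], universe[501:595])
  r5 <- hypergeometric_enrichment(hits, list(s = gset), universe)
  tail_sum <- sum(vapply(5:20, function(i)
    choose(20, i) * choose(980, 100 - i) / choose(1000, 100), numeric(1)))
  expect_equal(r5$p, tail_sum, tolerance = 1e-10)

  expect_error(hypergeometric_enrichment("x", list(a = "x"),
                                         character(0)), "universe")
  expect_error(hypergeometric_enrichment("zz", list(a = "x"),
                                         c("x", "y")), "subset")
})

test_that("BH-adjusted q-values are monotone in the p-value ranking", {
  set.seed(12)
  universe <- paste0("u", 1:400)
  hits <- sample(universe, 60)
  sets <- lapply(1:12, function(i) sample(universe, sample(10:60, 1)))
  names(sets) <- paste0("set", 1:12)
  r <- hypergeometric_enrichment(hits, sets, universe)
  expect_true(all(diff(r$q) >= -1e-12))
  expect_true(all(r$q >= r$p))
})

test_that("the aggregate report preserves its conservation identities", {
  cfg <- sim_config(seed = 6, genome = c(chr1 = 1.2e6), n_genes = 24,
                    n_mirna = 1, n_cgis = 20, n_planted_case = 8,
                    n_planted_control = 8, n_planted_common = 6)
  run <- suppressMessages(run_pipeline(pipeline_config(simulation = cfg,
                                                       seed = 6)))
  rep <- run$report
  for (cond in names(rep$conditions)) {
    pc <- rep$conditions[[cond]]
    expect_equal(sum(unlist(pc$primary)), pc$n_dmrs)
    expect_equal(sum(unlist(pc$cgi_feature)), pc$n_dmrs)
    expect_equal(pc$promoter_split$with_cgi + pc$promoter_split$without_cgi,
                 pc$promoter_split$total)
    expect_equal(pc$n_affected_genes,
                 length(unique(c(pc$venn$cgi_and_shore, pc$venn$cgi_only,
                                 pc$venn$shore_only))))
    expect_lte(pc$n_orphan_cgis_hit, pc$n_affected_cgis)
  }
  expect_true(is.finite(rep$chi_square$statistic) ||
                is.na(rep$chi_square$statistic))
})

test_that("an empty screen yields an all-zero report without division", {
  flat <- coverage_track("case", list(chr1 = rep(5L, 2000)), 50,
                         c(chr1 = 1e5))
  flat2 <- coverage_track("control", list(chr1 = rep(5L, 2000)), 50,
                          c(chr1 = 1e5))
  pk1 <- call_peaks(flat, 5, min_confidence = 0.95)
  pk2 <- call_peaks(flat2, 5, min_confidence = 0.95)
  ex <- extract_specific(pk1, pk2)
  expect_length(ex$case_specific$regions, 0)
  b <- tiny_bundle()
  # the report tolerates empty DMR sets: zero counts, suppressed
  # percentages, no chi-square
  rep <- build_report(ex, b)
  expect_equal(rep$conditions$case$n_dmrs, 0)
  expect_true(is.na(rep$conditions$case$orphan_pct))
  expect_true(is.na(rep$chi_square$p))
})
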