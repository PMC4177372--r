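test_that("the dual-threshold screen gates and subtracts as defined", {
  case <- make_peak_set(data.frame(chrom = "chr1", start = 101, end = 300,
                                   conf = 0.99), "case")
  ctrl <- make_peak_set(data.frame(chrom = "chr1", start = 201, end = 400,
                                   conf = 0.96), "control")
  ex <- extract_specific(case, ctrl)
  # strong case evidence minus weak control evidence: trimmed to [100,200)
  expect_equal(start(ex$case_specific$regions), 101)
  expect_equal(end(ex$case_specific$regions), 200)
  # the control peak is below the high gate, so nothing is
  # control-specific
  expect_length(ex$control_specific$regions, 0)
  # the overlap of the two low-confidence covers is common
  expect_equal(start(ex$common), 201)
  expect_equal(end(ex$common), 300)

  # a case peak below the high gate contributes nothing
  weak <- make_peak_set(data.frame(chrom = "chr1", start = 1001,
                                   end = 1400, conf = 0.96), "case")
  none <- make_peak_set(data.frame(chrom = "chr1", start = 9001,
                                   end = 9100, conf = 0.99), "control")
  ex2 <- extract_specific(weak, none)
  expect_length(ex2$case_specific$regions, 0)

  # an identical peak at 0.96 in both conditions is common, not specific
  p <- data.frame(chrom = "chr1", start = 501, end = 900, conf = 0.96)
  ex3 <- extract_specific(make_peak_set(p, "case"),
                          make_peak_set(p, "control"))
  expect_length(ex3$case_specific$regions, 0)
  expect_length(ex3$control_specific$regions, 0)
  expect_equal(start(ex3$common), 501)
  expect_equal(end(ex3$common), 900)

  expect_error(extract_specific(case, make_peak_set(p, "case")),
               "condition")
  expect_error(extract_specific(case, ctrl, high = 0.9, low = 0.95),
               "threshold")
})

test_that("random screens match the per-base set-algebra oracle", {
  L <- 100000
  for (seed in 1:5) {
    set.seed(seed)
    rand_peaks <- function() {
      s <- sample(L - 600, 200)
      data.frame(chrom = "chrZ", start = s,
                 end = pmin(s + sample(100:500, 200, TRUE), L),
                 conf = runif(200, 0.9, 1))
    }
    a <- rand_peaks()
    b <- rand_peaks()
    ex <- extract_specific(make_peak_set(a, "case"),
                           make_peak_set(b, "control"),
                           min_length_bp = 1)
    oracle <- oracle_dual_threshold(a, b, L)
    expect_identical(base_mask(ex$case_specific$regions, "chrZ", L),
                     oracle$case_specific)
    expect_identical(base_mask(ex$control_specific$regions, "chrZ", L),
                     oracle$control_specific)
    expect_identical(base_mask(ex$common, "chrZ", L), oracle$common)

    # the three outputs partition their bases: pairwise disjoint
    expect_equal(sum(width(intersect(ex$case_specific$regions,
                                     ex$control_specific$regions))), 0)
    expect_equal(sum(width(intersect(ex$case_specific$regions,
                                     ex$common))), 0)
    expect_equal(sum(width(intersect(ex$control_specific$regions,
                                     ex$common))), 0)
  }
})

test_that("threshold monotonicity: stricter gates shrink their sets", {
  set.seed(77)
  L <- 100000
  s <- sample(L - 600, 150)
  a <- data.frame(chrom = "chrZ", start = s,
                  end = pmin(s + sample(100:500, 150, TRUE), L),
                  conf = runif(150, 0.9, 1))
  s <- sample(L - 600, 150)
  b <- data.frame(chrom = "chrZ", start = s,
                  end = pmin(s + sample(100:500, 150, TRUE), L),
                  conf = runif(150, 0.9, 1))
  pa <- make_peak_set(a, "case")
  pb <- make_peak_set(b, "control")
  cs_bases <- vapply(c(0.95, 0.96, 0.975, 0.99), function(h) {
    sum(width(extract_specific(pa, pb, high = h, low = 0.95,
                               min_length_bp = 1)$case_specific$regions))
  }, numeric(1))
  expect_true(all(diff(cs_bases) <= 0))
  common_bases <- vapply(c(0.9, 0.95, 0.96), function(lo) {
    sum(width(extract_specific(pa, pb, high = 0.975, low = lo,
                               min_length_bp = 1)$common))
  }, numeric(1))
  expect_true(all(diff(common_bases) <= 0))
})

test_that("whole-peak mode vetoes overlapped peaks in their entirety", {
  case <- make_peak_set(data.frame(chrom = "chr1",
                                   start = c(101, 1001),
                                   end = c(300, 1300),
                                   conf = c(0.99, 0.99)), "case")
  ctrl <- make_peak_set(data.frame(chrom = "chr1", start = 291, end = 400,
                                   conf = 0.96), "control")
  base <- extract_specific(case, ctrl, mode = "base")
  whole <- extract_specific(case, ctrl, mode = "whole_peak")
  # base mode trims the overlapped peak; whole-peak mode discards it
  expect_equal(end(base$case_specific$regions), c(290, 1300))
  expect_equal(start(whole$case_specific$regions), 1001)
  expect_equal(end(whole$case_specific$regions), 1300)
})

test_that("post-subtraction slivers are dropped and logged", {
  case <- make_peak_set(data.frame(chrom = "chr1", start = 101, end = 300,
                                   conf = 0.99), "case")
  ctrl <- make_peak_set(data.frame(chrom = "chr1", start = 181, end = 400,
                                   conf = 0.96), "control")
  ex <- extract_specific(case, ctrl, min_length_bp = 100)
  # the 80 bp remnant is below the minimum length
  expect_length(ex$case_specific$regions, 0)
  expect_equal(ex$log$case_slivers_dropped, 1)
  ex2 <- extract_specific(case, ctrl, min_length_bp = 50)
  expect_equal(width(ex2$case_specific$regions), 80)
})
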