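test_that("symbolization follows the amplitude-quantile rule", {
  expect_equal(as.integer(symbolize(c(1, 5, 2, 7))), c(0L, 1L, 0L, 1L))
  s <- symbolize(rep(2.5, 50))
  expect_true(all(s == 0L))
  expect_true(attr(s, "degenerate"))
  expect_equal(as.integer(symbolize(1:9, alphabet_size = 3)),
               rep(0:2, each = 3))
  expect_false(attr(symbolize(c(1, 5, 2, 7)), "degenerate"))
  expect_error(symbolize(3), "too short")
  expect_error(symbolize(c(1, NA, 2)), "non-finite")
})

test_that("LZ76 phrase count matches hand-parsed and brute-force values", {
  expect_equal(lzc_raw("0001101001000101"), 6L)
  expect_equal(lzc_raw("0"), 1L)
  expect_equal(lzc_raw(strrep("0", 10)), 2L)
  expect_error(lzc_raw(integer(0)), "empty")
  # exhaustive agreement with the independent substring-search parser
  for (n in 1:10) {
    strs <- all_binary_strings(n)
    got <- apply(strs, 1, function(row) lzc_raw(row))
    want <- apply(strs, 1, lz76_oracle)
    expect_equal(got, want)
  }
})

test_that("normalized LZC separates random from periodic sequences", {
  set.seed(10)
  r <- sample(0:1, 10000, replace = TRUE)
  expect_gt(lzc_normalized(r), 0.85)
  expect_lt(lzc_normalized(r), 1.15)
  expect_lte(lzc_normalized(strrep("01", 5000)), 0.02)
  expect_error(lzc_normalized(c(0, 1, 0, 1, 0)), "too short")
})

test_that("sample entropy agrees exactly with the double-loop oracle", {
  set.seed(20)
  for (k in 1:5) {
    x <- stats::rnorm(150)
    expect_equal(sampen(x), sampen_oracle(x), tolerance = 1e-12)
  }
  # oscillatory epochs too, where matches are plentiful
  x <- sin(2 * pi * 3 * seq(0, 2, length.out = 150)) + 0.1 * stats::rnorm(150)
  expect_equal(sampen(x), sampen_oracle(x), tolerance = 1e-12)
})

test_that("sample entropy handles degenerate and undefined cases", {
  expect_identical(sampen(rep(1.3, 200)), 0)
  expect_error(sampen(stats::rnorm(50)), "too short")
  # with a minuscule tolerance no template pairs match: the entropy is
  # undefined and flagged, not infinite
  set.seed(60)
  x <- stats::rnorm(100)
  v <- sampen(x, sampen_params(r = 5e-4))
  expect_true(is.na(v))
  expect_true(attr(v, "undefined"))
})

test_that("sample entropy is nonincreasing in the tolerance r", {
  set.seed(30)
  x <- stats::rnorm(300)
  vals <- vapply(c(0.1, 0.15, 0.2, 0.3, 0.5),
                 function(r) sampen(x, sampen_params(r = r)), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("both metrics are invariant to positive affine rescaling", {
  set.seed(40)
  x <- stats::rnorm(400)
  y <- 12.5 * x + 3
  expect_identical(sampen(x), sampen(y))
  expect_identical(as.integer(symbolize(x)), as.integer(symbolize(y)))
})

test_that("white noise is more complex than a noisy sinusoid", {
  fs <- 250
  n <- 60 * fs
  set.seed(50)
  wn <- stats::rnorm(n)
  tone <- sin(2 * pi * 10 * seq_len(n) / fs) + 0.05 * stats::rnorm(n)
  # on raw epochs
  idx <- strokeeg:::epoch_indices(n, fs, 4)
  for (ii in idx[1:5]) {
    expect_gt(lzc_normalized(symbolize(wn[ii])),
              lzc_normalized(symbolize(tone[ii])))
    expect_gt(sampen(wn[ii]), sampen(tone[ii]))
  }
  # and in the alpha band, where the tone lives; in bands that exclude
  # 10 Hz both filtered signals are essentially filtered white noise, so
  # no ordering is expected there
  rec_w <- eeg_record(wn, fs, group = "a", subject_id = "wn")
  rec_t <- eeg_record(tone, fs, group = "a", subject_id = "tone")
  for (metric in c("LZC", "SampEn")) {
    tab <- complexity_table(list(rec_w, rec_t),
                            bands = canonical_bands()["alpha"],
                            metric = metric)
    expect_gt(tab$value[tab$subject_id == "wn"],
              tab$value[tab$subject_id == "tone"])
  }
})

test_that("complexity_table shapes, epoch lengthening and determinism", {
  coh <- make_test_cohort(n_per_group = 1)
  one <- complexity_table(coh[1], bands = canonical_bands()["theta"],
                          metric = "LZC")
  expect_equal(nrow(one), 1L)
  tab <- complexity_table(coh, metric = "SampEn")
  expect_equal(nrow(tab), length(coh) * 4L)
  expect_identical(attr(tab, "metric_name"), "SampEn")
  expect_equal(tab, complexity_table(coh, metric = "SampEn"))
  # delta epochs are lengthened to hold at least 8 low-edge cycles
  expect_equal(strokeeg:::band_epoch_s(canonical_bands()$delta, 4), 8)
  expect_equal(strokeeg:::band_epoch_s(canonical_bands()$theta, 4), 4)
})
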