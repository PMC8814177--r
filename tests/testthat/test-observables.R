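# hand-built minimal series for the pure observable functions
make_series <- function(mat, dt = 0.01, volume = 1e-18) {
  S <- nrow(mat)
  R <- 0
  structure(list(
    times = (seq_len(ncol(mat)) - 1) * dt,
    ticks = seq_len(ncol(mat)) - 1,
    free = mat,
    bound = mat * 0L,
    complex_partial = matrix(0, 0, ncol(mat)),
    complex_saturated = matrix(0, 0, ncol(mat)),
    completions = matrix(0, 0, ncol(mat)),
    species = rownames(mat),
    reactions = character(0),
    volume = volume,
    meta = list(seed = 1, tick = dt, record_every = 1,
                perception_distance = 10)), class = "conc_series")
}

test_that("counts convert to concentrations and back", {
  m <- make_series(rbind(A = c(602, 301, 0)))
  expect_equal(concentrations(m)["A", ], c(1, 0.5, 0), tolerance = 1e-3)
  for (n in c(0L, 1L, 602L, 54321L, 1000000L))
    expect_identical(concentration_to_count(count_to_concentration(n, 1e-18),
                                            1e-18), n)
})

test_that("depletion time is the first durable zero", {
  s <- make_series(rbind(GLC = c(5, 3, 0, 0, 0)))
  expect_equal(depletion_time(s, "GLC"), s$times[3])
  s2 <- make_series(rbind(GLC = c(5, 3, 0, 1, 0)))
  expect_equal(depletion_time(s2, "GLC"), s2$times[5])
  s3 <- make_series(rbind(GLC = c(5, 3, 2, 2, 1)))
  expect_true(is.na(depletion_time(s3, "GLC")))
  s4 <- make_series(rbind(GLC = c(0, 0, 0)))
  expect_equal(depletion_time(s4, "GLC"), s4$times[1])
})

test_that("dominant frequency recovers a planted sinusoid", {
  t <- seq(0, 0.99, by = 0.01)                 # 100 Hz sampling, 1 s window
  x <- sin(2 * pi * 2.8 * t)
  f <- dominant_frequency(x, times = t)
  expect_equal(f, 2.8, tolerance = 1 / 2.8)    # within one 1-Hz bin
  expect_lte(abs(f - 2.8), 1)
})

test_that("featureless series have no dominant frequency", {
  t <- seq(0, 0.99, by = 0.01)
  expect_true(is.na(dominant_frequency(rep(3, 100), times = t)))
  expect_true(is.na(dominant_frequency(5 * t + 2, times = t)))
  expect_error(dominant_frequency(rnorm(10), times = seq(0, 0.09, by = 0.01)),
               "32")
  expect_error(dominant_frequency(rnorm(64), times = cumsum(runif(64))),
               "uniform")
})

test_that("planted frequencies are recovered under noise (SNR >= 3)", {
  set.seed(20)
  hits <- 0
  for (i in 1:50) {
    f0 <- runif(1, 2, 20)
    t <- seq(0, 1.27, by = 0.01)
    amp <- 1
    noise_sd <- amp / sqrt(2) / sqrt(3)   # power SNR = 3
    x <- amp * sin(2 * pi * f0 * t + runif(1, 0, 2 * pi)) +
      rnorm(length(t), sd = noise_sd)
    f <- dominant_frequency(x, times = t)
    bin <- 1 / (length(t) * 0.01)
    if (!is.na(f) && abs(f - f0) <= bin + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("synchrony is the detrended zero-lag correlation", {
  t <- seq(0, 0.99, by = 0.01)
  x <- sin(2 * pi * 3 * t) + t
  s <- make_series(rbind(A = x, B = x, C = -x + 2 * t, D = rep(1, 100)))
  expect_equal(synchrony(s, "A", "B"), 1)
  expect_equal(synchrony(s, "A", "C"), -1)
  expect_true(is.na(synchrony(s, "A", "D")))
  set.seed(22)
  n <- make_series(rbind(A = rnorm(100), B = rnorm(100)))
  expect_lt(abs(synchrony(n, "A", "B")), 0.3)
})

test_that("series round-trip through CSV and RDS containers", {
  m <- toy_single_reaction(30)
  run <- run_simulation(m, quick_config(duration = 0.01, seed = 19,
                                        record_every = 5))
  s <- run$series
  fcsv <- withr::local_tempfile(fileext = ".csv")
  frds <- withr::local_tempfile(fileext = ".rds")
  write_series(s, fcsv)
  write_series(s, frds)
  s2 <- read_series(fcsv)
  s3 <- read_series(frds)
  expect_equal(s3, s)
  expect_equal(s2$times, s$times)
  expect_equal(s2$free, s$free + 0, ignore_attr = FALSE,
               tolerance = 0)
  expect_equal(s2$bound, s$bound + 0)
  expect_equal(s2$completions, s$completions, ignore_attr = TRUE)
  expect_equal(s2$meta$seed, s$meta$seed)
  expect_equal(s2$meta$config_hash, s$meta$config_hash)
  expect_equal(s2$volume, s$volume)
  # the CSV opens as a plain table with a header
  tab <- read.csv(fcsv, comment.char = "#")
  expect_true(all(c("time", "quantity", "name", "count") %in% names(tab)))
})
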