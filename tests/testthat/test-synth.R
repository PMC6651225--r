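test_that("trial generation is deterministic and label-symmetric at zero depth", {
  cfg <- synth_config(erd_depth = 0, noise_sd = 0.5)
  a <- synthesize_trial(cfg, "left", seed = 42)
  b <- synthesize_trial(cfg, "left", seed = 42)
  expect_identical(a$data, b$data)

  r <- synthesize_trial(cfg, "right", seed = 42)
  expect_identical(a$data, r$data)  # no attenuation => label has no effect

  expect_true(all(is.finite(a$data)))
  expect_identical(rownames(a$data), c("C3", "Cz", "C4"))
  expect_true(a$cue_index >= 0 && a$cue_index < ncol(a$data))
})

test_that("ERD attenuates the contralateral mu amplitude by 1 - depth", {
  cfg <- synth_config(erd_depth = 0.8, noise_sd = 0, beta_amp = 0)
  tr <- synthesize_trial(cfg, "right", seed = 1)  # right hand -> C3
  fs <- cfg$sampling_rate
  win <- (round((3 + 0.5) * fs) + 1):round((3 + 2.5) * fs)  # inside ERD window
  amp_c3 <- max(abs(tr$data["C3", win]))
  amp_cz <- max(abs(tr$data["Cz", win]))
  expect_equal(amp_c3, 0.2 * cfg$mu_amp, tolerance = 0.02)
  expect_equal(amp_cz, cfg$mu_amp, tolerance = 0.02)
  ## outside the ERD window C3 is back to full amplitude
  pre <- 1:round(2.5 * fs)
  expect_equal(max(abs(tr$data["C3", pre])), cfg$mu_amp, tolerance = 0.02)
})

test_that("synthesize_dataset yields balanced, reproducible, seed-sensitive sets", {
  cfg <- synth_config()
  ts <- synthesize_dataset(cfg, 10, seed = 5)
  labs <- vapply(ts$trials, `[[`, character(1), "label")
  expect_length(ts$trials, 20)
  expect_equal(sum(labs == "left"), 10)
  expect_equal(sum(labs == "right"), 10)

  ts2 <- synthesize_dataset(cfg, 10, seed = 5)
  expect_identical(ts$trials[[7]]$data, ts2$trials[[7]]$data)

  ts3 <- synthesize_dataset(cfg, 10, seed = 6)
  expect_false(identical(ts$trials[[1]]$data, ts3$trials[[1]]$data))
})

test_that("generator rejects invalid configurations and labels", {
  expect_error(synth_config(erd_depth = 1.5), "erd_depth")
  expect_error(synth_config(erd_window = c(2, 1)), "erd_window")
  expect_error(synth_config(cue_time = 7, erd_window = c(0.3, 2.8)),
               "trial_duration")
  expect_error(synthesize_trial(synth_config(), "foot"), "label")
  expect_error(synthesize_dataset(synth_config(), 0), "n_per_class")
})

test_that("band_power matches closed-form sinusoid power and is band-limited", {
  cfg <- synth_config(noise_sd = 0, mu_amp = 0, beta_amp = 0)
  tr <- synthesize_trial(cfg, "left", seed = 1)
  fs <- tr$sampling_rate
  t <- (seq_len(ncol(tr$data)) - 1) / fs

  expect_equal(band_power(tr, 1, c(8, 12), c(0, 2)), 0)  # zero signal

  tr$data[1, ] <- sin(2 * pi * 10 * t)
  p <- band_power(tr, 1, c(8, 12), c(0, 2))
  expect_equal(p, 0.5, tolerance = 0.1 * 0.5)

  ## out-of-band component leaves the band power nearly unchanged
  tr$data[1, ] <- sin(2 * pi * 10 * t) + sin(2 * pi * 45 * t)
  p2 <- band_power(tr, 1, c(8, 12), c(0, 2))
  expect_equal(p2, p, tolerance = 0.05 * p)
})

test_that("Cz statistics are label-independent and C3/C4 roles swap", {
  cfg <- synth_config(erd_depth = 0.8, noise_sd = 0.5)
  n <- 50
  win <- c(3.3, 5.8)  # the ERD window in absolute seconds
  mu_band <- c(8, 12)
  pow <- function(label, ch) {
    set.seed(if (label == "left") 100 else 200)
    mean(vapply(seq_len(n), function(i) {
      tr <- synthesize_trial(cfg, label, seed = i * 13 + 7)
      band_power(tr, ch, mu_band, win)
    }, numeric(1)))
  }
  ## contralateral channel carries the attenuation
  expect_lt(pow("left", "C4"), 0.6 * pow("left", "C3"))
  expect_lt(pow("right", "C3"), 0.6 * pow("right", "C4"))
  ## Cz is label-independent up to Monte-Carlo noise
  expect_equal(pow("left", "Cz"), pow("right", "Cz"), tolerance = 0.15)
})

test_that("contralateral mu power is monotone in depth with exact noise-free ratio", {
  win <- c(3.3, 5.8)
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  powers <- vapply(depths, function(d) {
    cfg <- synth_config(erd_depth = d, noise_sd = 0, beta_amp = 0)
    tr <- synthesize_trial(cfg, "right", seed = 3)
    band_power(tr, "C3", c(8, 12), win)
  }, numeric(1))
  expect_true(all(diff(powers) < 0))

  cfg <- synth_config(erd_depth = 0.8, noise_sd = 0, beta_amp = 0)
  tr <- synthesize_trial(cfg, "right", seed = 3)
  ratio <- band_power(tr, "C3", c(8, 12), win) /
    band_power(tr, "C4", c(8, 12), win)
  expect_equal(ratio, (1 - 0.8)^2, tolerance = 0.05 * (1 - 0.8)^2)
})

test_that("trial archives round-trip through the writer", {
  ts <- synthesize_dataset(synth_config(), 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  write_trialset(ts, path)
  back <- read_trialset(path)
  expect_length(back$trials, 6)
  expect_equal(back$trials[[2]]$data, ts$trials[[2]]$data)
  expect_identical(back$trials[[2]]$label, ts$trials[[2]]$label)
  expect_equal(back$trials[[4]]$cue_index, ts$trials[[4]]$cue_index)
})
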