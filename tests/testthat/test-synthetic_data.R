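test_that("shaker simulation reproduces the centripetal amplitude", {
  dev <- identity_device()

  # no motion: gravity only
  still <- simulate_shaker_trial(shaker_config(0), dev, seed = 1)
  expect_equal(still$x, rep(0, length(still$x)))
  expect_equal(still$y, rep(0, length(still$y)))
  expect_equal(still$z, rep(1, length(still$z)))

  # 240 rpm: in-plane amplitude equals the oracle (3.271 g)
  tr <- simulate_shaker_trial(shaker_config(240), dev, seed = 1)
  expect_equal(round(max(abs(tr$x)), 3), 3.271)

  # a 7% sensitivity error scales the amplitude accordingly
  hot <- device_model("hot", gain = 1.07)
  tr7 <- simulate_shaker_trial(shaker_config(240), hot, seed = 1)
  expect_equal(max(abs(tr7$x)), 3.500, tolerance = 1e-3)

  # ideal trial VM is constant at sqrt(A^2 + 1)
  A <- centripetal_acceleration(240)
  expect_lt(max(abs(vector_magnitude(tr) - sqrt(A^2 + 1))), 1e-9)
})

test_that("device model applies gain, offset, filter, noise, quantizer, clip in order", {
  n <- 800
  withr::with_seed(3, {
    rec <- recording(rnorm(n), rnorm(n), rnorm(n) + 1, fs = 80)
  })

  # identity model returns the input exactly
  ident <- identity_device()
  out <- apply_device_model(rec, ident, seed = 5)
  expect_identical(out$x, rec$x)
  expect_identical(out$z, rec$z)

  # clipping at the dynamic range
  big <- recording(rep(7, n), rep(0, n), rep(1, n), fs = 80)
  clipped <- apply_device_model(big, ident, seed = 1)
  expect_equal(clipped$x, rep(6, n))

  # uniform gain scales every VM sample exactly
  g <- device_model("g", gain = 1.05)
  outg <- apply_device_model(rec, g, seed = 1)
  expect_equal(vector_magnitude(outg), 1.05 * vector_magnitude(rec),
               tolerance = 1e-12)

  # quantizer puts samples on the step grid
  q <- device_model("q", adc_bits = 8)
  outq <- apply_device_model(rec, q, seed = 1)
  step <- 12 / 2^8
  expect_equal(outq$x, round(outq$x / step) * step, tolerance = 1e-12)

  # first-order low-pass attenuates a tone far above cutoff
  t <- (seq_len(n) - 1) / 80
  tone <- recording(sin(2 * pi * 30 * t), rep(0, n), rep(1, n), fs = 80)
  lp <- device_model("lp", lowpass_hz = 2)
  outlp <- apply_device_model(tone, lp, seed = 1)
  expect_lt(max(abs(outlp$x)), 0.2)
})

test_that("activity bouts are deterministic and share the true signal across devices", {
  models <- default_activity_models()
  dev <- identity_device("devX")

  a <- simulate_activity_bout(models$walk_2.0, "S1", dev, seed = 7)
  b <- simulate_activity_bout(models$walk_2.0, "S1", dev, seed = 7)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$z, b$z)

  # two devices with identical parameters and ids record identical samples
  d1 <- device_model("same", noise_sd = 0.01)
  r1 <- simulate_activity_bout(models$vacuum, "S1", d1, seed = 3)
  r2 <- simulate_activity_bout(models$vacuum, "S1", d1, seed = 3)
  expect_identical(r1$x, r2$x)

  # different seeds give different signals
  c2 <- simulate_activity_bout(models$walk_2.0, "S1", dev, seed = 8)
  expect_false(identical(a$x, c2$x))

  # harmonics at or above Nyquist alias and are refused
  badm <- activity_model("walk_2.0",
                         data.frame(freq = 40, amp = 0.5, amp_cv = 0.1))
  expect_error(simulate_activity_bout(badm, "S1", dev, seed = 1), "alias")
})

test_that("near-static and rhythmic bouts have the configured signatures", {
  dev <- identity_device()
  models <- default_activity_models()

  # computer work: VM variability bounded by the configured noise level
  comp <- simulate_activity_bout(models$computer, "S1", dev, seed = 2)
  expect_lt(sd(vector_magnitude(comp)), 0.05)

  # a 2.0 Hz dominant harmonic shows up as the spectral peak of the VM
  walkm <- activity_model("walk_2.0",
                          data.frame(freq = 2.0, amp = 0.5, amp_cv = 0.05),
                          baseline_sd = 0.02, subject_cv = 0.05)
  wrec <- simulate_activity_bout(walkm, "S1", dev, seed = 4)
  w <- make_windows(wrec)[[1]]
  fd <- fd_features(w$vm, fs = 80)
  expect_equal(fd$dom_freq, 2.0, tolerance = 0.05 + 1e-9)
})

test_that("study builder yields paired recordings with the expected counts", {
  study <- small_study()
  # 4 subjects x 8 fine activities x 2 devices
  expect_length(study$recordings, 64)
  ids <- vapply(study$recordings, function(r) r$device_id, character(1))
  expect_equal(as.vector(table(ids)[study$device_ids]), c(32L, 32L))

  wins <- small_windows()
  for (d in study$device_ids) {
    acts <- vapply(wins[[d]], function(w) w$activity, character(1))
    counts <- table(acts)
    expect_equal(as.vector(counts[c("clean", "computer", "throw", "vacuum")]),
                 rep(12L, 4))
    expect_equal(as.vector(counts[c("walk", "run")]), rep(24L, 2))
  }

  expect_error(build_study(subjects = c("S1", "S1")), "duplicate")

  # paired wear: identical device parameters and ids -> identical samples
  same <- list(A = device_model("twin", noise_sd = 0.01),
               B = device_model("twin", noise_sd = 0.01))
  st <- build_study(subjects = c("S1", "S2"),
                    models = default_activity_models()[c("computer", "throw")],
                    devices = same, master_seed = 5)
  expect_identical(st$recordings[[1]]$x, st$recordings[[2]]$x)
})

test_that("default device pair elevates mean shaker VM by 3-8% at every speed", {
  devs <- default_device_models()
  trials <- simulate_shaker_study(devs, n_trials = 3, master_seed = 7)
  for (r in c(40, 80, 140, 200, 240)) {
    sub <- Filter(function(tr) tr$rpm == r, trials)
    ma <- mean(vapply(sub, trial_mean_vm, numeric(1), device_id = "deviceA"))
    mb <- mean(vapply(sub, trial_mean_vm, numeric(1), device_id = "deviceB"))
    elev <- 100 * (mb - ma) / ma
    expect_gt(elev, 3)
    expect_lt(elev, 8)
  }
})
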