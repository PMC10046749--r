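test_that("DC remover matches the hand recursion and its closed forms", {
  # hand recursion: m = x + a m_prev, y = m - m_prev
  expect_equal(dc_remove(c(1, 1, 1), a = 0.5, m0 = 0), c(1, 0.5, 0.25))

  # a = 1: the transfer function reduces to 1
  x <- rnorm(200)
  expect_equal(dc_remove(x, a = 1), x)

  # constant input decays geometrically to zero (zero gain at DC)
  y <- dc_remove(rep(3, 80), a = 0.9, m0 = 0)
  expect_equal(y[2:80] / y[1:79], rep(0.9, 79))
  expect_lt(abs(y[80]), 1e-2)

  # steady-state initialization suppresses the start-up transient entirely
  expect_equal(dc_remove(rep(3, 50), a = 0.9), rep(0, 50))

  expect_error(dc_remove(x, a = 0), "0, 1")
  expect_error(dc_remove(x, a = 1.5), "0, 1")
})

test_that("DC remover gain is 0 at DC and 2/(1+a) at Nyquist for any a", {
  for (a in c(0.5, 0.9, 0.95, 0.99)) {
    dc <- dc_remove(rep(1, 3000), a, m0 = 0)
    expect_lt(abs(dc[3000]), 1e-10)
    nyq <- dc_remove(rep(c(1, -1), 1500), a, m0 = 0)
    # |H(pi)| = |1 - (-1)| / |1 + a| = 2 / (1 + a)
    expect_equal(abs(nyq[3000]), 2 / (1 + a), tolerance = 1e-6)
  }
})

test_that("Chebyshev-II bandpass passes the pulse band and rejects drift", {
  fs <- 100
  cfg <- preprocess_config()
  tt <- (0:5999) / fs
  tone <- sin(2 * pi * 1.5 * tt)
  out <- bandpass(tone, fs, cfg)
  rms <- function(v) sqrt(mean(v^2))
  keep <- 2000:6000  # past the filter transient
  expect_equal(rms(out[keep]) / rms(tone[keep]), 1, tolerance = 0.05)

  slow <- sin(2 * pi * 0.05 * (0:19999) / fs)
  out_slow <- bandpass(slow, fs, cfg)
  atten_db <- 20 * log10(rms(out_slow[10000:20000]) / rms(slow[10000:20000]))
  expect_lt(atten_db, -cfg$stop_atten_db)

  expect_equal(bandpass(numeric(100), fs, cfg), numeric(100))
  expect_error(bandpass(tone, fs = 6, cfg), "twice")
  expect_length(out, length(tone))
})

test_that("channel fusion is scale-invariant and averages down noise", {
  ir <- sin(2 * pi * 1.2 * (0:999) / 100)
  zs <- function(v) (v - mean(v)) / sd(v)
  expect_equal(fuse_channels(ir, ir), zs(ir))
  expect_equal(fuse_channels(ir, 2 * ir), zs(ir))

  set.seed(1)
  n1 <- rnorm(1000, 0, 0.5)
  n2 <- rnorm(1000, 0, 0.5)
  fused <- fuse_channels(ir + n1, ir + n2)
  # residual noise after fusing two independently corrupted copies
  noise_of <- function(v) v - zs(ir) * cor(v, zs(ir)) * sd(v)
  expect_lt(var(noise_of(fused)),
            max(var(noise_of(zs(ir + n1))), var(noise_of(zs(ir + n2)))))
  expect_error(fuse_channels(ir, ir[-1]), "equal length")
})

test_that("Pearson correlation handles the canonical cases", {
  x <- c(0.2, -1, 0.5, 2, -0.3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  expect_warning(r0 <- pearson_r(x, rep(2, 5)), "zero-variance")
  expect_equal(r0, 0)
  expect_error(pearson_r(x, x[-1]), "equal length")
})

test_that("reference selection picks the most correlated axis above threshold", {
  set.seed(7)
  ppg <- sin(2 * pi * 1.2 * (0:1999) / 100)
  acc <- rbind(x = ppg + rnorm(2000, 0, 0.05),
               y = rnorm(2000),
               z = rnorm(2000))
  sel <- select_reference(ppg, acc, 0.3)
  expect_equal(sel$axis, "x")
  expect_gt(abs(sel$r_max), 0.9)
  # independent oracle: plain cor() per axis
  expect_equal(unname(sel$r_per_axis),
               unname(apply(acc, 1, function(a) cor(ppg, a))))

  none <- select_reference(ppg, rbind(rnorm(2000), rnorm(2000), rnorm(2000)),
                           0.3)
  expect_equal(none$axis, "none")
  expect_lte(abs(none$r_max), 0.3)

  tie <- select_reference(ppg, rbind(x = ppg, y = ppg, z = rnorm(2000)), 0.3)
  expect_equal(tie$axis, "x")  # fixed x -> y -> z tie-break
})

test_that("RLS with a zero reference returns the input unchanged", {
  d <- rnorm(300)
  out <- rls_cancel(d, numeric(300))
  expect_equal(as.numeric(out), d)
  expect_equal(attr(out, "weights"), numeric(12))
})

test_that("RLS converges to the batch least-squares solution", {
  cfg <- preprocess_config(rls_order = 8)
  set.seed(11)
  T <- 6000
  ref <- as.numeric(stats::filter(rnorm(T), rep(0.25, 4), sides = 1))
  ref[is.na(ref)] <- 0
  s <- sin(2 * pi * 1.2 * (0:(T - 1)) / 100)
  h <- c(0.8, -0.4, 0.2)
  artifact <- as.numeric(stats::filter(ref, h, sides = 1))
  artifact[is.na(artifact)] <- 0
  d <- s + artifact

  out <- as.numeric(rls_cancel(d, ref, cfg))
  burn <- 1000
  rel_resid <- sum((out[burn:T] - s[burn:T])^2) / sum(s[burn:T]^2)
  expect_lt(rel_resid, 1e-2)
  # the batch LS projection onto the same lags is the oracle for how much
  # of the artifact is linearly removable at all
  oracle_resid <- lagged_ls_residual(d, ref, cfg$rls_order)
  oracle_rel <- sum((oracle_resid[burn:T] - s[burn:T])^2) / sum(s[burn:T]^2)
  expect_lt(oracle_rel, 1e-2)

  # lambda = 1 is exactly ridge-regularized growing-window least squares
  cfg1 <- preprocess_config(rls_order = 6, rls_lambda = 1)
  d2 <- artifact + rnorm(T, 0, 0.05)
  out2 <- rls_cancel(d2, ref, cfg1)
  w_ols <- lagged_ls_weights(d2, ref, 6, delta = cfg1$rls_delta)
  expect_equal(attr(out2, "weights"), as.numeric(w_ols), tolerance = 1e-6)
})

test_that("RLS improves the signal-to-artifact ratio under linear coupling", {
  cfg <- generator_config(duration_s = 60, noise_sd = 0.05, seed = 13)
  rec <- generate_recording(cfg, "S01", "non_stressed")
  clean_ref <- generate_recording(
    quiet_generator_config(duration_s = 60, seed = 13), "S01", "non_stressed")
  pcfg <- preprocess_config()
  # the generator's noise-free pulse, pushed through the same linear filters,
  # is the known clean component
  target <- bandpass(dc_remove(clean_ref$ppg_ir, pcfg$a), 100, pcfg)
  target <- (target - mean(target)) / sd(target)
  cl <- preprocess_recording(rec, pcfg)
  fused_raw <- fuse_channels(
    bandpass(dc_remove(rec$ppg_ir, pcfg$a), 100, pcfg),
    bandpass(dc_remove(rec$ppg_red, pcfg$a), 100, pcfg))
  snr <- function(v) {
    fit <- lm.fit(cbind(1, target), v)
    sum((v - fit$residuals)^2) / sum(fit$residuals^2)
  }
  expect_equal(cl$reference_axis_used, "x")
  expect_gt(snr(cl$signal), snr(fused_raw))
})

test_that("the full chain bypasses RLS without a reference and centers output", {
  cfg <- generator_config(duration_s = 30, ma_gain = 0, seed = 17)
  rec <- generate_recording(cfg, "S05", "stressed")
  cl <- preprocess_recording(rec)
  expect_equal(cl$reference_axis_used, "none")
  expect_lte(abs(cl$r_max), 0.3)
  pcfg <- preprocess_config()
  fused <- fuse_channels(
    bandpass(dc_remove(rec$ppg_ir, pcfg$a), 100, pcfg),
    bandpass(dc_remove(rec$ppg_red, pcfg$a), 100, pcfg))
  expect_equal(cl$signal, fused)  # pass-through, bit-identical

  cfg2 <- generator_config(duration_s = 30, seed = 17)
  rec2 <- generate_recording(cfg2, "S05", "stressed")
  cl2 <- preprocess_recording(rec2)
  expect_equal(cl2$reference_axis_used, "x")
  expect_length(cl2$signal, length(rec2$ppg_ir))
  expect_true(all(is.finite(cl2$signal)))
  expect_lt(abs(mean(cl2$signal)), 1e-2)
  # artifact leakage shrinks: correlation with the (preprocessed) reference
  ref <- bandpass(dc_remove(rec2$acc["x", ], pcfg$a), 100, pcfg)
  fused2 <- fuse_channels(
    bandpass(dc_remove(rec2$ppg_ir, pcfg$a), 100, pcfg),
    bandpass(dc_remove(rec2$ppg_red, pcfg$a), 100, pcfg))
  expect_lt(abs(cor(cl2$signal, ref)), abs(cor(fused2, ref)))
})
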