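make_punctum_stack <- function(n_frames, shifts = NULL, noise_sd = 0,
                               seed = 1) {
  set.seed(seed)
  base <- matrix(0, 48, 48)
  for (c0 in list(c(12, 15), c(30, 34), c(38, 12))) {
    xs <- outer((1:48 - c0[1])^2, (1:48 - c0[2])^2, "+")
    base <- base + 100 * exp(-xs / (2 * 2^2))
  }
  lapply(seq_len(n_frames), function(k) {
    fr <- if (is.null(shifts)) base
          else axovuln:::translate_int(base, shifts[k, 1], shifts[k, 2])
    fr + matrix(rnorm(48 * 48, 0, noise_sd), 48, 48)
  })
}

test_that("stack registration recovers planted translations", {
  still <- make_punctum_stack(4)
  expect_true(all(register_stack(still) == 0))

  shifts <- rbind(c(0, 0), c(3, -2), c(-4, 1))
  st <- make_punctum_stack(3, shifts = shifts)
  off <- register_stack(st)
  expect_equal(unname(off), unname(-shifts))
  # applying the offsets aligns every frame with frame 1
  aligned <- apply_offsets(st, off)
  expect_equal(aligned[[2]][5:44, 5:44], st[[1]][5:44, 5:44])

  noisy <- make_punctum_stack(3, shifts = shifts, noise_sd = 20, seed = 3)
  off_n <- register_stack(noisy)
  expect_true(all(abs(off_n - (-shifts)) <= 1))
})

test_that("trace extraction averages each ROI per frame", {
  stack <- lapply(c(100, 110, 120), function(v) matrix(v, 8, 8))
  rois <- matrix(0L, 8, 8); rois[2:3, 2:3] <- 1L; rois[6:7, 6:7] <- 2L
  epoch <- c("baseline", "DTT", "ALD")
  traces <- extract_traces(stack, rois, epoch)
  expect_length(traces, 2)
  expect_equal(traces[[1]]$intensity, c(100, 110, 120))
  expect_equal(traces[[2]]$intensity, c(100, 110, 120))
  expect_equal(as.character(traces[[1]]$epoch), epoch)
})

test_that("QC applies the >10% drift rule and responder requirement", {
  flat <- generate_trace(trace_spec(noise_sd = 0, seed = 1))
  qc <- qc_trace(flat)
  expect_true(qc$included)
  expect_lt(qc$drift_fraction, 0.01)

  drift <- generate_trace(trace_spec(noise_sd = 2, drift_fraction = -0.2,
                                     seed = 2))
  qd <- qc_trace(drift)
  expect_true(qd$excluded_drift)
  expect_gt(qd$drift_fraction, 0.10)

  small_drift <- generate_trace(trace_spec(noise_sd = 2,
                                           drift_fraction = -0.05, seed = 3))
  expect_false(qc_trace(small_drift)$excluded_drift)

  nonresp <- generate_trace(trace_spec(noise_sd = 2, responder = FALSE,
                                       seed = 4))
  qn <- qc_trace(nonresp)
  expect_true(qn$excluded_nonresponder)
  expect_false(qn$included)

  no_ald <- flat
  no_ald$epoch <- factor(rep("baseline", length(no_ald$intensity)),
                         levels = levels(flat$epoch))
  expect_error(qc_trace(no_ald), "epochs")
})

test_that("planted exclusion fractions are recovered over many traces", {
  set.seed(77)
  n <- 500
  drift_planted <- runif(n) < 0.12
  nonresp_planted <- !drift_planted & runif(n) < 0.10
  res <- vapply(seq_len(n), function(i) {
    tr <- generate_trace(trace_spec(
      drift_fraction = if (drift_planted[i]) sample(c(-0.25, 0.25), 1) else
        runif(1, -0.03, 0.03),
      responder = !nonresp_planted[i], noise_sd = 8, seed = 1000 + i))
    qc <- qc_trace(tr)
    c(qc$excluded_drift, qc$excluded_nonresponder)
  }, logical(2))
  expect_lt(abs(mean(res[1, ]) - mean(drift_planted)), 0.03)
  expect_lt(abs(mean(res[2, ]) - mean(nonresp_planted)), 0.03)
})

test_that("relative oxidation matches its formula and invariances", {
  expect_equal(relative_oxidation(1000, 1000, 200)$value, 0)
  expect_equal(relative_oxidation(200, 1000, 200)$value, 1)
  expect_equal(relative_oxidation(600, 1000, 200)$value, 0.5)
  expect_error(relative_oxidation(500, 200, 1000), "calibration")
  # affine invariance
  f <- 700; fd <- 1100; fa <- 300
  v0 <- relative_oxidation(f, fd, fa)$value
  for (tf in list(c(2, 0), c(0.5, 0), c(1, 50), c(3, -100))) {
    expect_equal(relative_oxidation(tf[1] * f + tf[2], tf[1] * fd + tf[2],
                                    tf[1] * fa + tf[2])$value, v0)
  }
  # strictly decreasing in F
  vals <- vapply(seq(fa, fd, length.out = 9), function(fi)
    relative_oxidation(fi, fd, fa)$value, numeric(1))
  expect_true(all(diff(vals) < 0))
  # out-of-range clipped and flagged
  over <- relative_oxidation(1100, 1000, 200)
  expect_equal(over$value, 0)
  expect_true(over$clipped)
})

test_that("oxidation is recovered from noisy traces with small error", {
  set.seed(55)
  ox_true <- runif(500)
  err <- vapply(seq_along(ox_true), function(i) {
    fd <- 1000; fa <- 200
    fb <- fd - ox_true[i] * (fd - fa)
    tr <- generate_trace(trace_spec(f_baseline = fb, f_dtt = fd, f_ald = fa,
                                    noise_sd = 0.02 * (fd - fa),
                                    seed = 2000 + i))
    r <- oxidation_result(tr)
    if (is.na(r$relative_oxidation)) NA_real_
    else abs(r$relative_oxidation - ox_true[i])
  }, numeric(1))
  expect_lt(mean(err, na.rm = TRUE), 0.03)
  # traces planted at extreme oxidation (baseline within noise of a
  # calibration plateau) are legitimately excluded as non-responders
  expect_gt(mean(!is.na(err)), 0.85)
})

test_that("inter-mitochondrial gaps are consecutive ordered differences", {
  expect_equal(intermito_distances(c(0, 10, 25)), c(10, 15))
  expect_length(intermito_distances(5), 0)
  set.seed(6)
  centers <- cumsum(runif(30, 5, 20))
  expect_equal(sort(intermito_distances(rev(centers))),
               sort(intermito_distances(centers)))
  pos <- generate_mito_positions(mito_spacing_spec(n_puncta = 2000, seed = 9))
  gaps <- intermito_distances(pos)
  expect_gt(mean(gaps), 12.5); expect_lt(mean(gaps), 13.5)
})

test_that("traces extracted from a generated stack match their specs", {
  specs <- list(trace_spec(f_baseline = 500, noise_sd = 4, seed = 1),
                trace_spec(f_baseline = 800, noise_sd = 4, seed = 2))
  traces <- lapply(specs, generate_trace)
  n_frames <- length(traces[[1]]$intensity)
  rois <- matrix(0L, 16, 16); rois[2:4, 2:4] <- 1L; rois[10:12, 10:12] <- 2L
  stack <- lapply(seq_len(n_frames), function(k) {
    fr <- matrix(0, 16, 16)
    fr[rois == 1L] <- traces[[1]]$intensity[k]
    fr[rois == 2L] <- traces[[2]]$intensity[k]
    fr
  })
  extracted <- extract_traces(stack, rois, as.character(traces[[1]]$epoch))
  for (i in 1:2) {
    expect_equal(extracted[[i]]$intensity, traces[[i]]$intensity)
    lv <- epoch_levels(extracted[[i]])
    expect_lt(abs(lv["F"] - specs[[i]]$f_baseline), 3 * specs[[i]]$noise_sd)
  }
})
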