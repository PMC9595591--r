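test_that("field generation is deterministic and respects the empty case", {
  f1 <- generate_field(field_spec(n_neurons = 5, seed = 7,
                                  neurite_total_length_um = 400,
                                  width_px = 192L, height_px = 192L))
  f2 <- generate_field(field_spec(n_neurons = 5, seed = 7,
                                  neurite_total_length_um = 400,
                                  width_px = 192L, height_px = 192L))
  expect_identical(f1$field$channels, f2$field$channels)
  expect_identical(f1$truth$varicosities, f2$truth$varicosities)

  empty <- generate_field(field_spec(n_neurons = 0, seed = 3,
                                     width_px = 128L, height_px = 128L))
  expect_equal(empty$truth$n_neurons, 0)
  expect_equal(length(empty$truth$skeleton_polylines), 0)
  # marker channel is pure background + noise
  m <- empty$field$channels$marker
  expect_lt(abs(mean(m) - 100), 1)
  expect_lt(max(m), 100 + 6 * 5)
})

test_that("generated neurite length tracks the requested total", {
  fg <- generate_field(field_spec(seed = 11, neurite_total_length_um = 5000))
  recomputed <- sum(vapply(fg$truth$skeleton_polylines, function(xy)
    sum(sqrt(rowSums(diff(xy)^2))), numeric(1)))
  expect_equal(fg$truth$total_neurite_length_um, recomputed)
  expect_lt(abs(recomputed - 5000) / 5000, 0.05)
})

test_that("ground-truth varicosities sit on their polylines", {
  tr <- default_field(seed = 2)$truth
  v <- tr$varicosities
  for (i in seq_len(min(nrow(v), 50))) {
    pl <- tr$skeleton_polylines[[v$polyline_id[i]]]
    d <- min(sqrt((pl[, 1] - v$x_um[i])^2 + (pl[, 2] - v$y_um[i])^2))
    expect_lt(d, v$width_um[i] / 2 + 0.35)
  }
})

test_that("Syt-1 mixture fractions are respected over many varicosities", {
  v <- do.call(rbind, lapply(1:4, function(s)
    generate_field(field_spec(seed = 100 + s,
                              syt1_pos_fraction = 0.6))$truth$varicosities))
  expect_gte(nrow(v), 500)
  in_gate <- !v$oversize
  expect_lt(abs(mean(v$is_syt1_positive[in_gate]) - 0.6), 0.03)
  # oversize swellings never carry the positive component
  expect_false(any(v$is_syt1_positive[v$oversize]))
})

test_that("trace generation reproduces the stated plateau structure", {
  tr <- generate_trace(trace_spec(noise_sd = 0, drift_fraction = 0, seed = 1))
  expect_equal(unique(tr$intensity[tr$epoch == "baseline"]), 600)
  expect_equal(unique(tr$intensity[tr$epoch == "DTT"]), 1000)
  expect_equal(unique(tr$intensity[tr$epoch == "ALD"]), 200)

  nr <- generate_trace(trace_spec(noise_sd = 0, responder = FALSE, seed = 2))
  expect_equal(unique(nr$intensity), 600)

  dr <- generate_trace(trace_spec(noise_sd = 0, drift_fraction = -0.2,
                                  seed = 3))
  base <- dr$intensity[dr$epoch == "baseline"]
  expect_equal(base[length(base)], 0.8 * 600)
  expect_equal(base[1], 600)
})

test_that("mito position generator matches its gamma moments", {
  reg <- generate_mito_positions(mito_spacing_spec(n_puncta = 4,
                                                   spacing_mean_um = 10,
                                                   spacing_sd_um = 0, seed = 1))
  expect_equal(reg, c(0, 10, 20, 30))

  two <- generate_mito_positions(mito_spacing_spec(n_puncta = 2, seed = 5))
  expect_length(intermito_distances(two), 1)

  pos <- generate_mito_positions(mito_spacing_spec(n_puncta = 2000, seed = 42))
  gaps <- diff(pos)
  expect_gt(mean(gaps), 12.5); expect_lt(mean(gaps), 13.5)
  expect_gt(sd(gaps), 5.0); expect_lt(sd(gaps), 5.8)
})

test_that("TIFF + JSON round trip preserves the field and truth", {
  fg <- generate_field(field_spec(n_neurons = 3, seed = 9,
                                  neurite_total_length_um = 300,
                                  width_px = 160L, height_px = 160L))
  tdir <- withr::local_tempdir()
  tif <- file.path(tdir, "f.tif"); js <- file.path(tdir, "f.json")
  write_field_tiff(fg$field, tif)
  write_ground_truth(fg$truth, js)
  rt <- read_field_tiff(tif, 0.3)
  # 16-bit quantization: within 1 grey level
  expect_lt(max(abs(rt$channels$marker - fg$field$channels$marker)), 0.51)
  expect_equal(names(rt$channels), names(fg$field$channels))
  tr <- read_ground_truth(js)
  expect_equal(tr$n_neurons, fg$truth$n_neurons)
  expect_equal(tr$total_neurite_length_um, fg$truth$total_neurite_length_um)
  expect_equal(tr$varicosities$width_um, fg$truth$varicosities$width_um)
})

test_that("invalid field specs are rejected", {
  expect_error(field_spec(syt1_pos_fraction = 1.2), "syt1_pos_fraction")
  expect_error(field_spec(syt1_pos_mean = 10, syt1_neg_mean = 30),
               "must exceed")
  expect_error(field_spec(width_px = 64, height_px = 64,
                          neurite_total_length_um = 1e6), "50%")
  expect_error(trace_spec(f_dtt = 100, f_ald = 200), "f_dtt > f_ald")
  expect_error(mito_spacing_spec(n_puncta = 1), "at least 2")
})
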