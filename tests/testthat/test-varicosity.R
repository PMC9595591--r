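test_that("the morphological gate is exact at its boundaries", {
  expect_true(varicosity_gate(0.2, 1))
  expect_true(varicosity_gate(1.0, 1))
  expect_false(varicosity_gate(0.199, 1))
  expect_false(varicosity_gate(1.001, 1))
  expect_true(varicosity_gate(0.5, 0.3))
  expect_false(varicosity_gate(0.5, 0.299))
  expect_true(varicosity_gate(0.5, 5))
  expect_false(varicosity_gate(0.5, 5.001))
  # strict literal length range
  expect_true(varicosity_gate(0.5, 0.5, strict_length_gate = TRUE))
  expect_false(varicosity_gate(0.5, 0.6, strict_length_gate = TRUE))
  # pure function of geometry: order never matters
  w <- runif(50, 0.1, 1.2); l <- runif(50, 0.2, 6)
  p <- sample(50)
  expect_equal(varicosity_gate(w, l)[p], varicosity_gate(w[p], l[p]))
})

test_that("planted enlargements on a straight neurite are recovered", {
  pos <- seq(10, 100, by = 10)
  st <- generate_neurite_strip(pos, widths_um = 0.6, lengths_um = 1.2,
                               seed = 5)
  sk <- skeletonize(segment_neurites(st$field), 0.3)
  v <- detect_varicosities(st$field, sk)
  d <- outer(v$x_um, pos, function(a, b) abs(a - b))
  matched <- sum(apply(d, 2, min) < 1)
  expect_gte(matched / length(pos), 0.9)          # recall
  expect_gte(matched / nrow(v), 0.9)              # precision
  expect_true(all(v$passes_gate[apply(d, 1, min) < 1]))
})

test_that("an oversize enlargement is returned but fails the width gate", {
  st <- generate_neurite_strip(c(30, 60, 90), widths_um = c(0.6, 1.5, 0.6),
                               seed = 6)
  sk <- skeletonize(segment_neurites(st$field), 0.3)
  v <- detect_varicosities(st$field, sk)
  big <- v[abs(v$x_um - 60) < 1.5, ]
  expect_equal(nrow(big), 1)
  expect_gt(big$width_um, 1)
  expect_false(big$passes_gate)
})

test_that("a uniform-width neurite yields no candidates", {
  st <- generate_neurite_strip(numeric(0), seed = 7)
  sk <- skeletonize(segment_neurites(st$field), 0.3)
  v <- detect_varicosities(st$field, sk)
  expect_equal(nrow(v), 0)
})

test_that("the Syt-1 cutoff follows its excluded-population convention", {
  mk <- function(x) data.frame(mean_syt1_intensity = x)
  expect_equal(syt1_cutoff(mk(rep(10, 8)))$cutoff, 10)
  grid <- syt1_cutoff(mk(1:100), method = "p95")$cutoff
  expect_lt(abs(grid - 95), 1)
  # the default envelope ignores a contaminated top minority
  set.seed(123)
  contaminated <- c(rnorm(60, 120, 12), rnorm(4, 230, 10))
  expect_lt(syt1_cutoff(mk(contaminated))$cutoff, 200)
  # fall-back with too few excluded candidates
  fb <- syt1_cutoff(mk(c(5, 6)), background = c(100, 5))
  expect_true(fb$fallback)
  expect_equal(fb$cutoff, 110)
  expect_error(syt1_cutoff(mk(numeric(0))), "undetermined")
  # mean + 2 SD alternative
  m2 <- syt1_cutoff(mk(c(1:10)), method = "mean_2sd")
  expect_equal(m2$cutoff, mean(1:10) + 2 * sd(1:10))
})

test_that("cutoffs from the negative component stay below the positive mean", {
  set.seed(31)
  ok <- vapply(1:200, function(i) {
    excl <- data.frame(mean_syt1_intensity = rnorm(30, 30, 12))
    syt1_cutoff(excl)$cutoff < 200
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("Syt-1 classification fraction behaves and is monotone in cutoff", {
  v <- data.frame(mean_syt1_intensity = c(5, 15), passes_gate = TRUE)
  expect_equal(classify_syt1(v, 10)$syt1_positive_fraction, 0.5)
  expect_equal(classify_syt1(v, 100)$syt1_positive_fraction, 0)
  v2 <- data.frame(mean_syt1_intensity = runif(200, 0, 100),
                   passes_gate = rep(c(TRUE, FALSE), 100))
  fr <- vapply(c(10, 30, 50, 70, 90), function(co)
    classify_syt1(v2, co)$syt1_positive_fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
  # no passing varicosities: undefined, flagged not crashed
  v3 <- data.frame(mean_syt1_intensity = 5, passes_gate = FALSE)
  expect_true(is.na(classify_syt1(v3, 10)$syt1_positive_fraction))
})

test_that("nearest-neighbor distances match the brute-force oracle", {
  expect_equal(nn_distances(cbind(c(0, 3, 7), 0)), c(3, 3, 4))
  expect_equal(nn_distances(cbind(c(0, 2.5), 0)), c(2.5, 2.5))
  expect_length(nn_distances(cbind(1, 1)), 0)
  set.seed(8)
  pts <- cbind(runif(100, 0, 50), runif(100, 0, 50))
  brute <- vapply(seq_len(nrow(pts)), function(i) {
    min(sqrt((pts[-i, 1] - pts[i, 1])^2 + (pts[-i, 2] - pts[i, 2])^2))
  }, numeric(1))
  expect_equal(unname(nn_distances(pts)), brute)
  # invariant under relabeling
  p <- sample(100)
  expect_equal(sort(unname(nn_distances(pts[p, ]))), sort(brute))
})

test_that("density per axon length follows its formula", {
  v <- data.frame(passes_gate = rep(TRUE, 30))
  expect_equal(density_per_length(v, 1000), 30)
  expect_equal(density_per_length(data.frame(passes_gate = logical(0)), 500), 0)
  expect_warning(d0 <- density_per_length(v, 0), "undefined")
  expect_true(is.na(d0))
})

test_that("varicosity density tracks the planted spacing on dense axons", {
  # spacing mean 3 um -> expected 1000/3 = 333 varicosities per mm
  dens <- vapply(1:2, function(s) {
    fg <- generate_field(field_spec(seed = 200 + s, varicosity_spacing_um = 3,
                                    oversize_fraction = 0))
    mask <- segment_somata(fg$field)
    sk <- skeletonize(segment_neurites(fg$field, mask),
                      fg$field$pixel_size_um)
    v <- detect_varicosities(fg$field, sk)
    density_per_length(v, sk$total_length_um)
  }, numeric(1))
  expect_lt(abs(mean(dens) - 1000 / 3) / (1000 / 3), 0.15)
})
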