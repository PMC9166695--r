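make_block <- function(series_fun, nt = 60, conf = NULL, drop = 10L) {
  dat <- array(0, c(2, 1, 1, nt))
  dat[1, 1, 1, ] <- series_fun(seq_len(nt))
  dat[2, 1, 1, ] <- series_fun(seq_len(nt))
  voxel_block(dat, repetition_time = 2, confounds = conf, drop_initial = drop)
}

test_that("conditioning removes constants, trends and confound projections", {
  cst <- condition_timeseries(make_block(function(i) rep(3.7, length(i))))
  expect_equal(max(abs(cst$data)), 0)
  ramp <- condition_timeseries(make_block(function(i) 2 * i + 1))
  expect_equal(max(abs(ramp$data)), 0, tolerance = 1e-10)
  conf <- matrix(sin(seq_len(60)), 60, 1)
  eq <- condition_timeseries(make_block(function(i) sin(i), conf = conf))
  expect_equal(max(abs(eq$data)), 0, tolerance = 1e-10)
  # initial volumes are dropped and confounds trimmed to match
  expect_equal(dim(eq$data)[4], 50)
  expect_equal(nrow(eq$confounds), 50)
})

test_that("band-pass upper edge must stay below Nyquist", {
  b <- make_block(function(i) rnorm(length(i)))
  expect_error(condition_timeseries(b, band = c(0.01, 0.25), bandpass = TRUE),
               "Nyquist")
})

test_that("ideal band-pass confines fALFF to the band", {
  set.seed(1)
  dat <- array(rnorm(2 * 200), c(2, 1, 1, 200))
  vb <- voxel_block(dat, 2, drop_initial = 0L)
  filt <- condition_timeseries(vb, band = c(0.01, 0.08), bandpass = TRUE)
  expect_gt(falff(filt$data[1, 1, 1, ], 2), 0.99)
})

test_that("fALFF analytic limits hold for pure sinusoids", {
  # length chosen so both tones sit exactly on a frequency bin (no leakage)
  tt <- (0:399) * 2
  expect_equal(falff(sin(2 * pi * 0.04 * tt), 2), 1, tolerance = 1e-6)
  expect_lte(falff(sin(2 * pi * 0.15 * tt), 2), 0.01)
  expect_equal(falff(numeric(440), 2), 0)
})

test_that("fALFF is invariant to positive rescaling of the series", {
  set.seed(2)
  x <- rnorm(128)
  expect_equal(falff(x, 2), falff(13.5 * x, 2))
})

test_that("fALFF rejects short series and empty bands", {
  expect_error(falff(rnorm(10), 2), "short")
  expect_error(falff(rnorm(64), 2, band = c(0.2499, 0.2499)), "bins")
})

test_that("ReHo equals 1 for identical series and matches rank oracles", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_identical(reho(rbind(x, x, x)), 1)
  # strictly decreasing transform of a series: perfect discordance for K=2
  m <- rbind(c(1, 3, 2, 4), c(8, 4, 6, 2))  # second = decreasing transform
  expect_equal(reho(m), oracle_W_enumerate(m))
  expect_equal(reho(m), oracle_W_spearman(m))
  expect_equal(reho(m), 0)
  # random small cases against both independent oracles, with and w/o ties
  set.seed(3)
  for (i in 1:20) {
    mm <- matrix(rnorm(5 * 7), 5, 7)
    expect_equal(reho(mm), oracle_W_enumerate(mm), tolerance = 1e-12)
    expect_equal(reho(mm), oracle_W_spearman(mm), tolerance = 1e-12)
    tied <- matrix(sample(1:4, 4 * 6, replace = TRUE), 4, 6)
    if (any(apply(tied, 1, sd) == 0)) next
    expect_equal(reho(tied), oracle_W_enumerate(tied), tolerance = 1e-12)
  }
})

test_that("ReHo is invariant under strictly monotone transforms", {
  set.seed(4)
  m <- matrix(rnorm(4 * 30), 4, 30)
  m2 <- m
  m2[1, ] <- exp(m[1, ])
  m2[2, ] <- m[2, ]^3
  expect_equal(reho(m), reho(m2))
})

test_that("ReHo handles constant-series degeneracies", {
  expect_warning(w <- reho(matrix(1, 3, 5)), "constant")
  expect_identical(w, 1)
  # one constant series among varying ones: tie correction applies, W finite
  m <- rbind(rep(2, 6), c(1, 2, 3, 4, 5, 6))
  expect_true(is.finite(reho(m)) && reho(m) >= 0 && reho(m) <= 1)
})

test_that("reho_map computes neighborhood concordance per voxel", {
  set.seed(5)
  dat <- array(rnorm(27 * 40), c(3, 3, 3, 40))
  vb <- voxel_block(dat, 2, drop_initial = 0L)
  rm_ <- reho_map(vb)
  center <- reho(matrix(dat, 27, 40))
  expect_equal(rm_[2, 2, 2], center)
  expect_true(all(rm_ >= 0 & rm_ <= 1))
})

test_that("regional_summary averages voxels by label", {
  lab <- array(0L, c(2, 2, 2))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L; lab[1, 2, 1] <- 2L
  vm <- array(0, c(2, 2, 2))
  vm[1, 1, 1] <- 1; vm[2, 1, 1] <- 3; vm[1, 2, 1] <- 7
  out <- regional_summary(vm, lab)
  expect_equal(unname(out[c("1", "2")]), c(2, 7))
  # constant map: every region equals the constant
  expect_true(all(regional_summary(array(4.2, dim(lab)), lab) == 4.2))
  expect_error(regional_summary(vm, array(0L, c(2, 2, 2))), "nonzero")
  expect_error(regional_summary(vm, array(1L, c(3, 2, 2))), "shapes")
  # region table: absent region reported NA with warning, stray label errors
  rt <- data.frame(label = c(1, 2, 9), region = c("a", "b", "ghost"))
  expect_warning(o2 <- regional_summary(vm, lab, rt), "zero voxels")
  expect_true(is.na(o2["ghost"]))
  expect_error(regional_summary(vm, lab, rt[1, , drop = FALSE]), "missing")
})

test_that("regional mean commutes with affine transforms", {
  set.seed(6)
  lab <- array(sample(0:3, 27, replace = TRUE), c(3, 3, 3))
  vm <- array(rnorm(27), c(3, 3, 3))
  expect_equal(regional_summary(2 * vm + 1, lab),
               2 * regional_summary(vm, lab) + 1)
})

test_that("flip_sides relabels left-treated and swaps right-treated", {
  ft <- toy_feature_table(n = 2)
  all_left <- flip_sides(ft, c("left", "left"))
  expect_equal(as.matrix(all_left), as.matrix(ft), ignore_attr = TRUE)
  expect_setequal(unique(annotations(all_left)$side), c("TS", "US", "mid"))
  mixed <- flip_sides(ft, c("left", "right"))
  ann <- annotations(ft)
  l <- which(ann$modality == "fALFF" & ann$region == "ctx_01" & ann$side == "L")
  r <- which(ann$modality == "fALFF" & ann$region == "ctx_01" & ann$side == "R")
  expect_equal(as.matrix(mixed)[2, l], as.matrix(ft)[2, r])
  expect_equal(as.matrix(mixed)[2, r], as.matrix(ft)[2, l])
  expect_equal(as.matrix(mixed)[1, l], as.matrix(ft)[1, l])
  # midline columns never move
  m <- which(ann$side == "mid")
  expect_equal(as.matrix(mixed)[, m], as.matrix(ft)[, m], ignore_attr = TRUE)
  # per-subject multiset of values is preserved (a column permutation)
  expect_equal(unname(sort(as.matrix(mixed)[2, ])),
               unname(sort(as.matrix(ft)[2, ])))
})

test_that("flipping is an involution for right-treated subjects", {
  ft <- toy_feature_table(n = 2)
  once <- flip_sides(ft, c("right", "right"))
  ann <- annotations(once)
  ann$side <- c(TS = "L", US = "R", mid = "mid")[ann$side]
  relabeled <- feature_table(as.matrix(once), ann)
  twice <- flip_sides(relabeled, c("right", "right"))
  expect_equal(as.matrix(twice), as.matrix(ft), ignore_attr = TRUE)
})

test_that("flip_sides validates homologues and side labels", {
  ann <- data.frame(modality = "fALFF", region = "ctx_01", side = "L")
  lonely <- feature_table(matrix(1, 1, 1), ann)
  expect_error(flip_sides(lonely, "right"), "ctx_01")
  ft <- toy_feature_table(n = 2)
  expect_error(flip_sides(flip_sides(ft, c("left", "left")),
                          c("left", "left")), "flipped")
})

test_that("compute_changes subtracts aligned tables and enforces contracts", {
  ft <- toy_feature_table(n = 3)
  expect_equal(max(abs(as.matrix(compute_changes(ft, ft)))), 0)
  shifted <- feature_table(as.matrix(ft) + 0.3, annotations(ft))
  d <- compute_changes(ft, shifted)
  expect_equal(as.matrix(d), matrix(0.3, 3, ncol(ft)), ignore_attr = TRUE)
  # anti-symmetry
  expect_equal(as.matrix(compute_changes(shifted, ft)),
               -as.matrix(compute_changes(ft, shifted)))
  # subject mismatch
  sub <- feature_table(as.matrix(ft)[1:2, ], annotations(ft))
  expect_error(compute_changes(ft, sub), "subject")
  # column mismatch names the offending annotation
  ann2 <- annotations(ft); ann2$region[1] <- "ctx_99"
  expect_error(compute_changes(ft, feature_table(as.matrix(ft), ann2)),
               "ctx_99")
})
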