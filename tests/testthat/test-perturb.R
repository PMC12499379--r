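test_that("silencing zeroes exactly the target region", {
  tr <- track("c", 0, 1000, rep(2, 100))
  s <- silence_region(tr, 40000, 41000)
  expect_equal(s$values[41], 0)
  expect_equal(sum(s$values == 0), 1)
  # silencing an already-zero region changes nothing
  expect_equal(silence_region(s, 40000, 41000)$values, s$values)
  # full-span silencing empties the track
  expect_true(all(silence_region(tr, 0, 1e5)$values == 0))
})

test_that("enhancer activation follows max and fold semantics", {
  tr <- track("c", 0, 1000, rep(10, 50))
  donor_low <- track("c", 0, 1000, rep(5, 50))
  donor_high <- track("c", 0, 1000, rep(20, 50))
  reg <- data.frame(start = 10000, end = 20000)
  expect_equal(activate_enhancers(tr, reg, "replace_if_greater",
                                  donor = donor_low)$values, tr$values)
  up <- activate_enhancers(tr, reg, "replace_if_greater",
                           donor = donor_high)
  expect_equal(up$values[11:20], rep(20, 10))
  expect_equal(up$values[21], 10)
  # replace-if-greater is idempotent
  expect_equal(activate_enhancers(up, reg, "replace_if_greater",
                                  donor = donor_high)$values, up$values)
  expect_equal(activate_enhancers(tr, reg, "fold", fold = 1)$values,
               tr$values)
  f <- activate_enhancers(tr, reg, "fold", fold = 1.1)
  expect_equal(f$values[11:20], rep(11, 10))
  expect_equal(f$values[1:10], rep(10, 10))
  expect_error(activate_enhancers(tr, reg, "fold", fold = 0), "positive")
})

test_that("a CTCF peak is Gaussian, max-combined and 79 bp wide", {
  tr <- track("c", 0, 1, rep(0, 300))
  # motif of length 19 at [100, 119): support [70, 149), width 79
  p <- add_ctcf_peak(tr, 100, 119, peak_value = 1000, extension = 30)
  touched <- which(p$values > 1e-6)
  expect_equal(min(touched), 71)   # 1-based step over [70, 71)
  expect_equal(max(touched), 149)
  expect_equal(max(touched) - min(touched) + 1, 79)
  apex <- which.max(p$values)
  expect_equal(p$values[apex], 1000, tolerance = 1e-3)
  expect_equal(tr$start + (apex - 0.5) * tr$step, 109.5)
  # monotone decay from the apex on each side
  expect_true(all(diff(p$values[71:apex]) >= 0))
  expect_true(all(diff(p$values[apex:149]) <= 0))
  # original signal wins where it is larger
  tall <- track("c", 0, 1, rep(2000, 300))
  expect_equal(add_ctcf_peak(tall, 100, 119)$values, tall$values)
})

test_that("segment permutation preserves content and is seeded", {
  set.seed(42)
  seq0 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  p1 <- permute_sequence(seq0, 50, 150, segment = 16, seed = 7)
  p2 <- permute_sequence(seq0, 50, 150, segment = 16, seed = 7)
  expect_identical(p1, p2)
  expect_equal(nchar(p1), nchar(seq0))
  count_bases <- function(s) table(strsplit(s, "")[[1]])
  expect_equal(count_bases(p1), count_bases(seq0))
  # outside the region untouched
  expect_identical(substr(p1, 1, 50), substr(seq0, 1, 50))
  expect_identical(substr(p1, 151, 200), substr(seq0, 151, 200))
  # a 32-bp region has exactly two orderings
  s32 <- substr(seq0, 1, 32)
  seg1 <- substr(s32, 1, 16); seg2 <- substr(s32, 17, 32)
  outs <- unique(vapply(1:20, function(sd) {
    permute_sequence(s32, 0, 32, seed = sd)
  }, character(1)))
  expect_true(all(outs %in% c(paste0(seg1, seg2), paste0(seg2, seg1))))
  expect_length(outs, 2)
})

test_that("global scaling multiplies every value", {
  tr <- track("c", 0, 1000, c(10, 0, 3))
  expect_equal(global_scale(tr, 1)$values, tr$values)
  expect_equal(global_scale(global_scale(tr, 2), 0.5)$values, tr$values)
  expect_equal(global_scale(tr, 1.1)$values[1], 11)
  expect_error(global_scale(tr, 0), "positive")
})

test_that("the surrogate is deterministic, local, and zero on zero input", {
  zero <- list(atac = track("c", 0, 1000, rep(0, 128)),
               ctcf = track("c", 0, 1000, rep(0, 128)))
  lf0 <- surrogate_predict(zero, c(0, 1.28e5), 2000)
  expect_true(all(lf0$values == 0))
  # bit-identical outputs for identical inputs
  atac <- rep(0.5, 128); atac[c(30, 60)] <- 6
  ctcf <- rep(0, 128); ctcf[c(30, 60)] <- 2.5; ctcf[90] <- 6
  tk <- list(atac = track("c", 0, 1000, atac),
             ctcf = track("c", 0, 1000, ctcf))
  a <- surrogate_predict(tk, c(0, 1.28e5), 2000)
  b <- surrogate_predict(tk, c(0, 1.28e5), 2000)
  expect_identical(a$values, b$values)
  # perturbation outside the window has exactly zero impact
  tk2 <- tk
  tk2$atac <- silence_region(tk2$atac, 100000, 101000)
  inwin <- surrogate_predict(tk2, c(0, 6.4e4), 2000)
  expect_equal(impact_score(surrogate_predict(tk, c(0, 6.4e4), 2000),
                            inwin), 0)
  # silencing an anchor inside the window has positive impact
  tk3 <- tk
  tk3$atac <- silence_region(tk3$atac, 29000, 30000)
  expect_gt(impact_score(a, surrogate_predict(tk3, c(0, 1.28e5), 2000)),
            0)
  expect_error(surrogate_predict(tk, c(0, 1.28e5), 3000), "multiple")
})

test_that("a lone CTCF boundary maximizes insulation at the window center", {
  ctcf <- rep(0, 2000); ctcf[1000] <- 6
  tk <- list(atac = track("c", 0, 1000, rep(0.5, 2000)),
             ctcf = track("c", 0, 1000, ctcf))
  lf <- surrogate_predict(tk, c(0, 2e6), 25000)
  cm <- sample_counts(lf, 1, 100, noise = FALSE)
  prof <- insulation_profile(cm, window_bins = 10)
  expect_equal(which.max(prof$insul), 40)
})

test_that("impact score is a mean absolute difference", {
  v <- matrix(0.3, 10, 10)
  a <- log_fold_matrix(v, 1000)
  expect_equal(impact_score(a, a), 0)
  w <- v; w[3, 7] <- w[7, 3] <- 0.3 + 1
  b <- log_fold_matrix(w, 1000)
  expect_equal(impact_score(a, b), 2 / 100)
  expect_equal(impact_score(b, a), impact_score(a, b))
  expect_error(impact_score(a, log_fold_matrix(matrix(0, 5, 5), 1000)),
               "shape")
})

test_that("screening scores fragments and takes the top decile", {
  atac <- rep(0.5, 50); ctcf <- rep(0, 50)
  atac[c(15, 35)] <- 6; ctcf[c(15, 35)] <- 2.5
  tk <- list(atac = track("c", 0, 1000, atac),
             ctcf = track("c", 0, 1000, ctcf))
  sr <- screen_fragments(tk, c(0, 5e4), scales = 4.8e4,
                         resolutions = 1000)
  expect_equal(nrow(sr$fragments), 50)
  expect_equal(sum(sr$his[, 1]), 5)
  expect_true(all(sr$impact >= 0))
  # anchor fragments outrank peak-free fragments
  expect_true(all(rank(-sr$impact[, 1])[c(15, 35)] <= 5))
  # all-zero accessibility: all impacts zero, HIS by coordinate order
  zero <- list(atac = track("c", 0, 1000, rep(0, 50)),
               ctcf = track("c", 0, 1000, ctcf))
  sr0 <- screen_fragments(zero, c(0, 5e4), scales = 4.8e4,
                          resolutions = 1000)
  expect_true(all(sr0$impact == 0))
  expect_equal(which(sr0$his[, 1]), 1:5)
})

test_that("screen categories cover every fragment and sum to one", {
  atac <- rep(0.5, 30); ctcf <- rep(0, 30)
  tk <- list(atac = track("c", 0, 1000, atac),
             ctcf = track("c", 0, 1000, ctcf))
  ann <- list(genes = data.frame(chrom = "c", start = 5000, end = 12000,
                                 strand = "+"),
              enhancers = data.frame(chrom = "c", start = 20000,
                                     end = 22000))
  sr <- screen_fragments(tk, c(0, 3e4), scales = 1.6e4,
                         resolutions = 1000, annotations = ann)
  frac <- table(sr$fragments$category) / nrow(sr$fragments)
  expect_equal(sum(frac), 1)
  expect_false(anyNA(sr$fragments$category))
})
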