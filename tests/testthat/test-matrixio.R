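test_that("triplet input is mirrored into a symmetric matrix", {
  bins <- bin_table("chr1", 2, 10)
  f <- withr::local_tempfile()
  writeLines(c("0\t0\t4", "0\t1\t2"), f)
  m <- read_contacts(f, "triplet", bins = bins)
  expect_equal(m$values, matrix(c(4, 2, 2, 0), 2, 2))
})

test_that("triplet parse errors carry the line number", {
  bins <- bin_table("chr1", 2, 10)
  f <- withr::local_tempfile()
  writeLines(c("0\t0\t4", "0\tx"), f)
  expect_error(read_contacts(f, "triplet", bins = bins), "line 2")
  writeLines(c("0\t5\t4"), f)
  expect_error(read_contacts(f, "triplet", bins = bins), "out of range")
})

test_that("dense matrices round-trip and asymmetry is rejected", {
  v <- random_positive_matrix(5, 1)
  m <- contact_matrix(v, 1000)
  f <- withr::local_tempfile()
  write_contacts(m, f, "dense")
  m2 <- read_contacts(f, "dense", resolution = 1000)
  expect_equal(m2$values, m$values, tolerance = 1e-6)
  # triplet round-trip too
  write_contacts(m, f, "triplet")
  m3 <- read_contacts(f, "triplet", bins = m$bins)
  expect_equal(m3$values, m$values, tolerance = 1e-6)
  writeLines(c("1 2", "3 4"), f)
  expect_error(read_contacts(f, "dense"), "symmetric")
})

test_that("iterative correction equalizes marginals and recovers biases", {
  # uniform matrix is a fixed point, returned unchanged
  u <- contact_matrix(matrix(2, 4, 4), 10)
  b <- ice_balance(u)
  expect_equal(b$values, u$values)
  expect_true(b$balanced)
  # multiplicative row biases are recovered proportionally
  sc <- c(1, 2, 3, 4)
  m <- contact_matrix(outer(sc, sc), 10)
  bal <- ice_balance(m, tol = 1e-10)
  expect_lt(stats::sd(rowSums(bal$values)) / mean(rowSums(bal$values)),
            1e-8)
  expect_equal(bal$bias / bal$bias[1], sc, tolerance = 1e-6)
  expect_error(ice_balance(contact_matrix(matrix(0, 3, 3), 10)),
               "degenerate")
})

test_that("post-balance row-sum CV meets tolerance on random matrices", {
  for (seed in 1:100) {
    m <- contact_matrix(random_positive_matrix(15, seed), 10)
    bal <- ice_balance(m, tol = 1e-6)
    s <- rowSums(bal$values)
    expect_lt(stats::sd(s) / mean(s), 1e-6)
  }
})

test_that("low-coverage bins are masked without changing shape", {
  v <- random_positive_matrix(12, 3)
  v[2, 4:12] <- 0; v[4:12, 2] <- 0  # row 2 keeps 3 nonzero entries
  m <- contact_matrix(v, 10)
  f <- filter_low_coverage_bins(m, min_nonzero = 10)
  expect_false(f$mask[2])
  expect_equal(sum(!f$mask), 1)
  expect_equal(dim(f$values), dim(v))
  expect_true(all(is.na(f$values[2, ])))
  # dense all-positive matrix: nothing masked
  dense <- contact_matrix(random_positive_matrix(12, 4), 10)
  expect_true(all(filter_low_coverage_bins(dense)$mask))
  # a zero row is masked for any threshold >= 1
  v[5, ] <- 0; v[, 5] <- 0
  mz <- filter_low_coverage_bins(contact_matrix(v, 10), min_nonzero = 1)
  expect_false(mz$mask[5])
})

test_that("average pooling matches block means and composes", {
  m <- contact_matrix(matrix(c(1, 5, 5, 7), 2, 2), 10)
  expect_equal(pool(m, 2)$values, matrix(4.5, 1, 1))
  expect_equal(pool(m, 2)$resolution, 20)
  cst <- contact_matrix(matrix(3, 8, 8), 10)
  expect_true(all(pool(cst, 2)$values == 3))
  big <- contact_matrix(random_positive_matrix(16, 5), 10)
  expect_equal(pool(pool(big, 2), 2)$values, pool(big, 4)$values)
  # global mean conserved when the factor divides the size
  expect_equal(mean(pool(big, 4)$values), mean(big$values))
  expect_error(pool(big, 1), "factor")
  # trailing partial block averaged over its actual members
  odd <- contact_matrix(random_positive_matrix(5, 6), 10)
  p <- pool(odd, 2)
  expect_equal(p$values[3, 3], odd$values[5, 5])
  expect_equal(p$values[1, 3], mean(odd$values[1:2, 5]))
})

test_that("distance-decay expected averages valid pairs only", {
  n <- 10
  f <- function(d) 10 / (d + 1)
  v <- outer(1:n, 1:n, function(i, j) f(abs(i - j)))
  m <- contact_matrix(v, 10)
  expect_equal(expected_by_distance(m), f(0:(n - 1)))
  expect_true(all(expected_by_distance(
    contact_matrix(matrix(2, 6, 6), 10)) == 2))
  # masked bin excluded: brute-force enumeration oracle
  vm <- random_positive_matrix(8, 7)
  mm <- contact_matrix(vm, 10, mask = c(TRUE, TRUE, FALSE, rep(TRUE, 5)))
  got <- expected_by_distance(mm)
  for (d in 0:7) {
    vals <- c()
    for (i in 1:(8 - d)) {
      j <- i + d
      if (i != 3 && j != 3) vals <- c(vals, vm[i, j])
    }
    expect_equal(got[d + 1], mean(vals))
  }
})

test_that("log fold over expected has its closed forms and inverse", {
  n <- 12
  e <- 5 / (1 + 0:(n - 1))
  v <- outer(1:n, 1:n, function(i, j) e[abs(i - j) + 1])
  m <- contact_matrix(v, 10)
  lf <- log_fold_oe(m, pseudocount = 0)
  expect_true(all(abs(lf$values) < 1e-12))
  lf2 <- log_fold_oe(contact_matrix(2 * v, 10), expected = e)
  expect_equal(unique(as.vector(round(lf2$values, 12))), log(2))
  expect_error(log_fold_oe(m, pseudocount = -1), "pseudocount")
  # exact inverse at pseudocount 0
  vr <- random_positive_matrix(10, 8)
  mr <- contact_matrix(vr, 10)
  lfr <- log_fold_oe(mr)
  d <- abs(outer(1:10, 1:10, "-"))
  back <- exp(lfr$values) * matrix(lfr$expected[d + 1], 10, 10)
  expect_equal(back, vr, tolerance = 1e-12)
})

test_that("a checkerboard map is centered per diagonal in fold space", {
  cb <- make_checkerboard(n_bins = 60, block = 10, intra = 3, inter = 1)
  lf <- log_fold_oe(cb$m)
  v <- exp(lf$values)  # observed over expected
  for (d in c(1, 5, 15, 30)) {
    i <- seq_len(60 - d)
    expect_lt(abs(mean(v[cbind(i, i + d)]) - 1), 1e-12)
  }
})

test_that("matrix operations preserve symmetry", {
  for (seed in 1:5) {
    v <- random_positive_matrix(14, seed)
    m <- contact_matrix(v, 10)
    for (out in list(ice_balance(m)$values, pool(m, 3)$values,
                     log_fold_oe(m)$values)) {
      expect_equal(out, t(out))
    }
  }
})
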