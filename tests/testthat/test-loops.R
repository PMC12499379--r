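test_that("sub-loop rule follows the anchor inequalities", {
  l <- function(lo, up, chrom = "c1") list(chrom = chrom, lower = lo,
                                           upper = up)
  expect_true(is_subloop(l(20, 50), l(10, 100)))
  expect_false(is_subloop(l(10, 100), l(20, 50)))
  expect_false(is_subloop(l(10, 100), l(10, 100)))  # no self-nesting
  expect_true(is_subloop(l(10, 50), l(10, 100)))    # shared lower anchor
  expect_false(is_subloop(l(20, 50), l(10, 100, chrom = "c2")))
})

test_that("hierarchy identifies mains, parents and valencies", {
  h <- loop_hierarchy(loop_table("c", c(10, 20, 30), c(100, 50, 40)))
  expect_equal(which(h$is_main), 1)
  expect_equal(h$valency[1], 2)
  expect_equal(h$parent, c(NA, 1L, 2L))
  disj <- loop_hierarchy(loop_table("c", c(0, 20), c(10, 30)))
  expect_true(all(disj$is_main))
  expect_equal(disj$valency, c(0L, 0L))
  expect_warning(
    dup <- loop_hierarchy(loop_table("c", c(1, 1, 5), c(9, 9, 8))),
    "duplicate")
  expect_equal(nrow(dup$loops), 2)
})

test_that("hierarchy equals the brute-force oracle on random sets", {
  for (seed in 1:200) {
    lp <- random_loop_set(n = 4 + seed %% 20, seed = seed)
    lp <- lp[!duplicated(paste(lp$lower, lp$upper)), ]
    h <- loop_hierarchy(lp)
    o <- oracle_hierarchy(lp$lower, lp$upper)
    expect_equal(h$is_main, o$is_main)
    expect_equal(h$parent, o$parent)
    expect_equal(h$valency[h$is_main], o$valency[o$is_main])
  }
})

test_that("nesting is a strict partial order", {
  for (seed in 1:30) {
    lp <- random_loop_set(n = 12, seed = seed + 500)
    lp <- lp[!duplicated(paste(lp$lower, lp$upper)), ]
    n <- nrow(lp)
    rel <- matrix(FALSE, n, n)
    for (a in 1:n) for (b in 1:n) {
      rel[a, b] <- is_subloop(lp[a, ], lp[b, ])
    }
    expect_false(any(diag(rel)))                  # irreflexive
    expect_false(any(rel & t(rel)))               # antisymmetric
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      if (rel[a, b] && rel[b, cc]) expect_true(rel[a, cc])  # transitive
    }
  }
})

test_that("mains plus valencies account for every loop in laminar sets", {
  # nested chains are laminar: each loop lies in at most one main
  lp <- loop_table("c", c(0, 5, 10, 100, 110, 300), c(50, 45, 40, 200,
                                                      190, 310))
  h <- loop_hierarchy(lp)
  expect_equal(sum(1 + h$valency[h$is_main]), nrow(lp))
})

test_that("anchors are categorized with promoter precedence", {
  promoters <- data.frame(chrom = "c", start = c(0, 90000),
                          end = c(20000, 110000))
  enhancers <- data.frame(chrom = "c", start = c(0, 40000),
                          end = c(20000, 60000))
  lp <- loop_table("c", c(10000, 10000, 50000, 200000),
                   c(100000, 50000, 210000, 300000))
  got <- classify_loops(lp, promoters, enhancers)
  expect_equal(got$category, c("PP", "EP", "other", "other"))
  # anchor overlapping promoter and enhancer resolves to promoter
  expect_equal(got$category[1], "PP")
})

test_that("loop statistics follow their definitions", {
  h <- loop_hierarchy(loop_table("c", c(10000, 20000, 30000),
                                 c(90000, 80000, 70000)))
  s <- loop_stats(h, region_length = 3e6)
  expect_equal(s$count_per_mb, 1)
  expect_equal(s$n_main, 1)
  expect_equal(s$mean_main_size, 80000)
  expect_equal(s$mean_size_per_valency, 40000)
  empty <- loop_stats(loop_hierarchy(loop_table(character(0), numeric(0),
                                                numeric(0))), 1e6)
  expect_equal(empty$count_per_mb, 0)
  expect_true(is.na(empty$mean_main_size))
})

test_that("the enrichment caller finds planted bumps and nothing else", {
  n <- 100
  grid <- 1:n
  pts <- rbind(c(10, 40), c(20, 80), c(35, 60), c(50, 90), c(70, 95))
  v <- matrix(0, n, n)
  for (k in 1:5) {
    ga <- exp(-(grid - pts[k, 1])^2 / 8)
    gb <- exp(-(grid - pts[k, 2])^2 / 8)
    v <- v + 1.5 * (outer(ga, gb) + outer(gb, ga))
  }
  lf <- log_fold_matrix((v + t(v)) / 2, 10000)
  calls <- naive_loop_caller(lf)
  expect_equal(nrow(calls), 5)
  expect_setequal(paste(calls$bin_lower, calls$bin_upper),
                  paste(pts[, 1], pts[, 2]))
  expect_equal(nrow(naive_loop_caller(
    log_fold_matrix(matrix(0.2, 50, 50), 1e4))), 0)
  # lowering the threshold never increases the call count
  counts <- vapply(c(1e-2, 1e-4, 1e-8, 1e-16),
                   function(p) nrow(naive_loop_caller(lf, p)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("loops round-trip through BEDPE", {
  lp <- loop_table("chr5", c(10000, 50000), c(90000, 200000),
                   score = c(0.001, 0.2))
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(lp, f)
  back <- read_bedpe(f)
  expect_equal(back$lower, lp$lower)
  expect_equal(back$upper, lp$upper)
  expect_equal(back$chrom, lp$chrom)
})
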