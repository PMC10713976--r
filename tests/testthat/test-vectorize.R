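ctx_of <- function(rt, mz, sample_id = "A", fid = "f") {
  data.table::data.table(rt_corrected = rt, mz = mz,
                         sample_id = sample_id, feature_id = fid)
}

test_that("build_context windows by RT rank and replicates at edges", {
  ft <- quick_table(mz = rep(700.01, 5) + (0:4) * 1e-4,
                    rt = c(10, 20, 30, 40, 50))
  ft$features$rt_scaled <- ft$features$rt
  ft$features$rt_corrected <- ft$features$rt
  bins <- assign_bins(list(ft))
  bid <- bins$features$bin_id[1]
  mid <- build_context(bins, bid, "S1", 3L)
  expect_equal(mid$rt_corrected, c(10, 20, 30, 40, 50))
  first <- build_context(bins, bid, "S1", 1L)
  expect_equal(first$rt_corrected, c(10, 10, 10, 20, 30))
  expect_error(build_context(bins, bid, "S1", 6L), "out of range")

  lone <- quick_table(800.5, 10)
  lone$features$rt_corrected <- 10
  lone$features$rt_scaled <- 10
  bins1 <- assign_bins(list(lone))
  solo <- build_context(bins1, bins1$features$bin_id[1], "S1", 1L)
  expect_equal(solo$rt_corrected, rep(10, 5))
})

test_that("the pair vector reproduces the worked normalization example", {
  # target pair RT 10 vs 12 min, m/z 500.015 vs 500.000
  ctx_n <- ctx_of(rt = c(8, 9, 10, 11, 12), mz = rep(500.015, 5))
  ctx_m <- ctx_of(rt = c(10, 11, 12, 13, 14), mz = rep(500.000, 5), "B")
  v <- make_pair_vector(ctx_n, ctx_m)$values
  expect_length(v, 40L)
  expect_equal(unname(v[5]), (10 - 12) / 5)           # -0.4
  expect_equal(unname(v[6]), 0.015 / 0.03)            # 0.5
  expect_equal(unname(v[15]), 0.4)                    # negation
  expect_equal(unname(v[16]), -0.5)
  expect_equal(unname(v[25]), 10 / 80)                # Part 1 center RT
  expect_equal(unname(v[26]), 500.015 / 1500)
  expect_equal(unname(v[35]), 12 / 80)                # Part 4 center RT
  expect_equal(unname(v[36]), 500.000 / 1500)
})

test_that("identical contexts give zero difference parts and equal originals", {
  ctx <- ctx_of(rt = c(1, 2, 3, 4, 5), mz = 400 + (1:5) * 1e-3)
  v <- make_pair_vector(ctx, ctx)$values
  expect_equal(unname(v[1:20]), rep(0, 20))
  expect_equal(unname(v[21:30]), unname(v[31:40]))
})

test_that("difference parts are antisymmetric and swapping exchanges parts", {
  set.seed(41)
  for (i in 1:25) {
    ctx_a <- ctx_of(sort(runif(5, 0, 80)), runif(1, 300, 1500) + runif(5, 0, 0.01))
    ctx_b <- ctx_of(sort(runif(5, 0, 80)), runif(1, 300, 1500) + runif(5, 0, 0.01), "B")
    v_ab <- make_pair_vector(ctx_a, ctx_b)$values
    v_ba <- make_pair_vector(ctx_b, ctx_a)$values
    expect_equal(unname(v_ab[11:20]), unname(-v_ab[1:10]))
    expect_equal(unname(v_ba[1:10]), unname(v_ab[11:20]))   # Part2 <-> Part3
    expect_equal(unname(v_ba[21:30]), unname(v_ab[31:40]))  # Part1 <-> Part4
  }
})

test_that("m/z-difference entries of binned pairs are bounded by one", {
  base <- bench_base()
  co <- inject_rt_shift(base, 0, 0.5, seed = 43L)
  coarse <- coarse_align_cohort(list(co$original, co$shifted))
  bins <- assign_bins(coarse$tables)
  ps <- sample_training_pairs(bins, co$truth, n_pos = 300L, n_neg = 300L,
                              seed = 44L)
  mz_cols <- c(6L, 16L)
  expect_true(all(abs(ps$X[, mz_cols]) <= 1 + 1e-9))
})

test_that("training-pair sampling is deterministic and respects the m/z tolerance", {
  base <- bench_base()
  co <- inject_rt_shift(base, 0, 0.5, seed = 45L)
  coarse <- coarse_align_cohort(list(co$original, co$shifted))
  bins <- assign_bins(coarse$tables)
  truth <- make_training_truth(co)
  a <- sample_training_pairs(bins, truth, 100L, 100L, seed = 7L)
  b <- sample_training_pairs(bins, truth, 100L, 100L, seed = 7L)
  expect_identical(a$X, b$X)
  expect_identical(a$ids, b$ids)
  expect_equal(a$label, c(rep(1L, 100), rep(0L, 100)))

  # all negatives lie within the tolerance and none is a true link
  f <- bins$features
  neg <- a$ids[a$label == 0L]
  mz1 <- f[match(paste(neg$sample_1, neg$feature_1),
                 paste(f$sample_id, f$feature_id)), mz]
  mz2 <- f[match(paste(neg$sample_2, neg$feature_2),
                 paste(f$sample_id, f$feature_id)), mz]
  expect_true(all(abs(mz1 - mz2) <= 0.03))
  expect_equal(nrow(data.table::as.data.table(neg)[truth, on = names(truth),
                                                   nomatch = NULL]), 0L)

  # positives are the true links themselves
  pos <- a$ids[a$label == 1L]
  expect_equal(nrow(data.table::as.data.table(pos)[truth, on = names(truth),
                                                   nomatch = NULL]), 100L)
})

test_that("requesting more pairs than exist is a capacity error", {
  # widely spaced m/z: no negative candidates at all
  ft <- quick_table(mz = seq(300, 400, by = 10), rt = 1:11, sample_id = "A")
  co <- inject_rt_shift(ft, 0, 0, seed = 46L)
  coarse <- coarse_align_cohort(list(co$original, co$shifted))
  bins <- assign_bins(coarse$tables)
  expect_error(sample_training_pairs(bins, co$truth, 5L, 5L, seed = 1L),
               "capacity error.*11 / 0")
})

test_that("pair sets survive a CSV round trip", {
  ps <- structure(list(X = matrix(round(runif(80), 6), 2L, 40L,
                                  dimnames = list(NULL, sprintf("v%02d", 1:40))),
                       label = c(1L, 0L),
                       ids = data.table::data.table(
                         sample_1 = "A", feature_1 = c("f1", "f2"),
                         sample_2 = "B", feature_2 = c("g1", "g2"))),
                  class = "pair_set")
  path <- withr::local_tempfile(fileext = ".csv")
  write_pair_vectors(ps, path)
  back <- read_pair_vectors(path)
  expect_equal(back$X, ps$X)
  expect_equal(back$label, ps$label)
  expect_equal(as.data.frame(back$ids), as.data.frame(ps$ids))
})
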