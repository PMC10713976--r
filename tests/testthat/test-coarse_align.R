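test_that("RT scaling maps the observed maximum onto the target range", {
  ft <- quick_table(mz = c(400, 500, 600), rt = c(10, 20, 40))
  s <- scale_rt(ft, 80)
  expect_equal(s$features$rt_scaled, c(20, 40, 80))
  # identity when the range already matches
  ft80 <- quick_table(mz = c(400, 500), rt = c(40, 80))
  expect_equal(scale_rt(ft80, 80)$features$rt_scaled, c(40, 80))
  # order is preserved
  expect_false(is.unsorted(s$features$rt_scaled[order(s$features$rt)]))
})

test_that("scaling a run with all-zero RTs is a degenerate-input error", {
  ft <- quick_table(mz = c(400, 500), rt = c(0, 0))
  expect_error(scale_rt(ft, 80), "degenerate")
})

test_that("per-m/z reduction keeps the most intense feature with deterministic ties", {
  ft <- quick_table(mz = c(500.251, 500.252, 500.26),
                    rt = c(10, 12, 14), intensity = c(1e6, 2e6, 5e5))
  red <- reduce_by_mz(ft, 2L)
  # keys 500.25 (twice) and 500.26: max intensity wins within a key
  expect_equal(sort(red$features$intensity), c(5e5, 2e6))
  # intensity tie -> earliest RT
  ft2 <- quick_table(mz = c(600.001, 600.002, 600.003),
                     rt = c(12, 10, 11), intensity = c(2e6, 2e6, 1e6))
  red2 <- reduce_by_mz(ft2, 2L)
  expect_equal(red2$features$rt, 10)
})

test_that("piece shifts are zero for self-alignment and recover a constant", {
  set.seed(11)
  mz <- runif(300, 300, 1500)
  rt <- runif(300, 0.6, 79.5)
  anchor <- quick_table(mz, rt, sample_id = "A")
  anchor <- scale_rt(anchor, 80, rt_max = 80)
  self_shifts <- compute_piece_shifts(reduce_by_mz(anchor), reduce_by_mz(anchor))
  expect_true(all(self_shifts$mean_shift == 0))

  # same features displaced by -0.5 min on the common scale
  moved <- quick_table(mz, rt - 0.5, sample_id = "B")
  moved <- scale_rt(moved, 80, rt_max = 80)
  sh <- compute_piece_shifts(reduce_by_mz(moved), reduce_by_mz(anchor))
  nonempty <- sh[sh$n_pairs > 0, ]
  expect_gt(nrow(nonempty), 0)
  expect_equal(nonempty$mean_shift, rep(0.5, nrow(nonempty)), tolerance = 1e-9)
})

test_that("features without an anchor partner within tolerance are ignored", {
  anchor <- quick_table(mz = c(500.000, 800.000), rt = c(10, 20))
  anchor <- scale_rt(anchor, 80, rt_max = 80)
  sample <- quick_table(mz = c(500.005, 600.000), rt = c(10.5, 30),
                        sample_id = "B")
  sample <- scale_rt(sample, 80, rt_max = 80)
  sh <- compute_piece_shifts(reduce_by_mz(sample), reduce_by_mz(anchor))
  # only the 500.005 feature (within 0.01 Th of 500.000) forms a pair
  expect_equal(sum(sh$n_pairs), 1L)
  expect_equal(sh$mean_shift[sh$n_pairs > 0], -0.5)
})

test_that("m/z ties between anchor candidates break by nearest scaled RT", {
  # offsets of 1/256 Th are exactly representable, so both anchor
  # candidates are at identical m/z distance from the query
  anchor <- quick_table(mz = c(700 + 1 / 256, 700 - 1 / 256), rt = c(30, 10),
                        sample_id = "A")
  anchor <- scale_rt(anchor, 80, rt_max = 80)
  qry <- quick_table(mz = 700.000, rt = 29, sample_id = "B")
  qry <- scale_rt(qry, 80, rt_max = 80)
  sh <- compute_piece_shifts(qry, anchor)
  # the rt = 30 candidate is nearer in RT than the rt = 10 one
  expect_equal(sh$mean_shift[sh$n_pairs > 0], 1)
})

test_that("applying shifts adds the piece mean and leaves the anchor unchanged", {
  ft <- quick_table(mz = c(400, 500), rt = c(10.2, 50))
  ft <- scale_rt(ft, 80, rt_max = 80)
  shifts <- data.frame(piece_index = 0:79, mean_shift = 0, n_pairs = 0L)
  shifts$mean_shift[shifts$piece_index == 10] <- 0.5
  out <- apply_coarse_alignment(ft, shifts)
  expect_equal(out$features$rt_corrected, c(10.7, 50))
  anchor_out <- apply_coarse_alignment(ft, NULL)
  expect_equal(anchor_out$features$rt_corrected, anchor_out$features$rt_scaled)
})

test_that("a constant shift on the common RT axis is removed exactly", {
  set.seed(12)
  mz <- runif(1000, 300, 1500)
  rt <- runif(1000, 1, 79)
  anchor <- scale_rt(quick_table(mz, rt, sample_id = "A"), 80, rt_max = 80)
  moved <- scale_rt(quick_table(mz, rt + 0.5, sample_id = "B"), 80, rt_max = 80)
  sh <- compute_piece_shifts(reduce_by_mz(moved), reduce_by_mz(anchor))
  corrected <- apply_coarse_alignment(moved, sh)
  expect_lt(max(abs(corrected$features$rt_corrected -
                      anchor$features$rt_scaled)), 1e-9)
})

test_that("piecewise correction preserves RT order within each piece", {
  set.seed(13)
  ft <- quick_table(runif(500, 300, 1500), runif(500, 0, 79.9))
  ft <- scale_rt(ft, 80)
  shifts <- data.frame(piece_index = 0:79,
                       mean_shift = rnorm(80, 0, 0.3), n_pairs = 1L)
  out <- apply_coarse_alignment(ft, shifts)
  piece <- floor(out$features$rt_scaled)
  for (p in unique(piece)) {
    sel <- piece == p
    expect_false(is.unsorted(out$features$rt_corrected[sel][
      order(out$features$rt_scaled[sel])]))
  }
})

test_that("cohort coarse alignment fills rt_corrected for every sample", {
  base <- bench_base()
  co <- inject_rt_shift(base, 0, 0.3, seed = 21L)
  out <- coarse_align_cohort(list(co$original, co$shifted))
  for (tab in out$tables) expect_false(anyNA(tab$features$rt_corrected))
  expect_null(out$shifts[[1]])
  expect_s3_class(out$shifts[[2]], "data.frame")
})
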