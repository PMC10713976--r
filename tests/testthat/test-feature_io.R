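test_that("generic CSV rows parse into canonical features", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,intensity,charge", "500.2500,10.50,1.0e6,2"), path)
  ft <- read_feature_table(path, "generic_csv", sample_id = "A")
  expect_s3_class(ft, "feature_table")
  f <- ft$features
  expect_equal(f$mz, 500.25)
  expect_equal(f$rt, 10.5)
  expect_equal(f$intensity, 1e6)
  expect_equal(f$charge, 2L)
  expect_equal(ft$rt_max_observed, 10.5)
})

test_that("tab-separated generic input is sniffed from the header", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("mz\trt\tintensity", "400.1\t5.0\t2e5", "401.2\t6.0\t3e5"), path)
  ft <- read_feature_table(path, "generic_csv", sample_id = "A")
  expect_equal(n_features(ft), 2L)
  expect_equal(ft$features$mz, c(400.1, 401.2))
})

test_that("rows violating invariants are dropped with a logged count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,intensity", "500.1,10,1e6", "-1,11,1e6", "600.2,12,2e6"),
             path)
  expect_message(ft <- read_feature_table(path, "generic_csv", "A"),
                 "dropped 1 of 3")
  expect_equal(n_features(ft), 2L)
  expect_equal(ft$n_dropped, 1L)
})

test_that("reader errors name the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt", "500,10"), path)
  expect_error(read_feature_table(path, "generic_csv", "A"), "intensity")
  expect_error(read_feature_table(path, "no_such_dialect", "A"),
               "unknown dialect")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,intensity", "-1,1,1"), bad)
  expect_error(suppressMessages(read_feature_table(bad, "generic_csv", "A")),
               "empty input")
})

test_that("featureXML RT seconds are converted to minutes", {
  path <- withr::local_tempfile(fileext = ".featureXML")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<featureMap xmlns="http://open-ms.sourceforge.net">',
    '<featureList count="2">',
    '<feature id="f_1"><position dim="0">630.0</position>',
    '<position dim="1">500.25</position>',
    '<intensity>1e6</intensity><charge>2</charge></feature>',
    '<feature id="f_2"><position dim="0">1200.0</position>',
    '<position dim="1">600.10</position>',
    '<intensity>5e5</intensity><charge>3</charge></feature>',
    '</featureList></featureMap>'), path)
  ft <- read_feature_table(path, "openms_featurexml", "X")
  expect_equal(ft$features$rt, c(10.5, 20))
  expect_equal(ft$features$mz, c(500.25, 600.10))
  expect_equal(ft$features$charge, c(2L, 3L))
})

test_that("MaxQuant and Dinosaur dialects map their native headers", {
  mq <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("m/z\tRetention time\tIntensity\tCharge",
               "612.33\t45.2\t8.1e7\t2"), mq)
  ft <- read_feature_table(mq, "maxquant_allpeptides", "MQ")
  expect_equal(ft$features$mz, 612.33)
  expect_equal(ft$features$rt, 45.2)

  dino <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\trtStart\trtApex\trtEnd\tintensityApex\tcharge",
               "712.88\t30.1\t30.5\t31.0\t4.2e6\t3"), dino)
  ft2 <- read_feature_table(dino, "dinosaur_tsv", "D")
  expect_equal(ft2$features$rt, 30.5)
  expect_equal(ft2$features$rt_start, 30.1)
  expect_equal(ft2$features$rt_end, 31.0)
})

test_that("reading the same file twice gives identical tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  writeLines(c("mz,rt,intensity",
               sprintf("%.4f,%.2f,%.0f", runif(50, 300, 1500),
                       runif(50, 0, 80), runif(50, 1e5, 1e9))), path)
  a <- read_feature_table(path, "generic_csv", "A")
  b <- read_feature_table(path, "generic_csv", "A")
  expect_identical(a$features, b$features)
})

make_toy_result <- function(groups) {
  samples <- unique(groups$sample_id)
  structure(list(groups = data.table::as.data.table(groups),
                 pairs = NULL, samples = samples, anchor = samples[1]),
            class = "alignment_result")
}

test_that("aligned output has one row per group and empty cells for absent samples", {
  g <- data.frame(group_id = c(1L, 1L, 2L),
                  sample_id = c("A", "B", "A"),
                  feature_id = c("fa1", "fb1", "fa2"),
                  mz = c(400.0, 400.001, 300.0),
                  rt = c(10, 10.1, 5),
                  intensity = c(1e6, 2e6, 3e6),
                  score = c(NA, 0.9, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_aligned_table(make_toy_result(g), path)
  out <- read.csv(path, colClasses = "character")
  expect_equal(nrow(out), 2L)
  # ascending median m/z: the 300.0 group comes first
  expect_equal(out$A_mz, c("300.0000", "400.0000"))
  expect_equal(out$B_feature_id, c("", "fb1"))
  expect_equal(out$B_mz[1], "")
})

test_that("write/read round trip preserves group membership exactly", {
  set.seed(3)
  n <- 30L
  g <- data.frame(group_id = rep(1:n, each = 2),
                  sample_id = rep(c("A", "B"), n),
                  feature_id = paste0("f", seq_len(2 * n)),
                  mz = rep(runif(n, 300, 1500), each = 2),
                  rt = rep(runif(n, 0, 80), each = 2),
                  intensity = 1e6, score = rep(c(NA, 0.8), n))
  path <- withr::local_tempfile(fileext = ".csv")
  write_aligned_table(make_toy_result(g), path)
  back <- read_aligned_table(path)
  # same partition of features into groups, regardless of group labels
  canon <- function(df) {
    sp <- split(paste(df$sample_id, df$feature_id), df$group_id)
    unname(sort(vapply(sp, function(x) paste(sort(x), collapse = ";"), "")))
  }
  expect_equal(canon(back), canon(g))
})

test_that("writing an empty result is an error", {
  empty <- make_toy_result(data.frame(group_id = integer(),
                                      sample_id = character(),
                                      feature_id = character(),
                                      mz = numeric(), rt = numeric(),
                                      intensity = numeric(), score = numeric()))
  expect_error(write_aligned_table(empty, tempfile()), "empty")
})
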