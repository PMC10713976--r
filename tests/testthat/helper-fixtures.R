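# Shared builders and cached expensive objects for the test suite.
# Everything is generated in code under fixed seeds; no binary fixtures.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# Default training pairs and desk classifier (shared across files; the
# model is trained once per test run).
training_pairs <- function() memo("pairs", simulate_training_pairs(seed = 42L))
desk_model <- function() memo("model",
  train_pair_model(training_pairs(), net_config(seed = 42L)))
undertrained_model <- function() memo("weak8",
  train_pair_model(training_pairs(), net_config(seed = 42L, epochs = 8L)))

# Small feature table built from explicit columns.
quick_table <- function(mz, rt, intensity = NULL, sample_id = "S1", ...) {
  n <- length(mz)
  feature_table(data.frame(mz = mz, rt = rt,
                           intensity = intensity %||% rep(1e6, n), ...),
                sample_id = sample_id)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Base run whose m/z values sit on a 0.1 Th grid: no two features are
# ever within one bin width, isolating RT-shift recovery from the
# near-isobaric discrimination problem.
separated_base <- function(n = 2000L, seed = 201L) {
  memo(sprintf("sep_%d_%d", n, seed), {
    set.seed(seed)
    feature_table(data.frame(mz = sample(seq(300, 1500, by = 0.1), n),
                             rt = runif(n, 0, 80),
                             intensity = 10^runif(n, 5, 9),
                             charge = 2L),
                  sample_id = "S1")
  })
}

# Default benchmark base: 2000 features, near-isobaric fraction 0.1.
bench_base <- function() memo("bench_base",
  generate_base_table(sim_spec(n_features = 2000L, seed = 101L)))

align_pr <- function(cohort, model, ...) {
  res <- align_cohort(list(cohort$original, cohort$shifted), model, ...)
  precision_recall(res$pairs[, c("feature_1", "feature_2")],
                   cohort$truth[, c("feature_1", "feature_2")])
}

# Pair vectors whose label depends only on the central m/z difference:
# RTs and neighbors are independent noise on both sides.
dmz_only_pairs <- function(n, seed) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n %/% 2)
  n <- length(y)
  d <- ifelse(y == 1L, 0, sample(c(-1, 1), n, TRUE) * runif(n, 0.003, 0.03))
  mzc <- runif(n, 300, 1500)
  X <- matrix(0, n, 40L)
  cfg <- vectorizer_config()
  for (i in seq_len(n)) {
    mz1 <- mzc[i] + c(runif(2, -0.01, 0.01), 0, runif(2, -0.01, 0.01))
    mz2 <- mzc[i] + d[i] + c(runif(2, -0.01, 0.01), 0, runif(2, -0.01, 0.01))
    rt1 <- sort(runif(5, 0, 80))
    rt2 <- sort(runif(5, 0, 80))
    X[i, ] <- rtalign:::.pair_values(matrix(rt1, 1), matrix(mz1, 1),
                                     matrix(rt2, 1), matrix(mz2, 1), cfg)
  }
  colnames(X) <- sprintf("v%02d", 1:40)
  list(X = X, label = y)
}

# Independent brute-force implementation of the per-sample-pair averaged
# precision/recall (plain loops over pair sets, no shared code).
brute_precision_recall <- function(aligned, truth) {
  stopifnot(length(aligned) == length(truth))
  precs <- numeric(0); recs <- numeric(0)
  for (k in seq_along(aligned)) {
    A <- unique(apply(as.data.frame(aligned[[k]]), 1L,
                      function(r) paste(r[1], r[2], sep = "|")))
    G <- unique(apply(as.data.frame(truth[[k]]), 1L,
                      function(r) paste(r[1], r[2], sep = "|")))
    if (length(A) == 0L) A <- character(0)
    inter <- 0L
    for (a in A) if (a %in% G) inter <- inter + 1L
    precs <- c(precs, if (length(A) == 0L) 0 else inter / length(A))
    recs <- c(recs, if (length(G) == 0L) 0 else inter / length(G))
  }
  list(precision = mean(precs), recall = mean(recs))
}

# Random small pair-set instances for the oracle-equivalence checks.
random_pr_instance <- function(seed) {
  set.seed(seed)
  N <- sample(1:5, 1L)
  mk <- function() {
    n <- sample(0:20, 1L)
    if (n == 0L) return(data.frame(a = character(0), b = character(0)))
    data.frame(a = paste0("x", sample(1:15, n, TRUE)),
               b = paste0("y", sample(1:15, n, TRUE)))
  }
  list(aligned = replicate(N, mk(), simplify = FALSE),
       truth = replicate(N, mk(), simplify = FALSE))
}
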