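# Pair-vector construction: every candidate feature-feature pair is
# encoded as 40 normalized values built from the two features and their
# two RT-neighbors on each side within the m/z window.

#' Vectorizer configuration
#'
#' The 40-value pair encoding divides RT/m/z *differences* by the first
#' base pair (5 min, 0.03 Th) and *original* RT/m/z values by the second
#' (80 min, 1500 Th), putting all entries on comparable scales.
#'
#' @param base_rt_diff divisor for RT differences, minutes (default 5).
#' @param base_mz_diff divisor for m/z differences, Th (default 0.03).
#' @param base_rt divisor for original RT values, minutes (default 80).
#' @param base_mz divisor for original m/z values, Th (default 1500).
#' @param n_context RT-neighbors taken on each side of the target
#'   feature; the encoding is defined for exactly 2.
#' @return an object of class `vectorizer_config`.
#' @export
vectorizer_config <- function(base_rt_diff = 5, base_mz_diff = 0.03,
                              base_rt = 80, base_mz = 1500, n_context = 2L) {
  for (nm in c("base_rt_diff", "base_mz_diff", "base_rt", "base_mz"))
    assert_number(get(nm), nm, 0, strict = TRUE)
  if (!identical(as.integer(n_context), 2L))
    stopf("the pair encoding is defined for n_context = 2")
  structure(list(base_rt_diff = base_rt_diff, base_mz_diff = base_mz_diff,
                 base_rt = base_rt, base_mz = base_mz, n_context = 2L),
            class = "vectorizer_config")
}

# Core encoding: rt1/mz1/rt2/mz2 are n x 5 matrices of the two contexts
# (columns = positions n-2 .. n+2, the target at column 3). Returns an
# n x 40 matrix laid out as Part2 (cols 1-10: differences sample1 -
# sample2), Part3 (11-20: negations), Part1 (21-30: sample1 originals),
# Part4 (31-40: sample2 originals); within each part the i-th context
# position occupies columns (2i-1, 2i) as (RT, m/z). The target pair's
# difference entries therefore sit at flat positions 5/6 and 15/16.
.pair_values <- function(rt1, mz1, rt2, mz2, cfg = vectorizer_config()) {
  n <- nrow(rt1)
  out <- matrix(NA_real_, n, 40L)
  for (i in 1:5) {
    d_rt <- (rt1[, i] - rt2[, i]) / cfg$base_rt_diff
    d_mz <- (mz1[, i] - mz2[, i]) / cfg$base_mz_diff
    out[, 2L * i - 1L] <- d_rt          # Part 2
    out[, 2L * i] <- d_mz
    out[, 10L + 2L * i - 1L] <- -d_rt   # Part 3
    out[, 10L + 2L * i] <- -d_mz
    out[, 20L + 2L * i - 1L] <- rt1[, i] / cfg$base_rt   # Part 1
    out[, 20L + 2L * i] <- mz1[, i] / cfg$base_mz
    out[, 30L + 2L * i - 1L] <- rt2[, i] / cfg$base_rt   # Part 4
    out[, 30L + 2L * i] <- mz2[, i] / cfg$base_mz
  }
  colnames(out) <- sprintf("v%02d", 1:40)
  out
}

.ctx_matrices <- function(ctx) {
  # ctx: 5-row data.frame/data.table with rt_corrected and mz
  if (nrow(ctx) != 5L) stopf("a context must contain exactly 5 features")
  rtv <- ctx$rt_corrected
  if (anyNA(rtv)) stopf("context features must carry rt_corrected")
  list(rt = matrix(rtv, 1L, 5L), mz = matrix(ctx$mz, 1L, 5L))
}

#' RT-neighbor context of a feature inside its m/z window
#'
#' Returns the five features at RT-rank positions `index - 2 ... index +
#' 2` of the given sample's list in the given window; missing neighbors
#' at the list edges are filled by replicating the terminal feature, so
#' all 40 vector entries stay on physical feature scales.
#'
#' @param bins an `mz_bin_set`.
#' @param bin_id window index.
#' @param sample_id sample whose list is indexed.
#' @param index 1-based RT-rank of the target feature in that list.
#' @return a 5-row `data.table` of features (target at row 3).
#' @export
build_context <- function(bins, bin_id, sample_id, index) {
  stopifnot(inherits(bins, "mz_bin_set"))
  sel_bin <- bin_id
  sel_sample <- sample_id
  rows <- bins$features[bin_id == sel_bin & sample_id == sel_sample]
  if (nrow(rows) == 0L) stopf("no features for sample '%s' in window %s",
                              sel_sample, format(sel_bin))
  if (index < 1L || index > nrow(rows))
    stopf("index %d out of range 1..%d", index, nrow(rows))
  rows[pmin(pmax(index + (-2:2), 1L), nrow(rows))]
}

#' Encode one candidate feature pair as a 40-value vector
#'
#' @param ctx_n 5-feature context of the target feature in sample 1
#'   (from [build_context()]).
#' @param ctx_m 5-feature context of the candidate in sample 2.
#' @param cfg a [vectorizer_config()].
#' @return an object of class `pair_vector`: list with `values` (named
#'   numeric of length 40), `ids`, and optional `label`.
#' @export
make_pair_vector <- function(ctx_n, ctx_m, cfg = vectorizer_config()) {
  a <- .ctx_matrices(ctx_n)
  b <- .ctx_matrices(ctx_m)
  vals <- .pair_values(a$rt, a$mz, b$rt, b$mz, cfg)[1L, ]
  if (!all(is.finite(vals))) stopf("pair vector contains non-finite values")
  structure(list(values = vals,
                 ids = c(sample_1 = ctx_n$sample_id[3L],
                         feature_1 = ctx_n$feature_id[3L],
                         sample_2 = ctx_m$sample_id[3L],
                         feature_2 = ctx_m$feature_id[3L]),
                 label = NULL),
            class = "pair_vector")
}

# Build the n x 40 matrix for candidate pairs given global row indices
# into the bin set's cached context matrices.
.pair_matrix <- function(bins, rows1, rows2, cfg = vectorizer_config()) {
  .pair_values(bins$ctx_rt[rows1, , drop = FALSE],
               bins$ctx_mz[rows1, , drop = FALSE],
               bins$ctx_rt[rows2, , drop = FALSE],
               bins$ctx_mz[rows2, , drop = FALSE], cfg)
}

#' Sample labeled training pairs from a ground-truth correspondence
#'
#' Positives are cross-sample feature pairs linked by the truth table
#' (the same analyte in both runs); negatives are cross-sample pairs not
#' linked by truth whose m/z values differ by at most `mz_tol` — the
#' hard negatives the classifier must learn to reject. Sampling is
#' without replacement under the given seed and fails with a capacity
#' error (reporting the available counts) when a side is short.
#'
#' @param bins an `mz_bin_set` over the coarse-aligned cohort.
#' @param truth `data.frame` with columns `sample_1`, `feature_1`,
#'   `sample_2`, `feature_2` linking same-analyte features.
#' @param n_pos,n_neg numbers of positive/negative pairs to draw.
#' @param mz_tol m/z tolerance for negative candidates, Th (default 0.03).
#' @param seed RNG seed.
#' @param cfg a [vectorizer_config()].
#' @return an object of class `pair_set`: list with `X` (n x 40 matrix),
#'   `label` (1 = positive, 0 = negative) and `ids` (a `data.table`).
#' @export
sample_training_pairs <- function(bins, truth, n_pos, n_neg, mz_tol = 0.03,
                                  seed = 1L, cfg = vectorizer_config()) {
  stopifnot(inherits(bins, "mz_bin_set"))
  truth <- as.data.table(truth)
  need <- c("sample_1", "feature_1", "sample_2", "feature_2")
  if (!all(need %in% names(truth)))
    stopf("truth must have columns %s", paste(need, collapse = ", "))

  feats <- bins$features
  lookup <- function(s, f) {
    idx <- feats[.(s, f), on = .(sample_id, feature_id), which = TRUE,
                 mult = "first"]
    idx
  }
  # positive pool: truth links present in the bin set
  pos_pool <- copy(truth)
  pos_pool[, row1 := lookup(sample_1, feature_1)]
  pos_pool[, row2 := lookup(sample_2, feature_2)]
  pos_pool <- pos_pool[!is.na(row1) & !is.na(row2)]

  # negative pool: close-m/z cross-sample pairs not linked by truth
  sample_pairs <- unique(truth[, .(sample_1, sample_2)])
  neg_pool <- rbindlist(lapply(seq_len(nrow(sample_pairs)), function(i) {
    s1 <- sample_pairs$sample_1[i]; s2 <- sample_pairs$sample_2[i]
    f1 <- feats[sample_id == s1, .(feature_1 = feature_id, mz1 = mz,
                                   row1 = .I)]
    f1[, row1 := which(feats$sample_id == s1)]
    f2 <- feats[sample_id == s2, .(feature_2 = feature_id, mz2 = mz)]
    f2[, row2 := which(feats$sample_id == s2)]
    setorder(f2, mz2)
    lo <- findInterval(f1$mz1 - mz_tol, f2$mz2, left.open = TRUE) + 1L
    hi <- findInterval(f1$mz1 + mz_tol, f2$mz2)
    n_each <- pmax(hi - lo + 1L, 0L)
    if (sum(n_each) == 0L) return(NULL)
    i1 <- rep.int(seq_len(nrow(f1)), n_each)
    i2 <- unlist(lapply(which(n_each > 0L), function(j) lo[j]:hi[j]))
    data.table(sample_1 = s1, feature_1 = f1$feature_1[i1],
               sample_2 = s2, feature_2 = f2$feature_2[i2],
               row1 = f1$row1[i1], row2 = f2$row2[i2])
  }))
  if (is.null(neg_pool) || nrow(neg_pool) == 0L)
    neg_pool <- data.table(sample_1 = character(), feature_1 = character(),
                           sample_2 = character(), feature_2 = character(),
                           row1 = integer(), row2 = integer())
  neg_pool <- neg_pool[!truth, on = need]

  if (nrow(pos_pool) < n_pos || nrow(neg_pool) < n_neg)
    stopf(paste0("capacity error: requested %d positives / %d negatives, ",
                 "but only %d / %d eligible pairs exist"),
          n_pos, n_neg, nrow(pos_pool), nrow(neg_pool))

  with_local_seed(seed, {
    pos_take <- pos_pool[sample.int(nrow(pos_pool), n_pos)]
    neg_take <- neg_pool[sample.int(nrow(neg_pool), n_neg)]
  })
  ids <- rbindlist(list(pos_take[, ..need], neg_take[, ..need]))
  X <- rbind(.pair_matrix(bins, pos_take$row1, pos_take$row2, cfg),
             .pair_matrix(bins, neg_take$row1, neg_take$row2, cfg))
  structure(list(X = X,
                 label = c(rep(1L, n_pos), rep(0L, n_neg)),
                 ids = ids),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs (%d positive, %d negative)\n",
              nrow(x$X), sum(x$label == 1L), sum(x$label == 0L)))
  invisible(x)
}

#' Serialize / restore labeled pair vectors as flat CSV
#'
#' 40 value columns (`v01`..`v40`), a `label` column and the four id
#' columns, so training sets can be reused across sessions.
#'
#' @param pairs a `pair_set`.
#' @param path CSV path.
#' @return `write_pair_vectors`: the path, invisibly;
#'   `read_pair_vectors`: a `pair_set`.
#' @export
write_pair_vectors <- function(pairs, path) {
  stopifnot(inherits(pairs, "pair_set"))
  dt <- as.data.table(pairs$X)
  dt[, label := pairs$label]
  dt <- cbind(dt, pairs$ids)
  fwrite(dt, path)
  invisible(path)
}

#' @rdname write_pair_vectors
#' @export
read_pair_vectors <- function(path) {
  dt <- fread(path, showProgress = FALSE)
  vcols <- sprintf("v%02d", 1:40)
  if (!all(vcols %in% names(dt))) stopf("not a pair-vector file: '%s'", path)
  structure(list(X = as.matrix(dt[, ..vcols]),
                 label = as.integer(dt$label),
                 ids = dt[, .(sample_1, feature_1, sample_2, feature_2)]),
            class = "pair_set")
}
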