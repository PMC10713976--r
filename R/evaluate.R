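# Alignment scoring: per-sample-pair averaged precision and recall
# against ground-truth pair sets, identification-to-feature mapping for
# building ground truth on real data, and a rank-statistic AUC.

.pair_keys <- function(df) {
  df <- as.data.frame(df)
  if (ncol(df) < 2L) stopf("pair sets need two id columns")
  paste(as.character(df[[1L]]), as.character(df[[2L]]), sep = "\r")
}

#' Precision and recall of an alignment against ground truth
#'
#' For each of the `N` sample pairs, let `A_k` be the set of aligned
#' feature pairs and `G_k` the ground-truth set. Then
#' `precision = mean_k |A_k intersect G_k| / |A_k|` and
#' `recall = mean_k |A_k intersect G_k| / |G_k|` — averages over sample
#' pairs, not pooled counts. A sample pair with an empty `A_k`
#' contributes 0 to the precision mean (the ratio is undefined there;
#' contributing 0 is the conservative choice) and is reported with a
#' message.
#'
#' @param aligned list of `N` two-column data.frames (feature id in
#'   sample 1, feature id in sample 2); a single data.frame is treated
#'   as `N = 1`.
#' @param truth ground-truth sets in the same shape and order.
#' @return an object of class `eval_report`: list with `N`, a `per_pair`
#'   table and the overall `precision` and `recall`.
#' @export
precision_recall <- function(aligned, truth) {
  if (is.data.frame(aligned)) aligned <- list(aligned)
  if (is.data.frame(truth)) truth <- list(truth)
  if (length(aligned) != length(truth))
    stopf("input error: %d aligned sets vs %d truth sets",
          length(aligned), length(truth))
  N <- length(aligned)
  if (N < 1L) stopf("input error: need at least one sample pair")
  per <- rbindlist(lapply(seq_len(N), function(k) {
    A <- unique(.pair_keys(aligned[[k]]))
    G <- unique(.pair_keys(truth[[k]]))
    n_corr <- length(intersect(A, G))
    if (length(A) == 0L)
      message(sprintf("precision_recall: sample pair %d has no aligned pairs; precision contribution set to 0", k))
    data.table(k = k, n_aligned = length(A), n_truth = length(G),
               n_correct = n_corr,
               precision = if (length(A) == 0L) 0 else n_corr / length(A),
               recall = if (length(G) == 0L) 0 else n_corr / length(G))
  }))
  structure(list(N = N, per_pair = per,
                 precision = mean(per$precision),
                 recall = mean(per$recall)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> N = %d sample pairs: precision %.4f, recall %.4f\n",
              x$N, x$precision, x$recall))
  invisible(x)
}

#' Map peptide identifications onto MS1 features
#'
#' An identification labels a feature when its precursor m/z is within
#' `ppm_tol` parts-per-million of the feature m/z and its RT falls
#' inside the feature's elution bounds `[rt_start, rt_end]`. Features
#' without elution bounds use a `rt_window`-minute window around the
#' apex instead. A feature hit by more than one distinct sequence is
#' ambiguous and excluded from ground truth.
#'
#' @param table a [feature_table()].
#' @param ids data.frame with columns `sequence`, `mz` (Th) and `rt`
#'   (minutes).
#' @param ppm_tol mass tolerance in ppm (default 10).
#' @param rt_window fallback half-window in minutes around the feature
#'   apex when `rt_start`/`rt_end` are absent (default 0.5).
#' @return a `data.table` of unambiguous labels (`feature_id`,
#'   `sequence`) with the number of ambiguous features attached as
#'   attribute `n_ambiguous`.
#' @export
map_ids_to_features <- function(table, ids, ppm_tol = 10, rt_window = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  ids <- as.data.table(ids)
  for (col in c("sequence", "mz", "rt"))
    if (!col %in% names(ids))
      stopf("format error: identification table lacks column '%s'", col)
  if (anyNA(ids$mz) || anyNA(ids$rt))
    stopf("format error: identifications must carry m/z and RT")
  f <- copy(table$features)
  f[, `:=`(lo = fifelse(is.na(rt_start), rt - rt_window, rt_start),
           hi = fifelse(is.na(rt_end), rt + rt_window, rt_end))]
  setorder(f, mz)
  hits <- rbindlist(lapply(seq_len(nrow(ids)), function(i) {
    q_mz <- ids$mz[i]; q_rt <- ids$rt[i]
    win <- q_mz * (ppm_tol + 1) * 1e-6  # coarse window, exact filter below
    lo_i <- findInterval(q_mz - win, f$mz, left.open = TRUE) + 1L
    hi_i <- findInterval(q_mz + win, f$mz)
    if (hi_i < lo_i) return(NULL)
    cand <- f[lo_i:hi_i]
    cand <- cand[abs(mz - q_mz) / mz <= ppm_tol * 1e-6 &
                   q_rt >= lo & q_rt <= hi]
    if (nrow(cand) == 0L) return(NULL)
    data.table(feature_id = cand$feature_id, sequence = ids$sequence[i])
  }))
  if (is.null(hits) || nrow(hits) == 0L) {
    out <- data.table(feature_id = character(), sequence = character())
    attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  hits <- unique(hits)
  n_seq <- hits[, .(n = uniqueN(sequence)), by = feature_id]
  ambiguous <- n_seq[n > 1L, feature_id]
  out <- hits[!feature_id %in% ambiguous]
  attr(out, "n_ambiguous") <- length(ambiguous)
  out[]
}

utils::globalVariables(c("lo", "hi", "n"))

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from score ranks (equivalent to the
#' Mann-Whitney statistic); ties contribute one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (1/TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(scores) != length(y)) stopf("scores and labels differ in length")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("undefined metric: both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
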