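# Assembly of pairwise classifier decisions into cohort-level aligned
# feature groups, and decoy-based FDR estimation of the result.

#' Alignment/assembly configuration
#'
#' @param decision_threshold minimum classifier probability for a pair
#'   to be accepted (default 0.5).
#' @param rt_candidate_window maximum |corrected RT difference| in
#'   minutes for a pair to be scored at all (default 5, the RT scale of
#'   the difference normalization).
#' @param one_to_one enforce that each feature joins at most one
#'   accepted pair, resolved greedily by descending score (default on).
#' @return an object of class `align_config`.
#' @export
align_config <- function(decision_threshold = 0.5, rt_candidate_window = 5,
                         one_to_one = TRUE) {
  assert_number(decision_threshold, "decision_threshold", 0, strict = TRUE)
  if (decision_threshold >= 1) stopf("decision_threshold must be < 1")
  assert_number(rt_candidate_window, "rt_candidate_window", 0, strict = TRUE)
  assert_flag(one_to_one, "one_to_one")
  structure(list(decision_threshold = decision_threshold,
                 rt_candidate_window = rt_candidate_window,
                 one_to_one = one_to_one),
            class = "align_config")
}

# Greedy one-to-one matching over candidate rows already ordered by
# preference; returns a logical keep mask.
.greedy_one_to_one <- function(id1, id2) {
  u1 <- unique(id1); u2 <- unique(id2)
  used1 <- logical(length(u1)); used2 <- logical(length(u2))
  i1 <- match(id1, u1); i2 <- match(id2, u2)
  keep <- logical(length(id1))
  for (r in seq_along(id1)) {
    if (!used1[i1[r]] && !used2[i2[r]]) {
      keep[r] <- TRUE
      used1[i1[r]] <- TRUE
      used2[i2[r]] <- TRUE
    }
  }
  keep
}

#' Align two samples of a binned cohort
#'
#' Within every m/z window, all cross-sample candidate pairs with
#' |corrected RT difference| at most `rt_candidate_window` are encoded
#' and scored by the classifier. Pairs scoring at least the decision
#' threshold are accepted greedily in descending score order under the
#' one-to-one constraint, ties broken by smaller |dm/z| then smaller
#' |dRT|, then feature ids (fully deterministic).
#'
#' @param bins an `mz_bin_set` built on coarse-aligned tables.
#' @param s1,s2 sample ids to align (`s1` is usually the anchor).
#' @param model a trained `pair_model`.
#' @param cfg an [align_config()].
#' @param vec_cfg a [vectorizer_config()].
#' @return a `data.table` of accepted pairs: ids, score, `d_mz`, `d_rt`.
#' @export
align_two_samples <- function(bins, s1, s2, model, cfg = align_config(),
                              vec_cfg = vectorizer_config()) {
  stopifnot(inherits(bins, "mz_bin_set"), inherits(model, "pair_model"))
  feats <- bins$features
  empty <- data.table(sample_1 = character(), feature_1 = character(),
                      sample_2 = character(), feature_2 = character(),
                      score = numeric(), d_mz = numeric(), d_rt = numeric())
  d1 <- data.table(bin_id = feats$bin_id, row1 = seq_len(nrow(feats)))[
    feats$sample_id == s1]
  d2 <- data.table(bin_id = feats$bin_id, row2 = seq_len(nrow(feats)))[
    feats$sample_id == s2]
  if (nrow(d1) == 0L || nrow(d2) == 0L) return(empty)
  cand <- merge(d1, d2, by = "bin_id", allow.cartesian = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cand[, d_rt := abs(feats$rt_corrected[row1] - feats$rt_corrected[row2])]
  cand <- cand[d_rt <= cfg$rt_candidate_window]
  if (nrow(cand) == 0L) return(empty)
  cand[, d_mz := abs(feats$mz[row1] - feats$mz[row2])]
  X <- .pair_matrix(bins, cand$row1, cand$row2, vec_cfg)
  cand[, score := predict(model, X)]
  cand <- cand[score >= cfg$decision_threshold]
  if (nrow(cand) == 0L) return(empty)
  cand[, `:=`(feature_1 = feats$feature_id[row1],
              feature_2 = feats$feature_id[row2])]
  setorder(cand, -score, d_mz, d_rt, feature_1, feature_2)
  # overlap binning can present the same feature pair twice
  cand <- unique(cand, by = c("feature_1", "feature_2"))
  if (isTRUE(cfg$one_to_one))
    cand <- cand[.greedy_one_to_one(feature_1, feature_2)]
  cand[, .(sample_1 = s1, feature_1, sample_2 = s2, feature_2,
           score, d_mz, d_rt)]
}

#' Align a whole cohort into cross-run feature groups
#'
#' Runs the full chain — RT scaling, per-m/z reduction, piece-shift
#' estimation and correction, m/z binning, then model-based pairwise
#' alignment of every non-anchor sample against the anchor. Groups are
#' formed by joining accepted pairs through their shared anchor feature:
#' a group holds the anchor feature plus its accepted partner from each
#' sample that has one.
#'
#' @param tables list of two or more [feature_table()]s.
#' @param model a trained `pair_model`.
#' @param coarse_cfg,bin_cfg,cfg,vec_cfg stage configurations.
#' @return an object of class `alignment_result`: `groups` (long table:
#'   `group_id`, `sample_id`, `feature_id`, `mz`, `rt`, `intensity`,
#'   `score`), `pairs` (all accepted pairs), `samples`, `anchor`.
#' @export
align_cohort <- function(tables, model, coarse_cfg = coarse_config(),
                         bin_cfg = bin_config(), cfg = align_config(),
                         vec_cfg = vectorizer_config()) {
  if (!is.list(tables) || length(tables) < 2L)
    stopf("input error: need at least 2 samples to align")
  coarse <- coarse_align_cohort(tables, coarse_cfg)
  bins <- assign_bins(coarse$tables, bin_cfg)
  if (isTRUE(bin_cfg$filter_enabled)) bins <- filter_bins(bins, bin_cfg)
  anchor_id <- coarse$tables[[coarse_cfg$anchor_index]]$sample_id
  sample_ids <- vapply(coarse$tables, `[[`, "", "sample_id")
  pairs <- rbindlist(lapply(sample_ids[sample_ids != anchor_id], function(s)
    align_two_samples(bins, anchor_id, s, model, cfg, vec_cfg)))
  if (nrow(pairs) == 0L) {
    groups <- data.table(group_id = integer(), sample_id = character(),
                         feature_id = character(), mz = numeric(),
                         rt = numeric(), intensity = numeric(),
                         score = numeric())
  } else {
    anchor_feats <- coarse$tables[[coarse_cfg$anchor_index]]$features
    anchors <- unique(pairs$feature_1)
    ainfo <- anchor_feats[feature_id %in% anchors][order(mz, rt)]
    gid <- seq_len(nrow(ainfo))
    names(gid) <- ainfo$feature_id
    feat_all <- rbindlist(lapply(coarse$tables, `[[`, "features"))
    members <- pairs[, .(group_id = unname(gid[feature_1]),
                         sample_id = sample_2, feature_id = feature_2,
                         score = score)]
    anchor_members <- data.table(group_id = unname(gid),
                                 sample_id = anchor_id,
                                 feature_id = names(gid),
                                 score = NA_real_)
    groups <- rbindlist(list(anchor_members, members))
    groups[feat_all, on = .(sample_id, feature_id),
           `:=`(mz = i.mz, rt = i.rt, intensity = i.intensity)]
    setorder(groups, group_id, sample_id)
    setcolorder(groups, c("group_id", "sample_id", "feature_id",
                          "mz", "rt", "intensity", "score"))
  }
  res <- structure(list(groups = groups[], pairs = pairs,
                        samples = sample_ids, anchor = anchor_id),
                   class = "alignment_result")
  .check_alignment_invariants(res)
  res
}

.check_alignment_invariants <- function(res) {
  g <- res$groups
  if (nrow(g) > 0L &&
      anyDuplicated(g[, paste(sample_id, feature_id, sep = "\r")]) > 0L)
    stopf("internal error: a feature occurs in two groups")
  invisible(res)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d groups over %d samples (anchor '%s'), %d accepted pairs\n",
              uniqueN(x$groups$group_id), length(x$samples), x$anchor,
              nrow(x$pairs)))
  invisible(x)
}

#' Decoy-based FDR estimate of a cohort alignment
#'
#' In each m/z window one non-anchor sample is selected at random under
#' `seed`; its features in that window form the target set, and a decoy
#' copy is built by shifting each feature's m/z by `+bin_width` — moving
#' it into the adjacent window while preserving its RT and neighborhood
#' geometry, so in theory none of the decoys should align. Target and
#' decoy sets are each aligned against the anchor exactly like a real
#' sample, and the FDR estimate is accepted decoy pairs over accepted
#' target pairs (guarded denominator).
#'
#' @param tables list of [feature_table()]s (same input as
#'   [align_cohort()]).
#' @param model a trained `pair_model`.
#' @param coarse_cfg,bin_cfg,cfg,vec_cfg stage configurations.
#' @param seed RNG seed for the per-window sample selection.
#' @return an object of class `qc_report`: `n_target_accepted`,
#'   `n_decoy_accepted`, `fdr_estimate`, `seed`.
#' @export
estimate_fdr <- function(tables, model, coarse_cfg = coarse_config(),
                         bin_cfg = bin_config(), cfg = align_config(),
                         vec_cfg = vectorizer_config(), seed = 1L) {
  coarse <- coarse_align_cohort(tables, coarse_cfg)
  bins <- assign_bins(coarse$tables, bin_cfg)
  if (isTRUE(bin_cfg$filter_enabled)) bins <- filter_bins(bins, bin_cfg)
  anchor_id <- coarse$tables[[coarse_cfg$anchor_index]]$sample_id
  feats <- bins$features
  other <- feats[sample_id != anchor_id]
  if (nrow(other) == 0L) stopf("input error: no non-anchor features")
  present <- unique(other[, .(bin_id, sample_id)])
  with_local_seed(seed, {
    chosen <- present[, .(target_sample = sample_id[sample.int(.N, 1L)]),
                      by = bin_id]
  })
  sel <- other[chosen, on = .(bin_id, sample_id = target_sample), nomatch = NULL]
  # unique ids across source samples for the pooled pseudo-run
  sel_dt <- copy(sel)[, feature_id := paste(sample_id, feature_id, sep = ":")]
  mk_table <- function(dt, id, mz_shift = 0) {
    d <- copy(dt)[, `:=`(mz = mz + mz_shift)]
    ft <- feature_table(d[, .(feature_id, mz, rt, intensity, charge)],
                        sample_id = id)
    ft$features[, `:=`(rt_scaled = d$rt_scaled, rt_corrected = d$rt_corrected)]
    ft
  }
  anchor_tab <- coarse$tables[[coarse_cfg$anchor_index]]
  target_tab <- mk_table(sel_dt, "pseudo_target")
  decoy_tab <- mk_table(sel_dt, "pseudo_decoy", mz_shift = bin_cfg$bin_width)
  n_acc <- function(tab) {
    b <- assign_bins(list(anchor_tab, tab), bin_cfg)
    nrow(align_two_samples(b, anchor_id, tab$sample_id, model, cfg, vec_cfg))
  }
  n_target <- n_acc(target_tab)
  n_decoy <- n_acc(decoy_tab)
  structure(list(n_target_accepted = n_target,
                 n_decoy_accepted = n_decoy,
                 fdr_estimate = n_decoy / max(n_target, 1L),
                 seed = as.integer(seed),
                 n_windows = nrow(chosen)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d target / %d decoy accepted; FDR estimate %.4f\n",
              x$n_target_accepted, x$n_decoy_accepted, x$fdr_estimate))
  invisible(x)
}
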