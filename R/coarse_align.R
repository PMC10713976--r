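# Coarse alignment: linear scaling of RT to a common range, then removal
# of per-piece average RT shifts against an anchor run (a piecewise
# pseudo warping function).

#' Coarse-alignment configuration
#'
#' @param target_rt_range common RT range in minutes that every run is
#'   scaled to (default 80, the gradient length of the training cohorts
#'   the method was developed on).
#' @param piece_width width in minutes of the RT pieces within which one
#'   average shift is estimated (default 1).
#' @param anchor_index 1-based position of the anchor run in the cohort
#'   (default 1: the first sample).
#' @param coarse_mass_tol mass tolerance in Th used to pair features with
#'   the anchor when estimating shifts (default 0.01).
#' @param mz_round_decimals decimals used to collapse each run to one
#'   feature per m/z before shift estimation (default 2).
#' @return an object of class `coarse_config`.
#' @export
coarse_config <- function(target_rt_range = 80, piece_width = 1,
                          anchor_index = 1L, coarse_mass_tol = 0.01,
                          mz_round_decimals = 2L) {
  assert_number(target_rt_range, "target_rt_range", 0, strict = TRUE)
  assert_number(piece_width, "piece_width", 0, strict = TRUE)
  assert_number(coarse_mass_tol, "coarse_mass_tol", 0, strict = TRUE)
  assert_number(mz_round_decimals, "mz_round_decimals", 0)
  assert_number(anchor_index, "anchor_index", 1)
  structure(list(target_rt_range = target_rt_range,
                 piece_width = piece_width,
                 anchor_index = as.integer(anchor_index),
                 coarse_mass_tol = coarse_mass_tol,
                 mz_round_decimals = as.integer(mz_round_decimals)),
            class = "coarse_config")
}

#' Linearly scale retention times to a common range
#'
#' Sets `rt_scaled = rt * target_rt_range / rt_max_observed`, mapping the
#' run's latest feature to `target_rt_range` while keeping 0 fixed, so RT
#' order is preserved.
#'
#' @param table a [feature_table()].
#' @param target_rt_range target range in minutes (default 80).
#' @param rt_max optional override for the observed RT maximum; useful to
#'   scale several runs acquired on the same gradient by one common factor.
#' @return the table with `rt_scaled` populated.
#' @export
scale_rt <- function(table, target_rt_range = 80, rt_max = NULL) {
  stopifnot(inherits(table, "feature_table"))
  assert_number(target_rt_range, "target_rt_range", 0, strict = TRUE)
  m <- rt_max %||% table$rt_max_observed
  if (!is.finite(m) || m <= 0)
    stopf("degenerate input: all retention times are zero in sample '%s'",
          table$sample_id)
  table$features <- copy(table$features)[, rt_scaled := rt * (target_rt_range / m)]
  table
}

#' Collapse a run to its most intense feature per m/z
#'
#' Features are keyed by m/z rounded to `mz_round_decimals` decimals
#' (round half to even); per key only the highest-intensity feature is
#' kept, ties broken by earliest RT, then lexicographic feature id. The
#' reduced list is used for piece-shift estimation only.
#'
#' @param table a [feature_table()].
#' @param mz_round_decimals decimals of the m/z key (default 2).
#' @return a reduced [feature_table()].
#' @export
reduce_by_mz <- function(table, mz_round_decimals = 2L) {
  stopifnot(inherits(table, "feature_table"))
  dt <- copy(table$features)
  if (nrow(dt) == 0L) stopf("empty input")
  dt[, mz_key := round(mz, mz_round_decimals)]
  setorder(dt, mz_key, -intensity, rt, feature_id)
  dt <- dt[!duplicated(mz_key)]
  dt[, mz_key := NULL]
  out <- table
  out$features <- dt[]
  out
}

# 0-based piece index of a scaled RT; values at/after the end of the
# range fall in the last piece.
.piece_of <- function(rt_scaled, cfg) {
  n_pieces <- max(1L, as.integer(ceiling(cfg$target_rt_range / cfg$piece_width)))
  pmin(pmax(as.integer(floor(rt_scaled / cfg$piece_width)), 0L), n_pieces - 1L)
}

# For every query m/z, index of the anchor feature within tol that is
# nearest in m/z; m/z-distance ties broken by nearest scaled RT. NA when
# no anchor feature lies within tol.
.nearest_mz_match <- function(q_mz, q_rt, a_mz, a_rt, tol) {
  ord <- order(a_mz, a_rt)
  a_mz_s <- a_mz[ord]
  a_rt_s <- a_rt[ord]
  lo <- findInterval(q_mz - tol, a_mz_s, left.open = TRUE) + 1L
  hi <- findInterval(q_mz + tol, a_mz_s)
  out <- rep(NA_integer_, length(q_mz))
  has <- which(hi >= lo)
  for (i in has) {
    cand <- lo[i]:hi[i]
    d_mz <- abs(a_mz_s[cand] - q_mz[i])
    best <- cand[d_mz <= min(d_mz) + 0]
    if (length(best) > 1L) {
      d_rt <- abs(a_rt_s[best] - q_rt[i])
      best <- best[which.min(d_rt)]
    }
    out[i] <- ord[best[1L]]
  }
  out
}

#' Estimate per-piece average RT shifts against the anchor
#'
#' The scaled RT axis is partitioned into consecutive half-open pieces
#' `[k*w, (k+1)*w)`. Every feature of the (reduced) sample is paired with
#' the anchor feature nearest in m/z within `coarse_mass_tol`; features
#' without an anchor partner are ignored. A pair's shift is
#' `anchor rt_scaled - sample rt_scaled`; each piece reports the
#' arithmetic mean over its pairs, and pieces without pairs report 0.
#'
#' @param sample_reduced,anchor_reduced [reduce_by_mz()]-reduced tables
#'   with `rt_scaled` populated.
#' @param cfg a [coarse_config()].
#' @return a `data.table` with one row per piece: `piece_index` (0-based),
#'   `mean_shift` (minutes, on the scaled axis) and `n_pairs`.
#' @export
compute_piece_shifts <- function(sample_reduced, anchor_reduced, cfg = coarse_config()) {
  stopifnot(inherits(cfg, "coarse_config"))
  n_pieces <- max(1L, as.integer(ceiling(cfg$target_rt_range / cfg$piece_width)))
  empty <- data.table(piece_index = seq_len(n_pieces) - 1L,
                      mean_shift = 0, n_pairs = 0L)
  s <- sample_reduced$features
  a <- anchor_reduced$features
  if (nrow(s) == 0L) return(empty)
  if (anyNA(s$rt_scaled) || anyNA(a$rt_scaled))
    stopf("rt_scaled must be populated (run scale_rt first)")
  match_idx <- .nearest_mz_match(s$mz, s$rt_scaled, a$mz, a$rt_scaled,
                                 cfg$coarse_mass_tol)
  keep <- !is.na(match_idx)
  if (!any(keep)) return(empty)
  shifts <- data.table(
    piece = .piece_of(s$rt_scaled[keep], cfg),
    shift = a$rt_scaled[match_idx[keep]] - s$rt_scaled[keep])
  agg <- shifts[, .(mean_shift = mean(shift), n_pairs = .N), by = piece]
  out <- copy(empty)
  out[match(agg$piece, piece_index), `:=`(mean_shift = agg$mean_shift,
                                          n_pairs = agg$n_pairs)]
  out[]
}

#' Apply piecewise shifts to a full feature list
#'
#' Adds each piece's mean shift to every feature of the sample (the full
#' list, not only the reduced one used for estimation):
#' `rt_corrected = rt_scaled + mean_shift(piece)`. Pass `shifts = NULL`
#' for the anchor sample, which is the reference and gets
#' `rt_corrected = rt_scaled`.
#'
#' @param sample a [feature_table()] with `rt_scaled` populated.
#' @param shifts piece-shift table from [compute_piece_shifts()], or
#'   `NULL` for the anchor.
#' @param cfg a [coarse_config()].
#' @return the table with `rt_corrected` populated.
#' @export
apply_coarse_alignment <- function(sample, shifts, cfg = coarse_config()) {
  stopifnot(inherits(sample, "feature_table"))
  dt <- copy(sample$features)
  if (anyNA(dt$rt_scaled)) stopf("rt_scaled must be populated (run scale_rt first)")
  if (is.null(shifts)) {
    dt[, rt_corrected := rt_scaled]
  } else {
    pc <- .piece_of(dt$rt_scaled, cfg)
    dt[, rt_corrected := rt_scaled +
         shifts$mean_shift[match(pc, shifts$piece_index)]]
  }
  sample$features <- dt[]
  sample
}

#' Coarse-align a whole cohort against its anchor
#'
#' Runs the full coarse stage: scale every run to the common RT range,
#' reduce each to one feature per m/z, estimate per-piece shifts of every
#' non-anchor run against the anchor, and apply them to the full lists.
#'
#' @param tables list of [feature_table()]s (first is the anchor by
#'   default, see `anchor_index` in [coarse_config()]).
#' @param cfg a [coarse_config()].
#' @return a list with `tables` (the corrected tables, same order) and
#'   `shifts` (per-sample piece-shift tables, `NULL` for the anchor).
#' @export
coarse_align_cohort <- function(tables, cfg = coarse_config()) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (cfg$anchor_index > length(tables))
    stopf("anchor_index %d exceeds cohort size %d", cfg$anchor_index, length(tables))
  scaled <- lapply(tables, scale_rt, target_rt_range = cfg$target_rt_range)
  reduced <- lapply(scaled, reduce_by_mz, mz_round_decimals = cfg$mz_round_decimals)
  anchor_red <- reduced[[cfg$anchor_index]]
  shifts <- vector("list", length(tables))
  out <- scaled
  for (i in seq_along(tables)) {
    if (i == cfg$anchor_index) {
      out[[i]] <- apply_coarse_alignment(scaled[[i]], NULL, cfg)
    } else {
      shifts[[i]] <- compute_piece_shifts(reduced[[i]], anchor_red, cfg)
      out[[i]] <- apply_coarse_alignment(scaled[[i]], shifts[[i]], cfg)
    }
  }
  list(tables = out, shifts = shifts)
}
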