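# m/z window (bin) assignment. Candidate matches are only attempted
# between features that fall in the same bin, and the RT-neighbor
# contexts that feed the pair vectors are defined per bin and sample.

#' Binning configuration
#'
#' @param bin_width m/z window size in Th (default 0.03).
#' @param bin_precision decimal places the m/z is rounded to (round half
#'   to even) before the window index is computed (default 2).
#' @param filter_enabled whether the optional per-window intensity filter
#'   is applied (default `FALSE`; filtering is off by default).
#' @param filter_rt_window RT window in minutes for the filter; required
#'   when `filter_enabled`.
#' @param overlap optional mode in which a feature within `bin_width/2`
#'   of a bin edge also joins the adjacent bin, so near-boundary pairs
#'   can still be compared (default `FALSE`: exactly one window per
#'   feature).
#' @return an object of class `bin_config`.
#' @export
bin_config <- function(bin_width = 0.03, bin_precision = 2L,
                       filter_enabled = FALSE, filter_rt_window = NULL,
                       overlap = FALSE) {
  assert_number(bin_width, "bin_width", 0, strict = TRUE)
  assert_number(bin_precision, "bin_precision", 0)
  assert_flag(filter_enabled, "filter_enabled")
  assert_flag(overlap, "overlap")
  if (filter_enabled) {
    if (is.null(filter_rt_window))
      stopf("filter_rt_window is required when filter_enabled")
    assert_number(filter_rt_window, "filter_rt_window", 0, strict = TRUE)
  }
  structure(list(bin_width = bin_width,
                 bin_precision = as.integer(bin_precision),
                 filter_enabled = filter_enabled,
                 filter_rt_window = filter_rt_window,
                 overlap = overlap),
            class = "bin_config")
}

# Window index of an m/z value: floor(rounded m/z / bin_width), with a
# small epsilon guarding against values sitting a representation error
# below an exact grid line.
.bin_id_of <- function(mz, cfg) {
  key <- round(mz, cfg$bin_precision)
  as.integer(floor(key / cfg$bin_width + 1e-7))
}

# Sort canonical order inside bins and attach per-(bin, sample) list
# positions plus the 5-wide RT-neighbor context matrices.
.index_bins <- function(dt) {
  setorder(dt, bin_id, sample_id, rt_corrected, mz, feature_id)
  dt[, pos := seq_len(.N), by = .(bin_id, sample_id)]
  grp_info <- dt[, .(grp_start = .I[1L], grp_n = .N), by = .(bin_id, sample_id)]
  dt[grp_info, on = .(bin_id, sample_id), `:=`(grp_start = grp_start, grp_n = grp_n)]
  n <- nrow(dt)
  ctx_rt <- matrix(NA_real_, n, 5L)
  ctx_mz <- matrix(NA_real_, n, 5L)
  for (k in 1:5) {
    off <- k - 3L
    idx <- dt$grp_start + pmin(pmax(dt$pos + off, 1L), dt$grp_n) - 1L
    ctx_rt[, k] <- dt$rt_corrected[idx]
    ctx_mz[, k] <- dt$mz[idx]
  }
  list(features = dt[], ctx_rt = ctx_rt, ctx_mz = ctx_mz)
}

#' Group coarse-aligned features into m/z windows
#'
#' Every feature's m/z is rounded to `bin_precision` decimals and the
#' window index is `floor(key / bin_width)`; each feature lands in
#' exactly one window (two windows in `overlap` mode when it sits within
#' `bin_width/2` of an edge). Within a window, per-sample lists are
#' sorted by `rt_corrected`, ties by m/z then feature id.
#'
#' @param tables list of [feature_table()]s with `rt_corrected` populated
#'   (see [coarse_align_cohort()]).
#' @param cfg a [bin_config()].
#' @return an object of class `mz_bin_set`: the pooled feature table with
#'   window indices and cached RT-neighbor contexts.
#' @export
assign_bins <- function(tables, cfg = bin_config()) {
  stopifnot(inherits(cfg, "bin_config"))
  if (inherits(tables, "feature_table")) tables <- list(tables)
  dt <- rbindlist(lapply(tables, `[[`, "features"))
  if (nrow(dt) == 0L) stopf("empty input")
  if (anyNA(dt$rt_corrected))
    stopf("rt_corrected must be populated before binning (run coarse alignment)")
  dt[, bin_id := .bin_id_of(mz, cfg)]
  if (isTRUE(cfg$overlap)) {
    key <- round(dt$mz, cfg$bin_precision)
    frac <- key / cfg$bin_width + 1e-7
    rel <- frac - floor(frac)
    lower <- dt[rel < 0.5][, bin_id := bin_id - 1L]
    upper <- dt[rel >= 0.5][, bin_id := bin_id + 1L]
    dt <- rbindlist(list(dt, lower[bin_id >= 0L], upper))
  }
  idx <- .index_bins(dt)
  structure(c(idx, list(cfg = cfg,
                        samples = unique(vapply(tables, `[[`, "", "sample_id")))),
            class = "mz_bin_set")
}

#' @export
print.mz_bin_set <- function(x, ...) {
  cat(sprintf("<mz_bin_set> %d features, %d windows, %d samples\n",
              nrow(x$features), uniqueN(x$features$bin_id), length(x$samples)))
  invisible(x)
}

#' Per-window intensity filtering
#'
#' Optional step: for each sample in each m/z window, only the
#' highest-intensity feature within each consecutive RT window of width
#' `filter_rt_window` survives; ties keep the earliest RT. Disabled by
#' default — call only with `filter_enabled` set in the config.
#'
#' @param bins an `mz_bin_set` from [assign_bins()].
#' @param cfg a [bin_config()] with `filter_enabled = TRUE`.
#' @return a filtered `mz_bin_set` (contexts rebuilt).
#' @export
filter_bins <- function(bins, cfg) {
  stopifnot(inherits(bins, "mz_bin_set"))
  if (!isTRUE(cfg$filter_enabled))
    stopf("configuration error: filter_bins called while filter_enabled is FALSE")
  w <- cfg$filter_rt_window
  dt <- copy(bins$features)
  dt[, win := as.integer(floor(rt_corrected / w))]
  setorder(dt, bin_id, sample_id, win, -intensity, rt_corrected, feature_id)
  dt <- dt[, .SD[1L], by = .(bin_id, sample_id, win)]
  dt[, c("win", "pos", "grp_start", "grp_n") := NULL]
  idx <- .index_bins(dt)
  structure(c(idx, list(cfg = cfg, samples = bins$samples)),
            class = "mz_bin_set")
}
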