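# Canonical feature-table container and readers for the supported
# feature-list dialects. All retention times are carried in minutes.

FEATURE_COLS <- c("feature_id", "sample_id", "mz", "rt", "rt_scaled",
                  "rt_corrected", "intensity", "charge", "rt_start", "rt_end")

#' Construct a feature table for one LC-MS run
#'
#' A feature table holds all MS1 features of a single run: m/z (Th),
#' retention time (minutes), intensity (arbitrary units) and charge
#' (0 = unknown), plus optional elution bounds `rt_start`/`rt_end`.
#' Rows violating the basic invariants (`mz > 0`, `rt >= 0`,
#' `intensity >= 0`, bounds bracketing the apex) are dropped with a
#' message; the count is kept in the `n_dropped` field. Real extractor
#' output routinely contains such sentinel rows, so they are not fatal.
#'
#' @param df data.frame with columns `mz`, `rt`, `intensity` and
#'   optionally `charge`, `rt_start`, `rt_end`, `feature_id`.
#' @param sample_id character scalar identifying the run.
#' @param rt_scaled,rt_corrected optional numeric vectors; normally left
#'   unset until [scale_rt()] / [apply_coarse_alignment()] populate them.
#' @return An object of class `feature_table`: a list with fields
#'   `features` (a `data.table`), `sample_id`, `rt_max_observed` and
#'   `n_dropped`.
#' @export
feature_table <- function(df, sample_id, rt_scaled = NULL, rt_corrected = NULL) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stopf("'sample_id' must be a non-empty string")
  df <- as.data.frame(df)
  for (col in c("mz", "rt", "intensity"))
    if (!col %in% names(df))
      stopf("format error: mandatory column '%s' is missing", col)
  n_in <- nrow(df)
  grab_num <- function(col, default) {
    if (col %in% names(df)) as.numeric(df[[col]])
    else rep(default, n_in)
  }
  charge <- if ("charge" %in% names(df))
    suppressWarnings(as.integer(df[["charge"]])) else rep(0L, n_in)
  charge <- fifelse(is.na(charge) | charge < 0L, 0L, charge)
  fid <- if ("feature_id" %in% names(df) && !anyNA(df[["feature_id"]]))
    as.character(df[["feature_id"]]) else sprintf("F%06d", seq_len(n_in))
  if (anyDuplicated(fid))
    stopf("feature_ids must be unique within sample '%s'", sample_id)
  dt <- data.table(
    feature_id = fid,
    sample_id = rep(sample_id, n_in),
    mz = as.numeric(df[["mz"]]),
    rt = as.numeric(df[["rt"]]),
    rt_scaled = if (!is.null(rt_scaled)) as.numeric(rt_scaled)
                else grab_num("rt_scaled", NA_real_),
    rt_corrected = if (!is.null(rt_corrected)) as.numeric(rt_corrected)
                   else grab_num("rt_corrected", NA_real_),
    intensity = as.numeric(df[["intensity"]]),
    charge = charge,
    rt_start = grab_num("rt_start", NA_real_),
    rt_end = grab_num("rt_end", NA_real_))

  ok <- with(dt, is.finite(mz) & mz > 0 & is.finite(rt) & rt >= 0 &
               is.finite(intensity) & intensity >= 0)
  bounds_bad <- with(dt, (!is.na(rt_start) & rt_start > rt) |
                       (!is.na(rt_end) & rt_end < rt))
  ok <- ok & !bounds_bad
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(sprintf("feature_table('%s'): dropped %d of %d rows failing invariants",
                    sample_id, n_dropped, n_in))
    dt <- dt[ok]
  }
  if (nrow(dt) == 0L)
    stopf("empty input: no valid feature rows for sample '%s'", sample_id)
  setcolorder(dt, FEATURE_COLS)
  structure(list(features = dt[],
                 sample_id = sample_id,
                 rt_max_observed = max(dt$rt),
                 n_dropped = n_dropped),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> sample '%s': %d features, RT max %.2f min%s\n",
              x$sample_id, nrow(x$features), x$rt_max_observed,
              if (x$n_dropped > 0) sprintf(" (%d rows dropped)", x$n_dropped) else ""))
  print(head(x$features, 5L))
  invisible(x)
}

#' Number of features in a table
#' @param x a `feature_table`.
#' @return integer count.
#' @export
n_features <- function(x) nrow(x$features)

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stopf("empty input: '%s'", path)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

.read_delim_dialect <- function(path, colmap, sep = NULL) {
  sep <- sep %||% .sniff_sep(path)
  raw <- fread(path, sep = sep, header = TRUE, data.table = TRUE,
               showProgress = FALSE)
  missing <- setdiff(unname(colmap[c("mz", "rt", "intensity")]), names(raw))
  if (length(missing) > 0L)
    stopf("format error: mandatory column '%s' is missing", missing[[1L]])
  out <- data.table(mz = as.numeric(raw[[colmap[["mz"]]]]),
                    rt = as.numeric(raw[[colmap[["rt"]]]]),
                    intensity = as.numeric(raw[[colmap[["intensity"]]]]))
  for (opt in c("charge", "rt_start", "rt_end")) {
    src <- unname(colmap[opt])
    if (!is.na(src) && src %in% names(raw))
      out[[opt]] <- raw[[src]]
  }
  out
}

.read_featurexml <- function(path) {
  doc <- xml2::read_xml(path)
  feats <- xml2::xml_find_all(doc, ".//*[local-name()='feature']")
  # drop nested subordinate features (convex hulls carry none, but be safe)
  if (length(feats) == 0L) stopf("format error: no <feature> elements in '%s'", path)
  get_pos <- function(dim) {
    vapply(feats, function(f) {
      node <- xml2::xml_find_first(
        f, sprintf("./*[local-name()='position' and @dim='%d']", dim))
      as.numeric(xml2::xml_text(node))
    }, numeric(1))
  }
  get_num <- function(name) {
    vapply(feats, function(f) {
      node <- xml2::xml_find_first(f, sprintf("./*[local-name()='%s']", name))
      if (inherits(node, "xml_missing")) NA_real_
      else as.numeric(xml2::xml_text(node))
    }, numeric(1))
  }
  # featureXML: dim 0 = RT in seconds, dim 1 = m/z in Th
  data.table(mz = get_pos(1L),
             rt = get_pos(0L) / 60,
             intensity = get_num("intensity"),
             charge = get_num("charge"))
}

#' Read a per-sample feature list into a canonical table
#'
#' Supported dialects:
#' \describe{
#'   \item{`generic_csv`}{comma- or tab-separated (sniffed from the header
#'     line) with header columns `mz`, `rt`, `intensity` and optionally
#'     `charge`, `rt_start`, `rt_end`. RT is assumed to be in minutes.}
#'   \item{`maxquant_allpeptides`}{MaxQuant `allPeptides.txt` TSV; maps
#'     `m/z`, `Retention time`, `Intensity`, `Charge`.}
#'   \item{`dinosaur_tsv`}{Dinosaur `.features.tsv`; maps `mz`, `rtApex`,
#'     `intensityApex`, `charge`, plus `rtStart`/`rtEnd` when present.}
#'   \item{`openms_featurexml`}{OpenMS featureXML; positions report RT in
#'     seconds (converted to minutes) and m/z in Th.}
#' }
#'
#' @param path input file.
#' @param dialect one of `"generic_csv"`, `"maxquant_allpeptides"`,
#'   `"dinosaur_tsv"`, `"openms_featurexml"`.
#' @param sample_id run identifier attached to every feature.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, dialect = c("generic_csv",
                                                 "maxquant_allpeptides",
                                                 "dinosaur_tsv",
                                                 "openms_featurexml"),
                               sample_id) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stopf("unknown dialect '%s'", dialect[[1L]]))
  df <- switch(dialect,
    generic_csv = .read_delim_dialect(path, c(
      mz = "mz", rt = "rt", intensity = "intensity", charge = "charge",
      rt_start = "rt_start", rt_end = "rt_end")),
    maxquant_allpeptides = .read_delim_dialect(path, c(
      mz = "m/z", rt = "Retention time", intensity = "Intensity",
      charge = "Charge"), sep = "\t"),
    dinosaur_tsv = .read_delim_dialect(path, c(
      mz = "mz", rt = "rtApex", intensity = "intensityApex",
      charge = "charge", rt_start = "rtStart", rt_end = "rtEnd"), sep = "\t"),
    openms_featurexml = .read_featurexml(path))
  feature_table(df, sample_id = sample_id)
}

#' Write an alignment result as a wide CSV
#'
#' One row per alignment group: the group id, then per sample the matched
#' feature's id, m/z (4 decimals), RT (2 decimals, minutes) and intensity
#' (empty cells where a sample has no member), and finally the group's
#' minimum accepted pair score. Rows are ordered by ascending group median
#' m/z, ties by median RT, so output is deterministic.
#'
#' @param result an `alignment_result` from [align_cohort()].
#' @param path output CSV path.
#' @return the output path, invisibly.
#' @export
write_aligned_table <- function(result, path) {
  stopifnot(inherits(result, "alignment_result"))
  g <- result$groups
  if (is.null(g) || nrow(g) == 0L) stopf("empty alignment result")
  samples <- result$samples
  ord <- g[, .(med_mz = stats::median(mz), med_rt = stats::median(rt)),
           by = group_id][order(med_mz, med_rt)]
  wide <- data.table(group_id = ord$group_id)
  for (s in samples) {
    gs <- g[sample_id == s]
    idx <- match(wide$group_id, gs$group_id)
    wide[[paste0(s, "_feature_id")]] <- gs$feature_id[idx]
    wide[[paste0(s, "_mz")]] <- ifelse(is.na(idx), "",
                                       sprintf("%.4f", gs$mz[idx]))
    wide[[paste0(s, "_rt")]] <- ifelse(is.na(idx), "",
                                       sprintf("%.2f", gs$rt[idx]))
    wide[[paste0(s, "_intensity")]] <- ifelse(is.na(idx), "",
                                              format(gs$intensity[idx]))
  }
  min_score <- g[!is.na(score), .(min_score = min(score)), by = group_id]
  wide[["min_score"]] <- min_score$min_score[match(wide$group_id,
                                                   min_score$group_id)]
  ok <- tryCatch({
    fwrite(wide, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("I/O error: cannot write '%s'", path)
  invisible(path)
}

#' Re-read group membership from an aligned CSV
#'
#' Inverse of [write_aligned_table()] for the membership columns: returns
#' a long table of (group_id, sample_id, feature_id).
#'
#' @param path CSV written by [write_aligned_table()].
#' @return a `data.table` with columns `group_id`, `sample_id`, `feature_id`.
#' @export
read_aligned_table <- function(path) {
  wide <- fread(path, colClasses = list(character = "group_id"),
                showProgress = FALSE)
  id_cols <- grep("_feature_id$", names(wide), value = TRUE)
  out <- rbindlist(lapply(id_cols, function(col) {
    s <- sub("_feature_id$", "", col)
    data.table(group_id = as.character(wide$group_id), sample_id = s,
               feature_id = as.character(wide[[col]]))
  }))
  out[!is.na(feature_id) & nzchar(feature_id)][order(group_id, sample_id)]
}
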