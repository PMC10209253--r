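# Validation of auto-segmentation against reference contours: lesion
# matching, voxel-wise confusion statistics, Dice, concordance, SUV
# threshold sweep, ROC-based optimum selection and the unmatched-lesion
# audit.

#' Match auto-segmented lesions to reference lesions
#'
#' One-to-one greedy matching on the combined cost
#' `distance_mm / d_scale + |delta SUVmax| / s_scale`, taking pairs in
#' ascending cost.  Candidate pairs whose SUVmax locations are farther
#' apart than `max_distance_mm` are never matched.  Cost ties resolve to
#' the lower reference label, then the lower auto label, so matching is
#' deterministic and independent of input row order.  Euclidean distance is
#' computed in physical mm between SUVmax coordinates.
#'
#' @param auto,ref lesion statistic frames from [quantify_lesions()] for
#'   the auto and reference segmentations of the same patient grid.
#' @param d_scale mm that count as much as `s_scale` SUV in the cost
#'   (default 10 mm).
#' @param s_scale SUV scale of the cost (default 1).
#' @param max_distance_mm matching gate (default 20 mm).
#' @return list with `pairs` (data frame: `auto_label`, `ref_label`,
#'   `suvmax_diff`, `centre_distance_mm`, `cost`), `unmatched_auto` and
#'   `unmatched_ref` (subsets of the inputs; the Fig.-9-style audit data).
#' @export
match_lesions <- function(auto, ref, d_scale = 10, s_scale = 1,
                          max_distance_mm = 20) {
  empty_pairs <- data.frame(auto_label = integer(0), ref_label = integer(0),
                            suvmax_diff = numeric(0),
                            centre_distance_mm = numeric(0),
                            cost = numeric(0))
  if (nrow(auto) == 0L || nrow(ref) == 0L)
    return(list(pairs = empty_pairs, unmatched_auto = auto,
                unmatched_ref = ref))
  auto <- auto[order(auto$label), , drop = FALSE]
  ref <- ref[order(ref$label), , drop = FALSE]
  na <- nrow(auto); nr <- nrow(ref)
  am <- as.matrix(auto[, c("max_x_mm", "max_y_mm", "max_z_mm")])
  rm_ <- as.matrix(ref[, c("max_x_mm", "max_y_mm", "max_z_mm")])
  cand <- expand.grid(i = seq_len(na), j = seq_len(nr))
  dist <- sqrt(rowSums((am[cand$i, , drop = FALSE] -
                        rm_[cand$j, , drop = FALSE])^2))
  sdiff <- abs(auto$suv_max[cand$i] - ref$suv_max[cand$j])
  cost <- dist / d_scale + sdiff / s_scale
  ok <- dist <= max_distance_mm
  ord <- order(cost, ref$label[cand$j], auto$label[cand$i])
  used_a <- logical(na); used_r <- logical(nr)
  rows <- list()
  for (q in ord) {
    if (!ok[q]) next
    i <- cand$i[q]; j <- cand$j[q]
    if (used_a[i] || used_r[j]) next
    used_a[i] <- TRUE; used_r[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      auto_label = auto$label[i], ref_label = ref$label[j],
      suvmax_diff = sdiff[q], centre_distance_mm = dist[q], cost = cost[q])
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty_pairs
  list(pairs = pairs,
       unmatched_auto = auto[!used_a, , drop = FALSE],
       unmatched_ref = ref[!used_r, , drop = FALSE])
}

#' Voxel-by-voxel confusion counts
#'
#' Counts are taken over an evaluation `domain` (both masks are intersected
#' with it first): `tp = |auto & ref|`, `fp = |auto & !ref|`,
#' `fn = |ref & !auto|`, `tn = domain size - tp - fp - fn`.  The domain is
#' typically the bone mask (the stricter choice) or the whole image.
#'
#' @param auto_mask,ref_mask,domain binary [volume_image]s on one grid;
#'   `domain = NULL` uses the whole image.
#' @return list of class `confusion_counts`: `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity` (each `NA` when its denominator is 0).
#' @export
voxel_confusion <- function(auto_mask, ref_mask, domain = NULL) {
  stopifnot(is_volume_image(auto_mask), is_volume_image(ref_mask))
  check_same_grid(auto_mask, ref_mask)
  a <- auto_mask$data != 0
  r <- ref_mask$data != 0
  if (!is.null(domain)) {
    check_same_grid(auto_mask, domain)
    dm <- domain$data != 0
    a <- a & dm; r <- r & dm
    n <- sum(dm)
  } else {
    n <- length(a)
  }
  tp <- sum(a & r); fp <- sum(a & !r); fn <- sum(r & !a)
  tn <- n - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "confusion_counts")
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 * |A & B| / (|A| + |B|)`.  Two empty masks are in perfect agreement
#' and return 1 (documented convention).
#'
#' @param auto_mask,ref_mask binary [volume_image]s on one grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(auto_mask, ref_mask) {
  stopifnot(is_volume_image(auto_mask), is_volume_image(ref_mask))
  check_same_grid(auto_mask, ref_mask)
  a <- auto_mask$data != 0; r <- ref_mask$data != 0
  denom <- sum(a) + sum(r)
  if (denom == 0) return(1)
  2 * sum(a & r) / denom
}

#' Pearson correlation as the concordance measure
#'
#' Degenerate inputs (fewer than two points, or zero variance in either
#' vector) raise an error rather than returning a silent `NaN`.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return Pearson r in `[-1, 1]`.
#' @export
concordance_r <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("undefined result: need at least 2 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined result: zero variance", call. = FALSE)
  stats::cor(x, y)
}

# run segmentation + quantification + matching for one case at one
# threshold; returns everything the sweep and report need
.evaluate_case <- function(case, threshold, connectivity = 26,
                           domain = c("bone", "whole"), ...) {
  domain <- match.arg(domain)
  masked <- apply_bone_mask(case$suv, case$bone)
  labels <- segment_lesions(masked, suv_threshold = threshold,
                            connectivity = connectivity)
  auto_stats <- quantify_lesions(labels, case$suv)
  ref_stats <- quantify_lesions(case$ref_labels, case$suv)
  m <- match_lesions(auto_stats, ref_stats, ...)
  dom <- if (domain == "bone") case$bone else NULL
  conf <- voxel_confusion(lesion_mask(labels), lesion_mask(case$ref_labels),
                          domain = dom)
  dscs <- if (nrow(m$pairs)) vapply(seq_len(nrow(m$pairs)), function(q)
    dice(lesion_mask(labels, m$pairs$auto_label[q]),
         lesion_mask(case$ref_labels, m$pairs$ref_label[q])), numeric(1))
    else numeric(0)
  list(labels = labels, auto_stats = auto_stats, ref_stats = ref_stats,
       match = m, confusion = conf, dsc = dscs)
}

#' Sweep the SUV threshold over a validation cohort
#'
#' For each threshold, lesions are segmented in every case, matched to the
#' reference lesions, and the metrics are pooled across cases: Pearson r of
#' matched-pair volumes and SUVmeans, the per-pair DSC distribution
#' (median and IQR), and sensitivity/specificity from summed voxel
#' confusion counts over the evaluation domain.
#'
#' @param cases list of cases; each a list with elements `suv`
#'   ([volume_image], SUV_BW), `bone` (binary mask) and `ref_labels`
#'   (reference lesion label map on the same grid).
#' @param thresholds strictly increasing SUV values; default
#'   `c(2.0, 2.5, 3.0, 3.5, 4, 6)`.
#' @param domain `"bone"` (default) or `"whole"` for the specificity
#'   denominator.
#' @param ... passed to [match_lesions()].
#' @return object of class `sweep_result`: `thresholds`, `metrics` (data
#'   frame with one row per threshold: `threshold`, `sensitivity`,
#'   `specificity`, `dsc_median`, `dsc_iqr`, `volume_r`, `suvmean_r`,
#'   `n_auto`, `n_matched`), and `dsc` (list of per-pair DSC vectors).
#' @export
sweep_thresholds <- function(cases, thresholds = c(2.0, 2.5, 3.0, 3.5, 4, 6),
                             domain = "bone", ...) {
  if (!length(cases)) stop("parameter error: need at least one case",
                           call. = FALSE)
  if (!length(thresholds))
    stop("parameter error: empty threshold list", call. = FALSE)
  thresholds <- as.numeric(thresholds)
  if (any(diff(thresholds) <= 0))
    stop("parameter error: thresholds must be strictly increasing",
         call. = FALSE)
  rows <- list(); dsc_all <- list()
  for (t in seq_along(thresholds)) {
    th <- thresholds[t]
    tp <- tn <- fp <- fn <- 0
    vols_a <- vols_r <- mus_a <- mus_r <- numeric(0)
    dscs <- numeric(0); n_auto <- 0L; n_matched <- 0L
    for (case in cases) {
      ev <- .evaluate_case(case, th, domain = domain, ...)
      cf <- ev$confusion
      tp <- tp + cf$tp; tn <- tn + cf$tn; fp <- fp + cf$fp; fn <- fn + cf$fn
      p <- ev$match$pairs
      if (nrow(p)) {
        ia <- match(p$auto_label, ev$auto_stats$label)
        ir <- match(p$ref_label, ev$ref_stats$label)
        vols_a <- c(vols_a, ev$auto_stats$volume_ml[ia])
        vols_r <- c(vols_r, ev$ref_stats$volume_ml[ir])
        mus_a <- c(mus_a, ev$auto_stats$suv_mean[ia])
        mus_r <- c(mus_r, ev$ref_stats$suv_mean[ir])
      }
      dscs <- c(dscs, ev$dsc)
      n_auto <- n_auto + nrow(ev$auto_stats)
      n_matched <- n_matched + nrow(p)
    }
    safe_r <- function(x, y) {
      if (length(x) >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
        stats::cor(x, y) else NA_real_
    }
    rows[[t]] <- data.frame(
      threshold = th,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      dsc_median = if (length(dscs)) stats::median(dscs) else NA_real_,
      dsc_iqr = if (length(dscs)) stats::IQR(dscs) else NA_real_,
      volume_r = safe_r(vols_a, vols_r),
      suvmean_r = safe_r(mus_a, mus_r),
      n_auto = n_auto, n_matched = n_matched)
    dsc_all[[t]] <- dscs
  }
  structure(list(thresholds = thresholds,
                 metrics = do.call(rbind, rows),
                 dsc = dsc_all),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Select the ROC-optimal SUV threshold from a sweep
#'
#' Returns the threshold maximising `sensitivity + specificity` (Youden's
#' J + 1).  Ties break toward the higher median DSC, then toward the lower
#' threshold.  The report carries the per-threshold ROC points
#' (sensitivity vs 1 - specificity) and median DSC.
#'
#' @param sweep a `sweep_result` from [sweep_thresholds()].
#' @return list with `threshold` and `report` (data frame: `threshold`,
#'   `sensitivity`, `one_minus_specificity`, `youden`, `dsc_median`).
#' @export
select_optimum_threshold <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  m <- sweep$metrics
  score <- m$sensitivity + m$specificity
  score[is.na(score)] <- -Inf
  dscm <- ifelse(is.na(m$dsc_median), -Inf, m$dsc_median)
  best <- order(-score, -dscm, m$threshold)[1]
  report <- data.frame(threshold = m$threshold,
                       sensitivity = m$sensitivity,
                       one_minus_specificity = 1 - m$specificity,
                       youden = m$sensitivity + m$specificity - 1,
                       dsc_median = m$dsc_median)
  list(threshold = m$threshold[best], report = report)
}

#' Per-patient validation report
#'
#' One row per case at a fixed threshold: volume and SUVmean concordance
#' over matched pairs (NA when fewer than two pairs or degenerate
#' variance, as single-lesion patients have no defined correlation),
#' sensitivity and specificity in percent, median DSC, and the reference /
#' auto lesion counts; plus the pooled lesion-count correlation across
#' patients.
#'
#' @param cases list of cases as in [sweep_thresholds()].
#' @param threshold SUV threshold (default 3.0).
#' @param domain `"bone"` (default) or `"whole"`.
#' @param ... passed to [match_lesions()].
#' @return list of class `patient_report`: `table` (data frame), and
#'   `lesion_count_r` (NA when undefined).
#' @export
patient_report <- function(cases, threshold = 3.0, domain = "bone", ...) {
  rows <- list()
  for (i in seq_along(cases)) {
    ev <- .evaluate_case(cases[[i]], threshold, domain = domain, ...)
    p <- ev$match$pairs
    safe_r <- function(x, y) {
      if (length(x) >= 2 && stats::sd(x) > 0 && stats::sd(y) > 0)
        stats::cor(x, y) else NA_real_
    }
    vol_r <- suv_r <- NA_real_
    if (nrow(p)) {
      ia <- match(p$auto_label, ev$auto_stats$label)
      ir <- match(p$ref_label, ev$ref_stats$label)
      vol_r <- safe_r(ev$auto_stats$volume_ml[ia], ev$ref_stats$volume_ml[ir])
      suv_r <- safe_r(ev$auto_stats$suv_mean[ia], ev$ref_stats$suv_mean[ir])
    }
    cf <- ev$confusion
    rows[[i]] <- data.frame(
      patient = i, volume_r = vol_r, suvmean_r = suv_r,
      sensitivity_pct = 100 * cf$sensitivity,
      specificity_pct = 100 * cf$specificity,
      dsc_median = if (length(ev$dsc)) stats::median(ev$dsc) else NA_real_,
      n_ref = nrow(ev$ref_stats), n_auto = nrow(ev$auto_stats),
      n_matched = nrow(p))
  }
  tab <- do.call(rbind, rows)
  lc_r <- if (nrow(tab) >= 2 && stats::sd(tab$n_ref) > 0 &&
              stats::sd(tab$n_auto) > 0)
    stats::cor(tab$n_ref, tab$n_auto) else NA_real_
  structure(list(table = tab, lesion_count_r = lc_r),
            class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report>\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("pooled lesion-count r: %s\n",
              if (is.na(x$lesion_count_r)) "undefined"
              else format(x$lesion_count_r, digits = 4)))
  invisible(x)
}

#' Unmatched-lesion audit
#'
#' Combines the unmatched auto-only and reference-only lesions of a
#' matching into one table of volume, SUVmean and SUVmax per lesion with a
#' `side` column (`"auto_only"`: segmented but absent from the reference;
#' `"ref_only"`: contoured but undetected by the algorithm).
#'
#' @param match result of [match_lesions()].
#' @return data frame with `side`, `label`, `volume_ml`, `suv_mean`,
#'   `suv_max`.
#' @export
unmatched_report <- function(match) {
  pick <- function(df, side) {
    if (!nrow(df)) return(NULL)
    data.frame(side = side, label = df$label, volume_ml = df$volume_ml,
               suv_mean = df$suv_mean, suv_max = df$suv_max)
  }
  out <- rbind(pick(match$unmatched_auto, "auto_only"),
               pick(match$unmatched_ref, "ref_only"))
  if (is.null(out))
    out <- data.frame(side = character(0), label = integer(0),
                      volume_ml = numeric(0), suv_mean = numeric(0),
                      suv_max = numeric(0))
  out
}
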