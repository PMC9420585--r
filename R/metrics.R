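#' Match predicted phase segments against beat truth
#'
#' Boundary-tolerance matching: a truth beat's systole is correct when some
#' predicted systolic segment has both boundaries within `tolerance_s` of
#' the true `(onset, notch)` pair; its diastole likewise against
#' `(notch, next_onset)`; the whole period is correct when both phases are.
#' Each predicted segment may support at most one truth beat (greedy
#' assignment in truth order by nearest onset; ties go to the earlier
#' predicted segment).
#'
#' @param segments predicted intervals (data.frame with `start`, `end`
#'   0-based half-open and `phase`), e.g. from a `segmentation_result`.
#' @param truths list of [beat_truth()] (non-overlapping).
#' @param tolerance_s boundary tolerance in seconds (default 0.05).
#' @param fs sampling rate in Hz.
#' @return data.frame with one row per truth beat: `systole_ok`,
#'   `diastole_ok`, `period_ok`.
#' @export
match_periods <- function(segments, truths, tolerance_s = 0.05, fs = 720) {
  if (tolerance_s <= 0) stop("tolerance_s must be positive")
  if (length(truths) > 1L) {
    on <- vapply(truths, `[[`, integer(1), "onset")
    nx <- vapply(truths, `[[`, integer(1), "next_onset")
    o <- order(on)
    if (any(on[o][-1] < nx[o][-length(nx)])) stop("overlapping truth periods")
    truths <- truths[o]
  }
  tol <- tolerance_s * fs
  # predicted segments as 1-based [start1, end1) bounds per phase
  seg1 <- segments[segments$phase == 1L, , drop = FALSE]
  seg2 <- segments[segments$phase == 2L, , drop = FALSE]
  used1 <- logical(nrow(seg1)); used2 <- logical(nrow(seg2))
  match_phase <- function(seg, used, lo, hi) {
    # both boundaries within tolerance; pick nearest-onset unused segment
    if (nrow(seg) == 0) return(list(ok = FALSE, used = used))
    d_start <- abs(seg$start + 1L - lo)
    cand <- which(!used & d_start <= tol & abs(seg$end + 1L - hi) <= tol)
    if (length(cand) == 0) return(list(ok = FALSE, used = used))
    pick <- cand[order(d_start[cand], cand)][1]
    used[pick] <- TRUE
    list(ok = TRUE, used = used)
  }
  out <- data.frame(systole_ok = logical(length(truths)),
                    diastole_ok = logical(length(truths)),
                    period_ok = logical(length(truths)))
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    m1 <- match_phase(seg1, used1, tr$onset, tr$notch); used1 <- m1$used
    m2 <- match_phase(seg2, used2, tr$notch, tr$next_onset); used2 <- m2$used
    out$systole_ok[i] <- m1$ok
    out$diastole_ok[i] <- m2$ok
    out$period_ok[i] <- m1$ok && m2$ok
  }
  out
}

#' Pool per-beat verdicts into a segmentation report
#'
#' Accuracies are pooled over periods (correct / total), overall and per
#' pulse type. A type with zero periods is reported as `NA`, not 0.
#'
#' @param verdicts list of data.frames from [match_periods()], one per
#'   record.
#' @param types character vector of pulse types, parallel to `verdicts`.
#' @param tolerance_s tolerance used, echoed into the report.
#' @return object of class `seg_report`: `systolic_acc`, `diastolic_acc`,
#'   `whole_period_acc`, `n_periods`, `per_type` (data.frame), and
#'   `tolerance_s`.
#' @export
score <- function(verdicts, types, tolerance_s = 0.05) {
  if (length(verdicts) == 0) stop("no verdicts to score")
  if (length(verdicts) != length(types)) stop("verdicts and types must be parallel")
  all_v <- do.call(rbind, verdicts)
  type_of_period <- rep(types, vapply(verdicts, nrow, integer(1)))
  pool <- function(v) {
    if (nrow(v) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(v$systole_ok), mean(v$diastole_ok), mean(v$period_ok))
  }
  overall <- pool(all_v)
  per_type <- do.call(rbind, lapply(unique(types), function(ty) {
    v <- all_v[type_of_period == ty, , drop = FALSE]
    acc <- pool(v)
    data.frame(pulse_type = ty, systolic_acc = acc[1], diastolic_acc = acc[2],
               whole_period_acc = acc[3], n_periods = nrow(v),
               stringsAsFactors = FALSE)
  }))
  rep <- structure(list(systolic_acc = overall[1], diastolic_acc = overall[2],
                        whole_period_acc = overall[3],
                        n_periods = nrow(all_v), per_type = per_type,
                        tolerance_s = tolerance_s),
                   class = "seg_report")
  # under the conjunction definition the whole period can never beat a phase
  stopifnot(is.na(rep$whole_period_acc) ||
              rep$whole_period_acc <= min(rep$systolic_acc, rep$diastolic_acc) + 1e-12)
  rep
}

#' @export
print.seg_report <- function(x, ...) {
  cat(sprintf("Segmentation report (+/- %g s boundary tolerance, %d periods)\n",
              x$tolerance_s, x$n_periods))
  cat(sprintf("  Systolic phase : %5.1f%%\n", 100 * x$systolic_acc))
  cat(sprintf("  Diastolic phase: %5.1f%%\n", 100 * x$diastolic_acc))
  cat(sprintf("  Whole period   : %5.1f%%\n", 100 * x$whole_period_acc))
  if (nrow(x$per_type) > 1) {
    cat("  Per pulse type:\n")
    for (i in seq_len(nrow(x$per_type))) {
      r <- x$per_type[i, ]
      cat(sprintf("    %-16s sys %5.1f%%  dia %5.1f%%  whole %5.1f%%  (n=%d)\n",
                  r$pulse_type, 100 * r$systolic_acc, 100 * r$diastolic_acc,
                  100 * r$whole_period_acc, r$n_periods))
    }
  }
  invisible(x)
}

#' Serialize a segmentation report to JSON
#'
#' @param report a `seg_report`.
#' @param path output path.
#' @export
write_seg_report <- function(report, path) {
  jsonlite::write_json(
    list(systolic_acc = report$systolic_acc,
         diastolic_acc = report$diastolic_acc,
         whole_period_acc = report$whole_period_acc,
         n_periods = report$n_periods,
         tolerance_s = report$tolerance_s,
         per_type = report$per_type),
    path, auto_unbox = TRUE, digits = 10, na = "null"
  )
  invisible(path)
}

#' Per-sample labelled-region accuracy
#'
#' Fraction of samples whose predicted class equals the truth, restricted to
#' samples where the truth is not background. Undefined (NA, with a
#' warning-free flag) when the truth has no labelled samples.
#'
#' @param pred,truth integer class vectors of equal length.
#' @return a single fraction, or `NA` if the truth is all background.
#' @export
per_sample_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  sup <- truth != 0L
  if (!any(sup)) return(NA_real_)
  mean(pred[sup] == truth[sup])
}
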