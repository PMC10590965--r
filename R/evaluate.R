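#' Score a decontamination run against ground truth
#'
#' Binary evaluation in the standard form for this problem: the positive
#' class is ancient-oral (`aOral`), everything else (Skin, SedimentSoil,
#' ...) is collapsed to negative. Sensitivity is the fraction of true
#' aOral reads retained; specificity the fraction of non-aOral reads
#' removed; `tpr == sensitivity`, `fpr == 1 - specificity`; retainment is
#' the fraction of all input reads retained.
#'
#' @param retained_ids character vector of retained read ids; must be a
#'   subset of the truth table ids.
#' @param truth data.frame with columns `read_id`, `label`.
#' @return one-row data.frame: `sensitivity`, `specificity`, `tpr`,
#'   `fpr`, `retainment`, plus the underlying counts.
#' @export
score_classification <- function(retained_ids, truth) {
  retained_ids <- as.character(retained_ids)
  stray <- setdiff(retained_ids, truth$read_id)
  if (length(stray))
    stop("retained id(s) absent from the truth table: ",
         paste(head(stray, 3), collapse = ", "))
  pos <- truth$label == "aOral"
  ret <- truth$read_id %in% retained_ids
  tp <- sum(pos & ret); fn <- sum(pos & !ret)
  fp <- sum(!pos & ret); tn <- sum(!pos & !ret)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  data.frame(sensitivity = sens, specificity = spec,
             tpr = sens, fpr = 1 - spec,
             retainment = sum(ret) / nrow(truth),
             tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Read retainment
#'
#' Fraction of input reads kept after decontamination — the headline
#' metric when no ground truth exists (real samples).
#'
#' @param n_in number of input reads (> 0).
#' @param n_out number of retained reads, `0 <= n_out <= n_in`.
#' @return `n_out / n_in`.
#' @export
retainment <- function(n_in, n_out) {
  if (!is.numeric(n_in) || n_in <= 0) stop("n_in must be positive")
  if (n_out < 0 || n_out > n_in) stop("n_out must be in [0, n_in]")
  n_out / n_in
}

#' ROC scan over the anchor-proportion threshold
#'
#' Runs pass 1 and the anchor-set construction once (both are
#' tau-independent), then re-thresholds pass 2 for every tau in the grid
#' — exactly equivalent to a full run per tau, at a fraction of the cost.
#' A final row reports the one-pass baseline (retain anchors directly),
#' with `tau = NA` and `mode = "one_pass"`.
#'
#' @param reads read-record data.frame or sequences.
#' @param bf `oral_bloom_filter` or exact [kmer_set()] of trusted k-mers.
#' @param truth ground-truth data.frame (`read_id`, `label`).
#' @param tau_grid thresholds to scan; default 0.1 to 0.9 by 0.1.
#' @param kcfg a [kmer_config()].
#' @return data.frame with one row per tau plus the baseline row:
#'   `tau`, `mode`, `tpr`, `fpr`, `sensitivity`, `specificity`,
#'   `retainment`.
#' @export
roc_scan <- function(reads, bf, truth, tau_grid = seq(0.1, 0.9, by = 0.1),
                     kcfg = kmer_config()) {
  if (!length(tau_grid) || any(tau_grid < 0 | tau_grid > 1))
    stop("tau_grid must be non-empty and within [0, 1]")
  ids <- read_ids(reads)
  p1 <- collect_anchor_set(reads, bf, kcfg)
  st <- .cpp_anchor_stats(read_sequences(reads), p1$anchors$ptr, kcfg$k)
  prop <- ifelse(st$n_valid > 0, st$n_hit / st$n_valid, 0)
  one_row <- function(keep, tau, mode) {
    s <- score_classification(ids[keep], truth)
    data.frame(tau = tau, mode = mode, tpr = s$tpr, fpr = s$fpr,
               sensitivity = s$sensitivity, specificity = s$specificity,
               retainment = s$retainment, stringsAsFactors = FALSE)
  }
  rows <- lapply(tau_grid, function(tau)
    one_row(prop >= tau, tau, "two_pass"))
  rows[[length(rows) + 1L]] <-
    one_row(p1$anchor_flags, NA_real_, "one_pass")
  do.call(rbind, rows)
}

#' Plot a ROC scan
#'
#' FPR against TPR with the threshold grid as a line and the one-pass
#' baseline as a separate point, in base graphics.
#'
#' @param scan data.frame from [roc_scan()].
#' @param ... passed to [plot()].
#' @return the scan, invisibly.
#' @export
plot_roc <- function(scan, ...) {
  two <- scan[scan$mode == "two_pass", ]
  one <- scan[scan$mode == "one_pass", ]
  plot(two$fpr, two$tpr, type = "b", pch = 19,
       xlab = "False positive rate", ylab = "True positive rate",
       xlim = c(0, max(scan$fpr, 0.1)), ylim = c(0, 1), ...)
  text(two$fpr, two$tpr, labels = format(two$tau), pos = 4, cex = 0.7)
  if (nrow(one))
    points(one$fpr, one$tpr, pch = 17, col = "blue")
  invisible(scan)
}
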