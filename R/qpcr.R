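#' A single qPCR measurement
#'
#' Ct values are technical-replicate means on the cycle scale; the reference
#' gene (e.g. GAPDH) controls for input amount.
#'
#' @param sample Sample name.
#' @param target_ct,reference_ct Positive, finite cycle-threshold values.
#' @param group `"treated"` or `"control"` (free-form labels allowed in
#'   [summarize_ddct()]).
#' @return List of class `"qpcr_measurement"`.
#' @export
qpcr_measurement <- function(sample, target_ct, reference_ct,
                             group = "treated") {
  for (v in list(target_ct, reference_ct)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("Ct values must be positive and finite", call. = FALSE)
    }
  }
  structure(list(sample = as.character(sample), target_ct = target_ct,
                 reference_ct = reference_ct, group = as.character(group)),
            class = "qpcr_measurement")
}

as_qpcr <- function(x) {
  if (inherits(x, "qpcr_measurement")) return(x)
  qpcr_measurement(if (!is.null(x$sample)) x$sample else "sample",
                   x$target_ct, x$reference_ct,
                   if (!is.null(x$group)) x$group else "treated")
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes `2^-ddCt` with
#' `ddCt = (target_ct - reference_ct)[treated] -
#'         (target_ct - reference_ct)[control]`,
#' i.e. the fold change of target expression in the treated sample relative
#' to the control, normalized to the reference gene. Assumes perfect (2x)
#' amplification efficiency.
#'
#' @param treated,control [qpcr_measurement()] objects (or lists with
#'   `target_ct` and `reference_ct`).
#' @return Positive fold change; 1 means no change.
#' @examples
#' tr <- qpcr_measurement("edited", 25, 20, "treated")
#' ct <- qpcr_measurement("untreated", 22, 20, "control")
#' ddct_fold_change(tr, ct)  # 2^-3 = 0.125
#' @export
ddct_fold_change <- function(treated, control) {
  treated <- as_qpcr(treated)
  control <- as_qpcr(control)
  ddct <- (treated$target_ct - treated$reference_ct) -
    (control$target_ct - control$reference_ct)
  2^(-ddct)
}

#' Summarize delta-delta-Ct fold changes per group
#'
#' Technical replicates (rows sharing `sample` and `group`) are averaged on
#' the Ct scale first; each biological sample's delta-Ct is then compared to
#' the mean control delta-Ct, and fold changes are summarized per group as
#' mean and sample standard deviation (n-1 denominator) across biological
#' replicates. A group with a single biological replicate reports `NA`
#' (not 0) for the SD.
#'
#' @param measurements Data frame with columns `sample`, `group`,
#'   `target_ct`, `reference_ct`.
#' @param control_group Group label of the untreated reference samples.
#' @return List with `samples` (per-sample fold changes) and `groups`
#'   (per-group `n`, `mean_fold`, `sd_fold`; the control group averages to 1
#'   by construction).
#' @export
summarize_ddct <- function(measurements, control_group = "control") {
  stopifnot(is.data.frame(measurements),
            all(c("sample", "group", "target_ct", "reference_ct") %in%
                  names(measurements)))
  if (any(!is.finite(measurements$target_ct)) ||
      any(!is.finite(measurements$reference_ct))) {
    stop("non-finite Ct value in measurements", call. = FALSE)
  }
  if (!control_group %in% measurements$group) {
    stop("no measurements in control group '", control_group, "'",
         call. = FALSE)
  }
  # technical replicates -> one delta-Ct per biological sample
  key <- interaction(measurements$sample, measurements$group, drop = TRUE)
  dct <- tapply(measurements$target_ct - measurements$reference_ct, key,
                mean)
  meta <- unique(data.frame(sample = measurements$sample,
                            group = measurements$group,
                            stringsAsFactors = FALSE))
  meta$dct <- as.numeric(dct[interaction(meta$sample, meta$group,
                                         drop = TRUE)])
  control_dct <- mean(meta$dct[meta$group == control_group])
  meta$fold <- 2^(-(meta$dct - control_dct))
  groups <- do.call(rbind, lapply(split(meta, meta$group), function(g) {
    data.frame(group = g$group[1L], n = nrow(g), mean_fold = mean(g$fold),
               sd_fold = if (nrow(g) > 1L) stats::sd(g$fold) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  list(samples = meta, groups = groups)
}
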