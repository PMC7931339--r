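# Relative quantification of validation qPCR by the 2^-ddCq method with
# multi-reference normalization and calibrator-cell scaling.

#' Delta-Cq against the mean of reference genes
#'
#' Normalizes a target Cq to the reference panel. The "geometric mean of
#' the reference genes" on the linear expression scale is exactly the
#' arithmetic mean of their Cq values (Cq is a log2 quantity), so the
#' computation stays on the Cq scale throughout: `dCq = cq_target -
#' mean(cq_refs)`.
#'
#' @param cq_target Numeric vector of target Cq values (one per sample).
#' @param cq_refs Numeric vector (single sample), or matrix/data frame
#'   with one row per sample and one column per reference gene.
#' @return Numeric vector of delta-Cq values (cycles).
#' @export
delta_cq <- function(cq_target, cq_refs) {
  if (is.null(dim(cq_refs))) {
    if (length(cq_refs) == 0) stop_fmt("at least one reference gene required")
    if (length(cq_target) == 1) {
      return(cq_target - mean(cq_refs))
    }
    cq_refs <- matrix(cq_refs, nrow = length(cq_target))
  }
  cq_refs <- as.matrix(cq_refs)
  if (ncol(cq_refs) == 0) stop_fmt("at least one reference gene required")
  stopifnot(nrow(cq_refs) == length(cq_target))
  cq_target - rowMeans(cq_refs)
}

#' Build a per-sample delta-Cq table from a long validation Cq table
#'
#' @param records Long data frame with columns `sample_id`, `group`,
#'   `sex`, `target_id`, `cq`; one row per sample-by-assay well.
#' @param ref_targets Character vector of reference-gene `target_id`s
#'   (e.g. `c("RNU24", "RNU6b", "miR-26b")`).
#' @return Data frame with columns `sample_id`, `group`, `sex`,
#'   `target_id`, `delta_cq` for all non-reference targets.
#' @export
delta_cq_table <- function(records, ref_targets) {
  needed <- c("sample_id", "group", "sex", "target_id", "cq")
  stopifnot(is.data.frame(records), all(needed %in% names(records)))
  if (length(ref_targets) == 0) {
    stop_fmt("at least one reference gene required")
  }
  missing_refs <- setdiff(ref_targets, records$target_id)
  if (length(missing_refs) > 0) {
    stop_fmt("reference target(s) absent from records: %s",
             paste(missing_refs, collapse = ", "))
  }
  refs <- records[records$target_id %in% ref_targets, , drop = FALSE]
  ref_mean <- tapply(refs$cq, refs$sample_id, mean)
  tar <- records[!(records$target_id %in% ref_targets), , drop = FALSE]
  if (any(!tar$sample_id %in% names(ref_mean))) {
    stop_fmt("sample(s) without reference wells: %s",
             paste(setdiff(unique(tar$sample_id), names(ref_mean)),
                   collapse = ", "))
  }
  data.frame(sample_id = tar$sample_id, group = tar$group, sex = tar$sex,
             target_id = tar$target_id,
             delta_cq = tar$cq - ref_mean[tar$sample_id],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Relative expression (2^-ddCq) calibrated to one group-sex cell
#'
#' Per-sample relative expression `2^(-delta_cq)` scaled so the
#' calibrator cell (female control offspring by default) averages 100%.
#' With `calibrator = "linear"` (default) the scaling divisor is the
#' arithmetic mean of the calibrator samples' linear quantities, so the
#' calibrator-cell mean relative expression is 100% exactly -- the
#' convention behind tables that print the calibrator as "100 +/- SD".
#' With `calibrator = "log"` the divisor is `2^(-mean(calibrator
#' delta_cq))` (equivalently `ddCq = dCq - mean(calibrator dCq)`); then
#' the calibrator's *geometric* mean is 100% while its arithmetic mean
#' exceeds 100 slightly.
#'
#' @param dcq Data frame from [delta_cq_table()] (columns `sample_id`,
#'   `group`, `sex`, `target_id`, `delta_cq`).
#' @param calibrator_group,calibrator_sex The calibrator cell (defaults
#'   `"Con"`, `"F"`).
#' @param calibrator Averaging scale for the calibrator level,
#'   `"linear"` or `"log"` (see Details).
#' @return A list with `samples` (per-sample `rel_pct`) and `cells`
#'   (per target x group-sex cell: `n`, `mean_pct`, `sd_pct`).
#' @export
relative_expression <- function(dcq, calibrator_group = "Con",
                                calibrator_sex = "F",
                                calibrator = c("linear", "log")) {
  needed <- c("sample_id", "group", "sex", "target_id", "delta_cq")
  stopifnot(is.data.frame(dcq), all(needed %in% names(dcq)))
  stopifnot(all(is.finite(dcq$delta_cq)))
  calibrator <- match.arg(calibrator)
  out <- dcq
  out$rel_pct <- NA_real_
  for (tg in unique(dcq$target_id)) {
    rows <- dcq$target_id == tg
    cal <- rows & dcq$group == calibrator_group & dcq$sex == calibrator_sex
    if (!any(cal)) {
      stop_fmt("empty calibrator cell %s-%s for target %s",
               calibrator_group, calibrator_sex, tg)
    }
    lin <- 2^(-dcq$delta_cq[rows])
    divisor <- if (calibrator == "linear") {
      mean(2^(-dcq$delta_cq[cal]))
    } else {
      2^(-mean(dcq$delta_cq[cal]))
    }
    out$rel_pct[rows] <- lin / divisor * 100
  }
  cell <- interaction(out$group, out$sex, sep = "-", drop = TRUE)
  agg <- aggregate(out$rel_pct,
                   by = list(target_id = out$target_id, cell = cell),
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = stats::sd(v)))
  cells <- data.frame(target_id = agg$target_id,
                      cell = as.character(agg$cell),
                      n = agg$x[, "n"], mean_pct = agg$x[, "mean"],
                      sd_pct = agg$x[, "sd"], stringsAsFactors = FALSE)
  list(samples = out, cells = cells)
}
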