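# Pooled qPCR-array screening: detection calls, M/A values, per-plate
# cyclic loess normalization and the adaptive quantile-regression cutoff.

#' Call detection for each assay in each group
#'
#' A well counts as detected when its Cq is present, not flagged
#' undetermined, and strictly below `cq_max` (the instrument cycle limit;
#' a reaction first crossing threshold at the final cycle is not trusted).
#'
#' @param cq A `cq_matrix` data frame (see [as_cq_matrix()]).
#' @param cq_max Detection threshold in cycles (default 40, the cycle
#'   count of the array protocol).
#' @return A data frame with one row per assay and logical columns
#'   `detected_con`, `detected_n3`, plus `cq_con`, `cq_n3` and `plate`.
#' @export
detect_calls <- function(cq, cq_max = 40) {
  cq <- as_cq_matrix(cq)
  stopifnot(cq_max > 0)
  assays <- unique(cq$assay_id)
  pick <- function(grp, col) {
    m <- match(paste(assays, grp), paste(cq$assay_id, cq$group))
    cq[[col]][m]
  }
  out <- data.frame(assay_id = assays,
                    plate = cq$plate[match(assays, cq$assay_id)],
                    cq_con = pick("Con", "cq"), cq_n3 = pick("N3", "cq"),
                    stringsAsFactors = FALSE)
  undet_con <- pick("Con", "undetermined"); undet_con[is.na(undet_con)] <- TRUE
  undet_n3 <- pick("N3", "undetermined"); undet_n3[is.na(undet_n3)] <- TRUE
  out$detected_con <- !undet_con & !is.na(out$cq_con) & out$cq_con < cq_max
  out$detected_n3 <- !undet_n3 & !is.na(out$cq_n3) & out$cq_n3 < cq_max
  out
}

#' Compute M/A values and the signed fold change for one assay
#'
#' The log2 fold change is defined on the expression scale: since template
#' abundance is proportional to 2^-Cq, `M = cq_con - cq_n3` so that a
#' positive M means higher expression in the intervention (N3) pool.
#' `A = (cq_con + cq_n3)/2` is the abundance axis of the MA plot (in
#' cycles; low A = high abundance). The signed fold change encodes
#' down-regulation as a negative ratio: `2^M` for `M >= 0`, `-2^(-M)`
#' otherwise, so its magnitude is always >= 1.
#'
#' @param cq_con,cq_n3 Numeric vectors of Cq values (cycles) for the
#'   control and intervention pools; recycled to common length.
#' @return A data frame with columns `M`, `A`, `signed_fc`.
#' @export
compute_MA <- function(cq_con, cq_n3) {
  if (any(!is.finite(cq_con)) || any(!is.finite(cq_n3))) {
    stop_fmt(paste0("undefined M: both groups must be detected; route ",
                    "group-unique assays to n3_only/con_only instead"))
  }
  M <- cq_con - cq_n3
  A <- (cq_con + cq_n3) / 2
  signed_fc <- ifelse(M >= 0, 2^M, -2^(-M))
  data.frame(M = M, A = A, signed_fc = signed_fc)
}

#' Per-plate cyclic loess normalization of M on A
#'
#' Removes intensity-dependent bias by fitting a locally weighted
#' regression of M on A separately for assays on each plate and
#' subtracting the fit. With one sample pair per group the cyclic scheme
#' reduces to repeated M-on-A passes; `iterations` fit-subtract passes
#' are applied (3 by default, stopping early once the fitted trend falls
#' below `tol`). Loess is a shrinkage smoother, not a projection, so
#' re-normalizing normalized data is a near-no-op rather than an exact
#' one: the dominant trend is removed in the first pass and later passes
#' touch only smoother-scale noise. Assays with undefined M
#' (group-unique or undetected) pass through as `NA`.
#'
#' @param M,A Numeric vectors (NA allowed, passed through).
#' @param plate Plate labels aligned with `M`; a single value recycles.
#' @param span Loess span (default 0.7).
#' @param degree Local polynomial degree of the loess fits (default 1).
#' @param iterations Number of fit-subtract passes (default 3).
#' @param tol Early-stop tolerance on the fitted trend in cycles
#'   (default 1e-8).
#' @param min_points Minimum defined points per plate for a loess fit
#'   (default 10); plates below it are median-centered with a warning.
#' @return Numeric vector `M_norm` aligned with the input order.
#' @export
cyclic_loess_normalize <- function(M, A, plate = "A", span = 0.7,
                                   degree = 1, iterations = 3, tol = 1e-8,
                                   min_points = 10) {
  stopifnot(length(M) == length(A))
  plate <- rep_len(as.character(plate), length(M))
  M_norm <- as.numeric(M)
  for (pl in unique(plate)) {
    sel <- which(plate == pl & is.finite(M) & is.finite(A))
    if (length(sel) == 0) next
    if (length(sel) < min_points) {
      warning(sprintf(
        "plate %s has %d point(s) < %d: falling back to median-centering",
        pl, length(sel), min_points), call. = FALSE)
      M_norm[sel] <- M[sel] - stats::median(M[sel])
      next
    }
    m <- M[sel]
    for (i in seq_len(iterations)) {
      fit <- stats::fitted(stats::loess(m ~ A[sel], span = span,
                                        degree = degree,
                                        family = "gaussian",
                                        surface = "direct"))
      m <- m - fit
      if (max(abs(fit)) < tol) break
    }
    M_norm[sel] <- m
  }
  M_norm
}

#' Adaptive differential-expression cutoff by polynomial quantile regression
#'
#' Fits quadratic quantile-regression curves of the normalized M on A at
#' the lower and upper quantiles (default 0.05 and 0.95) and flags assays
#' strictly below the lower curve or strictly above the upper curve. The
#' envelope widens where the M scatter widens (typically at high Cq), so
#' the cutoff adapts to abundance-dependent measurement noise instead of
#' using a fixed fold-change line.
#'
#' @param M_norm,A Numeric vectors; pairs with non-finite values are
#'   returned as flag `NA`.
#' @param taus Length-2 vector of quantile levels (default `c(0.05, 0.95)`).
#' @param degree Polynomial degree (default 2).
#' @param tie_tol Numeric tolerance within which a point sitting on a
#'   curve counts as inside (default 1e-8).
#' @return A data frame aligned to the input with columns `q_low`,
#'   `q_high` (curve values at each A) and `flag`
#'   (`"below"`/`"above"`/`"inside"`, `NA` for undefined input).
#' @export
adaptive_cutoff <- function(M_norm, A, taus = c(0.05, 0.95), degree = 2,
                            tie_tol = 1e-8) {
  stopifnot(length(M_norm) == length(A), length(taus) == 2, degree >= 0)
  taus <- sort(taus)
  ok <- is.finite(M_norm) & is.finite(A)
  if (sum(ok) < 10) {
    stop_fmt("adaptive cutoff needs >= 10 points with defined M, got %d",
             sum(ok))
  }
  f_low <- fit_quantile_poly(A[ok], M_norm[ok], tau = taus[1],
                             degree = degree)
  f_high <- fit_quantile_poly(A[ok], M_norm[ok], tau = taus[2],
                              degree = degree)
  q_low <- q_high <- rep(NA_real_, length(A))
  q_low[ok] <- predict(f_low, A[ok])
  q_high[ok] <- predict(f_high, A[ok])
  flag <- rep(NA_character_, length(A))
  flag[ok] <- "inside"
  flag[ok & M_norm < q_low - tie_tol] <- "below"
  flag[ok & M_norm > q_high + tie_tol] <- "above"
  data.frame(q_low = q_low, q_high = q_high, flag = flag,
             stringsAsFactors = FALSE)
}

#' Run the full screening chain and summarize it
#'
#' Detection calls, M/A computation, per-plate loess normalization, the
#' adaptive quantile cutoff, and the Venn/percentage bookkeeping, in one
#' call. Assays detected in exactly one group are classified `n3_only` /
#' `con_only` and count toward the differential total; assays detected in
#' neither group are `undetected` and excluded from every denominator
#' except the number screened.
#'
#' @param cq A `cq_matrix` data frame.
#' @param cq_max Detection threshold in cycles (default 40).
#' @param span Loess span (default 0.7).
#' @param taus Quantile levels for the cutoff (default `c(0.05, 0.95)`).
#' @param degree Quantile-polynomial degree (default 2).
#' @param n_screened Number of assays screened, the denominator for all
#'   percentages (defaults to the number of distinct assays in `cq`).
#' @return A list with elements `screen` (per-assay data frame of M, A,
#'   `M_norm`, curve values, `call`, `signed_fc`, `median_cq`) and `venn`
#'   (a `venn_summary`, see [venn_summary()]).
#' @export
classify_and_summarize <- function(cq, cq_max = 40, span = 0.7,
                                   taus = c(0.05, 0.95), degree = 2,
                                   n_screened = NULL) {
  cq <- as_cq_matrix(cq)
  det <- detect_calls(cq, cq_max = cq_max)
  n_screened <- n_screened %||% nrow(det)

  both <- det$detected_con & det$detected_n3
  M <- A <- signed_fc <- rep(NA_real_, nrow(det))
  if (any(both)) {
    ma <- compute_MA(det$cq_con[both], det$cq_n3[both])
    M[both] <- ma$M; A[both] <- ma$A; signed_fc[both] <- ma$signed_fc
  }
  M_norm <- cyclic_loess_normalize(M, A, det$plate, span = span)
  cut <- adaptive_cutoff(M_norm, A, taus = taus, degree = degree)

  call <- rep("undetected", nrow(det))
  call[both] <- "unchanged"
  call[both & cut$flag %in% "above"] <- "up"
  call[both & cut$flag %in% "below"] <- "down"
  call[det$detected_n3 & !det$detected_con] <- "n3_only"
  call[det$detected_con & !det$detected_n3] <- "con_only"

  median_cq <- vapply(seq_len(nrow(det)), function(i) {
    v <- c(det$cq_con[i], det$cq_n3[i])
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }, numeric(1))

  screen <- data.frame(assay_id = det$assay_id, plate = det$plate,
                       detected_con = det$detected_con,
                       detected_n3 = det$detected_n3,
                       M = M, A = A, M_norm = M_norm,
                       q_low = cut$q_low, q_high = cut$q_high,
                       call = call, signed_fc = signed_fc,
                       median_cq = median_cq, stringsAsFactors = FALSE)

  venn <- venn_summary(n_screened = n_screened,
                       n_det_con = sum(det$detected_con),
                       n_det_n3 = sum(det$detected_n3),
                       n_common = sum(both),
                       n_up = sum(call == "up"),
                       n_down = sum(call == "down"),
                       n_unique_con = sum(call == "con_only"),
                       n_unique_n3 = sum(call == "n3_only"))
  list(screen = screen, venn = venn)
}

#' Venn arithmetic for a two-group detection screen
#'
#' Given detection and differential counts, completes the inclusion-
#' exclusion bookkeeping of a two-pool screen and attaches percentages of
#' the number screened (rounded half-up to one decimal, printed-table
#' style). Counts can come from [classify_and_summarize()] or be supplied
#' directly, e.g. from a published figure.
#'
#' @param n_screened Total assays screened.
#' @param n_det_con,n_det_n3 Assays detected in the control/intervention
#'   pool.
#' @param n_common Assays detected in both pools.
#' @param n_up,n_down Differential assays among the common set
#'   (up/down in intervention vs control).
#' @param n_unique_con,n_unique_n3 Assays detected in exactly one pool
#'   (default: implied by `n_det_* - n_common`).
#' @return A list of class `venn_summary` with all counts, the derived
#'   `n_union`, `n_diff_common`, `n_diff_total`, and a `percentages`
#'   named vector (percent of `n_screened`, one decimal).
#' @examples
#' venn_summary(667, 488, 499, 483, n_up = 12, n_down = 13)
#' @export
venn_summary <- function(n_screened, n_det_con, n_det_n3, n_common,
                         n_up = 0, n_down = 0,
                         n_unique_con = n_det_con - n_common,
                         n_unique_n3 = n_det_n3 - n_common) {
  n_union <- n_det_con + n_det_n3 - n_common
  n_diff_common <- n_up + n_down
  n_diff_total <- n_unique_con + n_unique_n3 + n_diff_common
  counts <- c(n_screened = n_screened, n_det_con = n_det_con,
              n_det_n3 = n_det_n3, n_common = n_common, n_union = n_union,
              n_unique_con = n_unique_con, n_unique_n3 = n_unique_n3,
              n_up = n_up, n_down = n_down, n_diff_common = n_diff_common,
              n_diff_total = n_diff_total)
  if (any(counts < 0) || any(counts > n_screened)) {
    stop_fmt("inconsistent Venn counts: all must lie in [0, n_screened]")
  }
  pct <- round_half_up(100 * counts / n_screened, 1)
  structure(c(as.list(counts), list(percentages = pct)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("Screened assays: %d\n", x$n_screened))
  cat(sprintf("Detected: Con %d (%.1f%%), N3 %d (%.1f%%)\n",
              x$n_det_con, x$percentages[["n_det_con"]],
              x$n_det_n3, x$percentages[["n_det_n3"]]))
  cat(sprintf("Common %d (%.1f%%), union %d (%.1f%%)\n",
              x$n_common, x$percentages[["n_common"]],
              x$n_union, x$percentages[["n_union"]]))
  cat(sprintf(
    "Differential: %d (%.1f%%) = %d N3-only + %d Con-only + %d common\n",
    x$n_diff_total, x$percentages[["n_diff_total"]],
    x$n_unique_n3, x$n_unique_con, x$n_diff_common))
  cat(sprintf("  common differential: %d up + %d down (%.1f%%)\n",
              x$n_up, x$n_down, x$percentages[["n_diff_common"]]))
  invisible(x)
}
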