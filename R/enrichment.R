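# Seed-site enrichment: per-gene binding scores and a one-sided Wilcoxon
# rank-sum comparison of regulated vs background gene scores (a local
# emulation of server-side target-overrepresentation tests).

#' Aggregate seed sites into a per-gene binding score
#'
#' Default score: sum over sites of `w(region) / (1 + mismatches)` with
#' region weights 3'UTR 1.0, CDS 0.5, 5'UTR 0.25 -- perfect 3'UTR sites
#' count fully, mismatched or coding-region sites progressively less.
#'
#' @param sites Data frame of sites for one (miRNA, gene) pair, as
#'   returned by [find_seed_sites()] (needs `region` and `mismatches`).
#' @param region_weights Named numeric weights per region label.
#' @return A single non-negative score (0 for no sites).
#' @export
gene_binding_score <- function(sites,
                               region_weights = c(`3UTR` = 1, CDS = 0.5,
                                                  `5UTR` = 0.25)) {
  if (is.null(sites) || nrow(sites) == 0) return(0)
  bad <- setdiff(unique(sites$region), names(region_weights))
  if (length(bad) > 0) {
    stop_fmt("unknown region label(s): %s", paste(bad, collapse = ", "))
  }
  sum(region_weights[sites$region] / (1 + sites$mismatches))
}

#' One-sided Wilcoxon rank-sum enrichment test
#'
#' Tests whether the binding scores of regulated genes are stochastically
#' greater than the background scores. For pooled sample size
#' `n + m <= exact_max` the p-value is exact: all `choose(n+m, n)` group
#' assignments of the pooled midranks are enumerated. Above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param scores_regulated,scores_background Non-empty numeric vectors.
#' @param exact_max Pooled-size limit for the exact path (default 12).
#' @return A list of class `enrichment_test` with `n_regulated`,
#'   `n_background`, `W` (rank sum of the regulated group), `U`
#'   (Mann-Whitney statistic), `p_one_sided`, `method`
#'   (`"exact"`/`"normal"`), and `degenerate` (TRUE when all pooled
#'   values are identical, in which case p = 1).
#' @examples
#' wilcoxon_enrichment(c(5, 6, 7), c(1, 2, 3))$p_one_sided  # 0.05
#' @export
wilcoxon_enrichment <- function(scores_regulated, scores_background,
                                exact_max = 12) {
  x <- as.numeric(scores_regulated)
  y <- as.numeric(scores_background)
  if (length(x) == 0 || length(y) == 0) {
    stop_fmt("both score vectors must be non-empty")
  }
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  degenerate <- length(unique(pooled)) == 1

  if (degenerate) {
    p <- 1
    method <- "degenerate"
  } else if (N <= exact_max) {
    idx <- utils::combn(N, n)
    perm_W <- colSums(matrix(r[idx], nrow = n))
    p <- mean(perm_W >= W - 1e-9)
    method <- "exact"
  } else {
    mu <- n * m / 2
    ties <- table(r)
    sigma2 <- n * m / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  structure(list(n_regulated = n, n_background = m, W = W, U = U,
                 p_one_sided = p, method = method, degenerate = degenerate),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf(
    "One-sided Wilcoxon rank-sum (regulated > background), %s path\n",
    x$method))
  cat(sprintf("n = %d vs m = %d, W = %g (U = %g), p = %.4g\n",
              x$n_regulated, x$n_background, x$W, x$U, x$p_one_sided))
  invisible(x)
}

#' Count regulated genes with scores over a threshold
#'
#' @param scores Data frame with columns `mirna_id`, `gene_id`, `score`,
#'   `regulated` (logical).
#' @param threshold Non-negative score threshold; strictly greater counts
#'   (ties at the threshold are excluded).
#' @return Named integer vector of counts per miRNA.
#' @export
genes_over_threshold <- function(scores, threshold = 0.5) {
  stopifnot(is.data.frame(scores), threshold >= 0,
            all(c("mirna_id", "gene_id", "score", "regulated") %in%
                  names(scores)))
  sel <- scores[scores$regulated & scores$score > threshold, , drop = FALSE]
  counts <- table(factor(sel$mirna_id, levels = unique(scores$mirna_id)))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Enrichment summary for one miRNA from a gene-score table
#'
#' Convenience wrapper combining [wilcoxon_enrichment()] and
#' [genes_over_threshold()] for one miRNA's rows of a gene-score table.
#'
#' @param scores Data frame with columns `mirna_id`, `gene_id`, `score`,
#'   `regulated`.
#' @param mirna_id The miRNA to summarize.
#' @param threshold Threshold for the over-threshold count.
#' @return A one-row data frame: `mirna_id`, `n_regulated`,
#'   `n_background`, `genes_over_threshold`, `U`, `p_one_sided`.
#' @export
enrichment_result <- function(scores, mirna_id, threshold = 0.5) {
  rows <- scores[scores$mirna_id == mirna_id, , drop = FALSE]
  if (nrow(rows) == 0) stop_fmt("no rows for miRNA %s", mirna_id)
  if (anyDuplicated(rows$gene_id)) {
    stop_fmt("duplicate gene rows for miRNA %s", mirna_id)
  }
  wt <- wilcoxon_enrichment(rows$score[rows$regulated],
                            rows$score[!rows$regulated])
  got <- sum(rows$regulated & rows$score > threshold)
  data.frame(mirna_id = mirna_id, n_regulated = wt$n_regulated,
             n_background = wt$n_background, genes_over_threshold = got,
             U = wt$U, p_one_sided = wt$p_one_sided,
             stringsAsFactors = FALSE)
}
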