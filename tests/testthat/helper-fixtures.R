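# fixtures built in code, shared across test files

# a tiny valid Cq table data frame
toy_cq_df <- function() {
  data.frame(
    assay_id = c("a1", "a1", "a2", "a2"),
    plate = c("A", "A", "B", "B"),
    group = c("Con", "N3", "Con", "N3"),
    cq = c(20.5, 19.5, 33.0, NA),
    undetermined = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

write_toy_cq_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("assay_id\tplate\tgroup\tcq",
               "a1\tA\tCon\t20.5",
               "a1\tA\tN3\t19.5",
               "a2\tB\tCon\t33.0",
               "a2\tB\tN3\tUndetermined"), path)
  path
}

# independent brute-force seed scan: per window, count unpaired positions
# against the seed by direct character comparison (no shared code with
# find_seed_sites beyond the pairing definition)
oracle_seed_scan <- function(mirna_seq, transcript_seq, max_mismatch,
                             allow_wobble = FALSE) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  pairs_ok <- function(a, b) {
    wc <- comp[[a]] == b
    if (allow_wobble) wc || (a == "G" && b == "U") || (a == "U" && b == "G")
    else wc
  }
  seed <- substr(mirna_seq, 2, 8)
  sc <- strsplit(seed, "")[[1]]
  tc <- strsplit(transcript_seq, "")[[1]]
  n <- length(tc)
  out <- list()
  for (s in seq_len(n - 6)) {
    mm <- 0
    for (k in 1:7) {
      # antiparallel: window base k opposes seed base 8-k
      if (!pairs_ok(sc[8 - k], tc[s + k - 1])) mm <- mm + 1
    }
    if (mm <= max_mismatch) out[[length(out) + 1]] <- c(start = s, mm = mm)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), mm = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# exhaustive pinball-loss minimum over all interpolating bases (the LP
# vertex enumeration oracle for polynomial quantile regression)
oracle_quantile_loss <- function(x, y, tau, degree = 2) {
  p <- degree + 1
  X <- outer(x, 0:degree, `^`)
  combos <- utils::combn(length(x), p)
  best <- Inf
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    b <- tryCatch(solve(X[idx, , drop = FALSE], y[idx]),
                  error = function(e) NULL)
    if (is.null(b)) next
    r <- y - drop(X %*% b)
    loss <- sum(r * (tau - (r < 0)))
    if (loss < best) best <- loss
  }
  best
}

# independent Wilcoxon oracle: enumerate group assignments and compute the
# Mann-Whitney U by pairwise comparisons (no rank computation)
oracle_wilcoxon_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n))
  sets <- utils::combn(N, n)
  u_all <- apply(sets, 2, u_of)
  mean(u_all >= u_obs - 1e-9)
}

# four-cell cohort frame with specified cell means and iid noise
cells_frame <- function(n_per_cell = 6, means = c(0, 0, 0, 0), sd = 1) {
  cells <- rep(c("Con-F", "Con-M", "N3-F", "N3-M"), each = n_per_cell)
  data.frame(group = sub("-.*", "", cells), sex = sub(".*-", "", cells),
             y = rep(means, each = n_per_cell) +
               rnorm(length(cells), 0, sd),
             stringsAsFactors = FALSE)
}
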