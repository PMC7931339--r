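test_that("detection requires a present Cq strictly below the cycle limit", {
  cq <- as_cq_matrix(data.frame(
    assay_id = rep(c("a1", "a2", "a3"), each = 2),
    plate = "A", group = rep(c("Con", "N3"), 3),
    cq = c(17.5, 17.5, NA, 22, 40.0, 39.9),
    undetermined = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE))
  det <- detect_calls(cq, cq_max = 40)
  expect_true(det$detected_con[det$assay_id == "a1"])
  expect_false(det$detected_con[det$assay_id == "a2"])  # undetermined
  expect_true(det$detected_n3[det$assay_id == "a2"])
  expect_false(det$detected_con[det$assay_id == "a3"])  # Cq == limit
  expect_true(det$detected_n3[det$assay_id == "a3"])    # just under
})

test_that("M/A values and signed fold change follow the expression scale", {
  r <- compute_MA(c(20, 18), c(20, 17))
  expect_equal(r$M, c(0, 1))
  expect_equal(r$A, c(20, 17.5))
  expect_equal(r$signed_fc, c(1, 2))
  # down-regulated assay: M = -3.5176 encodes as a negative ratio,
  # magnitude 2^3.5176 computed independently
  r2 <- compute_MA(30, 33.5176)
  expect_equal(r2$signed_fc, -(2^3.5176))
  expect_equal(round(r2$signed_fc, 2), -11.45)
  expect_true(all(abs(compute_MA(runif(50, 15, 35),
                                 runif(50, 15, 35))$signed_fc) >= 1))
  expect_error(compute_MA(20, NA), "undefined M")
})

test_that("loess normalization removes a planted intensity trend", {
  set.seed(201)
  A <- runif(400, 14, 36)
  f <- 0.015 * (A - 25)^2 - 0.08 * (A - 25)   # planted quadratic bias
  M <- f + rnorm(400, 0, 0.3)
  M_norm <- cyclic_loess_normalize(M, A)
  refit <- fitted(stats::loess(M_norm ~ A, span = 0.7, degree = 1,
                               surface = "direct"))
  expect_lt(max(abs(refit)), 0.1 * max(abs(f)))
  # constant input is centered to ~0
  expect_lt(max(abs(cyclic_loess_normalize(rep(3.2, 50), runif(50, 14, 36)))),
            1e-6)
})

test_that("plates are normalized independently and NAs pass through", {
  set.seed(202)
  A <- runif(300, 14, 36)
  plate <- rep(c("A", "B"), length.out = 300)
  offset <- ifelse(plate == "A", 1.5, -2)   # plate-specific offsets
  M <- offset + rnorm(300, 0, 0.2)
  M[c(10, 20)] <- NA
  M_norm <- cyclic_loess_normalize(M, A, plate)
  expect_true(all(is.na(M_norm[c(10, 20)])))
  for (pl in c("A", "B")) {
    sel <- plate == pl & !is.na(M_norm)
    expect_lt(abs(mean(M_norm[sel])), 0.1)
  }
  # a nearly empty plate falls back to median centering with a warning
  expect_warning(
    res <- cyclic_loess_normalize(c(M[1:20], 5, 7), c(A[1:20], 20, 30),
                                  c(rep("A", 20), "B", "B")),
    "median-centering")
  expect_equal(res[21:22], c(-1, 1))
})

test_that("re-normalizing normalized data is a near-no-op", {
  set.seed(203)
  A <- runif(500, 14, 36)
  f <- 0.02 * (A - 25)^2 - 0.1 * (A - 25)
  M <- f + rnorm(500)
  M1 <- cyclic_loess_normalize(M, A)
  M2 <- cyclic_loess_normalize(M1, A)
  # loess is a shrinkage smoother, not a projection: exact idempotence is
  # unattainable, but the second pass must touch an order of magnitude
  # less signal than the bias the first pass removed
  expect_lt(max(abs(M2 - M1)), 0.1 * max(abs(f)))
})

test_that("quantile-polynomial fit attains the exhaustive-basis optimum", {
  set.seed(204)
  n <- 50
  x <- runif(n, 0, 10)
  y <- 0.5 * x - 0.03 * x^2 + rnorm(n)
  for (tau in c(0.05, 0.5, 0.95)) {
    f <- fit_quantile_poly(x, y, tau)
    oracle <- oracle_quantile_loss(x, y, tau)
    expect_lt(f$loss, oracle + 1e-8)
    expect_gt(f$loss, oracle - 1e-8)
    # LP coverage bound: at most degree+1 = 3 points sit on the curve
    frac_below <- mean(y < predict(f, x) - 1e-9)
    expect_lte(abs(frac_below - tau), 3 / n)
  }
  expect_error(fit_quantile_poly(rep(1, 50), rnorm(50), 0.5),
               "rank-deficient")
})

test_that("adaptive cutoff flags tails at the expected rate", {
  set.seed(205)
  n <- 500
  A <- runif(n, 14, 36)
  M <- rnorm(n)
  cut <- adaptive_cutoff(M, A)
  frac <- mean(cut$flag != "inside")
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / n))
  # a gross outlier is always flagged above
  M2 <- c(rnorm(200), 10 * sd(rnorm(200)))
  A2 <- runif(201, 14, 36)
  cut2 <- adaptive_cutoff(M2, A2)
  expect_equal(cut2$flag[201], "above")
  # undefined inputs pass through as NA flags
  M3 <- M; M3[1:3] <- NA
  cut3 <- adaptive_cutoff(M3, A)
  expect_true(all(is.na(cut3$flag[1:3])))
})

test_that("classification matches brute-force set arithmetic", {
  set.seed(206)
  sim <- simulate_cq_array(n_assays = 40, base_cq_range = c(20, 37),
                           dropout_midpoint = 34, seed = 99)
  res <- classify_and_summarize(sim$cq)
  det <- detect_calls(sim$cq)
  con_set <- det$assay_id[det$detected_con]
  n3_set <- det$assay_id[det$detected_n3]
  v <- res$venn
  expect_equal(v$n_det_con, length(con_set))
  expect_equal(v$n_det_n3, length(n3_set))
  expect_equal(v$n_common, length(intersect(con_set, n3_set)))
  expect_equal(v$n_union, length(union(con_set, n3_set)))
  expect_equal(v$n_unique_con, length(setdiff(con_set, n3_set)))
  expect_equal(v$n_unique_n3, length(setdiff(n3_set, con_set)))
  expect_equal(v$n_union, v$n_det_con + v$n_det_n3 - v$n_common)
  expect_equal(v$n_diff_total,
               v$n_unique_con + v$n_unique_n3 + v$n_up + v$n_down)
  # group-unique assays get the group-unique calls
  s <- res$screen
  expect_setequal(s$assay_id[s$call == "con_only"], setdiff(con_set, n3_set))
  expect_setequal(s$assay_id[s$call == "n3_only"], setdiff(n3_set, con_set))
})

test_that("sign coherence links call, fold change and the envelope", {
  sim <- simulate_cq_array(
    de_spec = setNames(c(rep(3, 5), rep(-3, 5)),
                       sprintf("assay_%04d", 301:310)), seed = 17)
  s <- classify_and_summarize(sim$cq)$screen
  up <- s$call == "up"
  down <- s$call == "down"
  expect_true(all(s$signed_fc[up] > 1))
  expect_true(all(s$M_norm[up] > s$q_high[up]))
  expect_true(all(s$signed_fc[down] < -1))
  expect_true(all(s$M_norm[down] < s$q_low[down]))
  # median Cq is the median of the assay's defined wells
  i <- match("assay_0301", s$assay_id)
  cqs <- sim$cq$cq[sim$cq$assay_id == "assay_0301"]
  expect_equal(s$median_cq[i], median(cqs, na.rm = TRUE))
})

test_that("power to flag planted effects increases with effect size", {
  set.seed(207)
  assays <- sprintf("assay_%04d", seq(50, 500, by = 50))
  rates <- vapply(c(1, 2, 3), function(effect) {
    hits <- vapply(1:5, function(r) {
      sim <- simulate_cq_array(
        de_spec = setNames(rep(effect, length(assays)), assays),
        seed = 7000 + r)
      s <- classify_and_summarize(sim$cq)$screen
      mean(s$call[match(assays, s$assay_id)] == "up")
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gte(rates[2], 0.9)
})

test_that("identical groups yield no unique and no differential calls", {
  set.seed(208)
  n <- 60
  base <- runif(n, 18, 30)
  cq <- as_cq_matrix(data.frame(
    assay_id = rep(sprintf("a%03d", 1:n), 2),
    plate = rep(rep(c("A", "B"), length.out = n), 2),
    group = rep(c("Con", "N3"), each = n),
    cq = c(base, base), stringsAsFactors = FALSE))
  v <- classify_and_summarize(cq)$venn
  expect_equal(v$n_unique_con, 0)
  expect_equal(v$n_unique_n3, 0)
  expect_equal(v$n_diff_common, 0)  # all M identically 0: no tails
})
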