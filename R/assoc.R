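# Cohort statistical layer: OLS models with and without a sex-by-group
# interaction plus pairwise cell contrasts, unadjusted/adjusted
# association regressions, and banded Spearman correlations.

cell_labels <- c("Con-F", "Con-M", "N3-F", "N3-M")

# linear combination of lm coefficients with t-based two-sided inference
lm_contrast <- function(fit, L) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  est <- drop(L %*% b)
  se <- sqrt(drop(L %*% V %*% L))
  df <- fit$df.residual
  tval <- est / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  c(estimate = est, se = se, t = tval, df = df, p = p)
}

#' Fit treatment-by-sex models with pairwise contrasts
#'
#' Two ordinary least-squares models for one outcome: model A,
#' `y ~ group + sex (+ covariates)`, supplies the main-effect Treatment
#' and Sex p-values; model B adds the `group:sex` interaction and
#' supplies the interaction p-value and the four exploratory pairwise
#' cell contrasts Con-M vs Con-F, N3-M vs N3-F, N3-F vs Con-F and N3-M
#' vs Con-M (t tests on coefficient combinations with the homoscedastic
#' residual variance). Skewed outcomes such as amino-acid levels can be
#' natural-log transformed first via `log_y`.
#'
#' @param data Data frame with columns `group` (`Con`/`N3`), `sex`
#'   (`F`/`M`), the outcome and any covariates. Rows with missing values
#'   in used columns are dropped (listwise).
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate column names (e.g. the
#'   week-15 baseline level), or `NULL`.
#' @param log_y Log-transform the outcome before fitting (default FALSE).
#' @return A list of class `group_sex_fit`: `p_treatment`, `p_sex`,
#'   `p_interaction`, `contrasts` (data frame with estimate, se, df, p
#'   per comparison), `cell_means` (model-B adjusted cell means),
#'   `n`, and the two `lm` fits (`model_main`, `model_interaction`).
#' @export
fit_group_sex_models <- function(data, outcome, covariates = NULL,
                                 log_y = FALSE) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss) > 0) {
      stop_fmt("covariate column(s) missing: %s", paste(miss, collapse = ", "))
    }
  }
  check_levels(data$group, c("Con", "N3"), "group")
  check_levels(data$sex, c("F", "M"), "sex")
  used <- c(outcome, "group", "sex", covariates)
  d <- data[stats::complete.cases(data[, used, drop = FALSE]), used,
            drop = FALSE]
  d$group <- factor(d$group, levels = c("Con", "N3"))
  d$sex <- factor(d$sex, levels = c("F", "M"))
  tab <- table(d$group, d$sex)
  if (any(tab < 2)) {
    i <- which(tab < 2, arr.ind = TRUE)[1, ]
    stop_fmt("cell %s-%s has %d observation(s); >= 2 required per cell",
             rownames(tab)[i[1]], colnames(tab)[i[2]],
             tab[i[1], i[2]])
  }
  y <- d[[outcome]]
  if (log_y) {
    if (any(y <= 0)) stop_fmt("log_y requires a strictly positive outcome")
    y <- log(y)
  }
  d$.y <- y
  fit_a <- stats::lm(stats::reformulate(c("group", "sex", covariates),
                                        response = ".y"), data = d)
  fit_b <- stats::lm(stats::reformulate(c("group * sex", covariates),
                                        response = ".y"), data = d)
  if (any(is.na(stats::coef(fit_a))) || any(is.na(stats::coef(fit_b)))) {
    stop_fmt("singular design for outcome %s", outcome)
  }
  sa <- summary(fit_a)$coefficients
  p_treatment <- sa["groupN3", "Pr(>|t|)"]
  p_sex <- sa["sexM", "Pr(>|t|)"]
  sb <- summary(fit_b)$coefficients
  p_interaction <- sb["groupN3:sexM", "Pr(>|t|)"]

  cn <- names(stats::coef(fit_b))
  L <- function(terms) {
    v <- stats::setNames(numeric(length(cn)), cn)
    v[names(terms)] <- terms
    v
  }
  contrast_defs <- list(
    `Con-M vs Con-F` = c(sexM = 1),
    `N3-M vs N3-F` = c(sexM = 1, `groupN3:sexM` = 1),
    `N3-F vs Con-F` = c(groupN3 = 1),
    `N3-M vs Con-M` = c(groupN3 = 1, `groupN3:sexM` = 1))
  contrasts <- do.call(rbind, lapply(names(contrast_defs), function(nm) {
    cc <- lm_contrast(fit_b, L(contrast_defs[[nm]]))
    data.frame(comparison = nm, estimate = cc["estimate"], se = cc["se"],
               df = cc["df"], p = cc["p"], row.names = NULL,
               stringsAsFactors = FALSE)
  }))

  # model-B adjusted cell means (at covariate means, if any)
  base <- stats::setNames(numeric(length(cn)), cn)
  base["(Intercept)"] <- 1
  if (!is.null(covariates)) {
    for (cv in covariates) base[cv] <- mean(d[[cv]])
  }
  cm <- vapply(cell_labels, function(cl) {
    v <- base
    if (grepl("^N3", cl)) v["groupN3"] <- 1
    if (grepl("M$", cl)) v["sexM"] <- 1
    if (cl == "N3-M") v["groupN3:sexM"] <- 1
    drop(v %*% stats::coef(fit_b))
  }, numeric(1))

  structure(list(outcome = outcome, n = nrow(d), log_y = log_y,
                 p_treatment = p_treatment, p_sex = p_sex,
                 p_interaction = p_interaction, contrasts = contrasts,
                 cell_means = cm, model_main = fit_a,
                 model_interaction = fit_b),
            class = "group_sex_fit")
}

#' @export
print.group_sex_fit <- function(x, ...) {
  cat(sprintf("Outcome: %s%s (n = %d)\n", x$outcome,
              if (x$log_y) " [log-transformed]" else "", x$n))
  cat(sprintf("Treatment p = %.4g, Sex p = %.4g, Interaction p = %.4g\n",
              x$p_treatment, x$p_sex, x$p_interaction))
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Unadjusted and adjusted association regressions
#'
#' Model 1 regresses the outcome on the predictor alone; Model 2 adds the
#' baseline confounders (week-15 maternal taurine and tryptophan), sex
#' and group, and -- for postnatal outcomes -- breastfeeding status at 4
#' months. Inference is OLS with t-based 95% confidence intervals and
#' two-sided p-values; no multiplicity correction is applied. Cases are
#' deleted listwise per model and the per-model n is reported.
#'
#' @param data Data frame; must contain `outcome`, `predictor` and, for
#'   Model 2, columns `p15_tau`, `p15_trp`, `sex`, `group` (and
#'   `breastfeeding` when `postnatal = TRUE`).
#' @param outcome,predictor Column names.
#' @param model 1 (unadjusted) or 2 (adjusted).
#' @param postnatal Outcome measured after birth: adds breastfeeding to
#'   Model 2 (default FALSE).
#' @return One-row data frame: `outcome`, `predictor`, `model`, `n`,
#'   `beta`, `ci_low`, `ci_high`, `p`.
#' @export
association_model <- function(data, outcome, predictor, model = 1,
                              postnatal = FALSE) {
  stopifnot(model %in% c(1, 2), outcome %in% names(data),
            predictor %in% names(data))
  covs <- character(0)
  if (model == 2) {
    covs <- c("p15_tau", "p15_trp", "sex", "group")
    if (postnatal) covs <- c(covs, "breastfeeding")
    miss <- setdiff(covs, names(data))
    if (length(miss) > 0) {
      stop_fmt("Model 2 requires column(s): %s", paste(miss, collapse = ", "))
    }
  }
  used <- c(outcome, predictor, covs)
  d <- data[stats::complete.cases(data[, used, drop = FALSE]), used,
            drop = FALSE]
  n_par <- 2 + length(covs)
  if (nrow(d) < n_par + 2) {
    stop_fmt("insufficient complete cases: need >= %d, have %d",
             n_par + 2, nrow(d))
  }
  for (cv in intersect(c("sex", "group", "breastfeeding"), covs)) {
    d[[cv]] <- factor(d[[cv]])
  }
  fit <- stats::lm(stats::reformulate(c(predictor, covs),
                                      response = outcome), data = d)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, predictor, level = 0.95)
  data.frame(outcome = outcome, predictor = predictor, model = model,
             n = nrow(d), beta = sm[predictor, "Estimate"],
             ci_low = ci[1], ci_high = ci[2],
             p = sm[predictor, "Pr(>|t|)"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Spearman correlation with strength banding
#'
#' Spearman's rho on midranks with a two-sided p-value -- exact (full
#' permutation enumeration of one rank vector) for n <= 9, t
#' approximation otherwise -- and the conventional strength band on
#' |rho|: < 0.4 weak, 0.4 to < 0.7 moderate, >= 0.7 strong.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped (n >= 4
#'   required).
#' @param exact_max Largest n for the exact permutation p (default 9).
#' @return A list: `rs`, `p_two_sided`, `band`, `n`, `method`.
#' @export
spearman_banded <- function(x, y, exact_max = 9) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop_fmt("need >= 4 complete pairs, got %d", n)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop_fmt("undefined correlation: constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    # permute the y ranks against fixed x ranks; rho for each permutation
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- as.vector(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc) /
      denom
    p <- mean(abs(rho_perm) >= abs(rs) - 1e-12)
    method <- "exact"
  } else {
    tval <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
    method <- "t"
  }
  list(rs = rs, p_two_sided = p, band = correlation_band(rs), n = n,
       method = method)
}

#' Band a correlation coefficient by strength
#'
#' The conventional interpretation bands on the absolute coefficient:
#' below 0.4 weak, 0.4 to below 0.7 moderate, 0.7 and above strong.
#'
#' @param rs Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector: `"weak"`, `"moderate"` or `"strong"`.
#' @examples
#' correlation_band(0.43)  # "moderate"
#' @export
correlation_band <- function(rs) {
  stopifnot(all(abs(rs) <= 1 + 1e-12))
  ifelse(abs(rs) < 0.4, "weak", ifelse(abs(rs) < 0.7, "moderate", "strong"))
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    blk <- nrow(sub)
    block <- matrix(0L, blk, n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[row:(row + blk - 1), ] <- block
    row <- row + blk
  }
  out
}
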