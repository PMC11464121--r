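#' Test-retest reliability via the intraclass correlation coefficient
#'
#' One-way random-effects model for technical replicates of the same
#' subject: `y_ij = mu + u_i + e_ij`, `u_i ~ N(0, sigma2_b)`,
#' `e_ij ~ N(0, sigma2_w)`, so
#' `ICC = sigma2_b / (sigma2_b + sigma2_w)` — the share of variance that
#' is stable between subjects rather than replicate noise. Primary
#' estimation is restricted maximum likelihood (`lme4::lmer`); the
#' one-way ANOVA moment estimator
#' `ICC(1,1) = (MSB - MSW) / (MSB + (k0 - 1) MSW)` (with the mean-k
#' correction `k0` for unbalanced designs) serves as cross-check and
#' fallback. Negative variance estimates are truncated at 0 and flagged.
#' When replicates are identical within every subject (`MSW = 0`) the ICC
#' is exactly 1.
#'
#' @param values Numeric vector of predictions (or a data.frame holding
#'   both columns; then give column names in `subjects`).
#' @param subjects Subject/replicate-group id per value, or (when `values`
#'   is a data.frame) `c(value_col, subject_col)`.
#' @param method `"reml"` (default) or `"anova"`.
#' @return List: `icc`, `sigma2_between`, `sigma2_within` (years^2),
#'   `n_subjects`, `n_values`, `replicates_per_subject`, `method`,
#'   `truncated`.
#' @export
estimateICC <- function(values, subjects, method = c("reml", "anova")) {
  method <- match.arg(method)
  if (is.data.frame(values)) {
    stopifnot(length(subjects) == 2L)
    df <- values
    y <- df[[subjects[[1L]]]]
    g <- as.character(df[[subjects[[2L]]]])
  } else {
    y <- values
    g <- as.character(subjects)
  }
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  k <- table(g)
  if (length(k) < 2L) stop("need at least 2 subjects")
  if (all(k < 2L)) stop("every subject has a single replicate; ",
                        "no within-subject variance is estimable")
  a <- length(k)
  N <- length(y)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  msb <- sum(k * (means[names(k)] - gm)^2) / (a - 1)
  msw <- sum((y - means[g])^2) / (N - a)
  k0 <- (N - sum(k^2) / N) / (a - 1)
  anova_est <- function() {
    s2b <- max((msb - msw) / k0, 0)
    list(icc = if (s2b + msw == 0) NA_real_ else s2b / (s2b + msw),
         s2b = s2b, s2w = msw, truncated = (msb - msw) / k0 < 0,
         used = "anova")
  }
  est <- NULL
  if (msw == 0) {
    # replicates identical within every subject: reliability is exactly 1
    est <- list(icc = 1, s2b = msb / k0, s2w = 0, truncated = FALSE,
                used = "degenerate")
  } else if (method == "reml") {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ 1 + (1 | g),
                   data = data.frame(y = y, g = g),
                   REML = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      s2b <- vc$vcov[vc$grp == "g"]
      s2w <- vc$vcov[vc$grp == "Residual"]
      est <- list(icc = s2b / (s2b + s2w), s2b = s2b, s2w = s2w,
                  truncated = FALSE, used = "reml")
    }
  }
  if (is.null(est)) est <- anova_est()
  icc <- min(max(est$icc, 0), 1)
  list(icc = icc, sigma2_between = est$s2b, sigma2_within = est$s2w,
       n_subjects = a, n_values = N,
       replicates_per_subject = as.integer(k),
       method = est$used, truncated = isTRUE(est$truncated) || icc != est$icc)
}
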