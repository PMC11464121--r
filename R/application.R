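#' @importFrom stats lm resid pt qt t.test complete.cases
NULL

#' Predict epigenetic age from a beta matrix
#'
#' Computes `intercept + sum_j coef_j * beta_j` per sample on the
#' response scale, then inverse-transforms to years. Clock CpGs absent
#' from the matrix (or missing in a sample) are imputed at their training
#' means and counted per sample; with imputation disabled (no stored
#' training means) any missing CpG is an error. Predictions are invariant
#' to row and column ordering.
#'
#' @param beta Probes x samples matrix.
#' @param model A [ClockModel-class].
#' @param max_imputed Warn when a sample's imputed fraction exceeds this
#'   (default 0.2).
#' @return Data.frame: `sample_id`, `predicted_age` (years),
#'   `n_missing_probes`, `imputed_fraction`.
#' @export
predictAge <- function(beta, model, max_imputed = 0.2) {
  stopifnot(is(model, "ClockModel"))
  cf <- model@coefficients
  cpgs <- names(cf)
  tm <- model@trainingMeans
  present <- cpgs[cpgs %in% rownames(beta)]
  absent <- setdiff(cpgs, present)
  V <- matrix(NA_real_, length(cpgs), ncol(beta),
              dimnames = list(cpgs, colnames(beta)))
  V[present, ] <- beta[present, , drop = FALSE]
  missing_mask <- is.na(V)
  if (any(missing_mask)) {
    if (!length(tm))
      stop("missing clock CpGs and imputation disabled: ",
           paste(utils::head(unique(rownames(V)[which(missing_mask,
                 arr.ind = TRUE)[, 1L]]), 10), collapse = ", "))
    V[missing_mask] <- tm[cpgs][row(V)[missing_mask]]
  }
  response <- drop(crossprod(V, unname(cf))) + model@intercept
  n_missing <- colSums(missing_mask)
  frac <- if (length(cpgs)) n_missing / length(cpgs) else rep(0, ncol(beta))
  if (any(frac > max_imputed))
    warning(sum(frac > max_imputed), " sample(s) above ",
            round(100 * max_imputed), "% imputed clock CpGs")
  data.frame(sample_id = colnames(beta),
             predicted_age = inverseTransformAge(response, model@transform),
             n_missing_probes = as.integer(n_missing),
             imputed_fraction = unname(frac),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evaluate age predictions
#'
#' Pearson correlation and the *median* absolute error between predicted
#' and chronological age in years — the convention in the epigenetic-clock
#' literature, where "MAE" denotes the median, not the mean, of absolute
#' errors. With zero variance on either side, `r` is undefined (`NA`)
#' while the error is still reported.
#'
#' @param predictions Output of [predictAge()] (or any data.frame with
#'   `sample_id`, `predicted_age`).
#' @param metadata Data.frame with `sample_id`, `age`.
#' @return List: `n`, `pearson_r`, `mae` (years).
#' @export
evaluatePredictions <- function(predictions, metadata) {
  m <- merge(predictions, metadata[, c("sample_id", "age")], by = "sample_id")
  m <- m[complete.cases(m[, c("predicted_age", "age")]), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 paired predictions to evaluate")
  r <- if (sd(m$predicted_age) == 0 || sd(m$age) == 0) NA_real_
       else cor(m$predicted_age, m$age)
  list(n = n, pearson_r = r, mae = median(abs(m$predicted_age - m$age)))
}

#' Epigenetic age acceleration
#'
#' `difference`: predicted minus chronological age, per sample — the
#' deviation of the clock from calendar time. `residual`: residuals of the
#' least-squares regression of predicted on chronological age within the
#' supplied cohort, which removes any systematic offset/slope of the clock
#' in that cohort (residuals sum to zero by construction).
#'
#' @param predictions Output of [predictAge()].
#' @param metadata Data.frame with `sample_id`, `age`.
#' @param method `"difference"` (default) or `"residual"`.
#' @return Data.frame: `sample_id`, `acceleration` (years), `method`.
#' @export
ageAcceleration <- function(predictions, metadata,
                            method = c("difference", "residual")) {
  method <- match.arg(method)
  m <- merge(predictions, metadata, by = "sample_id", sort = FALSE)
  if (anyNA(m$age)) stop("age required for every sample")
  if (method == "difference") {
    acc <- m$predicted_age - m$age
  } else {
    if (nrow(m) < 3L) stop("residual method needs at least 3 samples")
    acc <- unname(resid(lm(predicted_age ~ age, data = m)))
  }
  data.frame(sample_id = m$sample_id, acceleration = acc, method = method,
             stringsAsFactors = FALSE)
}

.t_from_diffs <- function(d, conf = 0.95) {
  n <- length(d)
  est <- mean(d)
  s <- sd(d)
  if (s == 0) {  # degenerate: no within-pair variability
    t <- if (est == 0) 0 else sign(est) * Inf
    p <- if (est == 0) 1 else 0
    ci <- c(est, est)
  } else {
    se <- s / sqrt(n)
    t <- est / se
    p <- 2 * pt(abs(t), n - 1, lower.tail = FALSE)
    ci <- est + c(-1, 1) * qt(1 - (1 - conf) / 2, n - 1) * se
  }
  list(estimate = est, t = t, df = n - 1, p_value = p, conf_low = ci[[1L]],
       conf_high = ci[[2L]])
}

#' Test age acceleration between groups or within pairs
#'
#' `two_group`: Student's two-sample t test with pooled variance (Welch
#' via `welch = TRUE`) of acceleration between the two levels of
#' `group_col`; the estimate is mean(level 2) - mean(level 1) in the
#' levels' sort order. `paired`: one-sample t test on within-donor
#' differences (second timepoint minus first); donors missing either
#' timepoint are an error. Two-sided p-values; 95% CI on the mean
#' difference.
#'
#' @param accel Output of [ageAcceleration()].
#' @param metadata Data.frame with `sample_id` plus the design columns.
#' @param design `"two_group"` or `"paired"`.
#' @param group_col Metadata column with exactly 2 levels (two_group).
#' @param donor_col,time_col Donor and timepoint columns (paired).
#' @param welch Use Welch's unequal-variance t instead of Student's.
#' @return List: `design`, `estimate` (years), `t`, `df`, `p_value`,
#'   `conf_low`, `conf_high`, `groups`, `n`.
#' @export
groupDifferenceTest <- function(accel, metadata,
                                design = c("two_group", "paired"),
                                group_col = "group", donor_col = "donor_id",
                                time_col = "timepoint", welch = FALSE) {
  design <- match.arg(design)
  m <- merge(accel, metadata, by = "sample_id", sort = FALSE)
  if (design == "two_group") {
    g <- as.character(m[[group_col]])
    lev <- sort(unique(g))
    if (length(lev) != 2L)
      stop("two_group design needs exactly 2 group levels, got ",
           length(lev))
    x1 <- m$acceleration[g == lev[[1L]]]
    x2 <- m$acceleration[g == lev[[2L]]]
    if (length(x1) < 2L || length(x2) < 2L)
      stop("each group needs at least 2 samples")
    if (sd(x1) == 0 && sd(x2) == 0) {
      out <- .t_from_diffs(rep(mean(x2) - mean(x1), 2))
      out$df <- length(x1) + length(x2) - 2
    } else {
      tt <- t.test(x2, x1, var.equal = !welch)
      out <- list(estimate = mean(x2) - mean(x1),
                  t = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, conf_low = tt$conf.int[[1L]],
                  conf_high = tt$conf.int[[2L]])
    }
    c(list(design = design, groups = lev,
           n = c(length(x1), length(x2))), out)
  } else {
    d_id <- as.character(m[[donor_col]])
    tp <- as.character(m[[time_col]])
    times <- sort(unique(tp))
    if (length(times) != 2L)
      stop("paired design needs exactly 2 timepoints, got ", length(times))
    wide <- split(m, d_id)
    bad <- names(wide)[!vapply(wide, function(w)
      setequal(w[[time_col]], times) && nrow(w) == 2L, logical(1))]
    if (length(bad))
      stop("unmatched pre/post pairs for donor(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    d <- vapply(wide, function(w)
      w$acceleration[w[[time_col]] == times[[2L]]] -
        w$acceleration[w[[time_col]] == times[[1L]]], numeric(1))
    c(list(design = design, groups = times, n = length(d)),
      .t_from_diffs(d))
  }
}

#' Exclusive intersections of clock CpG sets (UpSet counts)
#'
#' For every non-empty subset of the named sets, counts the elements
#' belonging to exactly that subset (UpSet semantics: the counts partition
#' the union). Also returns the pairwise overlap matrix.
#'
#' @param sets Named list of character vectors (>= 2 sets).
#' @return List: `exclusive` (data.frame `sets`, `degree`, `count`,
#'   empty patterns omitted), `pairwise` (matrix of |A intersect B|),
#'   `union_size`.
#' @export
compareClockCpGSets <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)) || any(names(sets) == ""))
    stop("need >= 2 named sets")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, names(sets)))
  pattern <- apply(memb, 1L, function(z)
    paste(names(sets)[z], collapse = "&"))
  tab <- table(pattern)
  excl <- data.frame(sets = names(tab),
                     degree = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                     count = as.integer(tab), stringsAsFactors = FALSE,
                     row.names = NULL)
  excl <- excl[order(-excl$count, excl$degree, excl$sets), , drop = FALSE]
  rownames(excl) <- NULL
  pairwise <- crossprod(memb)
  list(exclusive = excl, pairwise = pairwise,
       union_size = length(universe))
}
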