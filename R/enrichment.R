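#' @importFrom stats p.adjust phyper fisher.test
NULL

#' Fisher/hypergeometric enrichment of a CpG set in a feature set
#'
#' Builds the 2x2 table `a = |query & feature|`, `b = |query \\ feature|`,
#' `c = |feature \\ query|`, `d = |universe \\ (query | feature)|` after
#' intersecting the feature with the universe, and tests enrichment with
#' the one-sided hypergeometric tail (`P[X >= a]`; Fisher's exact test in
#' the "greater" direction). Fold enrichment is
#' `(a / |query|) / (|feature| / |universe|)`; the odds ratio is the
#' sample `ad/bc` (infinite when `bc = 0`).
#'
#' @param query Character vector of CpG ids (must lie in `universe`).
#' @param feature Character vector of CpG ids (the feature set's members).
#' @param universe Character vector: the background CpG universe.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`
#'   (Fisher's exact two-sided p).
#' @param name Feature name carried into the result.
#' @return One-row data.frame: `feature`, `overlap`, `query_size`,
#'   `feature_size`, `universe_size`, `fold_enrichment`, `odds_ratio`,
#'   `p_value`.
#' @export
fisherEnrichment <- function(query, feature, universe,
                             alternative = c("greater", "two.sided"),
                             name = "feature") {
  alternative <- match.arg(alternative)
  query <- unique(query); universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe))
    stop("query CpGs outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  feature <- unique(feature[feature %in% universe])
  a <- sum(query %in% feature)
  b <- length(query) - a
  cc <- length(feature) - a
  d <- length(universe) - a - b - cc
  p <- if (alternative == "greater") {
    phyper(a - 1, length(feature), length(universe) - length(feature),
           length(query), lower.tail = FALSE)
  } else {
    fisher.test(matrix(c(a, b, cc, d), 2L), alternative = "two.sided")$p.value
  }
  fold <- if (length(query) && length(feature))
    (a / length(query)) / (length(feature) / length(universe)) else NA_real_
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  data.frame(feature = name, overlap = a, query_size = length(query),
             feature_size = length(feature),
             universe_size = length(universe), fold_enrichment = fold,
             odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q(i) = min_{j >= i} m * p(j) / j` over the
#' sorted p-values, mapped back to input order (`stats::p.adjust`,
#' method `"BH"`). q-values are monotone in p and lie in \[0, 1\];
#' with a single test q equals p.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
adjustFdrBH <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Enrichment of a clock's CpG set across feature databases
#'
#' Runs [fisherEnrichment()] for each feature set and applies BH-FDR
#' *within each database group* (TFBS, chromatin states and histone marks
#' are separate families of hypotheses). Feature sets with no members in
#' the universe are skipped with a warning. Results are sorted by q-value
#' then decreasing fold enrichment.
#'
#' @param model A [ClockModel-class], or a character vector of CpG ids.
#' @param features Data.frame with columns `feature`, `probe_id` and
#'   optionally `database` (one row per feature membership), or a named
#'   list of character vectors.
#' @param universe Character vector: the CpG background. Under the
#'   `platform` universe mode this is the full manifest; under
#'   `retro_universe`, the annotated retroelement CpGs only.
#' @param alternative Passed to [fisherEnrichment()].
#' @return Data.frame of per-feature results with `database` and `q_value`.
#' @export
enrichClock <- function(model, features, universe,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  query <- if (is(model, "ClockModel")) clockCpGs(model) else model
  if (is.data.frame(features)) {
    if (!all(c("feature", "probe_id") %in% names(features)))
      stop("feature table needs 'feature' and 'probe_id' columns")
    db <- if ("database" %in% names(features))
      as.character(features$database) else "default"
    sets <- split(as.character(features$probe_id),
                  paste(db, features$feature, sep = "\r"))
  } else {
    if (is.null(names(features))) stop("feature list must be named")
    sets <- features
    names(sets) <- paste("default", names(sets), sep = "\r")
  }
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    key <- strsplit(names(sets)[[i]], "\r", fixed = TRUE)[[1L]]
    memb <- unique(sets[[i]])
    if (!any(memb %in% universe)) {
      warning("feature '", key[[2L]], "' has no members in the universe; ",
              "skipped")
      next
    }
    r <- fisherEnrichment(query, memb, universe, alternative = alternative,
                          name = key[[2L]])
    r$database <- key[[1L]]
    rows[[i]] <- r
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(feature = character(), database = character(),
                      overlap = integer(), fold_enrichment = numeric(),
                      odds_ratio = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (db in unique(out$database)) {
    sel <- out$database == db
    out$q_value[sel] <- adjustFdrBH(out$p_value[sel])
  }
  out <- out[order(out$q_value, -out$fold_enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
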