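#' Split samples into training and test sets
#'
#' Ungrouped: each sample is assigned independently so the training share
#' is `split_fraction` to within one sample. Grouped (`group_by` set,
#' e.g. `"donor_id"` for multi-tissue cohorts): whole donors are assigned
#' to one side — no donor ever straddles the split, which prevents leakage
#' between training and validation — by a greedy pass over donors in
#' seeded random order, each donor going to the side furthest below its
#' quota; the achieved share is then as close to `split_fraction` as donor
#' packing allows (within the largest donor).
#'
#' @param metadata Data.frame with `sample_id` (and `group_by` column when
#'   grouping).
#' @param split_fraction Training share in (0, 1); default 0.8.
#' @param group_by Optional metadata column naming the grouping unit.
#' @param seed Optional integer seed; omit to use the current RNG state.
#' @return List with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
splitSamples <- function(metadata, split_fraction = 0.8, group_by = NULL,
                         seed = NULL) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- as.character(metadata$sample_id)
  n <- length(ids)
  if (is.null(group_by)) {
    n_train <- round(split_fraction * n)
    if (n_train == 0L || n_train == n)
      stop("split leaves one side empty; adjust split_fraction")
    tr <- sample(ids, n_train)
    return(list(train = tr, test = setdiff(ids, tr)))
  }
  if (!group_by %in% names(metadata))
    stop("grouping column '", group_by, "' not in metadata")
  grp <- as.character(metadata[[group_by]])
  if (anyNA(grp))
    stop("grouped split requires '", group_by, "' for every sample")
  sizes <- table(grp)
  if (length(sizes) < 2L)
    stop("grouped split needs at least two groups")
  if (max(sizes) > n * max(split_fraction, 1 - split_fraction))
    stop("a single group exceeds the capacity of one side of the split; ",
         "change split_fraction or ungroup")
  donors <- sample(names(sizes))  # seeded random order
  target_train <- split_fraction * n
  target_test <- (1 - split_fraction) * n
  train_n <- 0; test_n <- 0
  side <- character(length(donors))
  for (i in seq_along(donors)) {
    k <- sizes[[donors[i]]]
    # relative deficit: which side is further below quota
    if ((target_train - train_n) / target_train >=
        (target_test - test_n) / target_test) {
      side[i] <- "train"; train_n <- train_n + k
    } else {
      side[i] <- "test"; test_n <- test_n + k
    }
  }
  tr_donors <- donors[side == "train"]
  list(train = ids[grp %in% tr_donors], test = ids[!grp %in% tr_donors])
}

#' Train a retroelement epigenetic clock
#'
#' End-to-end training pipeline: split samples (optionally grouped by
#' donor), map ages to the response scale, mean-impute missing betas from
#' training means only, fit a cross-validated elastic net, and evaluate on
#' both sides of the split in years (predictions inverse-transformed).
#' The fitted [ClockModel-class] stores the training means of its CpGs for
#' deployment-time imputation.
#'
#' Samples missing more than `max_missing` of the probe universe are
#' excluded with a warning before splitting.
#'
#' @param beta Probes x samples beta matrix (already restricted to the
#'   retroelement universe via [selectRetroProbes()] when appropriate).
#' @param metadata Data.frame with `sample_id` and `age` (years).
#' @param transform [AgeTransform-class] for the response scale.
#' @param alpha,n_folds,n_lambda,lambda_min_ratio,selection_rule
#'   Elastic-net controls, see [fitElasticNetCV()].
#' @param split_fraction,group_by Split controls, see [splitSamples()].
#' @param seed Integer seed fixing split, folds and hence the whole run.
#' @param name,platform Stored in the model.
#' @param max_missing Per-sample missing-probe fraction above which the
#'   sample is excluded (default 0.2).
#' @return List: `model` ([ClockModel-class]), `cv` ([ClockCV-class]),
#'   `train` and `test` evaluation summaries (see
#'   [evaluatePredictions()]), `split`.
#' @export
trainClock <- function(beta, metadata, transform = ageTransform("identity"),
                       alpha = 0.5, n_folds = 10, n_lambda = 100,
                       lambda_min_ratio = 1e-3,
                       selection_rule = c("lambda_min", "lambda_1se"),
                       split_fraction = 0.8, group_by = NULL, seed = 1,
                       name = "retro-clock", platform = "custom",
                       max_missing = 0.2) {
  selection_rule <- match.arg(selection_rule)
  meta <- metadata[match(colnames(beta), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing for samples: ",
         paste(utils::head(setdiff(colnames(beta), metadata$sample_id), 5),
               collapse = ", "))
  if (anyNA(meta$age))
    stop("age required for every sample")
  miss_frac <- colMeans(is.na(beta))
  if (any(miss_frac > max_missing)) {
    bad <- colnames(beta)[miss_frac > max_missing]
    warning("excluding ", length(bad), " sample(s) missing more than ",
            round(100 * max_missing), "% of probes: ",
            paste(utils::head(bad, 5), collapse = ", "))
    beta <- beta[, miss_frac <= max_missing, drop = FALSE]
    meta <- meta[miss_frac <= max_missing, , drop = FALSE]
  }
  set.seed(as.integer(seed))
  split <- splitSamples(meta, split_fraction = split_fraction,
                        group_by = group_by)
  if (!length(split$test)) stop("test set is empty")
  X <- t(beta)
  tr <- rownames(X) %in% split$train
  Xtr <- X[tr, , drop = FALSE]
  train_means <- colMeans(Xtr, na.rm = TRUE)
  usable <- is.finite(train_means)  # drop probes with no training data
  Xtr <- Xtr[, usable, drop = FALSE]
  train_means <- train_means[usable]
  for (j in which(colSums(is.na(Xtr)) > 0L))
    Xtr[is.na(Xtr[, j]), j] <- train_means[[j]]
  y_tr <- transformAge(meta$age[tr], transform)
  fit <- fitElasticNetCV(Xtr, y_tr, alpha = alpha, n_folds = n_folds,
                         n_lambda = n_lambda,
                         lambda_min_ratio = lambda_min_ratio,
                         selection_rule = selection_rule)
  model <- ClockModel(name, platform, fit$intercept, fit$coefficients,
                      transform,
                      trainingMeans = train_means[names(fit$coefficients)],
                      nTrain = sum(tr), seed = seed)
  eval_side <- function(ids) {
    pred <- predictAge(beta[, ids, drop = FALSE], model)
    evaluatePredictions(pred, meta)
  }
  list(model = model, cv = fit$cv,
       train = eval_side(split$train), test = eval_side(split$test),
       split = split)
}

#' Preprocess a retroelement expression count matrix for clock training
#'
#' Library-size normalization to counts-per-million per sample followed by
#' `log(x + 1)`, after removing loci with zero counts in at least
#' `1 - min_prevalence` of samples (all-zero loci always go). The result
#' has the same loci x samples orientation as a beta matrix and feeds
#' [trainClock()] / [fitElasticNetCV()] unchanged.
#'
#' @param counts Loci x samples matrix of non-negative integer counts.
#' @param min_prevalence Minimum fraction of samples with a nonzero count
#'   for a locus to be kept (default 0.1).
#' @return Numeric matrix of log-CPM features (filtered loci x samples).
#' @export
preprocessExpression <- function(counts, min_prevalence = 0.1) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (any(counts != round(counts), na.rm = TRUE))
    stop("counts must be integers")
  zero_frac <- rowMeans(counts == 0)
  keep <- zero_frac < 1 - min_prevalence
  out <- counts[keep, , drop = FALSE]
  lib <- colSums(counts)
  cpm <- sweep(out, 2L, lib / 1e6, "/")
  log(cpm + 1)
}
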