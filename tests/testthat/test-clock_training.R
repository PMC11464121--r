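test_that("elastic net satisfies its subgradient conditions", {
  set.seed(21)
  for (alpha in c(1, 0.5, 0.2)) {
    pr <- randomProblem(60, 30)
    pth <- enetPath(pr$X, pr$y, alpha = alpha, n_lambda = 25)
    for (i in seq_along(pth$lambda)) {
      v <- kktViolation(pr$X, pr$y, pth$a0[i], pth$beta[, i],
                        pth$lambda[i], alpha)
      expect_lt(v, 1e-6)
    }
  }
})

test_that("solution is all-zero at and above lambda_max", {
  set.seed(22)
  for (rep in 1:5) {
    pr <- randomProblem(50, 20)
    # independent closed form for lambda_max (alpha = 1)
    Xc <- sweep(pr$X, 2, colMeans(pr$X))
    Xs <- sweep(Xc, 2, sqrt(colMeans(Xc^2)), "/")
    lmax <- max(abs(drop(crossprod(Xs, pr$y - mean(pr$y))))) / nrow(pr$X)
    pth <- enetPath(pr$X, pr$y, alpha = 1, n_lambda = 10)
    expect_equal(pth$lambda_max, lmax, tolerance = 1e-12)
    for (lam in c(lmax, lmax * 1.5, lmax * 10)) {
      fit <- enetPath(pr$X, pr$y, alpha = 1, lambda = c(lam * 2, lam))
      expect_true(all(fit$beta == 0))
      expect_equal(fit$a0, rep(mean(pr$y), 2))
    }
    expect_true(all(pth$beta[, 1] == 0))  # path starts null
  }
})

test_that("the fitted solution beats random coefficient perturbations", {
  set.seed(23)
  pr <- randomProblem(80, 25)
  alpha <- 0.5
  pth <- enetPath(pr$X, pr$y, alpha = alpha, n_lambda = 20)
  i <- 10
  base <- enetObjective(pr$X, pr$y, pth$a0[i], pth$beta[, i],
                        pth$lambda[i], alpha)
  for (k in 1:1000) {
    d <- rnorm(25, 0, 0.02)
    pert <- enetObjective(pr$X, pr$y, pth$a0[i], pth$beta[, i] + d,
                          pth$lambda[i], alpha)
    expect_gte(pert, base - 1e-10)
  }
})

test_that("path agrees with glmnet where parameterizations coincide", {
  skip_if_not_installed("glmnet")
  set.seed(24)
  pr <- randomProblem(100, 40)
  # lasso: identical objectives, whole path must match
  pth <- enetPath(pr$X, pr$y, alpha = 1, n_lambda = 40)
  g <- glmnet::glmnet(pr$X, pr$y, alpha = 1, lambda = pth$lambda,
                      thresh = 1e-14, maxit = 1e7)
  expect_lt(max(abs(rbind(pth$a0, pth$beta) -
                    rbind(as.numeric(g$a0), as.matrix(g$beta)))), 1e-4)
  # alpha < 1: glmnet's gaussian path rescales the ridge term by the
  # 1/n-sd of y (internal response standardization); map our penalty onto
  # glmnet's (alpha', lambda') and compare at one lambda
  alpha <- 0.5
  p2 <- enetPath(pr$X, pr$y, alpha = alpha, n_lambda = 30)
  sy <- sqrt(mean((pr$y - mean(pr$y))^2))
  lam <- p2$lambda[20]
  L <- lam * alpha + lam * (1 - alpha) * sy
  A <- lam * alpha / L
  g2 <- glmnet::glmnet(pr$X, pr$y, alpha = A,
                       lambda = L * seq(2, 1, length.out = 5),
                       thresh = 1e-14, maxit = 1e7)
  cb <- as.numeric(glmnet::coef.glmnet(g2, s = L, exact = TRUE,
                                       x = pr$X, y = pr$y))
  expect_lt(max(abs(c(p2$a0[20], p2$beta[, 20]) - cb)), 1e-4)
})

test_that("cross-validation selects a lambda on a decreasing path", {
  set.seed(25)
  pr <- randomProblem(60, 20)
  fit <- fitElasticNetCV(pr$X, pr$y, alpha = 0.5, n_folds = 5,
                         n_lambda = 30, seed = 3)
  cv <- fit$cv
  expect_true(all(diff(cv@lambdaPath) < 0))
  expect_true(cv@chosenLambda %in% cv@lambdaPath)
  expect_equal(sort(unique(cv@foldAssignments)), 1:5)
  expect_equal(cv@nonzero[[1]], 0L)
  expect_lt(fit$kkt_violation, 1e-6)
  # lambda_1se picks a penalty at least as large as lambda_min
  f2 <- fitElasticNetCV(pr$X, pr$y, alpha = 0.5, n_folds = 5,
                        n_lambda = 30, selection_rule = "lambda_1se",
                        seed = 3)
  expect_gte(f2$cv@chosenLambda, fit$cv@chosenLambda)
})

test_that("a constant response yields an intercept-only model", {
  set.seed(26)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  expect_warning(fit <- fitElasticNetCV(X, rep(37, 20), n_folds = 4),
                 "constant")
  expect_equal(fit$intercept, 37)
  expect_length(fit$coefficients, 0)
})

test_that("ungrouped splits are disjoint, exhaustive and sized to fraction", {
  md <- data.frame(sample_id = paste0("S", 1:10))
  sp <- splitSamples(md, 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), md$sample_id)
  expect_identical(splitSamples(md, 0.8, seed = 5),
                   splitSamples(md, 0.8, seed = 5))
})

test_that("grouped splits never let a donor straddle the sides", {
  md <- data.frame(sample_id = paste0("S", 1:10),
                   donor_id = rep(c("a", "b", "c"), c(3, 3, 4)))
  sp <- splitSamples(md, 0.8, group_by = "donor_id", seed = 2)
  tr_donors <- unique(md$donor_id[md$sample_id %in% sp$train])
  te_donors <- unique(md$donor_id[md$sample_id %in% sp$test])
  expect_length(intersect(tr_donors, te_donors), 0)

  # randomized instances: no straddling, achieved share close to target
  for (seed in 1:50) {
    set.seed(seed)
    n_donors <- sample(4:12, 1)
    sizes <- sample(1:6, n_donors, replace = TRUE)
    md <- data.frame(
      sample_id = paste0("S", seq_len(sum(sizes))),
      donor_id = rep(paste0("D", seq_len(n_donors)), sizes))
    sp <- splitSamples(md, 0.8, group_by = "donor_id")
    tr_d <- unique(md$donor_id[md$sample_id %in% sp$train])
    te_d <- unique(md$donor_id[md$sample_id %in% sp$test])
    expect_length(intersect(tr_d, te_d), 0)
    expect_setequal(c(sp$train, sp$test), md$sample_id)
    # off target by at most the largest donor
    expect_lte(abs(length(sp$train) - 0.8 * sum(sizes)), max(sizes))
  }
  expect_error(splitSamples(
    data.frame(sample_id = paste0("S", 1:10),
               donor_id = rep(c("a", "b"), c(9, 1))),
    0.8, group_by = "donor_id"), "capacity")
})

test_that("training is deterministic: same seed, byte-identical model files", {
  sim <- simulateMethylationCohort(n_samples = 80, n_probes = 150,
                                   n_causal = 25, seed = 31)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  r1 <- trainClock(sim$beta, sim$metadata, n_folds = 5, n_lambda = 30,
                   seed = 7)
  r2 <- trainClock(sim$beta, sim$metadata, n_folds = 5, n_lambda = 30,
                   seed = 7)
  writeClockModel(r1$model, f1)
  writeClockModel(r2$model, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$split, r2$split)
})

test_that("clocks trained on age-independent methylation do not predict age", {
  rs <- vapply(1:8, function(seed) {
    sim <- simulateMethylationCohort(n_samples = 100, n_probes = 150,
                                     n_causal = 10, effect_scale = 0,
                                     seed = seed)
    res <- suppressWarnings(trainClock(sim$beta, sim$metadata, n_folds = 5,
                                       n_lambda = 30, seed = seed))
    r <- res$test$pearson_r
    if (is.na(r)) 0 else r
  }, numeric(1))
  # held-out correlation should hover around zero, not significantly above
  expect_gt(stats::t.test(rs, alternative = "greater")$p.value, 0.01)
  expect_lt(mean(rs), 0.3)
})

test_that("missing betas are mean-imputed and over-missing samples excluded", {
  sim <- simulateMethylationCohort(n_samples = 60, n_probes = 100,
                                   n_causal = 20, seed = 33)
  beta <- sim$beta
  set.seed(1)
  beta[sample(length(beta), 200)] <- NA      # ~3% missing
  beta[, 1] <- NA                            # sample fully missing
  expect_warning(res <- trainClock(beta, sim$metadata, n_folds = 5,
                                   n_lambda = 25, seed = 1), "excluding")
  expect_s4_class(res$model, "ClockModel")
  expect_true(all(clockCpGs(res$model) %in% names(trainingMeans(res$model))))
})

test_that("expression preprocessing applies CPM then log1p and filters", {
  counts <- matrix(c(100, 0, 50,
                     0,   0, 0,
                     10,  5, 2), 3, 3, byrow = TRUE,
                   dimnames = list(c("L1", "L2", "L3"), c("S1", "S2", "S3")))
  counts["L1", "S1"] <- 100
  counts[, 1] <- c(100, 0, 1e6 - 100)  # library size exactly 1e6
  out <- preprocessExpression(counts, min_prevalence = 0.1)
  expect_false("L2" %in% rownames(out))          # all-zero locus removed
  expect_equal(out["L1", "S1"], log(101))        # CPM 100 -> ln(101)
  expect_error(preprocessExpression(-counts), "non-negative")
  expect_error(preprocessExpression(counts + 0.5), "integers")
})

test_that("prevalence filter drops loci expressed in too few samples", {
  set.seed(4)
  counts <- matrix(rpois(20 * 50, 5), 20, 50,
                   dimnames = list(paste0("L", 1:20), paste0("S", 1:50)))
  counts[1, ] <- 0
  counts[2, ] <- c(rep(3, 4), rep(0, 46))  # present in 8% < 10%
  counts[3, ] <- c(rep(3, 6), rep(0, 44))  # present in 12%
  out <- preprocessExpression(counts, min_prevalence = 0.1)
  expect_false("L1" %in% rownames(out))
  expect_false("L2" %in% rownames(out))
  expect_true("L3" %in% rownames(out))
})
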