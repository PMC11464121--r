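test_that("prediction is the linear predictor, inverse-transformed", {
  m <- tinyClock(c(cg1 = 20, cg2 = -5), intercept = 10)
  beta <- matrix(c(0.5, 0.2), 2, 1, dimnames = list(c("cg1", "cg2"), "S1"))
  p <- predictAge(beta, m)
  expect_equal(p$predicted_age, 10 + 20 * 0.5 - 5 * 0.2)  # 19 years
  expect_equal(p$n_missing_probes, 0L)

  # zero-coefficient clock predicts the intercept everywhere
  m0 <- retroclock:::ClockModel("null", "custom", 42,
    stats::setNames(numeric(), character()), ageTransform("identity"))
  p0 <- predictAge(matrix(runif(6), 2, 3,
    dimnames = list(c("cg1", "cg2"), c("A", "B", "C"))), m0)
  expect_equal(p0$predicted_age, rep(42, 3))

  # log-offset clocks report years
  mt <- tinyClock(c(cg1 = 2), intercept = 3,
                  transform = ageTransform("log_offset", 2))
  pt <- predictAge(matrix(0.5, 1, 1, dimnames = list("cg1", "S1")), mt)
  expect_equal(pt$predicted_age, exp(3 + 1) - 2)
})

test_that("prediction ignores row/column order and is linear in beta", {
  set.seed(41)
  cf <- stats::setNames(rnorm(10), paste0("cg", 1:10))
  m <- tinyClock(cf, intercept = 5)
  beta <- matrix(runif(40), 10, 4,
                 dimnames = list(paste0("cg", 1:10), paste0("S", 1:4)))
  ref <- predictAge(beta, m)
  shuf <- predictAge(beta[sample(10), sample(4)], m)
  expect_equal(shuf$predicted_age[match(ref$sample_id, shuf$sample_id)],
               ref$predicted_age)
  # convex combination of two samples -> convex combination of responses
  lam <- 0.3
  mix <- lam * beta[, 1] + (1 - lam) * beta[, 2]
  pmix <- predictAge(matrix(mix, 10, 1, dimnames = list(names(mix), "M")), m)
  expect_equal(pmix$predicted_age,
               lam * ref$predicted_age[1] + (1 - lam) * ref$predicted_age[2])
})

test_that("missing clock CpGs are imputed at training means and counted", {
  m <- tinyClock(c(cg1 = 10, cg2 = 4), intercept = 0,
                 means = c(cg1 = 0.25, cg2 = 0.75))
  beta <- matrix(0.5, 1, 2, dimnames = list("cg1", c("S1", "S2")))
  expect_warning(p <- predictAge(beta, m), "imputed")
  expect_equal(p$predicted_age, rep(10 * 0.5 + 4 * 0.75, 2))
  expect_equal(p$n_missing_probes, c(1L, 1L))
  expect_equal(p$imputed_fraction, c(0.5, 0.5))
})

test_that("evaluation reports Pearson r and the median absolute error", {
  md <- data.frame(sample_id = c("a", "b", "c"), age = c(10, 20, 34))
  pred <- data.frame(sample_id = c("a", "b", "c"),
                     predicted_age = c(10, 21, 30))
  ev <- evaluatePredictions(pred, md)
  expect_equal(ev$mae, 1)                     # errors 0, 1, 4 -> median 1
  pred2 <- transform(pred, predicted_age = md$age)
  ev2 <- evaluatePredictions(pred2, md)
  expect_equal(ev2$mae, 0)
  expect_equal(ev2$pearson_r, 1)
  # affine predictions: perfect correlation, error = median |age + 7|
  set.seed(42)
  md3 <- data.frame(sample_id = paste0("s", 1:20), age = runif(20, 10, 90))
  pred3 <- data.frame(sample_id = md3$sample_id,
                      predicted_age = 2 * md3$age + 7)
  ev3 <- evaluatePredictions(pred3, md3)
  expect_equal(ev3$pearson_r, 1)
  expect_equal(ev3$mae, median(abs(md3$age + 7)))
  # degenerate: constant predictions have undefined r
  pred4 <- data.frame(sample_id = md3$sample_id, predicted_age = 50)
  ev4 <- evaluatePredictions(pred4, md3)
  expect_true(is.na(ev4$pearson_r))
  expect_equal(ev4$mae, median(abs(50 - md3$age)))
})

test_that("age acceleration: difference is exact, residuals center at zero", {
  md <- data.frame(sample_id = "x", age = 50)
  pred <- data.frame(sample_id = "x", predicted_age = 52.8)
  expect_equal(ageAcceleration(pred, md)$acceleration, 2.8)

  set.seed(43)
  md2 <- data.frame(sample_id = paste0("s", 1:30), age = runif(30, 20, 80))
  pred2 <- data.frame(sample_id = md2$sample_id,
                      predicted_age = md2$age + rnorm(30, 0, 3))
  res <- ageAcceleration(pred2, md2, method = "residual")
  expect_equal(sum(res$acceleration), 0, tolerance = 1e-10)
  # predictions identical to age: both methods give all zeros
  pred3 <- data.frame(sample_id = md2$sample_id, predicted_age = md2$age)
  expect_equal(ageAcceleration(pred3, md2)$acceleration, rep(0, 30))
  expect_equal(ageAcceleration(pred3, md2, "residual")$acceleration,
               rep(0, 30), tolerance = 1e-12)
  expect_error(ageAcceleration(pred[1, ], md[1, ], "residual"), "3")
})

test_that("two-group contrasts match the pooled-variance t test", {
  set.seed(44)
  md <- data.frame(sample_id = paste0("s", 1:40),
                   age = 50, group = rep(c("case", "control"), each = 20))
  acc <- data.frame(sample_id = md$sample_id,
                    acceleration = rnorm(40) + (md$group == "case") * 2,
                    method = "difference")
  out <- groupDifferenceTest(acc, md, "two_group")
  oracle <- t.test(acc$acceleration[md$group == "control"],
                   acc$acceleration[md$group == "case"], var.equal = TRUE)
  expect_equal(out$p_value, oracle$p.value)
  expect_equal(abs(out$t), abs(unname(oracle$statistic)))
  expect_equal(out$df, unname(oracle$parameter))
  expect_equal(out$estimate,
               mean(acc$acceleration[md$group == "control"]) -
                 mean(acc$acceleration[md$group == "case"]))
  w <- groupDifferenceTest(acc, md, "two_group", welch = TRUE)
  expect_lt(w$df, out$df)  # Welch df shrinks under unequal variances
})

test_that("paired contrasts handle degenerate and constant-shift designs", {
  md <- data.frame(sample_id = paste0("s", 1:8),
                   donor_id = rep(paste0("d", 1:4), each = 2),
                   timepoint = rep(c("pre", "post"), 4), age = 50)
  # identical pre/post values: t = 0, p = 1
  acc <- data.frame(sample_id = md$sample_id,
                    acceleration = rep(c(3, 3), 4), method = "difference")
  out <- groupDifferenceTest(acc, md, "paired", time_col = "timepoint")
  expect_equal(out$t, 0)
  expect_equal(out$p_value, 1)
  # constant -1.5 change with zero noise: estimate exact, p -> 0
  # (timepoints sort "post" < "pre", so estimate is pre - post = +1.5
  # when post = pre - 1.5; use explicit ordered labels instead)
  md$timepoint <- rep(c("t0", "t1"), 4)
  pre <- c(5, 6, 7, 8)
  acc2 <- data.frame(sample_id = md$sample_id,
                     acceleration = as.vector(rbind(pre, pre - 1.5)),
                     method = "difference")
  out2 <- groupDifferenceTest(acc2, md, "paired", time_col = "timepoint")
  expect_equal(out2$estimate, -1.5)
  expect_equal(out2$p_value, 0)
  # unmatched pairs are an error naming the donor
  expect_error(groupDifferenceTest(acc2[-1, ], md[-1, ], "paired",
                                   time_col = "timepoint"), "d1")
})

test_that("UpSet counts partition the union and match enumeration", {
  out <- compareClockCpGSets(list(one = c("a", "b", "c"),
                                  two = c("b", "c", "d")))
  ex <- stats::setNames(out$exclusive$count, out$exclusive$sets)
  expect_equal(ex[["one"]], 1L)
  expect_equal(ex[["two"]], 1L)
  expect_equal(ex[["one&two"]], 2L)
  expect_equal(out$pairwise["one", "two"], 2)

  # disjoint sets: all pairwise overlaps zero
  dj <- compareClockCpGSets(list(A = c("x1", "x2"), B = c("y1"),
                                 C = c("z1", "z2", "z3")))
  off_diag <- dj$pairwise[upper.tri(dj$pairwise)]
  expect_true(all(off_diag == 0))

  # random families: exclusive counts sum to |union| and match the
  # brute-force membership-vector enumeration
  set.seed(45)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) sample(paste0("cg", 1:40),
                                           sample(5:25, 1)))
    names(sets) <- paste0("clock", 1:4)
    out <- compareClockCpGSets(sets)
    uni <- unique(unlist(sets))
    expect_equal(sum(out$exclusive$count), length(uni))
    brute <- table(vapply(uni, function(el) {
      paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
            collapse = "&")
    }, character(1)))
    got <- stats::setNames(out$exclusive$count, out$exclusive$sets)
    expect_equal(got[sort(names(brute))],
                 stats::setNames(as.integer(brute[sort(names(brute))]),
                                 sort(names(brute))))
  }
})
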