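test_that("confusion counts follow the four-cell definition", {
  yt <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  yp <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(confusionCounts(yt, yp),
               c(TP = 3L, FP = 2L, TN = 6L, FN = 1L))
  expect_equal(confusionCounts(yt, yt)[c("FP", "FN")], c(FP = 0L, FN = 0L))
  allPos <- confusionCounts(yt, rep(1, 12))
  expect_equal(allPos[["TN"]], 0L)
  expect_equal(allPos[["FN"]], 0L)
  expect_error(confusionCounts(integer(0), integer(0)), "empty")
})

test_that("derived metrics match hand arithmetic", {
  met <- classificationMetrics(c(TP = 3, FP = 2, TN = 6, FN = 1))
  expect_equal(met[["TPR"]], 0.75)
  expect_equal(met[["TNR"]], 0.75)
  expect_equal(met[["BA"]], 0.75)
  expect_equal(met[["FPR"]], 0.25)
  expect_equal(met[["precision"]], 0.6)
  expect_equal(met[["F1"]], 2 * 0.6 * 0.75 / (0.6 + 0.75), tolerance = 1e-9)
  expect_equal(round(met[["F1"]], 6), 0.666667)
  perfect <- classificationMetrics(c(TP = 4, FP = 0, TN = 8, FN = 0))
  expect_true(all(perfect[c("TPR", "TNR", "BA", "precision", "F1")] == 1))
  expect_equal(perfect[["FPR"]], 0)
})

test_that("zero denominators are reported as undefined with a warning", {
  expect_warning(met <- classificationMetrics(c(TP = 0, FP = 2, TN = 6, FN = 0)),
                 "TPR")
  expect_true(is.na(met[["TPR"]]))
  expect_true(is.na(met[["BA"]]))
  expect_false(is.na(met[["TNR"]]))
  expect_error(classificationMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)),
               "zero")
})

test_that("metrics agree with a brute-force recount on random vectors", {
  set.seed(40)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    yt <- rbinom(n, 1, 0.3); yp <- rbinom(n, 1, 0.5)
    counts <- confusionCounts(yt, yp)
    expect_identical(counts, bruteCounts(yt, yp))
    met <- suppressWarnings(classificationMetrics(counts))
    TP <- counts[["TP"]]; FP <- counts[["FP"]]
    TN <- counts[["TN"]]; FN <- counts[["FN"]]
    if (TP + FN > 0) expect_equal(met[["TPR"]], TP / (TP + FN))
    if (FP + TN > 0) {
      expect_equal(met[["TNR"]], TN / (FP + TN))
      expect_equal(met[["FPR"]] + met[["TNR"]], 1)
    }
    if (TP + FN > 0 && FP + TN > 0)
      expect_equal(met[["BA"]], (met[["TPR"]] + met[["TNR"]]) / 2)
  }
})

test_that("balanced accuracy is symmetric under class relabelling", {
  set.seed(41)
  yt <- rbinom(30, 1, 0.25); yp <- rbinom(30, 1, 0.5)
  a <- suppressWarnings(classificationMetrics(confusionCounts(yt, yp)))
  b <- suppressWarnings(classificationMetrics(confusionCounts(1 - yt, 1 - yp)))
  expect_equal(a[["BA"]], b[["BA"]])
})

test_that("rank-based AUC equals the exhaustive pairwise estimator", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(rocAUC(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(rocAUC(runif(5), rep(1, 5)), "both classes")
  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.4))
    sc <- round(runif(n), 2)          # rounding induces ties
    expect_equal(rocAUC(sc, lab), bruteAUC(sc, lab))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(43)
  lab <- c(1, 0, rbinom(18, 1, 0.4))
  sc <- runif(20)
  a <- rocAUC(sc, lab)
  expect_equal(rocAUC(qlogis(sc), lab), a)
  expect_equal(rocAUC(sc^3 + 2 * sc, lab), a)
})

test_that("reports assemble, combine and serialise", {
  set.seed(44)
  yt <- rbinom(40, 1, 0.25); sc <- runif(40)
  rep1 <- evalReport(yt, sc)
  expect_s4_class(rep1, "EvalReport")
  expect_equal(rep1@TP + rep1@FP + rep1@TN + rep1@FN, 40)
  reps <- list(rep1, evalReport(rbinom(40, 1, 0.3), runif(40)))
  cv <- combineReports(reps)
  expect_equal(nrow(cv@perFold), 2)
  expect_equal(cv@metrics[["BA"]],
               mean(c(reps[[1]]@metrics[["BA"]], reps[[2]]@metrics[["BA"]])))
  jpath <- tempfile(fileext = ".json")
  writeReport(cv, jpath)
  back <- jsonlite::read_json(jpath)
  expect_equal(back$counts$TP, cv@TP)
  expect_length(back$perFold, 2)
  cpath <- tempfile(fileext = ".csv")
  writeReport(cv, cpath)
  tab <- read.csv(cpath)
  expect_equal(nrow(tab), 4)                      # 2 folds + mean + sd rows
  expect_equal(tab$fold[3:4], c("mean", "sd"))
})

test_that("pointwise t-test windows behave per construction", {
  set.seed(45)
  n <- 30; T <- 600
  base <- matrix(rnorm(n * T, sd = 0.5), n, T)
  # strictly identical conditions: no windows (all points degenerate)
  expect_warning(ident <- significantWindows(base, base), "zero within-pair")
  expect_equal(nrow(ident), 0)
  # exchangeable noise between conditions: only alpha-level noise windows
  same <- significantWindows(base, matrix(rnorm(n * T, sd = 0.5), n, T))
  expect_lt(sum(same$end - same$start), 0.15 * T)
  # constant +1 uV offset injected into samples 300..499 (0-based 300:500)
  condB <- matrix(rnorm(n * T, sd = 0.5), n, T)
  condA <- condB + matrix(rnorm(n * T, sd = 0.3), n, T)
  condA[, 301:500] <- condA[, 301:500] + 1
  win <- significantWindows(condA, condB, alpha = 0.05)
  expect_gt(nrow(win), 0)
  overlap <- any(win$start < 500 & win$end > 300)
  expect_true(overlap)
  # nesting: windows at alpha = 0.01 lie inside windows at alpha = 0.05
  w01 <- significantWindows(condA, condB, alpha = 0.01)
  if (nrow(w01) > 0) {
    for (i in seq_len(nrow(w01))) {
      inside <- any(win$start <= w01$start[i] & win$end >= w01$end[i])
      expect_true(inside)
    }
  }
})

test_that("zero within-pair variance points are flagged non-significant", {
  n <- 5; T <- 50
  a <- matrix(rnorm(n * T), n, T)
  b <- a
  b[, 1:10] <- b[, 1:10] + rnorm(n * 10)
  b[, 11:50] <- a[, 11:50]          # exact equality: zero variance
  expect_warning(win <- significantWindows(a, b), "zero within-pair")
  expect_true(all(win$end <= 10))
})
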