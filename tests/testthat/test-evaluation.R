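test_that("confusion matrices count truth rows against predicted columns", {
  cm <- confusion(c("NP", "GG", "GG"), c("NP", "NP", "GG"))
  expect_equal(cm["NP", "NP"], 1L)
  expect_equal(cm["GG", "NP"], 1L)
  expect_equal(cm["GG", "GG"], 1L)
  expect_equal(sum(cm), 3L)
  # perfect prediction -> diagonal; single predicted class -> single column
  y <- rep(tissue_classes(), 3)
  expect_equal(confusion(y, y), diag(3L, 8)[1:8, 1:8] * 1L,
               ignore_attr = TRUE)
  cm2 <- confusion(y, rep("NP", 24))
  expect_true(all(cm2[, -1] == 0))
  expect_true(all(cm2[, 1] == 3L))
  expect_error(confusion(c("NP", "GG"), "NP"), class = "lungtex_input_error")
  # row normalization
  nm <- normalize_confusion(cm)
  expect_equal(rowSums(nm)[c("NP", "GG")], c(NP = 1, GG = 1))
})

test_that("metrics match a brute-force one-vs-rest tally on random labels", {
  set.seed(51)
  for (r in 1:20) {
    n <- sample(100:1000, 1)
    truth <- sample(tissue_classes(), n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth,
                   sample(tissue_classes(), n, replace = TRUE))
    cm <- confusion(truth, pred)
    m <- metrics_from_confusion(cm)
    for (cl in tissue_classes()) {
      tp <- sum(truth == cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      fp <- sum(truth != cl & pred == cl)
      tn <- sum(truth != cl & pred != cl)
      row <- m$per_class[m$per_class$class == cl, ]
      expect_equal(row$SN, tp / (tp + fn))
      expect_equal(row$SP, tn / (tn + fp))
      expect_equal(row$GM, sqrt(row$SN * row$SP))
      expect_equal(row$BA, (row$SN + row$SP) / 2)
    }
    expect_equal(m$macro[["SN"]], mean(m$per_class$SN))
  }
})

test_that("macro averages are invariant to class ordering", {
  set.seed(52)
  truth <- sample(tissue_classes(), 400, replace = TRUE)
  pred <- sample(tissue_classes(), 400, replace = TRUE)
  m1 <- metrics_from_confusion(confusion(truth, pred))
  perm <- sample(tissue_classes())
  m2 <- metrics_from_confusion(confusion(truth, pred, classes = perm),
                               classes = perm)
  expect_equal(m1$macro, m2$macro)
})

test_that("a class with no true samples raises a named metric error", {
  truth <- rep("NP", 10)
  pred <- rep("NP", 10)
  err <- expect_error(metrics_from_confusion(confusion(truth, pred)),
                      class = "lungtex_metric_error")
  expect_match(conditionMessage(err), "GG")
})

test_that("macro ROC hits the analytic extremes", {
  set.seed(53)
  n <- 400
  truth <- sample(tissue_classes(), n, replace = TRUE)
  # perfectly separable scores
  S <- matrix(0.01, n, 8)
  S[cbind(1:n, match(truth, tissue_classes()))] <- 1
  r <- macro_roc(S, truth)
  expect_equal(r$auc, 1, tolerance = 1e-6)
  expect_true(all(r$per_class_auc == 1))
  # label-independent scores -> AUC near 1/2
  S2 <- matrix(rexp(n * 8), n, 8)
  r2 <- macro_roc(S2, truth)
  expect_lt(abs(r2$auc - 0.5), 0.07)
  # identical per-class behaviour: macro AUC equals the common per-class AUC
  expect_equal(r$auc, mean(r$per_class_auc), tolerance = 1e-6)
  expect_error(macro_roc(S[truth == "NP", ], truth[truth == "NP"]),
               class = "lungtex_roc_error")
})

test_that("the split construction reproduces the class-count arithmetic", {
  pts <- count_points(clinical_counts())
  plan <- make_split(pts, seed = 3)
  cnt <- plan$counts
  get <- function(cl, col) cnt[cnt$class == cl, col]
  expect_equal(get("RETIC", "n_train"), 600L)
  expect_equal(get("RETIC", "n_test"), 4809L)
  expect_equal(get("GG", "n_train"), 103L)   # ceil(0.75 * 137)
  expect_equal(get("LINSC", "n_train"), 147L)
  expect_equal(get("SUBPL", "n_train"), 310L)
  expect_equal(nrow(plan$roster), 4800L)
  expect_true(all(table(plan$roster$fold) == 480L))
  # train and test are disjoint row sets
  expect_equal(nrow(plan$train) + nrow(plan$test), sum(clinical_counts()))
})

test_that("splits are deterministic and subject hold-outs never leak", {
  counts <- c(NP = 900L, GG = 120L, RETIC = 850L, NOD = 40L, LINSC = 60L,
              SUBPL = 120L, PS = 820L, CL = 810L)
  pts <- count_points(counts, n_subjects = 30L)
  p1 <- make_split(pts, seed = 5, target = 100L, big_class = 200L)
  p2 <- make_split(pts, seed = 5, target = 100L, big_class = 200L)
  expect_identical(p1$roster, p2$roster)
  ps <- make_split(pts, level = "subject", seed = 5, target = 100L,
                   big_class = 200L, n_test_subjects = 6L)
  expect_length(intersect(unique(ps$train$subject_id),
                          unique(ps$test$subject_id)), 0)
  expect_true(all(table(ps$test$label) > 0))
  # a class absent from the annotations is a split error
  expect_error(make_split(pts[pts$label != "NOD", ], seed = 1),
               class = "lungtex_split_error")
})
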