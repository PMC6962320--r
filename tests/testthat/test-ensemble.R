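rand_prob_mat <- function(m, k = 8L) {
  P <- matrix(rexp(m * k), m, k)
  P / rowSums(P)
}

test_that("fusion is the weighted sum of member probabilities", {
  P1 <- c(1, 0, 0, 0, 0, 0, 0, 0)
  P2 <- c(0, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(fuse(rbind(P1, P2), c(0.5, 0.5)),
               c(0.5, 0.5, 0, 0, 0, 0, 0, 0))
  set.seed(41)
  P <- rand_prob_mat(7)
  # one-hot weight selects a single model
  w3 <- numeric(7); w3[3] <- 1
  expect_equal(fuse(P, w3), unname(P[3, ]))
  # all-ones on identical members scales without changing the argmax
  Pid <- matrix(rep(P[1, ], 7), 7, byrow = TRUE)
  expect_equal(fuse(Pid, rep(1, 7)), unname(7 * P[1, ]))
  expect_equal(which.max(fuse(Pid, rep(1, 7))), which.max(P[1, ]))
  expect_error(fuse(P, c(1, 2)), class = "lungtex_input_error")
})

test_that("fusion and decision match brute force on random instances", {
  set.seed(42)
  n_wrong <- 0
  for (r in 1:10000) {
    P <- rand_prob_mat(7)
    w <- runif(7)
    Y <- fuse(P, w)
    Yb <- colSums(sweep(P, 1, w, "*"))
    if (!isTRUE(all.equal(Y, unname(Yb), tolerance = 1e-12)) ||
        decide(Y) != tissue_classes()[which.max(Yb)]) n_wrong <- n_wrong + 1
  }
  expect_equal(n_wrong, 0)
})

test_that("the decision rule breaks exact ties to the lowest class index", {
  y <- c(0.3, 0.3, 0.1, 0.1, 0.05, 0.05, 0.05, 0.05)
  expect_equal(as.character(decide(y)), "NP")
  y2 <- c(0, 0.2, 0.5, 0.1, 0, 0, 0.1, 0.1)
  expect_equal(as.character(decide(y2)), "RETIC")
  # invariant to positive rescaling of the weights
  set.seed(43)
  P <- rand_prob_mat(7)
  w <- runif(7)
  expect_equal(decide(fuse(P, w)), decide(fuse(P, 3.7 * w)))
})

test_that("majority vote uses counts, then summed probability, then index", {
  expect_equal(as.character(majority_vote(c("NP", "NP", "NP", "NP", "GG",
                                            "GG", "GG"))), "NP")
  expect_equal(as.character(majority_vote(rep("CL", 7))), "CL")
  # 7 distinct votes: the class with the highest summed probability wins
  P <- matrix(0.01, 7, 8)
  for (i in 1:7) P[i, i] <- 0.5
  P[, 5] <- P[, 5] + 0.2
  votes <- 1:7
  expect_equal(as.character(majority_vote(votes, P)), "LINSC")  # class 5
  # counting oracle on random vote sets (no probabilities)
  set.seed(44)
  for (r in 1:200) {
    v <- sample(1:8, 7, replace = TRUE)
    counts <- tabulate(v, 8)
    expect_equal(match(as.character(majority_vote(v)), tissue_classes()),
                 which(counts == max(counts))[1])
  }
})

test_that("fusion is permutation-equivariant in (models, weights)", {
  set.seed(45)
  P <- rand_prob_mat(7)
  w <- runif(7)
  perm <- sample(7)
  expect_equal(fuse(P, w), fuse(P[perm, ], w[perm]))
})

test_that("weight search honours its bookkeeping and determinism contracts", {
  set.seed(46)
  N <- 60L
  labels <- sample(1:8, N, replace = TRUE)
  probs <- lapply(1:3, function(i) {
    P <- rand_prob_mat(N)
    P[cbind(1:N, labels)] <- P[cbind(1:N, labels)] + 0.3 * i
    P / rowSums(P)
  })
  cfg <- search_config(n_trials = 30, seed = 9)
  ew <- optimize_weights(probs, labels, cfg)
  expect_equal(nrow(ew$history), 30L)
  expect_equal(ew$score, min(ew$history$score))
  ew2 <- optimize_weights(probs, labels, cfg)
  expect_identical(ew$history, ew2$history)
  # degenerate: one model duplicated - every weight vector scores the same
  dup <- list(probs[[1]], probs[[1]], probs[[1]])
  ewd <- optimize_weights(dup, labels, search_config(n_trials = 10, seed = 2))
  expect_equal(length(unique(round(ewd$history$score, 12))), 1L)
  one <- lungtex:::ensemble_objective(c(1, 0, 0), dup, labels, "ba")
  expect_equal(ewd$score, one)
  expect_error(search_config(n_trials = 0), class = "lungtex_config_error")
  expect_error(search_config(gamma = 1), class = "lungtex_config_error")
})

test_that("random search and majority-vote methods run and are recorded", {
  set.seed(47)
  N <- 40L
  labels <- rep(1:8, 5)
  probs <- lapply(1:2, function(i) {
    P <- rand_prob_mat(N)
    P[cbind(1:N, labels)] <- P[cbind(1:N, labels)] + 0.5
    P / rowSums(P)
  })
  rs <- optimize_weights(probs, labels, search_config("RS", n_trials = 25,
                                                      seed = 3))
  expect_equal(rs$method, "RS")
  expect_equal(nrow(rs$history), 25L)
  mv <- optimize_weights(probs, labels, search_config("MVR", seed = 3))
  expect_equal(mv$method, "MVR")
  expect_true(is.finite(mv$score))
  bo <- optimize_weights(probs, labels, search_config("BO", n_trials = 15,
                                                      seed = 3))
  expect_equal(bo$method, "BO")
})

test_that("weights round-trip through the JSON side file", {
  set.seed(48)
  labels <- rep(1:8, 3)
  probs <- list(rand_prob_mat(24), rand_prob_mat(24))
  ew <- optimize_weights(probs, labels, search_config(n_trials = 12, seed = 5))
  path <- tempfile(fileext = ".json")
  save_weights(ew, path)
  back <- load_weights(path)
  expect_equal(back$w, ew$w, tolerance = 1e-12)
  expect_equal(back$method, ew$method)
})
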