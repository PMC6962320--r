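#' Weighted fusion of per-model probability outputs
#'
#' The ensemble output for a sample is the weighted sum of the individual
#' networks' probability vectors, `Y[c] = sum_i w_i * P_i[c]`. The fused
#' score vector is deliberately *not* renormalized (its sum is `sum(w)`);
#' the decision rule is scale-invariant.
#'
#' @param probs the per-model probabilities for one sample or a batch:
#'   either an `n_models x n_classes` matrix (one sample) or an
#'   `n_models x n_classes x N` array / list of per-model `N x n_classes`
#'   matrices.
#' @param w numeric vector of `n_models` nonnegative fusion weights.
#' @return For one sample, the fused length-8 score vector; for a batch an
#'   `N x 8` matrix.
#' @examples
#' P <- rbind(c(1, 0, 0, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0, 0, 0))
#' fuse(P, c(0.5, 0.5))   # 0.5, 0.5, 0, ...
#' @export
fuse <- function(probs, w) {
  if (is.list(probs)) {
    if (length(probs) != length(w))
      stop_lungtex("length(w) must equal the number of models",
                   "lungtex_input_error")
    out <- 0
    for (i in seq_along(probs)) out <- out + w[i] * probs[[i]]
    return(out)
  }
  d <- dim(probs)
  if (length(d) == 2L) {
    if (d[1] != length(w))
      stop_lungtex("length(w) must equal nrow(probs)", "lungtex_input_error")
    # ordered accumulation (i = 1..m), reproducible against a scalar oracle
    Y <- numeric(d[2])
    for (i in seq_len(d[1])) Y <- Y + w[i] * probs[i, ]
    as.numeric(Y)
  } else if (length(d) == 3L) {
    if (d[1] != length(w))
      stop_lungtex("length(w) must equal dim(probs)[1]", "lungtex_input_error")
    Y <- matrix(0, d[3], d[2])
    for (i in seq_len(d[1])) Y <- Y + w[i] * t(probs[i, , ])
    Y
  } else {
    stop_lungtex("probs must be a matrix, 3D array or list of matrices",
                 "lungtex_input_error")
  }
}

#' Decision rule on fused scores
#'
#' The predicted class has the highest fused score; exact ties break to the
#' lowest class index (the canonical [tissue_classes()] order). Invariant to
#' positive rescaling of the weights.
#'
#' @param Y fused score vector (length 8) or `N x 8` matrix.
#' @return A factor over the 8 tissue codes.
#' @export
decide <- function(Y) {
  if (is.matrix(Y)) idx <- apply(Y, 1, which.max)
  else idx <- which.max(Y)
  factor(tissue_classes()[idx], levels = tissue_classes())
}

#' Majority vote over per-model predictions
#'
#' The modal predicted class across models; ties between equally voted
#' classes break by the highest summed probability among the tied classes,
#' then by lowest class index.
#'
#' @param votes per-model predicted classes for one sample (character /
#'   factor / integer vector of length `n_models`).
#' @param probs optional `n_models x n_classes` probability matrix used for
#'   tie-breaking.
#' @return The winning class as a factor over the 8 codes.
#' @export
majority_vote <- function(votes, probs = NULL) {
  cls <- tissue_classes()
  if (is.factor(votes) || is.character(votes)) idx <- match(as.character(votes), cls)
  else idx <- as.integer(votes)
  counts <- tabulate(idx, nbins = length(cls))
  top <- which(counts == max(counts))
  if (length(top) > 1L && !is.null(probs)) {
    sums <- colSums(probs)[top]
    top <- top[sums == max(sums)]
  }
  factor(cls[min(top)], levels = cls)
}

#' Ensemble weight search configuration
#'
#' @param method `"TPE"` (Tree-structured Parzen Estimator, the default),
#'   `"RS"` (uniform random search), `"BO"` or `"MVR"` (majority voting,
#'   no weights). The Bayesian-optimization variant is executed with the
#'   TPE engine (the two samplers are treated as interchangeable here;
#'   the method name is recorded in the search metadata).
#' @param n_trials number of objective evaluations (>= 1).
#' @param gamma TPE quantile splitting observed scores into "good" and
#'   "bad" sets (0 < gamma < 1).
#' @param n_candidates candidate draws per TPE trial.
#' @param n_startup trials sampled uniformly before the TPE model kicks in
#'   (the deterministic seeds - uniform weights and every one-hot vector -
#'   count towards these).
#' @param objective `"ba"` (1 - macro balanced accuracy, default), `"gm"`
#'   (1 - macro geometric mean) or `"xent"` (cross-entropy of renormalized
#'   fused scores).
#' @param seed RNG seed; fixed seed reproduces the full trial history.
#' @export
search_config <- function(method = c("TPE", "RS", "BO", "MVR"),
                          n_trials = 200L, gamma = 0.25, n_candidates = 24L,
                          n_startup = 10L,
                          objective = c("ba", "gm", "xent"), seed = 1L) {
  method <- match.arg(method)
  objective <- match.arg(objective)
  if (n_trials < 1L)
    stop_lungtex("n_trials must be >= 1", "lungtex_config_error")
  if (gamma <= 0 || gamma >= 1)
    stop_lungtex("gamma must lie in (0, 1)", "lungtex_config_error")
  structure(list(method = method, n_trials = as.integer(n_trials),
                 gamma = gamma, n_candidates = as.integer(n_candidates),
                 n_startup = as.integer(n_startup), objective = objective,
                 seed = seed),
            class = "search_config")
}

# Objective of a weight vector on held-out predictions.
ensemble_objective <- function(w, probs, labels, objective = "ba") {
  Y <- fuse(probs, w)
  if (objective == "xent") {
    Yn <- Y / pmax(rowSums(Y), 1e-12)
    return(-mean(log(pmax(Yn[cbind(seq_along(labels), labels)], 1e-12))))
  }
  pred <- decide(Y)
  truth <- factor(tissue_classes()[labels], levels = tissue_classes())
  keep <- levels(truth)[table(truth) > 0]
  cm <- confusion(truth, pred)
  m <- metrics_from_confusion(cm, classes = keep)
  1 - if (objective == "gm") m$macro[["GM"]] else m$macro[["BA"]]
}

#' Optimize ensemble fusion weights on held-out predictions
#'
#' Searches the weight hypercube `[0, 1]^m` for the vector minimizing the
#' ensemble objective (default: 1 - macro balanced accuracy) on
#' precomputed validation predictions - the member networks are never
#' retrained inside the search. The TPE sampler models `p(w | score)` with
#' two per-dimension Parzen (Gaussian kernel) density estimators, split at
#' the `gamma` quantile of observed scores, and at each trial evaluates the
#' candidate maximizing the good/bad density ratio. The trial history is
#' seeded with the uniform-weight vector and every one-hot vector, so the
#' returned optimum can never be worse than the best single model.
#'
#' @param probs per-model validation predictions: `n_models x n_classes x N`
#'   array or list of `N x n_classes` matrices.
#' @param labels integer true classes (1..8) of the N validation samples.
#' @param config a [search_config].
#' @return An `ensemble_weights` object: list with `w` (named weights),
#'   `score` (best objective), `method`, `history` (data.frame of every
#'   trial: `trial`, `w1..wm`, `score`), `config`.
#' @export
optimize_weights <- function(probs, labels, config = search_config()) {
  if (is.list(probs)) {
    m <- length(probs)
    nms <- names(probs) %||% paste0("model", seq_len(m))
  } else {
    m <- dim(probs)[1]
    nms <- dimnames(probs)[[1]] %||% paste0("model", seq_len(m))
  }
  labels <- as.integer(labels)
  obj <- function(w) ensemble_objective(w, probs, labels, config$objective)

  if (config$method == "MVR") {
    votes_score <- mvr_objective(probs, labels, config$objective)
    w <- rep(1, m); names(w) <- nms
    return(structure(list(w = w, score = votes_score, method = "MVR",
                          history = data.frame(), config = config),
                     class = "ensemble_weights"))
  }

  with_seed(config$seed, {
    W <- matrix(NA_real_, nrow = 0, ncol = m)
    scores <- numeric(0)
    propose <- function(t) {
      # deterministic seeds first: uniform, then one-hot per model
      if (t == 1L) return(rep(0.5, m))
      if (t <= m + 1L) { w <- numeric(m); w[t - 1L] <- 1; return(w) }
      if (config$method == "RS" || t <= max(config$n_startup, m + 1L))
        return(runif(m))
      tpe_propose(W, scores, config)
    }
    for (t in seq_len(config$n_trials)) {
      w <- propose(t)
      s <- obj(w)
      W <- rbind(W, w)
      scores <- c(scores, s)
    }
    best <- which.min(scores)
    w <- W[best, ]
    names(w) <- nms
    hist <- data.frame(trial = seq_along(scores), W, score = scores)
    names(hist) <- c("trial", paste0("w", seq_len(m)), "score")
    structure(list(w = w, score = scores[best],
                   method = config$method, history = hist, config = config),
              class = "ensemble_weights")
  })
}

mvr_objective <- function(probs, labels, objective) {
  if (is.list(probs)) {
    N <- nrow(probs[[1]])
    getP <- function(n) do.call(rbind, lapply(probs, function(p) p[n, ]))
  } else {
    N <- dim(probs)[3]
    getP <- function(n) probs[, , n]
  }
  pred <- factor(character(N), levels = tissue_classes())
  for (n in seq_len(N)) {
    P <- getP(n)
    votes <- apply(P, 1, which.max)
    pred[n] <- majority_vote(votes, P)
  }
  truth <- factor(tissue_classes()[labels], levels = tissue_classes())
  keep <- levels(truth)[table(truth) > 0]
  mtr <- metrics_from_confusion(confusion(truth, pred), classes = keep)
  1 - if (objective == "gm") mtr$macro[["GM"]] else mtr$macro[["BA"]]
}

# One TPE proposal: split observations at the gamma quantile, fit
# per-dimension truncated Gaussian Parzen estimators to each set, draw
# candidates from the "good" density and keep the best l(w)/g(w) ratio.
tpe_propose <- function(W, scores, config) {
  n <- length(scores)
  n_good <- max(1L, ceiling(config$gamma * n))
  ord <- order(scores)
  good <- W[ord[seq_len(n_good)], , drop = FALSE]
  bad <- W[ord[-seq_len(n_good)], , drop = FALSE]
  if (nrow(bad) == 0L) bad <- W
  m <- ncol(W)
  bw <- function(x) max(1.06 * stats::sd(x) * length(x)^(-1/5), 0.05)
  logdens <- function(x, centers, h) {
    # Parzen mixture of N(center, h) truncated to [0,1]
    comp <- vapply(centers, function(c0) {
      stats::dnorm(x, c0, h) /
        max(stats::pnorm(1, c0, h) - stats::pnorm(0, c0, h), 1e-12)
    }, numeric(length(x)))
    if (is.null(dim(comp))) comp <- matrix(comp, nrow = length(x))
    log(pmax(rowMeans(comp), 1e-300))
  }
  hg <- apply(good, 2, bw)
  hb <- apply(bad, 2, bw)
  cand <- matrix(NA_real_, config$n_candidates, m)
  for (d in seq_len(m)) {
    centers <- good[sample.int(nrow(good), config$n_candidates, replace = TRUE), d]
    x <- rnorm(config$n_candidates, centers, hg[d])
    cand[, d] <- pmin(pmax(x, 0), 1)
  }
  ratio <- numeric(config$n_candidates)
  for (d in seq_len(m)) {
    ratio <- ratio + logdens(cand[, d], good[, d], hg[d]) -
      logdens(cand[, d], bad[, d], hb[d])
  }
  cand[which.max(ratio), ]
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat(sprintf("<ensemble_weights> method %s, objective score %.4f\n",
              x$method, x$score))
  print(round(x$w, 3))
  invisible(x)
}

#' Save / load ensemble weights
#'
#' Weights are stored as JSON `{model_name: weight}` plus the search
#' metadata (method, seed, trials, objective, best score).
#'
#' @param ew an `ensemble_weights` object.
#' @param path JSON file path.
#' @export
save_weights <- function(ew, path) {
  stopifnot(inherits(ew, "ensemble_weights"))
  jsonlite::write_json(list(
    weights = as.list(ew$w), method = ew$method, score = ew$score,
    n_trials = ew$config$n_trials, objective = ew$config$objective,
    seed = ew$config$seed), path, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- search_config(method = j$method, n_trials = j$n_trials,
                       objective = j$objective, seed = j$seed)
  structure(list(w = unlist(j$weights), score = j$score, method = j$method,
                 history = data.frame(), config = cfg),
            class = "ensemble_weights")
}

#' Bundle trained models and weights into an ensemble classifier
#'
#' @param models named list of `lungtex_model`s (weight order).
#' @param w an `ensemble_weights` object or a bare numeric vector.
#' @return A `lungtex_ensemble` usable with [predict_proba_ensemble()] and
#'   [classify_scan()].
#' @export
ensemble_classifier <- function(models, w) {
  if (inherits(w, "ensemble_weights")) w <- w$w
  if (length(models) != length(w))
    stop_lungtex("one weight per model required", "lungtex_input_error")
  structure(list(models = models, w = as.numeric(w)),
            class = "lungtex_ensemble")
}

#' Fused ensemble scores for a set of samples
#'
#' Runs every member network on its own input representation and fuses the
#' probability outputs with the ensemble weights.
#'
#' @param ens a `lungtex_ensemble`.
#' @param sample_sets either a list of per-model sample lists / input
#'   tensors (one per member, in weight order) or a single list of
#'   multi-mode extractions per point (see [extract_point_inputs()]).
#' @return `N x 8` matrix of fused (unnormalized) scores.
#' @export
predict_proba_ensemble <- function(ens, sample_sets) {
  stopifnot(inherits(ens, "lungtex_ensemble"))
  P <- lapply(seq_along(ens$models), function(i)
    predict_proba(ens$models[[i]], sample_sets[[i]]))
  fuse(P, ens$w)
}
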