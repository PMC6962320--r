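#' Train / validation / test split with class equalization
#'
#' Implements the evaluation protocol: for each tissue class with at least
#' `big_class` points, exactly `target` points are drawn for training (at
#' most 75% of the class); classes below `big_class` contribute
#' `ceiling(frac * n)` training points which are then augmented with
#' geometric transforms until the class roster reaches `target` (see
#' [balance_classes()]). Every point not selected for training goes to the
#' test set. The balanced `8 * target` roster is partitioned into `folds`
#' cross-validation folds (stratified by class). With `level = "subject"`
#' whole subjects are first held out so no subject contributes to both
#' sides, with every class represented among the held-out subjects.
#'
#' @param points annotation data.frame (columns `label`, `subject_id`, ...).
#' @param level `"point"` (default) or `"subject"`.
#' @param target balanced per-class roster size (600).
#' @param big_class threshold above which classes are subsampled rather
#'   than augmented (800).
#' @param frac training fraction for small classes (0.75, rounded up).
#' @param folds number of cross-validation folds (10).
#' @param n_test_subjects held-out subjects for `level = "subject"` (5).
#' @param config an [augment_config] for the balancing transforms.
#' @param seed RNG seed; the plan is deterministic given (inputs, seed).
#' @return A `split_plan`: list with `train` (selected original training
#'   points), `roster` (balanced training roster incl. transform columns
#'   and `fold`), `test`, `level`, `counts` (per-class data.frame with
#'   `n`, `n_train`, `n_test`).
#' @export
make_split <- function(points, level = c("point", "subject"), target = 600L,
                       big_class = 800L, frac = 0.75, folds = 10L,
                       n_test_subjects = 5L, config = augment_config(),
                       seed = 1L) {
  level <- match.arg(level)
  points$label <- as_tissue_factor(points$label)
  cls <- tissue_classes()
  counts <- table(points$label)
  missing_cls <- cls[counts == 0]
  if (length(missing_cls) > 0)
    stop_lungtex(sprintf("class(es) absent from the annotation set: %s",
                         paste(missing_cls, collapse = ", ")),
                 "lungtex_split_error")
  with_seed(seed, {
    subject_test <- NULL
    pool <- points
    if (level == "subject") {
      subs <- unique(points$subject_id)
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cand <- sample(subs, min(n_test_subjects, length(subs)))
        test_rows <- points$subject_id %in% cand
        if (all(table(points$label[test_rows]) > 0) &&
            all(table(points$label[!test_rows]) > 0)) { ok <- TRUE; break }
      }
      if (!ok)
        stop_lungtex(
          "could not find a subject hold-out with all 8 classes on both sides",
          "lungtex_split_error")
      subject_test <- points[test_rows, , drop = FALSE]
      pool <- points[!test_rows, , drop = FALSE]
    }
    train_idx <- integer(0)
    for (cl in cls) {
      rows <- which(pool$label == cl)
      n <- length(rows)
      n_train <- if (n >= big_class) target else ceiling(frac * n)
      train_idx <- c(train_idx, sort(sample(rows, n_train)))
    }
    train <- pool[sort(train_idx), , drop = FALSE]
    test <- pool[setdiff(seq_len(nrow(pool)), train_idx), , drop = FALSE]
    if (level == "subject") test <- subject_test
    roster <- balance_classes(train, target = target, config = config)
    # stratified fold assignment on the balanced roster
    roster$fold <- NA_integer_
    for (cl in cls) {
      rows <- which(roster$label == cl)
      roster$fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    cnt <- data.frame(class = cls,
                      n = as.integer(counts[cls]),
                      n_train = as.integer(table(train$label)[cls]),
                      n_test = as.integer(table(test$label)[cls]))
    structure(list(train = train, roster = roster, test = test,
                   level = level, folds = folds, counts = cnt, seed = seed),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> level %s, roster %d entries, %d folds\n",
              x$level, nrow(x$roster), x$folds))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
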