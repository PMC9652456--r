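#' Build epoch features for press decoding
#'
#' One feature vector per epoch: each neuron's mean fluorescence over a 1-s
#' window. Two balanced classes are built — `pre_press` (the 1 s immediately
#' before each active lever press) and `baseline` (an equal number of random
#' 1-s epochs drawn from session time that stays clear of the exclusion zone
#' around any press, so baselines never overlap modeled responses). Baseline
#' epochs are sampled without replacement and do not overlap each other.
#'
#' @param traces A [trace_matrix()].
#' @param events An `event_log`.
#' @param epoch_s Epoch length, seconds (default 1).
#' @param exclusion_s Length-2 vector: exclusion zone around each press,
#'   seconds relative to press (default `c(-10, 13)`, matching the
#'   peri-event window).
#' @param min_presses Minimum usable presses (default 5).
#' @param seed Seed for baseline sampling.
#' @return An `epoch_feature_set`: list with `x` (samples x neurons), `y`
#'   (factor `pre_press`/`baseline`), `epoch_start_s`.
#' @export
build_epoch_features <- function(traces, events, epoch_s = 1,
                                 exclusion_s = c(-10, 13), min_presses = 5,
                                 seed = 1L) {
  fr <- frame_rate(traces)
  n_frames <- ncol(traces)
  duration_s <- n_frames / fr
  press <- active_press_times(events)
  press <- press[press - epoch_s >= 0]          # complete pre-press epoch
  if (length(press) < min_presses)
    stop("insufficient data: need at least ", min_presses,
         " usable presses, got ", length(press), call. = FALSE)
  epoch_frames <- max(1L, round(epoch_s * fr))
  epoch_mean <- function(start_s) {
    j0 <- round(start_s * fr) + 1L
    rowMeans(unclass(traces)[, j0:(j0 + epoch_frames - 1L), drop = FALSE])
  }
  pre_starts <- press - epoch_s
  # allowed baseline start times: epoch must fit the session and avoid the
  # exclusion zone around every press
  grid <- (seq_len(max(0L, n_frames - epoch_frames)) - 1L) / fr
  ok <- rep(TRUE, length(grid))
  for (tp in press)
    ok <- ok & (grid + epoch_s <= tp + exclusion_s[1] |
                  grid >= tp + exclusion_s[2])
  allowed <- grid[ok]
  n_b <- length(press)
  base_starts <- withr::with_seed(as.integer(seed), {
    picked <- numeric(0)
    pool <- sample(allowed)
    for (cand in pool) {
      if (length(picked) == n_b) break
      if (all(abs(cand - picked) >= epoch_s)) picked <- c(picked, cand)
    }
    picked
  })
  if (length(base_starts) < n_b)
    stop("no allowed baseline region for ", n_b,
         " epochs; use a longer session", call. = FALSE)
  starts <- c(pre_starts, base_starts)
  x <- t(vapply(starts, epoch_mean, numeric(nrow(traces))))
  y <- factor(rep(c("pre_press", "baseline"), c(n_b, n_b)),
              levels = c("baseline", "pre_press"))
  structure(list(x = x, y = y, epoch_start_s = starts, epoch_s = epoch_s),
            class = "epoch_feature_set")
}

# stratified fold assignment, deterministic given seed
stratified_folds <- function(y, cv_folds, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  })
  folds
}

# 1-D two-class LDA (equal priors, pooled variance) reduces to the
# midpoint-of-class-means rule; vectorised over feature columns.
per_neuron_cv_accuracy <- function(x, y, folds) {
  cv_folds <- max(folds)
  correct <- matrix(0, ncol(x), 2)  # hits, total per neuron
  for (f in seq_len(cv_folds)) {
    tr <- folds != f; te <- !tr
    if (!any(te)) next
    m1 <- colMeans(x[tr & y == levels(y)[1], , drop = FALSE])
    m2 <- colMeans(x[tr & y == levels(y)[2], , drop = FALSE])
    mid <- (m1 + m2) / 2
    hi_is_2 <- m2 >= m1
    xt <- x[te, , drop = FALSE]
    pred_is_2 <- t(t(xt) > mid)
    pred_is_2[, !hi_is_2] <- !pred_is_2[, !hi_is_2]
    truth_is_2 <- y[te] == levels(y)[2]
    correct[, 1] <- correct[, 1] + colSums(pred_is_2 == truth_is_2)
    correct[, 2] <- correct[, 2] + sum(te)
  }
  correct[, 1] / correct[, 2]
}

population_cv_accuracy <- function(x, y, folds, n_pcs, classifier) {
  cv_folds <- max(folds)
  hits <- 0; total <- 0
  for (f in seq_len(cv_folds)) {
    tr <- folds != f; te <- !tr
    if (!any(te)) next
    npc <- min(n_pcs, sum(tr) - 2, ncol(x))
    pca <- prcomp(x[tr, , drop = FALSE], center = TRUE, scale. = FALSE)
    npc <- min(npc, ncol(pca$x))
    keep <- which(pca$sdev[seq_len(npc)] > 1e-10)
    ztr <- pca$x[, keep, drop = FALSE]
    zte <- predict(pca, x[te, , drop = FALSE])[, keep, drop = FALSE]
    pred <- if (classifier == "lda") {
      fit <- tryCatch(MASS::lda(ztr, grouping = y[tr]), error = function(e) e)
      if (inherits(fit, "error")) {
        # zero within-class variance: LDA degenerates to nearest centroid
        cen <- rbind(colMeans(ztr[y[tr] == levels(y)[1], , drop = FALSE]),
                     colMeans(ztr[y[tr] == levels(y)[2], , drop = FALSE]))
        d2 <- outer(rowSums(zte^2), rowSums(cen^2), "+") -
          2 * tcrossprod(zte, cen)
        factor(levels(y)[max.col(-d2)], levels = levels(y))
      } else {
        predict(fit, zte)$class
      }
    } else {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("classifier 'svm' requires the e1071 package", call. = FALSE)
      fit <- e1071::svm(ztr, y[tr], kernel = "linear", scale = FALSE)
      predict(fit, zte)
    }
    hits <- hits + sum(pred == y[te])
    total <- total + sum(te)
  }
  hits / total
}

#' Cross-validated binary decoding of upcoming lever presses
#'
#' Linear-discriminant classification of `pre_press` vs `baseline` epochs
#' with stratified cross-validation. `per_neuron` decodes from each neuron's
#' single feature column independently (the exact 1-D closed form of LDA);
#' `population` decodes from all neurons jointly after a PCA reduction of
#' the training features (samples are fewer than neurons, so LDA is fit on
#' the leading principal components).
#'
#' @param features An `epoch_feature_set`.
#' @param unit `"per_neuron"` or `"population"`.
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Seed controlling fold assignment.
#' @param n_pcs Principal components kept for population decoding.
#' @param classifier `"lda"` (default) or linear-kernel `"svm"`.
#' @return `per_neuron`: numeric vector of per-neuron held-out accuracies;
#'   `population`: a single accuracy.
#' @export
decode <- function(features, unit = c("per_neuron", "population"),
                   cv_folds = 5, seed = 1L, n_pcs = 10,
                   classifier = c("lda", "svm")) {
  unit <- match.arg(unit)
  classifier <- match.arg(classifier)
  x <- features$x; y <- features$y
  if (nlevels(droplevels(y)) < 2)
    stop("degenerate input: a single class", call. = FALSE)
  if (min(table(y)) < cv_folds * 2)
    stop("need at least 2 samples per class per fold", call. = FALSE)
  folds <- stratified_folds(y, cv_folds, seed)
  if (unit == "per_neuron") per_neuron_cv_accuracy(x, y, folds)
  else population_cv_accuracy(x, y, folds, n_pcs, classifier)
}

#' Label-shuffle null distribution of decoding accuracy
#'
#' Permutes the class labels uniformly at random and re-runs the decoder,
#' `n_shuffles` times. The permutation is of labels, not of the time series.
#'
#' @inheritParams decode
#' @param n_shuffles Number of label permutations (default 100).
#' @return `per_neuron`: an `n_shuffles` x n_neurons matrix of null
#'   accuracies; `population`: a length-`n_shuffles` vector.
#' @export
shuffle_null <- function(features, unit = c("per_neuron", "population"),
                         n_shuffles = 100, cv_folds = 5, seed = 1L,
                         n_pcs = 10, classifier = c("lda", "svm")) {
  unit <- match.arg(unit)
  classifier <- match.arg(classifier)
  if (n_shuffles < 1)
    stop("n_shuffles must be >= 1 for a null distribution", call. = FALSE)
  perms <- withr::with_seed(as.integer(seed),
    replicate(n_shuffles, sample(length(features$y)), simplify = FALSE))
  one <- function(p, i) {
    f <- features
    f$y <- features$y[p]
    decode(f, unit = unit, cv_folds = cv_folds, seed = as.integer(seed) + i,
           n_pcs = n_pcs, classifier = classifier)
  }
  res <- lapply(seq_len(n_shuffles), function(i) one(perms[[i]], i))
  if (unit == "per_neuron") do.call(rbind, res) else unlist(res)
}

#' Shuffle-subtracted decoding scores
#'
#' Each neuron's real accuracy minus the mean null accuracy of its group
#' (e.g. its ensemble, or all neurons of a session): score_i = accuracy_i -
#' mean(null accuracies of group(i)).
#'
#' @param accuracy Per-neuron real accuracies.
#' @param null_accuracy Matrix of null accuracies, shuffles x neurons (from
#'   [shuffle_null()]).
#' @param grouping Per-neuron group labels (e.g. ensemble categories);
#'   a single group when `NULL`.
#' @return Per-neuron numeric scores.
#' @export
shuffle_subtracted_scores <- function(accuracy, null_accuracy,
                                      grouping = NULL) {
  if (is.null(dim(null_accuracy)) || nrow(null_accuracy) < 1)
    stop("empty null distribution: run shuffle_null with n_shuffles >= 1",
         call. = FALSE)
  n <- length(accuracy)
  stopifnot(ncol(null_accuracy) == n)
  if (is.null(grouping)) grouping <- rep("all", n)
  if (length(grouping) != n)
    stop("grouping must have one label per neuron", call. = FALSE)
  grouping <- as.character(grouping)
  null_mean <- vapply(unique(grouping), function(g)
    mean(null_accuracy[, grouping == g, drop = FALSE]), numeric(1))
  accuracy - null_mean[grouping]
}

#' Full decoding analysis of one session
#'
#' Convenience wrapper: builds epoch features, computes per-neuron and
#' population accuracies, the shuffle nulls, and per-neuron
#' shuffle-subtracted scores grouped by ensemble category when supplied.
#'
#' @inheritParams build_epoch_features
#' @inheritParams decode
#' @param grouping Optional per-neuron ensemble labels for score grouping.
#' @param n_shuffles Label permutations for the null.
#' @return A `decoding_result` list: `accuracy` (per neuron), `population_
#'   accuracy`, `null_accuracy` (shuffles x neurons), `population_null`,
#'   `score` (per neuron, shuffle-subtracted), `grouping`, `cv_folds`,
#'   `seed`.
#' @export
decode_session <- function(traces, events, grouping = NULL, cv_folds = 5,
                           n_shuffles = 100, seed = 1L, n_pcs = 10,
                           classifier = "lda") {
  features <- build_epoch_features(traces, events, seed = seed)
  acc <- decode(features, "per_neuron", cv_folds = cv_folds, seed = seed)
  pop <- decode(features, "population", cv_folds = cv_folds, seed = seed,
                n_pcs = n_pcs, classifier = classifier)
  null_pn <- shuffle_null(features, "per_neuron", n_shuffles = n_shuffles,
                          cv_folds = cv_folds, seed = seed)
  null_pop <- shuffle_null(features, "population", n_shuffles = n_shuffles,
                           cv_folds = cv_folds, seed = seed, n_pcs = n_pcs,
                           classifier = classifier)
  structure(list(accuracy = acc, population_accuracy = pop,
                 null_accuracy = null_pn, population_null = null_pop,
                 score = shuffle_subtracted_scores(acc, null_pn, grouping),
                 grouping = grouping, cv_folds = cv_folds, seed = seed),
            class = "decoding_result")
}
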