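# Evaluation protocol: stratified k-fold splitting and AUC.

#' Stratified k-fold assignment
#'
#' Shuffles each class independently (seeded), then deals samples
#' round-robin to folds, so every fold size is within 1 of `n/k` and every
#' per-class fold count is within 1 of `class_count/k`. Folds are numbered
#' 1..k (R convention).
#'
#' @param labels binary vector (0/1) of length n.
#' @param k number of folds, >= 2; every class must have at least k
#'   members.
#' @param rng_seed integer seed; the assignment is deterministic given it.
#' @return object of class `fold_assignment`: list with `fold_index`
#'   (integer per sample, in 1..k), `k`, `rng_seed`.
#' @export
stratified_kfold <- function(labels, k, rng_seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < k))
    stopf("class %s has %d members, fewer than k = %d",
          names(counts)[which.min(counts)], min(counts), k)
  fold <- integer(length(labels))
  local_seed(rng_seed, {
    # deal classes consecutively round-robin so per-class counts AND
    # total fold sizes are each within 1
    pos <- 0L
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  structure(list(fold_index = fold, k = as.integer(k),
                 rng_seed = rng_seed),
            class = "fold_assignment")
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' The fraction of (positive, negative) pairs in which the positive sample
#' scores higher, with ties credited 0.5 — computed via mid-ranks, which is
#' exactly the pair-enumeration definition. Invariant under any strictly
#' monotone transform of the scores.
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels binary vector (1 = positive); both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("AUC undefined: only one class present")
  if (length(scores) != length(labels)) stopf("length mismatch")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC
#'
#' For each of `k` stratified folds, `scorer_factory` is trained on the
#' other k-1 folds, the held-out fold is scored, and its AUC recorded.
#' Per-fold AUCs are reported individually — with small test folds the
#' per-fold spread is large and a mean alone would hide it.
#'
#' @param dataset a `labeled_mesh_set` (see [sample_population()]).
#' @param scorer_factory function `(train_meshes, train_labels) ->`
#'   [scoring_function()]. Use [analytic_scorer_factory()] for a fixed
#'   (training-free) analytic scorer.
#' @param k number of folds (default 5).
#' @param rng_seed seed for the fold assignment.
#' @return list with `per_fold` (data.frame: fold, n_test, auc) and
#'   `mean_auc`.
#' @export
cross_validated_auc <- function(dataset, scorer_factory, k = 5,
                                rng_seed = 1L) {
  fa <- stratified_kfold(dataset$labels, k, rng_seed)
  rows <- lapply(seq_len(k), function(fold) {
    test <- which(fa$fold_index == fold)
    train <- which(fa$fold_index != fold)
    scorer <- scorer_factory(dataset$meshes[train], dataset$labels[train])
    s <- vapply(dataset$meshes[test], function(m) score_mesh(scorer, m),
                numeric(1))
    data.frame(fold = fold, n_test = length(test),
               auc = auc(s, dataset$labels[test]))
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold, mean_auc = mean(per_fold$auc))
}

#' @rdname cross_validated_auc
#' @export
analytic_scorer_factory <- function() {
  function(train_meshes, train_labels) analytic_scorer()
}

#' Accuracy at a threshold
#'
#' Thresholded accuracy as a secondary metric. AUC is the primary metric
#' because score calibration drifts (predictions can be biased toward 0 or
#' 1 with a midpoint far from 0.5), which makes fixed-threshold accuracy
#' unstable even when ranking is good.
#'
#' @inheritParams auc
#' @param threshold classification cut on the score (default 0.5).
#' @return fraction of correct predictions.
#' @export
accuracy_at <- function(scores, labels, threshold = 0.5) {
  mean(as.integer(scores > threshold) == as.integer(labels))
}

#' Read a dataset manifest (CSV of file, label)
#'
#' @param path manifest CSV with at least columns `file` (STL paths,
#'   relative to the manifest's directory) and `label` (0/1).
#' @return a `labeled_mesh_set` (without `params`).
#' @export
read_manifest <- function(path) {
  man <- read.csv(path)
  if (!all(c("file", "label") %in% names(man)))
    stopf("manifest needs columns 'file' and 'label': %s", path)
  base <- dirname(path)
  meshes <- lapply(seq_len(nrow(man)), function(i) {
    fp <- file.path(base, man$file[i])
    if (!file.exists(fp))
      stopf("manifest row %d: unreadable mesh %s", i, fp)
    read_stl(fp)
  })
  structure(list(meshes = meshes, labels = as.integer(man$label),
                 params = NULL),
            class = "labeled_mesh_set")
}
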