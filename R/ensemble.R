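# Subject-level stratified cross-validation with a ten-network ensemble
# vote. All leakage-prone steps (normative fit, range normalization, network
# training, early stopping) see only the outer-training subjects of a fold.

#' Build a subject-level fold plan
#'
#' Subjects (never scans) are assigned to `k_outer` folds, stratified by
#' diagnosis so each fold's class mix approximates the cohort's. Within each
#' outer training set, subjects are further split into `k_inner` subsets used
#' in turn as validation sets by the ensemble members.
#'
#' @param records a [subject_records()] data.frame.
#' @param k_outer,k_inner outer folds and inner validation subsets.
#' @param seed integer seed; the plan is deterministic given it.
#' @return object of class `fold_plan`: `subjects` (subject_id, diagnosis,
#'   fold) and `inner` (list per outer fold: named vector subject -> subset).
#' @export
make_fold_plan <- function(records, k_outer = 10L, k_inner = 10L, seed = 1L) {
  subj <- unique(records[, c("subject_id", "diagnosis")])
  if (anyDuplicated(subj$subject_id))
    stop("subjects with inconsistent diagnoses; run validate_cohort first")
  counts <- table(subj$diagnosis)
  if (any(counts < k_outer))
    stop("too few subjects in class(es): ",
         paste(names(counts)[counts < k_outer], collapse = ", "))
  set.seed(seed)
  fold <- integer(nrow(subj))
  for (g in unique(subj$diagnosis)) {
    idx <- which(subj$diagnosis == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k_outer), length(idx))
  }
  subjects <- data.frame(subject_id = subj$subject_id,
                         diagnosis = subj$diagnosis, fold = fold,
                         stringsAsFactors = FALSE)
  inner <- lapply(seq_len(k_outer), function(f) {
    tr <- subjects[subjects$fold != f, ]
    subset <- integer(nrow(tr))
    for (g in unique(tr$diagnosis)) {
      idx <- which(tr$diagnosis == g)
      idx <- idx[sample.int(length(idx))]
      subset[idx] <- rep_len(seq_len(k_inner), length(idx))
    }
    stats::setNames(subset, tr$subject_id)
  })
  structure(list(subjects = subjects, inner = inner,
                 k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

diagnosis_to_int <- function(d) match(d, c("NC", "AD", "FTD"))

#' Classification metrics
#'
#' @param truth,predicted integer (or NC/AD/FTD character) label vectors.
#' @param K number of classes.
#' @return list with `confusion` (truth x predicted), `accuracy` and
#'   `sensitivity` (per-class recall, `N(true c) / N(c)`).
#' @export
compute_metrics <- function(truth, predicted, K = 3L) {
  if (length(truth) == 0) stop("empty input")
  stopifnot(length(truth) == length(predicted))
  if (is.character(truth)) truth <- diagnosis_to_int(truth)
  if (is.character(predicted)) predicted <- diagnosis_to_int(predicted)
  cm <- matrix(0L, K, K, dimnames = list(truth = c("NC", "AD", "FTD")[1:K],
                                         predicted = c("NC", "AD", "FTD")[1:K]))
  for (i in seq_along(truth)) cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  sens <- diag(cm) / pmax(rowSums(cm), 1L)
  sens[rowSums(cm) == 0] <- NA_real_
  list(confusion = cm, accuracy = sum(diag(cm)) / length(truth),
       sensitivity = sens)
}

#' Average ensemble probabilities and vote
#'
#' The per-network probability vectors are averaged and passed through a
#' softmax before the argmax (order-preserving, so equivalent to the argmax
#' of the mean; both vectors are reported). Ties resolve to the lowest class
#' index.
#'
#' @param prob_list list of N x K probability matrices, one per network.
#' @return list with `mean_probs`, `post_softmax` and `labels`.
#' @export
ensemble_vote <- function(prob_list) {
  stopifnot(length(prob_list) >= 1)
  mean_probs <- Reduce(`+`, prob_list) / length(prob_list)
  post <- softmax_rows(mean_probs)
  list(mean_probs = mean_probs, post_softmax = post,
       labels = max.col(post, ties.method = "first"))
}

#' Run one outer fold of the ensemble pipeline
#'
#' Fits the normative model on the fold-training NC rows, w-scores all rows,
#' optionally range-normalizes (GAN path), trains `n_networks` classifiers
#' each with a different inner validation subset, and votes on the held-out
#' test rows.
#'
#' @param fold outer fold index.
#' @param table raw [feature_table()] for the whole cohort.
#' @param records matching [subject_records()].
#' @param plan a [make_fold_plan()].
#' @param cfg a [train_config()].
#' @param use_gan train GAN-augmented four-channel discriminators instead of
#'   plain three-class networks.
#' @param n_networks ensemble size (default 10; 1 disables the ensemble).
#' @param gcfg a [gan_config()] (GAN path only).
#' @param covariates normative covariates (see [fit_normative()]).
#' @return list with `metrics`, `mean_probs`, `post_softmax`, `predicted`,
#'   `truth`, per-network accuracies and the test row indices.
#' @export
run_ensemble_fold <- function(fold, table, records, plan, cfg = train_config(),
                              use_gan = FALSE, n_networks = 10L,
                              gcfg = gan_config(),
                              covariates = c("age", "sex", "icv", "field_strength")) {
  records <- align_records(records, table)
  test_subj <- plan$subjects$subject_id[plan$subjects$fold == fold]
  is_test <- records$subject_id %in% test_subj
  tr_rec <- records[!is_test, , drop = FALSE]

  # normative fit strictly on fold-training NC rows
  nc_sel <- !is_test & records$diagnosis == "NC"
  nc_table <- feature_table(table$ids[nc_sel, , drop = FALSE],
                            table$X[nc_sel, , drop = FALSE], table$sets, "raw")
  nm <- fit_normative(nc_table, records[nc_sel, , drop = FALSE],
                      covariates = covariates)
  wtab <- compute_wscore(nm, table, records)
  X <- wtab$X
  y <- diagnosis_to_int(records$diagnosis)
  rn <- NULL
  if (use_gan) {
    rn <- fit_range_normalizer(X[!is_test, , drop = FALSE])
    X <- range_normalize(X, rn)
  }
  inner <- plan$inner[[fold]]
  net_probs <- vector("list", n_networks)
  net_acc <- numeric(n_networks)
  truth <- y[is_test]
  for (i in seq_len(n_networks)) {
    val_subj <- names(inner)[inner == (1L + (i - 1L) %% plan$k_inner)]
    is_val <- records$subject_id %in% val_subj
    is_tr <- !is_test & !is_val
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + 7919L * i + fold
    if (use_gan) {
      gm <- train_gan(X[is_tr, , drop = FALSE], y[is_tr], table$blocks,
                      cfg = cfg_i, gcfg = gcfg,
                      Xval = X[is_val, , drop = FALSE], yval = y[is_val])
      pr <- discriminator_predict3(gm$discriminator,
                                   X[is_test, , drop = FALSE], table$blocks)
    } else {
      m <- fit_multibranch(X[is_tr, , drop = FALSE], y[is_tr], table$blocks,
                           K = 3L, cfg = cfg_i,
                           Xval = X[is_val, , drop = FALSE], yval = y[is_val])
      pr <- mb_predict(m, X[is_test, , drop = FALSE], table$blocks)
    }
    net_probs[[i]] <- pr$probs
    net_acc[i] <- mean(pr$labels == truth)
  }
  vote <- ensemble_vote(net_probs)
  list(metrics = compute_metrics(truth, vote$labels),
       mean_probs = vote$mean_probs, post_softmax = vote$post_softmax,
       predicted = vote$labels, truth = truth,
       network_accuracies = net_acc, test_rows = which(is_test))
}

#' Full subject-level cross-validated evaluation
#'
#' @inheritParams run_ensemble_fold
#' @param k_outer,k_inner fold counts for [make_fold_plan()].
#' @param seed seed for the fold plan.
#' @return list of class `crossval_result`: per-fold results, fold
#'   accuracies/sensitivities, pooled confusion matrix and overall accuracy.
#' @export
run_crossval <- function(table, records, cfg = train_config(),
                         k_outer = 10L, k_inner = 10L, seed = 1L,
                         use_gan = FALSE, n_networks = 10L,
                         gcfg = gan_config(),
                         covariates = c("age", "sex", "icv", "field_strength")) {
  plan <- make_fold_plan(records, k_outer, k_inner, seed = seed)
  folds <- lapply(seq_len(k_outer), function(f)
    run_ensemble_fold(f, table, records, plan, cfg = cfg, use_gan = use_gan,
                      n_networks = n_networks, gcfg = gcfg,
                      covariates = covariates))
  acc <- vapply(folds, function(f) f$metrics$accuracy, numeric(1))
  sens <- t(vapply(folds, function(f) f$metrics$sensitivity, numeric(3)))
  cm <- Reduce(`+`, lapply(folds, function(f) f$metrics$confusion))
  structure(list(folds = folds, plan = plan, fold_accuracy = acc,
                 fold_sensitivity = sens, confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm),
                 sensitivity = diag(cm) / rowSums(cm)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds, overall accuracy %.4f\n",
              length(x$folds), x$accuracy))
  cat(sprintf("  mean fold accuracy %.4f (SD %.4f)\n",
              mean(x$fold_accuracy), stats::sd(x$fold_accuracy)))
  cat("  sensitivity:",
      paste(sprintf("%s %.4f", names(x$sensitivity), x$sensitivity),
            collapse = ", "), "\n")
  invisible(x)
}

#' Paired one-tailed comparison of two experiments
#'
#' Paired one-tailed t-test on per-fold accuracies, alternative: experiment
#' `b` improves on experiment `a`. Zero-variance differences use the
#' convention p = 1 when the mean difference is <= 0 and p = 0.5 otherwise,
#' flagged in the output.
#'
#' @param acc_a,acc_b fold-accuracy vectors, paired by fold.
#' @return list with `t`, `df`, `p`, `mean_diff` and `degenerate` flag.
#' @export
compare_runs <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2)
  d <- acc_b - acc_a
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L,
                p = if (mean(d) <= 0) 1 else 0.5,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p <- stats::pt(t, df = length(d) - 1L, lower.tail = FALSE)
  list(t = t, df = length(d) - 1L, p = p, mean_diff = mean(d),
       degenerate = FALSE)
}

#' Compare a family of experiments with FDR control
#'
#' @param comparisons named list; each element a list with `a` and `b`
#'   fold-accuracy vectors ([compare_runs()] semantics).
#' @param q FDR level for Benjamini-Hochberg.
#' @return data.frame: comparison, t, p, p_adj, significant, mean_diff.
#' @export
compare_experiments <- function(comparisons, q = 0.05) {
  res <- lapply(comparisons, function(cp) compare_runs(cp$a, cp$b))
  p <- vapply(res, `[[`, numeric(1), "p")
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(comparison = names(comparisons),
             t = vapply(res, `[[`, numeric(1), "t"),
             p = p, p_adj = p_adj, significant = p_adj <= q,
             mean_diff = vapply(res, `[[`, numeric(1), "mean_diff"),
             row.names = NULL, stringsAsFactors = FALSE)
}
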