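# Order of increasing disease severity; the more-diseased class of a pair
# is the positive class for F1/AUROC.
severity_order <- c("healthy", "NAFL", "NASH")

disease_class <- function(pair) {
  pair[which.max(match(pair, severity_order))]
}

#' Stratified train/test split for a two-class comparison
#'
#' Per-class training count is `ceiling(fraction * class size)`, matching
#' the published 75/25 splits (51/16 for healthy+NAFL, 34/10 for
#' healthy+NASH, 47/14 for NAFL+NASH).
#'
#' @param subjects data.frame with columns `id` and `group`.
#' @param pair Character vector of the two group labels to keep.
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed for the shuffle.
#' @return List of class `split_plan` with `train_ids`, `test_ids`,
#'   `pair`, `fraction`, `seed`.
#' @export
split_cohort <- function(subjects, pair, fraction = 0.75, seed = 2022L) {
  stopifnot(length(pair) == 2, all(pair %in% subjects$group))
  set.seed(as.integer(seed))
  train <- character(0); test <- character(0)
  for (grp in pair) {
    ids <- subjects$id[subjects$group == grp]
    if (length(ids) < 4) stop("class ", grp, " has < 4 subjects")
    n_train <- ceiling(fraction * length(ids))
    ids <- sample(ids)
    train <- c(train, ids[seq_len(n_train)])
    test <- c(test, ids[-seq_len(n_train)])
  }
  structure(list(train_ids = train, test_ids = test, pair = pair,
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_plan")
}

# mtry tuning grid as functions of the feature count; tuned once at the
# full feature count, the chosen rule is then re-applied at each k of the
# halving sequence.
mtry_rules <- function() {
  list(sqrt = function(m) max(1L, floor(sqrt(m))),
       third = function(m) max(1L, floor(m / 3)),
       half = function(m) max(1L, floor(m / 2)))
}

rf_fit <- function(X, y01, ntree, mtry, seed, permutation = FALSE) {
  .rf_fit_cpp(X, as.integer(y01), as.integer(ntree), as.integer(mtry),
              1L, as.integer(seed), permutation)
}

rf_predict <- function(fit, X) .rf_predict_cpp(fit$forest, X)

# stratified fold assignment
make_folds <- function(y01, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Random-forest feature ranking with cross-validated tuning
#'
#' Fits a bagged ensemble of Gini-criterion classification trees (500 by
#' default), tuning the per-split feature count over
#' \{sqrt(m), m/3, m/2\} by the requested cross-validation scheme, and
#' returns the features ordered by decreasing mean-impurity-decrease
#' importance. Constant features are legal and receive importance 0.
#'
#' @param panel Numeric subjects x metabolites matrix (training data).
#' @param labels Two-class label per subject.
#' @param cv `"kfold10"` or `"loocv"` tuning scheme.
#' @param seed Integer seed (default 2022).
#' @param ntree Number of trees.
#' @param importance `"gini"` (default) or `"permutation"` (OOB accuracy
#'   decrease) for the returned ranking.
#' @return List of class `feature_ranking`: `ranking` (feature names by
#'   decreasing importance), `importance` (named vector), `mtry_rule`,
#'   `mtry`, `cv_accuracy` (per rule), `fit` (the tuned forest).
#' @export
rank_features_rf <- function(panel, labels, cv = c("kfold10", "loocv"),
                             seed = 2022L, ntree = 500L,
                             importance = c("gini", "permutation")) {
  cv <- match.arg(cv)
  importance <- match.arg(importance)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("single-class input")
  if (ncol(panel) < 2) stop("need >= 2 features")
  pos <- disease_class(classes)
  y01 <- as.integer(labels == pos)
  n <- nrow(panel)

  rules <- mtry_rules()
  nfold <- if (cv == "kfold10") min(10L, n) else n
  fold <- if (cv == "loocv") seq_len(n) else make_folds(y01, nfold, seed)
  cv_acc <- vapply(names(rules), function(rn) {
    mtry <- rules[[rn]](ncol(panel))
    correct <- 0L
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(y01[tr])) < 2) next
      fit <- rf_fit(panel[tr, , drop = FALSE], y01[tr], ntree, mtry,
                    seed + f)
      pr <- rf_predict(fit, panel[!tr, , drop = FALSE])
      correct <- correct + sum((pr >= 0.5) == (y01[!tr] == 1))
    }
    correct / n
  }, numeric(1))
  rule <- names(rules)[which.max(cv_acc)]  # ties -> first (sqrt, smallest)

  fit <- rf_fit(panel, y01, ntree, rules[[rule]](ncol(panel)), seed,
                permutation = identical(importance, "permutation"))
  imp <- if (importance == "permutation") fit$permutation_importance else
    fit$importance
  imp <- stats::setNames(as.numeric(imp), colnames(panel))
  structure(list(ranking = names(sort(imp, decreasing = TRUE)),
                 importance = imp, mtry_rule = rule,
                 mtry = rules[[rule]](ncol(panel)),
                 cv_accuracy = cv_acc, positive = pos, fit = fit),
            class = "feature_ranking")
}

#' Feature-halving evaluation (f79 ... f4)
#'
#' Ranks features once from the full-feature forest on the training split,
#' then for each k in the halving sequence refits on the top-k features
#' and evaluates accuracy, kappa, F1 and AUROC on the held-out test split.
#' Feature sets are nested by construction. k values exceeding the
#' available feature count are skipped with a message.
#'
#' @param panel Numeric subjects x metabolites matrix (whole cohort).
#' @param labels Label per subject (rows of `panel`).
#' @param split A [split_cohort()] plan; rownames of `panel` must contain
#'   its ids.
#' @param cv Tuning scheme passed to [rank_features_rf()].
#' @param seed Integer seed.
#' @param ks Feature-count sequence (default `c(79, 64, 32, 16, 8, 4)`).
#' @param ntree Number of trees.
#' @return List of class `halving_result`: `ranking`, `positive`, and
#'   `by_k` (named list with `features` and `metrics` per k).
#' @export
halving_evaluate <- function(panel, labels, split, cv = "kfold10",
                             seed = 2022L, ks = c(79L, 64L, 32L, 16L, 8L, 4L),
                             ntree = 500L) {
  stopifnot(inherits(split, "split_plan"))
  if (ncol(panel) < 4) stop("need >= 4 features")
  names(labels) <- rownames(panel)
  tr <- panel[split$train_ids, , drop = FALSE]
  te <- panel[split$test_ids, , drop = FALSE]
  ytr <- labels[split$train_ids]; yte <- labels[split$test_ids]

  rk <- rank_features_rf(tr, ytr, cv = cv, seed = seed, ntree = ntree)
  pos <- rk$positive
  y01tr <- as.integer(ytr == pos)
  rules <- mtry_rules()

  by_k <- list()
  for (k in ks) {
    if (k > ncol(panel)) {
      message("skipping k = ", k, ": only ", ncol(panel), " features")
      next
    }
    feats <- rk$ranking[seq_len(k)]
    fit <- rf_fit(tr[, feats, drop = FALSE], y01tr, ntree,
                  rules[[rk$mtry_rule]](k), seed + k)
    pr <- rf_predict(fit, te[, feats, drop = FALSE])
    met <- classifier_metrics(
      truth = ifelse(yte == pos, pos, paste0("non-", pos)),
      predictions = ifelse(pr >= 0.5, pos, paste0("non-", pos)),
      scores = pr, positive = pos)
    by_k[[paste0("f", k)]] <- list(k = k, features = feats, metrics = met)
  }
  structure(list(ranking = rk$ranking, positive = pos, by_k = by_k,
                 mtry_rule = rk$mtry_rule),
            class = "halving_result")
}

#' Choose the representative feature count from a halving result
#'
#' Computes each k's rank on each of the four metrics (higher metric =
#' better rank), averages them into a composite, and selects the smallest
#' k whose composite is within one rank of the best; exact ties also break
#' toward smaller k.
#'
#' @param halving A [halving_evaluate()] result.
#' @return List with `k`, `features`, `composite` (named vector).
#' @export
select_representative_set <- function(halving) {
  stopifnot(inherits(halving, "halving_result"), length(halving$by_k) > 0)
  ks <- vapply(halving$by_k, `[[`, integer(1), "k")
  mat <- t(vapply(halving$by_k, function(e)
    unlist(e$metrics[c("accuracy", "kappa", "f1", "auroc")]), numeric(4)))
  rks <- apply(-mat, 2, rank, ties.method = "average")
  if (is.null(dim(rks))) rks <- matrix(rks, nrow = 1)
  composite <- rowMeans(rks)
  names(composite) <- names(halving$by_k)
  best <- min(composite)
  cand <- ks[composite <= best + 1]
  k <- min(cand)
  list(k = k, features = halving$by_k[[paste0("f", k)]]$features,
       composite = composite)
}
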