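make_subjects <- function(sizes = c(healthy = 25, NAFL = 42, NASH = 19)) {
  data.frame(id = sprintf("S%03d", seq_len(sum(sizes))),
             group = rep(names(sizes), sizes), stringsAsFactors = FALSE)
}

test_that("stratified splits reproduce the published train/test counts", {
  sub <- make_subjects()
  cases <- list(list(pair = c("healthy", "NAFL"), train = 51, test = 16),
                list(pair = c("healthy", "NASH"), train = 34, test = 10),
                list(pair = c("NAFL", "NASH"), train = 47, test = 14))
  for (cs in cases) {
    sp <- split_cohort(sub, cs$pair, seed = 1)
    expect_length(sp$train_ids, cs$train)
    expect_length(sp$test_ids, cs$test)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    keep <- sub$id[sub$group %in% cs$pair]
    expect_setequal(c(sp$train_ids, sp$test_ids), keep)
    # reproducible under the same seed
    expect_identical(sp$train_ids, split_cohort(sub, cs$pair, seed = 1)$train_ids)
  }
  expect_error(split_cohort(make_subjects(c(healthy = 3, NAFL = 10, NASH = 5)),
                            c("healthy", "NAFL")), "< 4")
})

test_that("classifier metrics match hand computations", {
  # perfect predictions
  m <- classifier_metrics(truth = c("NASH", "NASH", "non"),
                          predictions = c("NASH", "NASH", "non"),
                          scores = c(0.9, 0.8, 0.1), positive = "NASH")
  expect_equal(unlist(m[c("accuracy", "kappa", "f1", "auroc")]),
               c(accuracy = 1, kappa = 1, f1 = 1, auroc = 1))
  # TP=3 FP=1 FN=1 TN=5 -> accuracy .8, F1 .75, kappa (0.8-0.52)/0.48
  truth <- c(rep("D", 4), rep("N", 6))
  pred <- c("D", "D", "D", "N", "D", rep("N", 5))
  m2 <- classifier_metrics(truth, pred, positive = "D")
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$f1, 0.75)
  expect_equal(m2$kappa, (0.8 - 0.52) / 0.48, tolerance = 1e-12)
  # full separation
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # single-class truth: flagged
  expect_warning(a <- auroc(1:3, c(TRUE, TRUE, TRUE)), "single-class")
  expect_true(is.na(a))
})

test_that("AUROC equals the exhaustive pairwise oracle", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(truth) || !any(truth)) next
    scores <- sample(1:10, n, replace = TRUE) + # heavy ties
      sample(c(0, 0.5), n, replace = TRUE)
    expect_equal(auroc(scores, truth), oracle_auroc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("kappa is zero for constant predictions and one iff perfect", {
  truth <- rep(c("D", "N"), each = 10)
  m <- classifier_metrics(truth, rep("D", 20), positive = "D")
  expect_equal(m$kappa, 0)
  m2 <- classifier_metrics(truth, truth, positive = "D")
  expect_equal(m2$kappa, 1)
})

test_that("forest ranking recovers a planted separating feature", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 60
    y <- rep(c("NAFL", "NASH"), each = n / 2)
    X <- matrix(rnorm(n * 21), n, 21,
                dimnames = list(NULL, paste0("f", 1:21)))
    X[, 1] <- ifelse(y == "NASH", 1, 0) + rnorm(n, sd = 0.05)
    rk <- rank_features_rf(X, y, seed = s, ntree = 100)
    rk$ranking[1] == "f1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permuted labels yield no outstanding importance", {
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- sample(rep(c("NAFL", "NASH"), each = n / 2))
  rk <- rank_features_rf(X, y, seed = 9, ntree = 200)
  # permutation-test flavour: the max importance under the null should not
  # stand far above the rest of the distribution
  imp <- rk$importance
  expect_lt(max(imp), median(imp) + 4 * mad(imp))
})

test_that("a duplicated informative feature splits the top ranks", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 80
    y <- rep(c("NAFL", "NASH"), each = n / 2)
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    sig <- ifelse(y == "NASH", 1.5, 0) + rnorm(n, sd = 0.4)
    X[, 1] <- sig
    X[, 2] <- sig  # exact copy
    rk <- rank_features_rf(X, y, seed = s, ntree = 150)
    all(c("f1", "f2") %in% rk$ranking[1:2])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("constant features are tolerated with zero importance", {
  set.seed(3)
  n <- 40
  y <- rep(c("NAFL", "NASH"), each = n / 2)
  X <- cbind(sig = ifelse(y == "NASH", 1, 0) + rnorm(n, sd = 0.2),
             const = rep(5, n), noise = rnorm(n))
  rk <- rank_features_rf(X, y, seed = 3, ntree = 100)
  expect_equal(unname(rk$importance["const"]), 0)
  expect_error(rank_features_rf(X, rep("NASH", n)), "single-class")
})

test_that("halving produces nested feature sets and sane metrics", {
  co <- tiny_cohort(seed = 21)
  sub <- co$subjects
  sp <- split_cohort(sub, c("healthy", "NASH"), seed = 21)
  h <- halving_evaluate(co$panel, setNames(sub$group, sub$id), sp,
                        seed = 21, ntree = 200)
  ks <- vapply(h$by_k, `[[`, integer(1), "k")
  expect_equal(unname(sort(ks, decreasing = TRUE)),
               c(79L, 64L, 32L, 16L, 8L, 4L))
  feats <- lapply(h$by_k, `[[`, "features")
  ord <- order(ks, decreasing = TRUE)
  for (i in seq_along(ord)[-1])
    expect_true(all(feats[[ord[i]]] %in% feats[[ord[i - 1]]]))
  # signal concentrates: top-4 panel keeps most of the discrimination
  a79 <- h$by_k$f79$metrics$auroc
  a4 <- h$by_k$f4$metrics$auroc
  expect_gte(a4, a79 - 0.1)
  # ks larger than the feature count are skipped with a message
  expect_message(
    h2 <- halving_evaluate(co$panel[, 1:10], setNames(sub$group, sub$id),
                           sp, seed = 21, ks = c(16L, 8L, 4L), ntree = 50),
    "skipping")
  expect_named(h2$by_k, c("f8", "f4"))
})

test_that("representative-set selection follows composite rank rules", {
  fake <- function(vals) {
    by_k <- lapply(seq_along(vals), function(i)
      list(k = c(16L, 8L, 4L)[i],
           features = paste0("f", seq_len(c(16, 8, 4)[i])),
           metrics = list(accuracy = vals[[i]][1], kappa = vals[[i]][2],
                          f1 = vals[[i]][3], auroc = vals[[i]][4])))
    names(by_k) <- paste0("f", c(16, 8, 4))
    structure(list(by_k = by_k), class = "halving_result")
  }
  # strictly improving with smaller k -> k = 4
  h <- fake(list(c(.7, .4, .7, .8), c(.8, .5, .8, .85), c(.9, .6, .9, .9)))
  expect_equal(select_representative_set(h)$k, 4L)
  # identical metrics -> tie broken toward smaller k
  h2 <- fake(rep(list(c(.8, .5, .8, .85)), 3))
  expect_equal(select_representative_set(h2)$k, 4L)
  # clear best at k = 16 with the two smaller k tied (composite 2.5,
  # more than one rank away) -> k = 16 kept despite the small-k bias
  h3 <- fake(list(c(.95, .9, .95, .99), c(.7, .4, .7, .75),
                  c(.7, .4, .7, .75)))
  expect_equal(select_representative_set(h3)$k, 16L)
})

test_that("LOOCV and 10-fold tuning agree on the top-8 features", {
  agree <- vapply(1:3, function(s) {
    co <- tiny_cohort(seed = 40 + s)
    keep <- co$subjects$group != "healthy"
    X <- co$panel[keep, ]
    y <- co$subjects$group[keep]
    a <- rank_features_rf(X, y, cv = "kfold10", seed = 40 + s, ntree = 100)
    b <- rank_features_rf(X, y, cv = "loocv", seed = 40 + s, ntree = 100)
    length(intersect(a$ranking[1:8], b$ranking[1:8])) >= 5
  }, logical(1))
  expect_gte(mean(agree), 0.5)
})
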