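test_that("weights are powers of two indexed by importance rank", {
  w <- assign_weights(c("Aspartic acid", "Isocitric acid", "Glutamic acid"))
  expect_equal(unname(w), c(1, 2, 4))
  expect_equal(unname(w["Aspartic acid"]), 1)  # most important -> weight 1
  expect_equal(unname(assign_weights("solo")), 1)
  expect_equal(unname(assign_weights(paste0("f", 1:4))), c(1, 2, 4, 8))
  ws <- assign_weights(paste0("f", 1:3), mode = "strengthen")
  expect_equal(unname(ws), c(4, 2, 1))
  expect_error(assign_weights(c("a", "a")), "duplicate")
  expect_error(assign_weights(paste0("f", 1:9)), "1 to 8")
})

test_that("the score formula and its scale identities hold", {
  expect_equal(meta_nash_score(1, 1, 1), 0)
  expect_equal(meta_nash_score(10, 10, 10), 7)
  expect_equal(meta_nash_score(25.4, 2.0, 12.74), 6.427571,
               tolerance = 1e-6)
  expect_error(meta_nash_score(0, 1, 1), "non-positive")
  set.seed(2)
  for (i in 1:50) {
    a <- runif(1, 0.1, 50); s <- runif(1, 0.01, 5); g <- runif(1, 1, 30)
    k <- runif(1, 0.5, 20)
    expect_equal(meta_nash_score(k * a, s, g),
                 meta_nash_score(a, s, g) + log10(k), tolerance = 1e-12)
    expect_equal(meta_nash_score(10 * a, 10 * s, 10 * g),
                 meta_nash_score(a, s, g) + 7, tolerance = 1e-12)
    # strictly increasing in each argument
    expect_gt(meta_nash_score(a + 1, s, g), meta_nash_score(a, s, g))
    expect_gt(meta_nash_score(a, s + 1, g), meta_nash_score(a, s, g))
    expect_gt(meta_nash_score(a, s, g + 1), meta_nash_score(a, s, g))
    # agreement with the generic weighted log-product route
    pan <- matrix(c(a, s, g), 1, 3,
                  dimnames = list("x", c("Aspartic acid", "Isocitric acid",
                                         "Glutamic acid")))
    expect_equal(weighted_log_score(pan, assign_weights(colnames(pan))),
                 meta_nash_score(a, s, g), tolerance = 1e-12)
  }
})

test_that("three-feature weights sum to 7 and match exact powers", {
  w <- assign_weights(c("a", "b", "c"))
  expect_equal(sum(w), 7)
  # verified against exact integer arithmetic: 2^1 * 3^2 * 5^4 = 11250
  pan <- matrix(c(2, 3, 5), 1, 3, dimnames = list("x", c("a", "b", "c")))
  expect_equal(weighted_log_score(pan, w), log10(11250), tolerance = 1e-12)
})

test_that("comparator indices match their published formulas", {
  cs <- comparator_scores(
    data.frame(age = 50, bmi = 30, ast = 80, alt = 64, platelets = 200,
               albumin = 4.0, ifg_or_diabetes = TRUE, c3 = 120),
    glu = 10, ser = 12, gly = 8, gln = 30)
  expect_equal(cs$gsg, 0.5)
  expect_equal(cs$glu_gln, 10 / 30)
  expect_equal(cs$fib4, 2.5)  # 50 * 80 / (200 * sqrt(64))
  expect_equal(cs$nfs,
               -1.675 + 0.037 * 50 + 0.094 * 30 + 1.13 + 0.99 * 80 / 64 -
                 0.013 * 200 - 0.66 * 4.0, tolerance = 1e-12)
  expect_equal(cs$c3, 120)
  expect_error(comparator_scores(
    data.frame(age = 50, bmi = 30, ast = 80, alt = 64, platelets = 200,
               albumin = 4, ifg_or_diabetes = FALSE, c3 = 100),
    glu = 15, ser = 0, gly = 0, gln = 2), "GSG")
})

test_that("cutoff selection is Youden with sensitivity-first tie-break", {
  r <- select_cutoff(c(5, 6, 7, 3, 4), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$cutoff, 4.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)
  # J ties at 0.5 for 3.5 and 5.5; sensitivity-first picks 3.5
  r2 <- select_cutoff(c(4, 6, 3, 5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$cutoff, 3.5)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 0.5)
  # degenerate constant scores
  r3 <- select_cutoff(rep(2, 6), rep(c(TRUE, FALSE), 3))
  expect_true(r3$degenerate)
  expect_error(select_cutoff(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("cutoff selection equals exhaustive enumeration on random data", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    is_nash <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(is_nash) || !any(is_nash)) next
    scores <- round(rnorm(n, mean = is_nash), 1)  # ties likely
    got <- select_cutoff(scores, is_nash)
    orc <- oracle_cutoff(scores, is_nash)
    expect_equal(got$cutoff, unname(orc["t"]))
    expect_equal(got$youden_j, unname(orc["j"]), tolerance = 1e-12)
    expect_equal(got$sensitivity, unname(orc["sens"]), tolerance = 1e-12)
    expect_equal(got$specificity, unname(orc["spec"]), tolerance = 1e-12)
  }
})

test_that("fixed-cutoff evaluation reports the confusion detail", {
  m <- evaluate_score(c(5, 6, 7, 3, 4), c(TRUE, TRUE, TRUE, FALSE, FALSE),
                      4.5)
  expect_equal(m$accuracy, 1)
  expect_equal(m$false_negatives, 0)
  expect_equal(m$cutoff, 4.5)
  # single-class truth: AUROC is flagged undefined but counts still work
  expect_warning(m2 <- evaluate_score(c(5, 3), c(TRUE, TRUE), 4),
                 "single-class")
  expect_equal(m2$false_negatives, 1)
  expect_true(is.na(m2$auroc))
})

test_that("covariate matching trims to comparable groups", {
  sub <- data.frame(id = sprintf("S%02d", 1:20),
                    group = rep(c("NAFL", "NASH"), each = 10),
                    bmi = c(seq(24, 33, length.out = 10),
                            seq(27, 36, length.out = 10)))
  scores <- setNames(c(rnorm(10, 4), rnorm(10, 5.3)), sub$id)
  r <- matched_subset_eval(sub, scores, "bmi")
  expect_lt(abs(r$mean_nash - r$mean_nafl), 0.25 *
              sd(sub$bmi) + 1e-9)  # loose sanity on the matched gap
  expect_true(all(r$kept_ids %in% sub$id))
  # identical distributions: everyone inside the overlap is retained
  sub2 <- sub
  sub2$bmi <- rep(seq(25, 34, length.out = 10), 2)
  r2 <- matched_subset_eval(sub2, scores, "bmi")
  expect_equal(r2$n_nafl + r2$n_nash, 20L)
  # disjoint ranges error
  sub3 <- sub
  sub3$bmi <- c(seq(20, 24, length.out = 10), seq(30, 35, length.out = 10))
  expect_error(matched_subset_eval(sub3, scores, "bmi"), "overlap")
})

test_that("published comparator cutoffs ship as constants", {
  pc <- published_cutoffs()
  expect_equal(unname(pc["metanash"]), 4.543)
  expect_equal(unname(pc["c3"]), 175)
  expect_equal(unname(pc["nfs"]), -1.46)
})

test_that("cohort-level score behaviour matches its own closed form", {
  # closed-form AUROC from the generator's latent score distribution vs
  # the empirical AUROC averaged over replicates
  spec <- build_default_spec(seed = 1, plant_featured = TRUE)
  cal <- spec$calibrated
  lp <- function(met, grp) {
    r <- cal[cal$metabolite == met & cal$group == grp, ]
    s2 <- log(1 + (r$sd / r$mean)^2)
    c(mu = (log(r$mean) - s2 / 2) / log(10), sd = sqrt(s2) / log(10))
  }
  w <- c("Aspartic acid" = 1, "Isocitric acid" = 2, "Glutamic acid" = 4)
  rho <- spec$rho
  stat <- function(grp) {
    ps <- vapply(names(w), lp, numeric(2), grp = grp)
    m <- sum(w * ps["mu", ])
    v <- sum((w * ps["sd", ])^2)
    for (i in 1:2) for (j in (i + 1):3)
      v <- v + 2 * rho * w[i] * w[j] * ps["sd", i] * ps["sd", j]
    c(m = m, v = unname(v))
  }
  sh <- stat("healthy"); sf <- stat("NAFL"); sn <- stat("NASH")
  d <- function(a, b) (a["m"] - b["m"]) / sqrt(a["v"] + b["v"])
  auroc_pred <- unname((25 * pnorm(d(sn, sh)) + 42 * pnorm(d(sn, sf))) / 67)
  emp <- mean(vapply(1:30, function(s) {
    co <- tiny_cohort(seed = 7000 + s, plant = TRUE)
    sc <- meta_nash_score(co$panel[, "Aspartic acid"],
                          co$panel[, "Isocitric acid"],
                          co$panel[, "Glutamic acid"])
    auroc(sc, co$subjects$group == "NASH")
  }, numeric(1)))
  expect_lt(abs(emp - auroc_pred), 0.05)
})

test_that("simple ratio indices underperform the weighted score", {
  # only the three score metabolites carry NAFL-to-NASH effects relevant
  # to GSG and glu/gln here (serine, glycine, glutamine are null)
  diffs <- vapply(1:20, function(s) {
    co <- tiny_cohort(seed = 8000 + s, plant = TRUE)
    nash <- co$subjects$group == "NASH"
    keep <- co$subjects$group != "healthy"
    sc <- meta_nash_score(co$panel[, "Aspartic acid"],
                          co$panel[, "Isocitric acid"],
                          co$panel[, "Glutamic acid"])
    gsg <- co$panel[, "Glutamic acid"] /
      (co$panel[, "Serine"] + co$panel[, "Glycine"])
    gg <- co$panel[, "Glutamic acid"] / co$panel[, "Glutamine"]
    auroc(sc[keep], nash[keep]) -
      max(auroc(gsg[keep], nash[keep]), auroc(gg[keep], nash[keep]))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
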