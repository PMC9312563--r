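#' Published comparator cutoffs
#'
#' Fixed decision thresholds used when comparing diagnostic indices:
#' 4.543 for the MetaNASH score, 175 mg/dL for serum C3, and -1.46 for the
#' NAFLD fibrosis score.
#'
#' @return Named numeric vector.
#' @export
published_cutoffs <- function() {
  c(metanash = 4.543, c3 = 175, nfs = -1.46)
}

#' Exponential rank weights for the score formula
#'
#' Weight `w = 2^(i - 1)` where `i` is the per-feature index. In
#' `"balance"` mode the most important feature gets index 1 (weight 1), so
#' the least important feature carries the largest weight; `"strengthen"`
#' reverses the indexing so the most important feature carries the largest
#' weight.
#'
#' @param features Character vector ordered by decreasing importance
#'   (rank 1 first), at most 8.
#' @param mode `"balance"` (default, the published choice) or
#'   `"strengthen"`.
#' @return Named numeric vector of weights in the order given.
#' @export
#' @examples
#' assign_weights(c("Aspartic acid", "Isocitric acid", "Glutamic acid"))
assign_weights <- function(features, mode = c("balance", "strengthen")) {
  mode <- match.arg(mode)
  k <- length(features)
  if (k < 1 || k > 8) stop("1 to 8 features required")
  if (anyDuplicated(features)) stop("duplicate features (duplicate ranks)")
  i <- if (mode == "balance") seq_len(k) else rev(seq_len(k))
  stats::setNames(2^(i - 1), features)
}

#' The MetaNASH score
#'
#' `log10(aspartic acid^1 x isocitric acid^2 x glutamic acid^4)` on
#' concentrations in mg/L (numerically identical to the panel unit
#' ng/uL). Strictly increasing in each argument; scaling all three inputs
#' by 10 adds exactly 7.
#'
#' @param asp,iso,glu Concentrations (mg/L) of aspartic, isocitric and
#'   glutamic acid; vectors are recycled by the usual rules.
#' @return Numeric score (dimensionless, log10 scale).
#' @export
#' @examples
#' meta_nash_score(1, 1, 1)     # 0
#' meta_nash_score(10, 10, 10)  # 7
meta_nash_score <- function(asp, iso, glu) {
  if (any(asp <= 0) || any(iso <= 0) || any(glu <= 0))
    stop("non-positive concentration")
  log10(asp) + 2 * log10(iso) + 4 * log10(glu)
}

#' Generic weighted log-product score
#'
#' `log10(prod_i f_i^{w_i})` over a weight assignment; the MetaNASH score
#' is the special case with weights (1, 2, 4) on aspartic, isocitric and
#' glutamic acid.
#'
#' @param panel Numeric subjects x metabolites matrix (all positive).
#' @param weights Named numeric vector; names must be panel columns.
#' @return Numeric score per subject.
#' @export
weighted_log_score <- function(panel, weights) {
  if (!all(names(weights) %in% colnames(panel)))
    stop("weight features missing from panel")
  x <- panel[, names(weights), drop = FALSE]
  if (any(x <= 0)) stop("non-positive concentration")
  as.numeric(log10(x) %*% weights)
}

#' Comparator diagnostic indices
#'
#' GSG index `glu / (ser + gly)`, glutamate/glutamine ratio, FIB-4
#' `age * AST / (platelets * sqrt(ALT))`, and the NAFLD fibrosis score
#' `-1.675 + 0.037 age + 0.094 BMI + 1.13 IFG/diabetes + 0.99 AST/ALT -
#' 0.013 platelets - 0.66 albumin` (standard published formulas), plus the
#' serum C3 level passed through.
#'
#' @param clinical data.frame with columns `age`, `bmi`, `ast`, `alt`,
#'   `platelets`, `albumin`, `ifg_or_diabetes`, `c3`.
#' @param glu,ser,gly,gln Metabolite concentrations (mg/L).
#' @return data.frame with columns `gsg`, `glu_gln`, `fib4`, `nfs`, `c3`.
#' @export
comparator_scores <- function(clinical, glu, ser, gly, gln) {
  if (any(ser + gly == 0)) stop("zero denominator in GSG index")
  if (any(gln == 0)) stop("zero denominator in glutamate/glutamine ratio")
  if (any(clinical$platelets == 0) || any(clinical$alt == 0))
    stop("zero denominator in FIB-4")
  data.frame(
    gsg = glu / (ser + gly),
    glu_gln = glu / gln,
    fib4 = clinical$age * clinical$ast /
      (clinical$platelets * sqrt(clinical$alt)),
    nfs = -1.675 + 0.037 * clinical$age + 0.094 * clinical$bmi +
      1.13 * as.numeric(clinical$ifg_or_diabetes) +
      0.99 * clinical$ast / clinical$alt -
      0.013 * clinical$platelets - 0.66 * clinical$albumin,
    c3 = clinical$c3
  )
}

#' Youden-equivalent cutoff selection minimizing false negatives
#'
#' Candidate thresholds are the midpoints of adjacent sorted unique scores
#' plus plus/minus infinity; a subject is called NASH when
#' `score >= cutoff`. Among thresholds maximizing Youden's
#' J = sensitivity + specificity - 1, ties prefer higher sensitivity and
#' then higher specificity, implementing the strategy of selecting the
#' highest-specificity point among the highest-sensitivity candidates.
#'
#' @param scores Numeric score per subject.
#' @param is_nash Logical (or label vector equal to `"NASH"`) marking the
#'   positive class.
#' @return List of class `cutoff_result`: `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `accuracy`, `f1`, `kappa`, `auroc`,
#'   `degenerate`.
#' @export
select_cutoff <- function(scores, is_nash) {
  if (!is.logical(is_nash)) is_nash <- is_nash == "NASH"
  if (!any(is_nash) || all(is_nash)) stop("both classes must be present")
  u <- sort(unique(scores))
  degenerate <- length(u) < 2
  cand <- if (degenerate) c(-Inf, Inf) else
    c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  n1 <- sum(is_nash); n0 <- sum(!is_nash)
  sens <- vapply(cand, function(t) sum(scores[is_nash] >= t) / n1, 0)
  spec <- vapply(cand, function(t) sum(scores[!is_nash] < t) / n0, 0)
  j <- sens + spec - 1
  tol <- 1e-9
  best <- which(j >= max(j) - tol)
  best <- best[sens[best] >= max(sens[best]) - tol]
  best <- best[spec[best] >= max(spec[best]) - tol]
  b <- best[1]
  met <- evaluate_score(scores, is_nash, cand[b])
  structure(list(cutoff = cand[b], sensitivity = sens[b],
                 specificity = spec[b], youden_j = j[b],
                 accuracy = met$accuracy, f1 = met$f1, kappa = met$kappa,
                 auroc = met$auroc, degenerate = degenerate),
            class = "cutoff_result")
}

#' Evaluate a score at a fixed cutoff
#'
#' Calls NASH when `score >= cutoff` and delegates to
#' [classifier_metrics()], additionally reporting sensitivity, specificity
#' and the false-negative count (the quantity the cutoff strategy
#' minimizes).
#'
#' @param scores Numeric score per subject.
#' @param is_nash Logical (or `"NASH"` label vector) truth.
#' @param cutoff Decision threshold.
#' @return A `classifier_metrics` list with extra elements `sensitivity`,
#'   `specificity`, `false_negatives`, `cutoff`.
#' @export
evaluate_score <- function(scores, is_nash, cutoff) {
  if (!is.logical(is_nash)) is_nash <- is_nash == "NASH"
  met <- classifier_metrics(
    truth = ifelse(is_nash, "NASH", "non-NASH"),
    predictions = ifelse(scores >= cutoff, "NASH", "non-NASH"),
    scores = scores, positive = "NASH")
  met$sensitivity <- unname(met$confusion["TP"] /
                              (met$confusion["TP"] + met$confusion["FN"]))
  met$specificity <- unname(met$confusion["TN"] /
                              (met$confusion["TN"] + met$confusion["FP"]))
  met$false_negatives <- unname(met$confusion["FN"])
  met$cutoff <- cutoff
  met
}

#' Evaluate the score on a covariate-matched NAFL/NASH subset
#'
#' Restricts NAFL and NASH subjects to the overlap of their covariate
#' ranges, then greedily trims the extreme value of whichever group pulls
#' the means apart until the group means differ by less than `tolerance`
#' (default one quarter of the pooled SD), and evaluates the score on the
#' matched subset at the fixed cutoff.
#'
#' @param subjects data.frame with `id`, `group` and the covariate column.
#' @param scores Named numeric score vector (names = subject ids) or a
#'   vector aligned with `subjects`.
#' @param covariate Covariate column name (e.g. `"bmi"`, `"insulin"`,
#'   `"glucose"`).
#' @param tolerance Maximum allowed absolute difference of subset group
#'   means; default `0.25 * pooled SD`.
#' @param cutoff Fixed decision threshold (default the published 4.543).
#' @return List: `metrics` (from [evaluate_score()]), `n_nafl`, `n_nash`,
#'   `mean_nafl`, `mean_nash`, `kept_ids`.
#' @export
matched_subset_eval <- function(subjects, scores, covariate,
                                tolerance = NULL,
                                cutoff = published_cutoffs()[["metanash"]]) {
  stopifnot(covariate %in% names(subjects))
  if (is.null(names(scores))) names(scores) <- subjects$id
  keep <- subjects$group %in% c("NAFL", "NASH")
  sub <- subjects[keep, c("id", "group", covariate)]
  names(sub)[3] <- "x"
  if (any(is.na(sub$x))) stop("covariate missing for some subjects")
  lo <- max(tapply(sub$x, sub$group, min))
  hi <- min(tapply(sub$x, sub$group, max))
  if (lo > hi) stop("empty covariate overlap between NAFL and NASH")
  sub <- sub[sub$x >= lo & sub$x <= hi, ]
  if (is.null(tolerance)) {
    v <- tapply(sub$x, sub$group, stats::var)
    n <- table(sub$group)
    pooled <- sqrt(sum((n - 1) * v) / (sum(n) - 2))
    tolerance <- 0.25 * pooled
  }
  repeat {
    mns <- tapply(sub$x, sub$group, mean)
    if (abs(mns["NASH"] - mns["NAFL"]) < tolerance) break
    if (any(table(sub$group) <= 2))
      stop("matching failed: a group shrank to 2 subjects")
    hi_grp <- names(which.max(mns))
    lo_grp <- names(which.min(mns))
    # candidate trims: highest value of the high group, lowest of the low
    i_hi <- which(sub$group == hi_grp)[which.max(sub$x[sub$group == hi_grp])]
    i_lo <- which(sub$group == lo_grp)[which.min(sub$x[sub$group == lo_grp])]
    gap <- function(drop) {
      s <- sub[-drop, ]
      m <- tapply(s$x, s$group, mean)
      abs(m["NASH"] - m["NAFL"])
    }
    sub <- sub[-(if (gap(i_hi) <= gap(i_lo)) i_hi else i_lo), ]
  }
  sc <- scores[sub$id]
  met <- evaluate_score(sc, sub$group == "NASH", cutoff)
  mns <- tapply(sub$x, sub$group, mean)
  list(metrics = met, n_nafl = sum(sub$group == "NAFL"),
       n_nash = sum(sub$group == "NASH"),
       mean_nafl = unname(mns["NAFL"]), mean_nash = unname(mns["NASH"]),
       kept_ids = sub$id)
}
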