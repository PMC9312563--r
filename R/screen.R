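#' Shapiro-Wilk normality screen
#'
#' Advisory per-metabolite normality check used to justify the
#' nonparametric tests downstream; constant (degenerate) columns are
#' flagged instead of tested.
#'
#' @param panel Numeric subjects x metabolites matrix.
#' @return data.frame with columns `metabolite`, `W`, `p`, `degenerate`.
#' @export
normality_screen <- function(panel) {
  stopifnot(is.matrix(panel), nrow(panel) >= 3)
  res <- lapply(colnames(panel), function(met) {
    x <- panel[, met]
    if (length(unique(x)) < 2)
      return(data.frame(metabolite = met, W = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    sw <- stats::shapiro.test(x)
    data.frame(metabolite = met, W = unname(sw$statistic), p = sw$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis screen across the three groups
#'
#' Tie-corrected Kruskal-Wallis H per metabolite with p-values from the
#' chi-square distribution on (groups - 1) degrees of freedom. All-equal
#' columns yield H = 0 and p = 1 by convention.
#'
#' @param panel Numeric subjects x metabolites matrix.
#' @param labels Group label per subject (three groups, each with at least
#'   two subjects).
#' @return data.frame with `metabolite`, `H`, `kw_p`.
#' @export
kw_screen <- function(panel, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 3)
    stop("kw_screen requires all three groups present")
  if (any(table(labels) < 2)) stop("every group needs >= 2 subjects")
  res <- lapply(colnames(panel), function(met) {
    x <- panel[, met]
    if (length(unique(x)) < 2)
      return(data.frame(metabolite = met, H = 0, kw_p = 1,
                        stringsAsFactors = FALSE))
    kt <- stats::kruskal.test(x, labels)
    data.frame(metabolite = met, H = unname(kt$statistic), kw_p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pairwise Wilcoxon rank-sum screen
#'
#' Two-sided rank-sum test per metabolite for one group pair. Exact
#' enumeration is used when both groups have at most 25 subjects and the
#' data are tie-free; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param panel Numeric subjects x metabolites matrix.
#' @param labels Group label per subject.
#' @param pair Character vector of the two group labels to compare.
#' @return data.frame with `metabolite`, `p`.
#' @export
pairwise_wilcoxon <- function(panel, labels, pair) {
  stopifnot(length(pair) == 2)
  i1 <- which(labels == pair[1]); i2 <- which(labels == pair[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("both groups need >= 2 subjects")
  res <- lapply(colnames(panel), function(met) {
    x <- panel[i1, met]; y <- panel[i2, met]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && max(length(x), length(y)) <= 25
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    data.frame(metabolite = met, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min_{j >= i} m * p(j) / j` over the sorted p-values, capped at
#' 1 and returned in the original order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.04))
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  q <- pmin(1, rev(cummin(rev(m * pvals[o] / seq_len(m)))))
  q[order(o)]
}

#' Full univariate screen table
#'
#' Kruskal-Wallis across the three groups, BH-FDR over the full panel
#' (one family per comparison), and the three pairwise Wilcoxon columns.
#' A metabolite is significant iff its FDR-adjusted q is below 0.05.
#'
#' @param panel Numeric subjects x metabolites matrix.
#' @param labels Group label per subject.
#' @param alpha Significance threshold on q (default 0.05).
#' @return data.frame with columns `metabolite`, `H`, `kw_p`, `q`,
#'   `p_NAFL_vs_healthy`, `p_NASH_vs_healthy`, `p_NASH_vs_NAFL`,
#'   `significant`.
#' @export
screen_metabolites <- function(panel, labels, alpha = 0.05) {
  kw <- kw_screen(panel, labels)
  kw$q <- bh_fdr(kw$kw_p)
  kw$p_NAFL_vs_healthy <-
    pairwise_wilcoxon(panel, labels, c("NAFL", "healthy"))$p
  kw$p_NASH_vs_healthy <-
    pairwise_wilcoxon(panel, labels, c("NASH", "healthy"))$p
  kw$p_NASH_vs_NAFL <-
    pairwise_wilcoxon(panel, labels, c("NASH", "NAFL"))$p
  kw$significant <- kw$q < alpha
  kw
}

#' Control-normalized star-pattern profile
#'
#' Divides each non-control group mean by the control (healthy) mean per
#' metabolite, yielding the dimensionless rays of the star plots, ordered
#' by chemical class.
#'
#' @param stats data.frame with columns `metabolite`, `group`, `mean` (one
#'   row per metabolite and group), e.g. [calibrated_six()] or group means
#'   computed from a panel via [group_distribution_table()].
#' @param catalog Catalog used to order rays and attach classes.
#' @param control Name of the reference group (default `"healthy"`).
#' @return data.frame with `metabolite`, `class`, `group`,
#'   `normalized_value`; the control group itself normalizes to exactly 1
#'   and is omitted.
#' @export
#' @examples
#' normalize_to_control(calibrated_six())
normalize_to_control <- function(stats, catalog = metabolite_catalog(),
                                 control = "healthy") {
  stopifnot(all(c("metabolite", "group", "mean") %in% names(stats)))
  ctrl <- stats[stats$group == control, c("metabolite", "mean")]
  if (!nrow(ctrl)) stop("control group absent from stats")
  if (any(ctrl$mean == 0)) stop("zero control mean")
  rest <- stats[stats$group != control, ]
  rest$normalized_value <-
    rest$mean / ctrl$mean[match(rest$metabolite, ctrl$metabolite)]
  rest$class <- catalog$class[match(rest$metabolite, catalog$metabolite)]
  ord <- order(match(rest$metabolite, catalog$metabolite), rest$group)
  rest <- rest[ord, c("metabolite", "class", "group", "normalized_value")]
  rownames(rest) <- NULL
  rest
}

#' Per-group (mean, sd) table from a panel
#'
#' @param panel Numeric subjects x metabolites matrix.
#' @param labels Group label per subject.
#' @return data.frame with `metabolite`, `group`, `mean`, `sd`.
#' @export
group_distribution_table <- function(panel, labels) {
  labels <- as.character(labels)
  out <- lapply(colnames(panel), function(met) {
    do.call(rbind, lapply(unique(labels), function(grp)
      data.frame(metabolite = met, group = grp,
                 mean = mean(panel[labels == grp, met]),
                 sd = stats::sd(panel[labels == grp, met]),
                 stringsAsFactors = FALSE)))
  })
  do.call(rbind, out)
}
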