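# Independent brute-force oracles used by the dual-route checks. These
# deliberately share no code with the implementation paths they verify.

# AUROC by exhaustive pairwise comparison with half credit for ties
oracle_auroc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# BH q-values straight from the definition q(i) = min_{j>=i} m p(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive threshold enumeration implementing "max J, then max
# sensitivity, then max specificity"
oracle_cutoff <- function(scores, is_nash) {
  u <- sort(unique(scores))
  cand <- if (length(u) < 2) c(-Inf, Inf) else
    c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[is_nash] >= t)
    spec <- mean(scores[!is_nash] < t)
    cur <- c(j = sens + spec - 1, sens = sens, spec = spec, t = t)
    if (is.null(best) ||
        cur["j"] > best["j"] + 1e-12 ||
        (abs(cur["j"] - best["j"]) <= 1e-12 &&
         (cur["sens"] > best["sens"] + 1e-12 ||
          (abs(cur["sens"] - best["sens"]) <= 1e-12 &&
           cur["spec"] > best["spec"] + 1e-12))))
      best <- cur
  }
  best
}

# exhaustive Gini search over every (feature, midpoint threshold) pair
oracle_best_split <- function(X, y01) {
  n <- length(y01); n1 <- sum(y01)
  best <- list(gain = -Inf)
  for (j in seq_len(ncol(X))) {
    u <- sort(unique(X[, j]))
    if (length(u) < 2) next
    for (t in (u[-length(u)] + u[-1]) / 2) {
      l <- X[, j] <= t
      nl <- sum(l); nr <- n - nl
      c1l <- sum(y01[l]); c1r <- n1 - c1l
      gain <- n1 * (n - n1) / n -
        (c1l * (nl - c1l) / nl + c1r * (nr - c1r) / nr)
      if (gain > best$gain + 1e-12)
        best <- list(gain = gain, feature = j, threshold = t)
    }
  }
  best
}

# small three-group cohort generator for quick checks
tiny_cohort <- function(seed, plant = FALSE) {
  generate_cohort(build_default_spec(seed = seed, plant_featured = plant))
}
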