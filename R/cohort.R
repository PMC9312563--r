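#' Construct a synthetic cohort specification
#'
#' A `cohort_spec` describes the stated world the generator draws from:
#' per-group sample sizes, the 79-metabolite catalog, per-metabolite
#' per-group (mean, sd) calibration for the discriminating metabolites,
#' an optional equicorrelation block on the latent Gaussian scale, and a
#' seed. Metabolites without calibration entries are "null": they share a
#' single distribution across the three groups.
#'
#' @param group_sizes Named integer vector with entries `healthy`, `NAFL`,
#'   `NASH`; all counts must be positive.
#' @param catalog data.frame as returned by [metabolite_catalog()].
#' @param calibrated data.frame with columns `metabolite`, `group`, `mean`,
#'   `sd`; every metabolite must appear in the catalog, means must be
#'   positive and sds nonnegative.
#' @param correlation_block Character vector of catalog metabolites sharing
#'   a common pairwise latent correlation, or `NULL` for none.
#' @param rho Common latent correlation coefficient in `[0, 1)`.
#' @param seed Integer seed stored with the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(healthy = 25L, NAFL = 42L, NASH = 19L),
                        catalog = metabolite_catalog(),
                        calibrated = calibrated_six(),
                        correlation_block = NULL,
                        rho = 0,
                        seed = 2022L) {
  groups <- c("healthy", "NAFL", "NASH")
  if (!all(groups %in% names(group_sizes)))
    stop("group_sizes must name healthy, NAFL and NASH")
  group_sizes <- as.integer(group_sizes[groups])
  names(group_sizes) <- groups
  if (any(group_sizes <= 0)) stop("all group sizes must be positive")
  if (!all(c("metabolite", "class") %in% names(catalog)))
    stop("catalog needs 'metabolite' and 'class' columns")
  if (anyDuplicated(catalog$metabolite)) stop("duplicate catalog entries")
  if (!is.null(calibrated) && nrow(calibrated)) {
    if (!all(calibrated$metabolite %in% catalog$metabolite))
      stop("calibrated metabolite not in catalog: ",
           paste(setdiff(calibrated$metabolite, catalog$metabolite),
                 collapse = ", "))
    if (!all(calibrated$group %in% groups))
      stop("calibrated group labels must be healthy/NAFL/NASH")
    if (any(calibrated$mean <= 0)) stop("calibrated means must be positive")
    if (any(calibrated$sd < 0)) stop("calibrated sds must be nonnegative")
  }
  if (!is.null(correlation_block)) {
    if (!all(correlation_block %in% catalog$metabolite))
      stop("correlation_block metabolite not in catalog")
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  }
  structure(
    list(group_sizes = group_sizes, catalog = catalog,
         calibrated = calibrated, correlation_block = correlation_block,
         rho = rho, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Default synthetic cohort specification
#'
#' The default stated world: group sizes 25/42/19 (86 subjects), the
#' 79-metabolite catalog, the six published discriminating metabolites
#' calibrated to their per-group means/SDs, all remaining metabolites null,
#' and an equicorrelation block (`rho = 0.4` on the latent Gaussian scale)
#' over the eight machine-learning-featured metabolites emulating TCA-cycle
#' co-variation.
#'
#' @param seed Integer seed.
#' @param plant_featured If `TRUE`, the four featured metabolites outside
#'   the calibrated six (cis-aconitic, aspartic, isocitric, oxaloacetic
#'   acids) additionally receive synthetic planted group effects whose
#'   directions follow the reported univariate behaviour. Default `FALSE`:
#'   six calibrated + 73 null metabolites.
#' @param rho Latent equicorrelation of the featured block.
#' @return A `cohort_spec`.
#' @export
build_default_spec <- function(seed = 2022L, plant_featured = FALSE,
                               rho = 0.4) {
  calib <- calibrated_six()
  if (plant_featured) calib <- rbind(calib, planted_four_synthetic())
  cohort_spec(calibrated = calib, correlation_block = featured_eight(),
              rho = rho, seed = seed)
}

# Shared null distribution per uncalibrated metabolite: class-specific
# log-spaced mean grids at a fixed CV of 0.45. Deterministic, so the seed
# only drives sampling.
null_distributions <- function(catalog) {
  ranges <- list(AA = c(3, 150), KYN = c(0.005, 1.5), NUC = c(0.1, 4),
                 OA = c(0.3, 40), FA = c(0.1, 80))
  out <- data.frame(metabolite = catalog$metabolite,
                    mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (cl in names(ranges)) {
    idx <- which(catalog$class == cl)
    r <- ranges[[cl]]
    out$mean[idx] <- exp(seq(log(r[1]), log(r[2]), length.out = length(idx)))
  }
  out$sd <- 0.45 * out$mean
  out
}

# Moment-matched log-normal parameters: arithmetic mean m > 0, sd s >= 0.
lnorm_params <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Generate a seeded synthetic cohort
#'
#' Concentrations are drawn per metabolite and group from a log-normal
#' distribution moment-matched to the specified arithmetic (mean, sd), so
#' the printed group means/SDs are preserved while keeping values positive
#' and right-skewed. Metabolites in the correlation block share a common
#' latent Gaussian factor (equicorrelation `rho`); marginals are unchanged,
#' so null metabolites stay null. Clinical covariates are drawn per group
#' from the published Table-of-characteristics means/SDs, truncated by
#' resampling outside (0, mean + 6 sd). A fixed seed reproduces the cohort
#' exactly.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @return A list with elements `panel` (numeric subjects x metabolites
#'   matrix, ng/uL) and `subjects` (data.frame of ids, group and clinical
#'   covariates).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(as.integer(seed))

  groups <- rep(names(spec$group_sizes), times = spec$group_sizes)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  mets <- spec$catalog$metabolite
  p <- length(mets)

  # latent Gaussian matrix with optional equicorrelation block
  z <- matrix(stats::rnorm(n * p), n, p, dimnames = list(ids, mets))
  if (!is.null(spec$correlation_block) && spec$rho > 0) {
    g <- stats::rnorm(n)
    j <- match(spec$correlation_block, mets)
    z[, j] <- sqrt(spec$rho) * g + sqrt(1 - spec$rho) * z[, j]
  }

  nulls <- null_distributions(spec$catalog)
  panel <- matrix(NA_real_, n, p, dimnames = list(ids, mets))
  calib <- spec$calibrated
  for (j in seq_len(p)) {
    met <- mets[j]
    rows <- if (!is.null(calib)) calib[calib$metabolite == met, ] else calib
    if (!is.null(rows) && nrow(rows)) {
      for (grp in names(spec$group_sizes)) {
        r <- rows[rows$group == grp, ]
        if (nrow(r) != 1L)
          stop("calibration for ", met, " must cover every group once")
        sel <- groups == grp
        if (r$sd > 0) {
          pp <- lnorm_params(r$mean, r$sd)
          panel[sel, j] <- exp(pp$mu + pp$sigma * z[sel, j])
        } else panel[sel, j] <- r$mean
      }
    } else {
      pp <- lnorm_params(nulls$mean[j], nulls$sd[j])
      panel[, j] <- exp(pp$mu + pp$sigma * z[, j])
    }
  }

  subjects <- data.frame(id = ids, group = groups, stringsAsFactors = FALSE)
  clin <- clinical_reference()
  for (v in unique(clin$variable)) {
    x <- numeric(n)
    for (grp in names(spec$group_sizes)) {
      r <- clin[clin$variable == v & clin$group == grp, ]
      sel <- which(groups == grp)
      draw <- stats::rnorm(length(sel), r$mean, r$sd)
      bad <- which(draw <= 0 | draw > r$mean + 6 * r$sd)
      while (length(bad)) {
        draw[bad] <- stats::rnorm(length(bad), r$mean, r$sd)
        bad <- bad[draw[bad] <= 0 | draw[bad] > r$mean + 6 * r$sd]
      }
      x[sel] <- draw
    }
    subjects[[v]] <- x
  }
  mf <- male_fraction()
  subjects$sex <- ifelse(stats::runif(n) < mf[groups], "M", "F")
  subjects$ifg_or_diabetes <- subjects$glucose >= 100
  # biopsy NAS available for a minority: NASH cases score 4-7, biopsied
  # NAFL cases 1-3, healthy controls never biopsied
  nas <- rep(NA_integer_, n)
  biopsied <- stats::runif(n) < ifelse(groups == "NASH", 0.4,
                                       ifelse(groups == "NAFL", 0.2, 0))
  nas[biopsied & groups == "NASH"] <-
    sample(4:7, sum(biopsied & groups == "NASH"), replace = TRUE)
  nas[biopsied & groups == "NAFL"] <-
    sample(1:3, sum(biopsied & groups == "NAFL"), replace = TRUE)
  subjects$nas <- nas

  list(panel = panel, subjects = subjects)
}

#' Assign a disease-group label from clinical covariates
#'
#' Implements the clinical classification rule: biopsy takes precedence,
#' with NASH defined by NAS >= 4; without (or with sub-threshold) biopsy,
#' NASH requires MRI-PDFF >= 16.1% together with MRE-LSM >= 3.8 kPa;
#' healthy requires MRI-PDFF < 5% plus normal liver enzymes (AST < 40 U/L
#' in both sexes; ALT < 35 U/L in males, < 25 U/L in females); remaining
#' subjects with MRI-PDFF >= 5% are NAFL. Subjects with MRI-PDFF < 5% but
#' abnormal enzymes and no qualifying biopsy cannot be classified and are
#' returned as `"unclassifiable"` so the caller can decide on exclusion.
#'
#' @param mri_pdff MRI proton-density fat fraction, percent.
#' @param mre_lsm MR elastography liver stiffness, kPa (may be `NA` if
#'   MRI-PDFF alone decides).
#' @param ast,alt Liver transaminases, U/L.
#' @param sex `"M"` or `"F"`.
#' @param nas Optional NAFLD activity score 0-8 (`NA` when not biopsied).
#' @return One of `"healthy"`, `"NAFL"`, `"NASH"`, `"unclassifiable"`.
#' @export
#' @examples
#' assign_group_label(3.4, 3.0, ast = 20, alt = 18, sex = "M")  # healthy
#' assign_group_label(20, 4.0)                                   # NASH
#' assign_group_label(6.0, 3.0, nas = 5)                         # NASH
assign_group_label <- function(mri_pdff, mre_lsm = NA, ast = NA, alt = NA,
                               sex = c("M", "F"), nas = NA) {
  sex <- match.arg(sex)
  if (is.na(mri_pdff)) stop("mri_pdff is required")
  if (!is.na(nas)) {
    if (nas < 0 || nas > 8) stop("nas must lie in 0..8")
    if (nas >= 4) return("NASH")
  }
  if (!is.na(mre_lsm) && mri_pdff >= 16.1 && mre_lsm >= 3.8) return("NASH")
  if (mri_pdff < 5) {
    alt_limit <- if (sex == "M") 35 else 25
    enzymes_normal <- !is.na(ast) && !is.na(alt) && ast < 40 && alt < alt_limit
    if (enzymes_normal) return("healthy")
    return("unclassifiable")
  }
  "NAFL"
}

#' Write / read a cohort spec as YAML
#'
#' Round-trip serialization of the scalar fields, calibration table and
#' correlation block; `read_cohort_spec(write_cohort_spec(s, f))` restores
#' an equivalent spec.
#'
#' @param spec A `cohort_spec`.
#' @param path Output YAML path.
#' @return `path` (write) or a `cohort_spec` (read).
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- list(
    group_sizes = as.list(spec$group_sizes),
    seed = spec$seed,
    rho = spec$rho,
    correlation_block = spec$correlation_block,
    calibrated = if (is.null(spec$calibrated)) NULL else
      lapply(seq_len(nrow(spec$calibrated)), function(i)
        as.list(spec$calibrated[i, , drop = FALSE]))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  calib <- NULL
  if (!is.null(obj$calibrated))
    calib <- do.call(rbind, lapply(obj$calibrated, function(r)
      data.frame(metabolite = r$metabolite, group = r$group,
                 mean = as.numeric(r$mean), sd = as.numeric(r$sd),
                 stringsAsFactors = FALSE)))
  cohort_spec(group_sizes = unlist(obj$group_sizes),
              calibrated = calib,
              correlation_block = unlist(obj$correlation_block),
              rho = if (is.null(obj$rho)) 0 else obj$rho,
              seed = obj$seed)
}
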