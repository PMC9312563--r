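#' Metabolite catalog for the targeted panel
#'
#' The targeted GC-MS/MS + LC-MS/MS panel covers 79 plasma metabolites in
#' five chemical classes: 33 amino acids (AA), 4 kynurenine-pathway
#' metabolites (KYN), 4 nucleosides (NUC), 18 organic acids (OA), and 20
#' fatty acids (FA). All concentrations are expressed in ng/uL, which is
#' numerically identical to mg/L; this is the canonical unit throughout the
#' package.
#'
#' @return A data.frame with columns `metabolite` (character) and `class`
#'   (factor with levels AA, KYN, NUC, OA, FA), 79 rows, in fixed panel
#'   order.
#' @export
#' @examples
#' nrow(metabolite_catalog())  # 79
#' table(metabolite_catalog()$class)
metabolite_catalog <- function() {
  aa <- c(
    "Alanine", "Glycine", "Serine", "Valine", "Leucine", "Isoleucine",
    "Proline", "Threonine", "Methionine", "Phenylalanine", "Tyrosine",
    "Tryptophan", "Lysine", "Histidine", "Arginine", "Glutamic acid",
    "Glutamine", "Aspartic acid", "Asparagine", "Cysteine", "Ornithine",
    "Citrulline", "Taurine", "4-Hydroxyproline",
    "alpha-Aminoadipic acid", "alpha-Aminobutyric acid", "beta-Alanine",
    "1-Methylhistidine", "3-Methylhistidine", "Sarcosine", "Ethanolamine",
    "Cystathionine", "Homocysteine"
  )
  kyn <- c("Kynurenic acid", "Kynurenine", "3-Hydroxykynurenine",
           "Quinolinic acid")
  nuc <- c("Adenosine", "Inosine", "Uridine", "Cytidine")
  oa <- c(
    "Pyruvic acid", "Lactic acid", "Glycolic acid",
    "2-Hydroxybutyric acid", "3-Hydroxybutyric acid",
    "3-Hydroxypropionic acid", "Acetoacetic acid", "Oxaloacetic acid",
    "alpha-Ketoglutaric acid", "Malic acid", "2-Hydroxyglutaric acid",
    "cis-Aconitic acid", "Isocitric acid", "Citric acid", "Malonic acid",
    "Succinic acid", "Fumaric acid", "4-Hydroxyphenyllactic acid"
  )
  fa <- c(
    "Lauric acid (C12:0)", "Myristic acid (C14:0)",
    "Myristoleic acid (C14:1)", "Palmitic acid (C16:0)",
    "Palmitoleic acid (C16:1)", "Stearic acid (C18:0)",
    "Oleic acid (C18:1)", "Linoleic acid (C18:2)",
    "alpha-Linolenic acid (C18:3)", "gamma-Linolenic acid (C18:3)",
    "Arachidic acid (C20:0)", "Arachidonic acid (C20:4)",
    "Eicosapentaenoic acid (C20:5)", "Docosanoic acid (C22:0)",
    "Erucic acid (C22:1)", "Docosapentaenoic acid (C22:5)",
    "Docosahexaenoic acid (C22:6)", "Lignoceric acid (C24:0)",
    "Nervonic acid (C24:1)", "Hexacosanoic acid (C26:0)"
  )
  data.frame(
    metabolite = c(aa, kyn, nuc, oa, fa),
    class = factor(rep(c("AA", "KYN", "NUC", "OA", "FA"),
                       times = c(length(aa), length(kyn), length(nuc),
                                 length(oa), length(fa))),
                   levels = c("AA", "KYN", "NUC", "OA", "FA")),
    stringsAsFactors = FALSE
  )
}

#' Per-group calibration of the six screening-significant metabolites
#'
#' Published per-group arithmetic means and SDs (ng/uL) for the six
#' metabolites that survive the Kruskal-Wallis + FDR screen: glutamic acid,
#' tyrosine, kynurenic acid, alpha-ketoglutaric acid, myristoleic acid, and
#' palmitoleic acid. These drive the calibrated part of the synthetic
#' cohort generator.
#'
#' @return A data.frame with one row per (metabolite, group) and columns
#'   `metabolite`, `group`, `mean`, `sd`.
#' @export
calibrated_six <- function() {
  m <- rbind(
    c("Glutamic acid",             6.52, 2.47, 12.74, 6.45, 15.88, 6.36),
    c("Tyrosine",                 20.15, 9.59, 28.21, 18.65, 32.41, 19.79),
    c("Kynurenic acid",           0.005, 0.006, 0.010, 0.009, 0.009, 0.006),
    c("alpha-Ketoglutaric acid",   1.70, 0.56,  2.63, 1.32,  3.71, 1.85),
    c("Myristoleic acid (C14:1)",  0.13, 0.08,  0.22, 0.15,  0.31, 0.19),
    c("Palmitoleic acid (C16:1)",  3.26, 1.87,  5.53, 3.97,  7.18, 5.16)
  )
  data.frame(
    metabolite = rep(m[, 1], each = 3),
    group = rep(c("healthy", "NAFL", "NASH"), times = nrow(m)),
    mean = as.numeric(t(m[, c(2, 4, 6)])),
    sd = as.numeric(t(m[, c(3, 5, 7)])),
    stringsAsFactors = FALSE
  )
}

#' The eight machine-learning-featured metabolites
#'
#' Union of the random-forest classifier features confirmed by multinomial
#' probability analysis: cis-aconitic acid, aspartic acid, glutamic acid,
#' isocitric acid, alpha-ketoglutaric acid, oxaloacetic acid, myristoleic
#' acid, and tyrosine. Used as the default equicorrelation block of the
#' generator and as the candidate set for score construction.
#'
#' @return Character vector of eight metabolite names (panel spelling).
#' @export
featured_eight <- function() {
  c("cis-Aconitic acid", "Aspartic acid", "Glutamic acid",
    "Isocitric acid", "alpha-Ketoglutaric acid", "Oxaloacetic acid",
    "Myristoleic acid (C14:1)", "Tyrosine")
}

# Synthetic planted effects for the four featured metabolites that are not
# in the calibrated six. Directions follow the reported univariate
# behaviour (aspartic and cis-aconitic comparable between NAFL and NASH;
# isocitric and oxaloacetic elevated in NASH vs NAFL); standardized effect
# sizes are kept below those of the calibrated six, since these four did
# not survive the FDR screen. SYNTHETIC values, not published.
planted_four_synthetic <- function() {
  m <- rbind(
    c("cis-Aconitic acid", 1.20, 0.65, 1.70, 0.95, 1.80, 1.05),
    c("Aspartic acid",     9.00, 4.50, 24.0, 18.0, 26.0, 20.0),
    c("Isocitric acid",    0.30, 0.14, 0.36, 0.20, 0.48, 0.26),
    c("Oxaloacetic acid",  0.80, 0.40, 1.05, 0.60, 1.40, 0.85)
  )
  data.frame(
    metabolite = rep(m[, 1], each = 3),
    group = rep(c("healthy", "NAFL", "NASH"), times = nrow(m)),
    mean = as.numeric(t(m[, c(2, 4, 6)])),
    sd = as.numeric(t(m[, c(3, 5, 7)])),
    stringsAsFactors = FALSE
  )
}

#' Published per-group clinical covariate statistics
#'
#' Group means and SDs of the clinical covariates used by the generator
#' (age, BMI, AST, ALT, platelets, glucose, insulin, C3, MRI-PDFF,
#' MRE-LSM), as printed for the study cohort. Albumin is not printed for
#' this cohort; the values shipped here are realistic synthetic choices
#' (documented in the methods vignette) needed only by the NFS comparator.
#'
#' @return data.frame with columns `variable`, `group`, `mean`, `sd`.
#' @export
clinical_reference <- function() {
  v <- rbind(
    c("age",       35.2, 15.3,  43.2, 15.7,  41.0, 16.2),
    c("bmi",       23.2,  2.9,  30.6,  5.9,  35.5,  7.0),
    c("ast",       20.4,  5.5,  42.8, 45.1,  87.1, 58.1),
    c("alt",       18.4,  7.4,  62.3, 78.3, 118.8, 100.3),
    c("platelets", 244.1, 59.1, 267.6, 73.2, 242.2, 94.2),
    c("glucose",   86.5, 18.3, 108.3, 31.9, 129.8, 57.0),
    c("insulin",    6.8,  3.8,  17.6, 16.1,  27.9, 17.6),
    c("c3",        94.9, 30.5, 125.9, 43.4, 154.3, 26.1),
    c("mri_pdff",   3.4,  0.8,  12.6,  6.6,  23.2, 10.0),
    c("mre_lsm",    3.1,  0.6,   3.4,  0.7,   5.2,  1.0),
    # albumin (g/dL): synthetic, not printed for this cohort
    c("albumin",    4.5,  0.30,  4.4, 0.35,   4.2,  0.40)
  )
  data.frame(
    variable = rep(v[, 1], each = 3),
    group = rep(c("healthy", "NAFL", "NASH"), times = nrow(v)),
    mean = as.numeric(t(v[, c(2, 4, 6)])),
    sd = as.numeric(t(v[, c(3, 5, 7)])),
    stringsAsFactors = FALSE
  )
}

# Male fraction per group (15/25, 19/42, 12/19 in the reference cohort).
male_fraction <- function() {
  c(healthy = 15 / 25, NAFL = 19 / 42, NASH = 12 / 19)
}
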