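# Statistical-genetics layer: Hardy-Weinberg testing, genetic-model coding,
# genotype-group comparisons, variance decomposition across genetic models,
# likelihood-ratio covariate tests, and sample-size / power arithmetic.

#' Pearson chi-square test for Hardy-Weinberg equilibrium
#'
#' Estimates the allele frequency from the genotype counts, forms the
#' expected counts `n * (p^2, 2pq, q^2)` and compares with a Pearson
#' chi-square statistic on 1 degree of freedom (one allele frequency is
#' estimated from the data).
#'
#' @param counts integer vector `(hom1, het, hom2)` of genotype counts.
#' @return list `chi_square`, `df` (= 1), `p_value`, `allele_freq` (frequency
#'   of the allele counted by `hom2`), `expected`.
#' @export
hwe_chi_square <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("counts must be three non-negative genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("zero total count", call. = FALSE)
  q <- (counts[2] / 2 + counts[3]) / n   # frequency of the second allele
  p <- 1 - q
  expected <- n * c(p^2, 2 * p * q, q^2)
  keep <- expected > 0
  chi2 <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  list(chi_square = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       allele_freq = q, expected = expected)
}

#' Genetic-model coding scheme
#'
#' Numeric codes per genotype for the three classical single-locus models.
#' For ACE I/D: additive II=0, ID=0.5, DD=1; I-dominant II=0, ID=0, DD=1;
#' D-dominant II=0, ID=1, DD=1. The ACTN3 R577X locus mirrors the scheme
#' with X as the counted (loss-of-function) allele: RR takes the role of II
#' and XX of DD, so "I_dominant" reads as R-dominant and "D_dominant" as
#' X-dominant.
#'
#' @param model "additive", "I_dominant" or "D_dominant".
#' @param locus "ace" or "actn3".
#' @return list of class `genetic_model_coding` with `model`, `locus`,
#'   `code_map` (named genotype -> code).
#' @export
genetic_model_coding <- function(model = c("additive", "I_dominant", "D_dominant"),
                                 locus = c("ace", "actn3")) {
  model <- match.arg(model)
  locus <- match.arg(locus)
  genos <- if (locus == "ace") c("II", "ID", "DD") else c("RR", "RX", "XX")
  codes <- switch(model,
                  additive = c(0, 0.5, 1),
                  I_dominant = c(0, 0, 1),
                  D_dominant = c(0, 1, 1))
  structure(list(model = model, locus = locus,
                 code_map = as.list(stats::setNames(codes, genos))),
            class = "genetic_model_coding")
}

#' Apply a genetic-model coding to genotype labels
#'
#' @param genotypes character vector of genotype labels.
#' @param coding a [genetic_model_coding()].
#' @return numeric vector of codes.
#' @export
code_genetic_model <- function(genotypes, coding) {
  stopifnot(inherits(coding, "genetic_model_coding"))
  bad <- setdiff(unique(genotypes), names(coding$code_map))
  if (length(bad))
    stop("unknown genotype(s): ", paste(bad, collapse = ", "), call. = FALSE)
  unname(unlist(coding$code_map[genotypes]))
}

#' One-way genotype ANOVA with eta-squared and Tukey HSD
#'
#' Model-free comparison of an outcome across genotype groups: one-way ANOVA
#' F test, the genotype variance fraction `eta^2 = SS_between / SS_total`,
#' and Tukey honest-significant-difference pairwise comparisons.
#'
#' @param outcome numeric outcome vector.
#' @param genotypes genotype labels, same length.
#' @return list `f_statistic`, `df`, `p_value`, `eta_squared`, `groups`
#'   (per-genotype n/mean/sd), `tukey` (data frame of pairwise contrasts).
#' @export
genotype_anova <- function(outcome, genotypes) {
  keep <- is.finite(outcome) & !is.na(genotypes)
  outcome <- outcome[keep]
  g <- factor(genotypes[keep])
  tab <- table(g)
  if (length(tab) < 2L)
    stop("need at least 2 genotype groups", call. = FALSE)
  if (any(tab < 2L))
    stop("every genotype group needs at least 2 observations (",
         names(tab)[tab < 2][1], " has ", min(tab), ")", call. = FALSE)
  fit <- stats::aov(outcome ~ g)
  an <- suppressWarnings(stats::anova(fit))
  ssb <- an[["Sum Sq"]][1]
  ssw <- an[["Sum Sq"]][2]
  sst <- ssb + ssw
  # an outcome that is numerically constant explains nothing
  if (sst <= 1e-12 * max(1, sum(outcome^2))) ssb <- sst <- 0
  tk <- stats::TukeyHSD(fit)$g
  groups <- data.frame(
    genotype = names(tab), n = as.integer(tab),
    mean = as.numeric(tapply(outcome, g, mean)),
    sd = as.numeric(tapply(outcome, g, stats::sd)),
    stringsAsFactors = FALSE
  )
  list(
    f_statistic = an[["F value"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    p_value = an[["Pr(>F)"]][1],
    eta_squared = if (sst > 0) ssb / sst else 0,
    groups = groups,
    tukey = data.frame(contrast = rownames(tk), tk, row.names = NULL,
                       check.names = FALSE)
  )
}

#' Two-group genotype comparison with normality checks
#'
#' Two-sample t test between a dominant genotype grouping (e.g. RR+RX vs XX,
#' or DD+ID vs II), Welch by default, plus a one-sample Kolmogorov-Smirnov
#' test of each group against the normal distribution fitted to it.
#'
#' @param outcome numeric outcome vector.
#' @param group two-level grouping (logical or factor/character with two
#'   levels), same length.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return list `t_statistic`, `df`, `p_value`, `group_means`, `ks_p`
#'   (normality p per group), `grouping_levels`.
#' @export
dominant_group_ttest <- function(outcome, group, var_equal = FALSE) {
  keep <- is.finite(outcome) & !is.na(group)
  outcome <- outcome[keep]
  g <- factor(group[keep])
  if (nlevels(g) != 2L)
    stop("grouping must have exactly 2 levels", call. = FALSE)
  if (any(table(g) < 2L))
    stop("both groups need at least 2 observations", call. = FALSE)
  tt <- stats::t.test(outcome ~ g, var.equal = var_equal)
  ks <- vapply(levels(g), function(l) {
    x <- outcome[g == l]
    if (stats::sd(x) == 0) return(NA_real_)
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }, numeric(1))
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       group_means = stats::setNames(as.numeric(tapply(outcome, g, mean)),
                                     levels(g)),
       ks_p = ks, grouping_levels = levels(g))
}

#' Variance explained by each genetic model, as a share of the ANOVA effect
#'
#' For each coding scheme, `r^2` is the squared Pearson correlation between
#' the coded genotype and the outcome; it is expressed as a percentage of the
#' model-free genotype variance fraction (`eta^2` from [genotype_anova()]):
#' `percent = 100 * r^2 / eta^2`. The model with the largest share is the
#' best-fitting architecture; exact ties resolve toward the additive model.
#'
#' @param outcome numeric outcome vector.
#' @param genotypes genotype labels.
#' @param locus "ace" or "actn3" (selects the genotype vocabulary).
#' @param models codings to evaluate (default all three).
#' @return list `eta_squared`, `table` (model, r_squared, percent_of_anova),
#'   `best_model`.
#' @export
model_variance_percent <- function(outcome, genotypes, locus = c("ace", "actn3"),
                                   models = c("additive", "I_dominant", "D_dominant")) {
  locus <- match.arg(locus)
  keep <- is.finite(outcome) & !is.na(genotypes)
  outcome <- outcome[keep]
  genotypes <- genotypes[keep]
  an <- genotype_anova(outcome, genotypes)
  eta2 <- an$eta_squared
  if (eta2 <= 0)
    stop("undefined percentage: genotype explains no variance (eta^2 = 0)",
         call. = FALSE)
  r2 <- vapply(models, function(m) {
    code <- code_genetic_model(genotypes, genetic_model_coding(m, locus))
    if (stats::sd(code) == 0) return(0)
    stats::cor(code, outcome)^2
  }, numeric(1))
  pct <- 100 * r2 / eta2
  # ties toward additive: stable order with additive first
  ord <- c("additive", setdiff(models, "additive"))
  pct_o <- pct[match(ord, models)]
  best <- ord[which.max(pct_o)]
  list(eta_squared = eta2,
       table = data.frame(model = models, r_squared = unname(r2),
                          percent_of_anova = unname(pct),
                          stringsAsFactors = FALSE),
       best_model = best)
}

#' Likelihood-ratio test for one covariate in a Gaussian linear model
#'
#' Fits the full and the reduced (covariate-dropped) linear models by
#' maximum likelihood and compares them: `LR = 2 * (logLik_full -
#' logLik_null)`, with a chi-square reference on the difference in parameter
#' count.
#'
#' @param data data frame holding the outcome and covariates.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate names for the full model.
#' @param drop the covariate of interest, removed in the null model; must be
#'   an element of `covariates` (nesting requirement).
#' @return list `lr_statistic`, `df`, `p_value`, `full_formula`,
#'   `null_formula`.
#' @export
lrt_covariate <- function(data, outcome, covariates, drop) {
  if (!all(drop %in% covariates))
    stop("non-nested specification: dropped covariate(s) not in the full model",
         call. = FALSE)
  null_cov <- setdiff(covariates, drop)
  f_full <- stats::reformulate(covariates, response = outcome)
  f_null <- if (length(null_cov)) stats::reformulate(null_cov, response = outcome)
            else stats::reformulate("1", response = outcome)
  data <- data[stats::complete.cases(data[c(outcome, covariates)]), , drop = FALSE]
  fit_full <- stats::lm(f_full, data = data)
  fit_null <- stats::lm(f_null, data = data)
  ll_full <- stats::logLik(fit_full)
  ll_null <- stats::logLik(fit_null)
  df <- attr(ll_full, "df") - attr(ll_null, "df")
  lr <- max(0, 2 * (as.numeric(ll_full) - as.numeric(ll_null)))
  list(lr_statistic = lr, df = df,
       p_value = if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE) else 1,
       full_formula = deparse(f_full), null_formula = deparse(f_null))
}

#' Attrition-adjusted recruitment target
#'
#' Inflates a base sample size for expected dropout:
#' `ceiling(base_n * (1 + dropout_rate))`. With the planning base of 269 and
#' 5% attrition this yields a recruitment target of 283.
#'
#' @param base_n base sample size from the power analysis.
#' @param dropout_rate expected dropout fraction in `[0, 1)`.
#' @return integer adjusted sample size.
#' @export
attrition_adjusted_n <- function(base_n, dropout_rate) {
  if (base_n <= 0 || base_n != round(base_n))
    stop("base_n must be a positive integer", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  as.integer(ceiling(base_n * (1 + dropout_rate)))
}

#' Monte-Carlo power of a balanced one-way ANOVA
#'
#' Simulates `reps` datasets of `k` groups totalling `total_n` observations
#' (balanced allocation, any remainder going to the first groups), with group
#' means spaced symmetrically so that the population between-group standard
#' deviation equals `cohen_f` times the unit within-group standard deviation,
#' and reports the fraction of replicates whose one-way ANOVA rejects at
#' `alpha`.
#'
#' @param k number of groups (>= 2).
#' @param total_n total sample size.
#' @param cohen_f Cohen's f effect size (>= 0).
#' @param alpha significance level.
#' @param reps number of Monte-Carlo replicates.
#' @param seed RNG seed (`NULL` = current RNG state).
#' @return list `power`, `mc_se`, `reps`, `group_sizes`, `group_means`.
#' @export
empirical_power_oneway <- function(k = 3, total_n = 269, cohen_f = 0.25,
                                   alpha = 0.05, reps = 1000, seed = NULL) {
  if (k < 2 || total_n < 2 * k || cohen_f < 0 || alpha <= 0 || alpha >= 1 || reps < 1)
    stop("invalid parameters", call. = FALSE)
  sizes <- rep(total_n %/% k, k)
  rem <- total_n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  # equally spaced means, scaled so the n-weighted between-group sd is f
  raw <- seq_len(k) - (k + 1) / 2
  mbar <- sum(sizes * raw) / total_n
  sd_b <- sqrt(sum(sizes * (raw - mbar)^2) / total_n)
  means <- if (cohen_f == 0 || sd_b == 0) rep(0, k) else raw * cohen_f / sd_b
  g <- rep.int(seq_len(k), sizes)
  mu <- means[g]
  run <- function() {
    y <- matrix(stats::rnorm(total_n * reps), total_n, reps) + mu
    gm <- rowsum(y, g) / sizes                    # k x reps group means
    grand <- colSums(y) / total_n
    ssb <- colSums(sizes * (gm - rep(grand, each = k))^2)
    sst <- colSums((y - rep(grand, each = total_n))^2)
    ssw <- sst - ssb
    fstat <- (ssb / (k - 1)) / (ssw / (total_n - k))
    mean(fstat > stats::qf(1 - alpha, k - 1, total_n - k))
  }
  power <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(power = power, mc_se = sqrt(power * (1 - power) / reps), reps = reps,
       group_sizes = sizes, group_means = means)
}
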