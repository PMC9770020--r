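# Group-statistics stage: linear mixed model over channel-pair records with a
# random intercept per patient, estimated marginal-mean contrasts with
# Bonferroni correction, plus the rank test, Cohen's d and Pearson
# correlation used for simpler comparisons.

#' Fit the pair-level linear mixed model
#'
#' Models a connectivity index over channel-pair records with zone
#' (inside/outside/between SOZ), region network and surgical outcome as fixed
#' factors (full factorial among those supplied), interictal spike rate and
#' inter-contact distance as covariates, and a random intercept per patient.
#' Estimation is REML via `lmerTest` (Satterthwaite degrees of freedom).
#'
#' @param table a pair table from [build_pair_table()] covering >= 2 patients.
#' @param dependent response column (default `"h_high_gamma"`).
#' @param fixed fixed-factor columns (default `c("zone_pair", "outcome")`);
#'   only factors with >= 2 observed levels are entered.
#' @param covariates numeric covariate columns
#'   (default `c("spike_rate", "distance_mm")`).
#' @param transform optional response transform: "none", "log" (log(y + eps))
#'   or "rank".
#' @return a `mixed_fit`: list with the fitted `model`, the `formula`,
#'   `singular` flag, and the data used.
#' @export
fit_mixed_model <- function(table,
                            dependent = "h_high_gamma",
                            fixed = c("zone_pair", "outcome"),
                            covariates = c("spike_rate", "distance_mm"),
                            transform = c("none", "log", "rank")) {
  transform <- match.arg(transform)
  if (!dependent %in% names(table))
    stop("dependent column '", dependent, "' not present in table")
  if (length(unique(table$patient)) < 2)
    stop("at least 2 patients are required for a random patient intercept")
  dat <- as.data.frame(table)
  y <- dat[[dependent]]
  if (transform == "log") y <- log(y + 1e-6)
  if (transform == "rank") y <- rank(y) / (length(y) + 1)
  dat$.y <- y
  fixed <- fixed[vapply(fixed, function(f)
    length(unique(dat[[f]][!is.na(dat$.y)])) >= 2, TRUE)]
  if (!length(fixed)) stop("no fixed factor has 2 or more observed levels")
  for (f in fixed) dat[[f]] <- factor(dat[[f]])
  covariates <- covariates[covariates %in% names(dat)]
  rhs <- paste(c(paste(fixed, collapse = " * "), covariates, "(1 | patient)"),
               collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  model <- lmerTest::lmer(fml, data = dat, REML = TRUE)
  structure(
    list(model = model, formula = fml, dependent = dependent,
         fixed = fixed, covariates = covariates,
         singular = lme4::isSingular(model), data = dat),
    class = "mixed_fit"
  )
}

#' Marginal-mean contrasts from a fitted mixed model
#'
#' Pairwise differences of estimated marginal means for one fixed factor,
#' optionally within the levels of another (e.g. zone within outcome), with
#' Bonferroni correction over the contrast family.
#'
#' @param fit a `mixed_fit` from [fit_mixed_model()].
#' @param factor the factor to contrast (default `"zone_pair"`).
#' @param by optional conditioning factor (default `"outcome"` when present).
#' @param adjust multiplicity adjustment (default `"bonferroni"`).
#' @return tibble with columns `contrast`, (optional `by` column),
#'   `estimate` (difference of marginal means), `SE`, `df`, `t`, `p_raw`,
#'   `p_adj`.
#' @export
marginal_contrasts <- function(fit, factor = "zone_pair", by = NULL,
                               adjust = "bonferroni") {
  if (is.null(by) && "outcome" %in% fit$fixed && factor != "outcome")
    by <- "outcome"
  if (!factor %in% fit$fixed) stop("'", factor, "' is not a model factor")
  spec <- stats::as.formula(paste(
    "~", factor, if (!is.null(by)) paste("|", by) else ""))
  emm <- emmeans::emmeans(fit$model, spec,
                          lmer.df = "satterthwaite",
                          lmerTest.limit = 1e6, pbkrtest.limit = 1)
  raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  adj <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = adjust))
  out <- tibble::as_tibble(raw)
  names(out)[names(out) == "p.value"] <- "p_raw"
  names(out)[names(out) == "t.ratio"] <- "t"
  out$p_adj <- adj$p.value
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' @param x,y non-empty numeric samples.
#' @return list with `statistic` (rank-sum W), `p`.
#' @export
rank_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    stop("degenerate input: all observations tied")
  # ties fall back to the normal approximation; the warning is expected
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = NULL))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Cohen's d effect size
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled standard deviation
#' weighted by degrees of freedom.
#'
#' @param x,y numeric samples with `n >= 2` each.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Pearson correlation with test
#'
#' @param x,y numeric vectors, `n >= 3`.
#' @return list with `r`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`; monotone in the family size `m`.
#'
#' @param p vector of raw p-values.
#' @param m family size (default `length(p)`).
#' @return corrected p-values.
#' @export
bonferroni_correct <- function(p, m = length(p)) {
  if (m < 1) stop("family size must be at least 1")
  pmin(1, p * m)
}
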