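## Cross-network statistics: paired two-tailed t-tests on network-level
## metrics, and mixed-effects comparisons of species-level metrics with
## the source study as a random blocking effect.

#' Paired two-tailed Student's t-test
#'
#' Thin, validated wrapper around the standard paired t-test:
#' t = mean(d) / (sd(d)/sqrt(n)) with d = a - b pairwise, df = n - 1,
#' two-tailed p from the t distribution. The sign of t follows
#' mean(a - b).
#'
#' @param a,b equal-length numeric vectors of paired observations
#'   (length >= 2, at least one nonzero difference).
#' @param metric optional metric name carried into the output.
#' @return one-row `data.frame`: `metric`, `n_pairs`, `mean_a`, `se_a`,
#'   `mean_b`, `se_b`, `mean_diff`, `t`, `df`, `p_two_tailed`.
#' @examples
#' pairedT(c(2, 3, 4), c(1, 1, 1))  # d = 1,2,3: t = 3.464, p ~ 0.074
#' @export
pairedT <- function(a, b, metric = NA_character_) {
  if (length(a) != length(b))
    stop("a and b must have equal length")
  if (length(a) < 2L)
    stop("paired t-test needs at least 2 pairs")
  if (anyNA(a) || anyNA(b))
    stop("missing values in paired observations")
  d <- a - b
  if (all(d == 0))
    stop("degenerate: zero variance (all pairwise differences are zero)")
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  se <- function(x) stats::sd(x) / sqrt(length(x))
  data.frame(metric = metric, n_pairs = length(a),
             mean_a = mean(a), se_a = se(a),
             mean_b = mean(b), se_b = se(b),
             mean_diff = mean(d),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_two_tailed = tt$p.value, stringsAsFactors = FALSE)
}

## as pairedT, but a zero-variance contrast yields an NA test rather
## than an error (used where whole comparison tables must not abort)
.pairedTSafe <- function(a, b, metric = NA_character_) {
  tryCatch(pairedT(a, b, metric = metric), error = function(e) {
    d <- a - b
    data.frame(metric = metric, n_pairs = length(a),
               mean_a = mean(a), se_a = stats::sd(a) / sqrt(length(a)),
               mean_b = mean(b), se_b = stats::sd(b) / sqrt(length(b)),
               mean_diff = mean(d), t = NA_real_, df = length(a) - 1,
               p_two_tailed = NA_real_, stringsAsFactors = FALSE)
  })
}

#' Table-style paired comparisons of network-metric variants
#'
#' Takes the per-network variant metric table produced by
#' [variantMetrics()] and computes, for each network-level metric
#' (connectance, mean links, generality, vulnerability) and each
#' contrast (full vs natives-only, full vs random-control, full vs
#' null-model mean, natives-only vs null-model mean), a paired
#' two-tailed t-test across networks. Networks flagged `excluded`
#' (degenerate after non-native removal) are dropped from every
#' contrast, so the degrees of freedom shrink accordingly. The result
#' is invariant to the ordering of networks in the table.
#'
#' @param variants `data.frame` from [variantMetrics()].
#' @return `data.frame` with one row per metric x contrast: the
#'   [pairedT()] columns plus `contrast` (`"a_vs_b"` names: `a` minus `b`).
#' @export
networkComparisonTable <- function(variants) {
  need <- c("network_id", "variant", "excluded",
            "connectance", "mean_links", "generality", "vulnerability")
  if (!all(need %in% names(variants)))
    stop("variants table is missing required columns")
  keep <- !variants$network_id %in% unique(variants$network_id[variants$excluded])
  v <- variants[keep, , drop = FALSE]
  contrasts <- list(
    full_vs_natives_only   = c("full", "natives_only"),
    full_vs_random_control = c("full", "random_control"),
    full_vs_null           = c("full", "null_mean"),
    natives_only_vs_null   = c("natives_only", "null_mean"))
  metrics <- c("connectance", "mean_links", "generality", "vulnerability")
  rows <- list()
  for (cn in names(contrasts)) {
    va <- v[v$variant == contrasts[[cn]][1], , drop = FALSE]
    vb <- v[v$variant == contrasts[[cn]][2], , drop = FALSE]
    va <- va[order(va$network_id), , drop = FALSE]
    vb <- vb[order(vb$network_id), , drop = FALSE]
    if (!identical(va$network_id, vb$network_id))
      stop(sprintf("variant '%s' and '%s' cover different networks",
                   contrasts[[cn]][1], contrasts[[cn]][2]))
    for (mt in metrics) {
      r <- pairedT(va[[mt]], vb[[mt]], metric = mt)
      r$contrast <- cn
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out[, c("metric", "contrast", setdiff(names(out), c("metric", "contrast")))]
}

#' Mixed-effects comparison of a species-level metric by origin
#'
#' Assembles the species-level metric table across a collection and
#' fits a linear mixed model with the source study as a random
#' intercept: `value ~ origin + level + (1 | study_id)` (REML; the
#' `level` fixed effect is dropped when the metric exists at one level
#' only, as for PSI). The quantity of interest is the origin contrast
#' (non-native minus native), reported with its Satterthwaite t and p.
#'
#' @param collection a [NetworkCollection-class] (for
#'   [compareSpeciesMetrics()]) or, for [fitOriginModel()], an assembled
#'   species table with columns `study_id`, `origin`, `level`, `value`.
#' @param metric one of `"normalized_degree"`, `"degree"`,
#'   `"betweenness"`, `"closeness"`, `"psi"`.
#' @param beta PSI exponent passed to [speciesMetrics()].
#' @return list of class `"MixedModelResult"`: `response`,
#'   `fixed_effects` (data.frame: term, estimate, se, df, t, p),
#'   `origin_effect`, `origin_se`, `origin_t`, `origin_p`,
#'   `random_intercept_variance`, `residual_variance`, `n_obs`,
#'   `n_studies`.
#' @export
compareSpeciesMetrics <- function(collection, metric = "normalized_degree",
                                  beta = 1) {
  stopifnot(is(collection, "NetworkCollection"))
  metric <- match.arg(metric, c("normalized_degree", "degree",
                                "betweenness", "closeness", "psi"))
  tabs <- lapply(collection@networks, speciesMetrics, beta = beta)
  tab <- do.call(rbind, tabs)
  tab$value <- tab[[metric]]
  tab <- tab[!is.na(tab$value), , drop = FALSE]
  fitOriginModel(tab, response = metric)
}

#' @rdname compareSpeciesMetrics
#' @param table species table with columns `study_id`, `origin`,
#'   `level`, `value`.
#' @param response name carried into the result.
#' @export
fitOriginModel <- function(table, response = "value") {
  need <- c("study_id", "origin", "level", "value")
  if (!all(need %in% names(table)))
    stop("species table is missing required columns")
  if (length(unique(table$study_id)) < 2L)
    stop("mixed model needs at least 2 studies")
  if (length(unique(table$origin)) < 2L)
    stop("both native and non-native species are required")
  table$origin <- factor(table$origin, levels = c("native", "nonnative"))
  table$level <- factor(table$level, levels = c("plant", "animal"))
  form <- if (length(unique(as.character(table$level))) > 1L)
    value ~ origin + level + (1 | study_id)
  else
    value ~ origin + (1 | study_id)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = table, REML = TRUE))),
    error = function(e) stop(sprintf("mixed model failed to fit: %s",
                                     conditionMessage(e))))
  sm <- summary(fit)$coefficients
  fe <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], df = sm[, "df"],
                   t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- list(
    response = response,
    fixed_effects = fe,
    origin_effect = fe$estimate[fe$term == "originnonnative"],
    origin_se = fe$se[fe$term == "originnonnative"],
    origin_t = fe$t[fe$term == "originnonnative"],
    origin_p = fe$p[fe$term == "originnonnative"],
    random_intercept_variance = vc$vcov[vc$grp == "study_id"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    n_obs = nrow(table),
    n_studies = length(unique(table$study_id)))
  class(res) <- "MixedModelResult"
  res
}

#' @export
print.MixedModelResult <- function(x, ...) {
  cat(sprintf(
    "Mixed model for %s: origin (nonnative - native) = %.4f +/- %.4f (t = %.3f, p = %.4g)\n  %d observations, %d studies; study variance %.4g\n",
    x$response, x$origin_effect, x$origin_se, x$origin_t, x$origin_p,
    x$n_obs, x$n_studies, x$random_intercept_variance))
  invisible(x)
}

#' Simulate a species-level metric table
#'
#' Generates a flat species table with known study, level and origin
#' effects, for calibrating and validating [fitOriginModel()]: value =
#' baseline + study intercept (N(0, studySD)) + `originEffect` for
#' non-natives + `levelEffect` for animals + N(0, residualSD) noise.
#'
#' @param nStudies number of studies.
#' @param speciesPerStudy species rows per study (half plants, half
#'   animals; a fraction `fracNonnative` of each level non-native).
#' @param originEffect,levelEffect,baseline fixed effects.
#' @param studySD,residualSD standard deviations of the random study
#'   intercept and the residual noise.
#' @param fracNonnative fraction of species that are non-native.
#' @param rngSeed integer seed; `NULL` uses the current RNG state.
#' @return `data.frame` with columns `study_id`, `origin`, `level`,
#'   `value`.
#' @export
simulateSpeciesTable <- function(nStudies = 30, speciesPerStudy = 50,
                                 originEffect = 0.2, levelEffect = 0,
                                 baseline = 0.3, studySD = 0.05,
                                 residualSD = 0.1, fracNonnative = 0.1,
                                 rngSeed = NULL) {
  if (!is.null(rngSeed)) set.seed(rngSeed)
  rows <- lapply(seq_len(nStudies), function(s) {
    u <- stats::rnorm(1, 0, studySD)
    n <- speciesPerStudy
    level <- rep(c("plant", "animal"), length.out = n)
    nonnat <- stats::runif(n) < fracNonnative
    value <- baseline + u + originEffect * nonnat +
      levelEffect * (level == "animal") + stats::rnorm(n, 0, residualSD)
    data.frame(study_id = sprintf("study%02d", s),
               origin = ifelse(nonnat, "nonnative", "native"),
               level = level, value = value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
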