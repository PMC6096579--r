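#' Assemble a per-nucleus record
#'
#' Collects all per-nucleus quantities into one row of the results table:
#' nuclear volume, per-channel spot metrics, d_max, polarity, NPB totals.
#' Missing components leave their fields NA so partially analyzed nuclei
#' are still recorded.
#'
#' @param mask nucleus mask.
#' @param spots named list of `spot_set` per channel (e.g. a, b).
#' @param radial named list of `radial_profile` per channel.
#' @param polarity named list of `polarity_result` per channel.
#' @param npbs an `npb_set` (after [associate()]) or NULL.
#' @param stage stage label (e.g. "2-cell").
#' @param nucleus_id,embryo_id identifiers.
#' @param spacing voxel spacing for bare-array masks.
#' @return One-row data.frame.
#' @export
measure_nucleus <- function(mask, spots = list(), radial = list(),
                            polarity = list(), npbs = NULL,
                            stage = NA_character_, nucleus_id = 1L,
                            embryo_id = NA_character_, spacing = NULL) {
  v <- as_volume(mask, spacing)
  rec <- data.frame(embryo_id = embryo_id, nucleus_id = nucleus_id,
                    stage = stage,
                    nuclear_volume = sum(v$values != 0) * voxel_volume(v$spacing))
  for (ch in union(names(spots), union(names(radial), names(polarity)))) {
    sm <- if (!is.null(spots[[ch]]))
      spot_metrics(spots[[ch]], mask, spacing = spacing)
    else data.frame(count = NA_integer_, total_volume = NA_real_,
                    mean_volume = NA_real_, volume_fraction = NA_real_)
    rec[[paste0("n_spots_", ch)]] <- sm$count
    rec[[paste0("total_spot_volume_", ch)]] <- sm$total_volume
    rec[[paste0("mean_spot_volume_", ch)]] <- sm$mean_volume
    rec[[paste0("spot_volume_fraction_", ch)]] <- sm$volume_fraction
    rec[[paste0("d_max_", ch)]] <-
      if (!is.null(radial[[ch]])) radial[[ch]]$d_max else NA_real_
    pr <- polarity[[ch]]
    rec[[paste0("polarity_distance_", ch)]] <-
      if (!is.null(pr)) pr$observed else NA_real_
    rec[[paste0("polarity_p_", ch)]] <- if (!is.null(pr)) pr$p else NA_real_
  }
  rec$n_npb <- if (!is.null(npbs)) npbs$n_npb else NA_integer_
  rec$n_npb_associated <-
    if (!is.null(npbs) && !is.null(npbs$n_associated)) npbs$n_associated
    else NA_integer_
  rec$npb_ratio <-
    if (!is.null(npbs) && !is.null(npbs$ratio)) npbs$ratio else NA_real_
  rec
}

#' One-sample Student's t test (raw values or summary form)
#'
#' Tests the mean of a sample against a theoretical value mu0 - e.g. the
#' observed spot counts against the metaphase expectation (24 for channel
#' A, 12 for channel B), or d_max values against 0. Accepts either the raw
#' values or the summary statistics (n, mean, sd), as printed in
#' stage-wise tables.
#'
#' @param x numeric vector of raw values (or NULL when using summaries).
#' @param mu0 theoretical mean.
#' @param n,mean,sd summary form (used when `x` is NULL).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return data.frame: `t`, `df`, `p`.
#' @export
one_sample_t <- function(x = NULL, mu0, n = NULL, mean = NULL, sd = NULL,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!is.null(x)) {
    if (length(x) < 2) stop("need at least 2 values")
    if (stats::sd(x) == 0) stop("zero variance")
    ht <- t.test(x, mu = mu0, alternative = alternative)
    return(data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
                      p = ht$p.value))
  }
  if (is.null(n) || is.null(mean) || is.null(sd))
    stop("supply raw values x, or all of n, mean, sd")
  if (n < 2) stop("need n >= 2")
  if (sd <= 0) stop("zero variance")
  tt <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(tt), df),
              less = pt(tt, df),
              greater = pt(tt, df, lower.tail = FALSE))
  data.frame(t = tt, df = df, p = p)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two distributions (e.g. d_max values at two stages); returns
#' the KS statistic D and the asymptotic p value.
#'
#' @param a,b numeric samples (>= 2 values each).
#' @return data.frame: `D`, `p`.
#' @export
ks_two_sample <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- suppressWarnings(ks.test(a, b, exact = FALSE))
  data.frame(D = unname(ht$statistic), p = ht$p.value)
}

#' Linear model with a stage factor and one covariate
#'
#' Ordinary least squares of a per-nucleus response on the developmental
#' stage (categorical fixed factor) plus one numeric covariate, with the
#' customary diagnostics: Shapiro-Wilk normality of residuals and
#' Bartlett homogeneity of variances across stages.
#'
#' @param records data.frame of per-nucleus records.
#' @param response name of the response column.
#' @param covariate name of the numeric covariate column (NULL for a
#'   stage-only model).
#' @param stage_col name of the stage column (default "stage").
#' @return Object of class `model_summary`: `formula`, `coefficients`
#'   (estimate, p per term), `normality_p`, `homogeneity_p`, `fit` (the
#'   lm object).
#' @export
fit_group_model <- function(records, response, covariate = NULL,
                            stage_col = "stage") {
  stopifnot(response %in% names(records), stage_col %in% names(records))
  if (!is.null(covariate) && !covariate %in% names(records))
    stop(sprintf("covariate '%s' not found", covariate))
  records[[stage_col]] <- factor(records[[stage_col]])
  if (nlevels(records[[stage_col]]) < 2)
    stop("need at least 2 stage levels")
  rhs <- if (is.null(covariate)) stage_col
         else paste(stage_col, covariate, sep = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- lm(fml, data = records)
  if (fit$rank < length(coef(fit))) stop("rank-deficient model")
  sm <- summary(fit)$coefficients
  res <- stats::residuals(fit)
  norm_p <- if (length(res) >= 3 && length(res) <= 5000)
    shapiro.test(res)$p.value else NA_real_
  hom_p <- tryCatch(
    bartlett.test(records[[response]], records[[stage_col]])$p.value,
    error = function(e) NA_real_)
  structure(list(formula = deparse(fml),
                 coefficients = data.frame(term = rownames(sm),
                                           estimate = sm[, 1],
                                           p = sm[, 4], row.names = NULL),
                 normality_p = norm_p, homogeneity_p = hom_p, fit = fit),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat(sprintf("<model_summary> %s\n", x$formula))
  print(x$coefficients, digits = 4)
  cat(sprintf("residual normality p = %.3g, variance homogeneity p = %.3g\n",
              x$normality_p, x$homogeneity_p))
  invisible(x)
}

#' Compare binary-parameter frequencies between two stages
#'
#' For a visually annotated parameter scored 0/1 per nucleus (e.g.
#' "necklace", "aggregate"), builds the 2 x 2 contingency table between
#' two stages and applies Fisher's exact test (two-sided; chi-square with
#' continuity correction optional).
#'
#' @param annotations data.frame with a stage column and binary parameter
#'   columns.
#' @param parameter name of the binary column to compare.
#' @param stage_a,stage_b the two stage labels.
#' @param method "fisher" (default) or "chisq".
#' @param stage_col name of the stage column.
#' @return data.frame: `p`, `present_a`, `n_a`, `present_b`, `n_b`.
#' @export
compare_binary_frequencies <- function(annotations, parameter, stage_a,
                                       stage_b, method = c("fisher", "chisq"),
                                       stage_col = "stage") {
  method <- match.arg(method)
  if (!parameter %in% names(annotations))
    stop(sprintf("parameter '%s' not found in the annotation table", parameter))
  sa <- annotations[annotations[[stage_col]] == stage_a, parameter]
  sb <- annotations[annotations[[stage_col]] == stage_b, parameter]
  if (length(sa) == 0 || length(sb) == 0)
    stop("both stages must be present in the annotation table")
  tab <- rbind(c(sum(sa == 1), sum(sa == 0)),
               c(sum(sb == 1), sum(sb == 0)))
  p <- if (method == "fisher") fisher.test(tab)$p.value
       else suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
  data.frame(p = p, present_a = tab[1, 1], n_a = length(sa),
             present_b = tab[2, 1], n_b = length(sb))
}

#' Stage-wise summary table of spot counts with t tests against mu0
#'
#' Reproduces the layout of a per-stage spot-count table: n, mean, sd of
#' the counts per stage, and the two-sided one-sample t-test p value
#' against the theoretical count.
#'
#' @param records per-nucleus records.
#' @param count_col name of the spot-count column.
#' @param mu0 theoretical count (24 for channel A, 12 for channel B).
#' @param stage_col stage column name.
#' @return data.frame, one row per stage: stage, n, mean, sd, p.
#' @export
stage_count_table <- function(records, count_col, mu0, stage_col = "stage") {
  stages <- unique(records[[stage_col]])
  do.call(rbind, lapply(stages, function(st) {
    x <- records[records[[stage_col]] == st, count_col]
    x <- x[!is.na(x)]
    p <- if (length(x) >= 2 && stats::sd(x) > 0)
      one_sample_t(x, mu0 = mu0)$p else NA_real_
    data.frame(stage = st, n = length(x), mean = mean(x),
               sd = stats::sd(x), p = p)
  }))
}
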