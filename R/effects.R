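#' Cohen's d for a change score
#'
#' Standardised mean difference of a within-group change: the mean change
#' divided by the group's baseline standard deviation. Labelled by the
#' conventional thresholds — trivial below 0.20, small 0.20-0.49, medium
#' 0.50-0.79, large at or above 0.80. This baseline-SD standardisation is
#' one of several Cohen's d variants; `sd_type` switches to the SD of the
#' change scores or an externally supplied pooled SD, which matter when
#' comparing against other studies.
#'
#' @param mean_change Mean change score.
#' @param sd Standard deviation used for standardisation (baseline SD by
#'   convention here).
#' @param n Optional sample size; when given, an approximate 95% CI of d
#'   is included (normal approximation,
#'   `SE = sqrt(1/n + d^2/(2*n))`).
#' @return Tibble `d` (2-decimal reporting value), `d_raw`, `label`, and
#'   `ci_low`/`ci_high` when `n` is given.
#' @export
#' @examples
#' cohens_d_change(0.23, 0.48) # d = 0.48, small
cohens_d_change <- function(mean_change, sd, n = NULL) {
  if (is.na(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  d <- mean_change / sd
  out <- tibble::tibble(
    d = round(d, 2),
    d_raw = d,
    label = effect_size_label(d)
  )
  if (!is.null(n)) {
    se <- sqrt(1 / n + d^2 / (2 * n))
    out$ci_low <- d - 1.96 * se
    out$ci_high <- d + 1.96 * se
  }
  out
}

effect_size_label <- function(d) {
  a <- abs(d)
  dplyr::case_when(
    a >= 0.80 ~ "large",
    a >= 0.50 ~ "medium",
    a >= 0.20 ~ "small",
    TRUE ~ "trivial"
  )
}

#' Parametric-assumption gate
#'
#' Tests every sample with the Shapiro-Wilk normality test and, for two or
#' more samples, Levene's test for homogeneity of variance. A parametric
#' test is licensed only when every Shapiro-Wilk p exceeds `alpha` and
#' Levene's p exceeds `alpha`. Samples with fewer than 3 observations or
#' zero variance force the nonparametric route with a warning.
#'
#' @param samples List of numeric vectors (or a single vector).
#' @param alpha Gate threshold (default 0.05).
#' @return Tibble `shapiro_p` (minimum across samples), `levene_p`
#'   (`NA` for a single sample), `parametric`.
#' @export
parametric_gate <- function(samples, alpha = 0.05) {
  if (is.numeric(samples)) samples <- list(samples)
  degenerate <- any(vapply(samples, function(s) {
    length(s) < 3 || isTRUE(all.equal(stats::var(s), 0))
  }, logical(1)))
  if (degenerate) {
    warning("Sample too small or degenerate; nonparametric test forced",
            call. = FALSE)
    return(tibble::tibble(shapiro_p = NA_real_, levene_p = NA_real_,
                          parametric = FALSE))
  }
  shapiro_p <- min(vapply(samples, function(s) stats::shapiro.test(s)$p.value,
                          numeric(1)))
  levene_p <- NA_real_
  if (length(samples) > 1) {
    df <- data.frame(
      y = unlist(samples),
      g = factor(rep(seq_along(samples), lengths(samples)))
    )
    levene_p <- car::leveneTest(y ~ g, data = df, center = mean)[["Pr(>F)"]][1]
  }
  tibble::tibble(
    shapiro_p = shapiro_p, levene_p = levene_p,
    parametric = shapiro_p > alpha && (is.na(levene_p) || levene_p > alpha)
  )
}

#' Compare two groups with assumption gating
#'
#' Independent two-sample comparison: Student's t-test when both samples
#' pass the parametric gate, otherwise the Mann-Whitney U test (exact
#' p-value for samples of up to 20 per group without ties, normal
#' approximation above). The reported U statistic is the number of
#' (x, y) pairs with x > y (+ half the ties), so U + U' = n1 * n2.
#'
#' @param x,y Numeric samples (e.g. training and control arm values).
#' @param paired Paired comparison (default FALSE; uses t or Wilcoxon
#'   signed-rank accordingly).
#' @param alpha Gate threshold (default 0.05).
#' @return Tibble `chosen_test`, `statistic`, `p_value`, `shapiro_p`,
#'   `levene_p`, `d` (Cohen's d on pooled SD, unpaired only).
#' @export
compare_groups <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample", call. = FALSE)
  gate <- suppressWarnings(
    parametric_gate(if (paired) list(x - y) else list(x, y), alpha)
  )
  n1 <- length(x); n2 <- length(y)
  if (gate$parametric) {
    res <- stats::t.test(x, y, paired = paired, var.equal = !paired)
    chosen <- if (paired) "paired-t" else "t"
    stat <- unname(res$statistic)
    p <- res$p.value
  } else if (paired) {
    res <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    chosen <- "wilcoxon"
    stat <- unname(res$statistic)
    p <- res$p.value
  } else {
    exact <- n1 <= 20 && n2 <= 20
    res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    chosen <- "mann-whitney"
    stat <- unname(res$statistic) # U: pairs with x > y
    p <- res$p.value
  }
  d <- NA_real_
  if (!paired) {
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    if (sp > 0) d <- (mean(x) - mean(y)) / sp
  }
  tibble::tibble(
    chosen_test = chosen, statistic = stat, p_value = p,
    shapiro_p = gate$shapiro_p, levene_p = gate$levene_p, d = d
  )
}

#' Within-group time course across three test weeks
#'
#' Repeated-measures one-way ANOVA of a measurement across the programme's
#' test weeks (baseline, mid, post) within one group, with Friedman's test
#' as the nonparametric fallback when any week's values fail the
#' normality gate. Participants with an incomplete week series are dropped
#' with a warning.
#'
#' @param df Tibble `participant_id`, `week`, `value`.
#' @param alpha Gate threshold (default 0.05).
#' @return Tibble `chosen_test` (`rm-anova` or `friedman`), `statistic`
#'   (F or chi-square), `p_value`, `n` (complete cases), `shapiro_p`.
#' @export
within_group_course <- function(df, alpha = 0.05) {
  df <- tibble::as_tibble(df)
  weeks <- sort(unique(df$week))
  complete <- df |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::filter(dplyr::n() == length(weeks)) |>
    dplyr::ungroup()
  n_dropped <- dplyr::n_distinct(df$participant_id) -
    dplyr::n_distinct(complete$participant_id)
  if (n_dropped > 0) {
    warning(n_dropped, " participant(s) with incomplete week series dropped",
            call. = FALSE)
  }
  if (dplyr::n_distinct(complete$participant_id) < 3) {
    stop("Fewer than 3 complete cases", call. = FALSE)
  }
  samples <- split(complete$value, complete$week)
  gate <- suppressWarnings(parametric_gate(samples, alpha))
  complete$week <- factor(complete$week)
  complete$participant_id <- factor(complete$participant_id)
  if (gate$parametric) {
    fit <- stats::aov(value ~ week + Error(participant_id),
                      data = complete)
    tab <- summary(fit)[["Error: Within"]][[1]]
    stat <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    if (is.na(p)) { stat <- 0; p <- 1 }
    chosen <- "rm-anova"
  } else {
    m <- tidyr::pivot_wider(complete, names_from = "week",
                            values_from = "value")
    m <- as.matrix(m[, -1])
    res <- stats::friedman.test(m)
    stat <- unname(res$statistic)
    p <- res$p.value
    if (is.na(p)) { stat <- 0; p <- 1 } # all-tied degenerate case
    chosen <- "friedman"
  }
  tibble::tibble(
    chosen_test = chosen, statistic = stat, p_value = p,
    n = dplyr::n_distinct(complete$participant_id),
    shapiro_p = gate$shapiro_p
  )
}

#' One-sample test of within-group heterogeneity of change
#'
#' One-sample t-test of the individual change scores against zero, with
#' the 95% confidence interval of the mean change. A significant result
#' with a wide interval indicates that participants responded, and
#' responded differently, to the same programme.
#'
#' @param changes Numeric vector of change scores (e.g. percent
#'   improvements), n >= 3.
#' @param mu Null value (default 0).
#' @return Tibble `statistic`, `p_value`, `mean`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
heterogeneity_test <- function(changes, mu = 0) {
  changes <- changes[!is.na(changes)]
  if (length(changes) < 3) stop("Need n >= 3", call. = FALSE)
  if (isTRUE(all.equal(stats::var(changes), 0))) {
    stop("Zero variance in changes; test undefined", call. = FALSE)
  }
  res <- stats::t.test(changes, mu = mu)
  tibble::tibble(
    statistic = unname(res$statistic), p_value = res$p.value,
    mean = mean(changes), ci_low = res$conf.int[1],
    ci_high = res$conf.int[2], n = length(changes)
  )
}

#' Percent difference between two group means
#'
#' `100 * (a - b) / b`, rounded to the nearest integer when
#' `round = TRUE` — the convention used when contrasting training-arm and
#' control-arm load averages.
#'
#' @param a,b Group means (`b` is the reference).
#' @param round Round to nearest integer (default FALSE).
#' @return Percent difference of `a` relative to `b`.
#' @export
#' @examples
#' percent_difference(2421, 1461, round = TRUE) # 66
percent_difference <- function(a, b, round = FALSE) {
  if (any(b == 0)) stop("reference mean is zero", call. = FALSE)
  out <- 100 * (a - b) / b
  if (round) round(out) else out
}

#' Probability of repeatedly hitting one gene at random
#'
#' If screen hits were pure false positives drawn independently at the
#' screen's significance level, the chance of the same gene being hit `k`
#' times is `alpha^k`; scaled by the panel size it gives the expected
#' percentage chance of any particular gene being so identified from the
#' panel. Used to argue that repeated hits in one gene are unlikely to be
#' chance.
#'
#' @param alpha Per-test significance level (default 0.05).
#' @param k Number of independent hits in the same gene (default 3).
#' @param n_snps Panel size after QC (default 715).
#' @return Tibble `p_single` (`alpha^k`) and `panel_pct`
#'   (`alpha^k * n_snps`, expressed as a percentage chance).
#' @export
#' @examples
#' random_gene_hit() # p_single 1.25e-4, panel_pct ~0.089
random_gene_hit <- function(alpha = 0.05, k = 3, n_snps = 715) {
  p <- alpha^k
  tibble::tibble(p_single = p, panel_pct = p * n_snps)
}
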