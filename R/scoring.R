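#' Score one genotype against its favorable allele
#'
#' Additive coding of a biallelic genotype: homozygous for the favorable
#' allele scores 2, heterozygous 1, homozygous for the other allele 0.
#' Vectorised over calls.
#'
#' @param a1,a2 Allele vectors (A/C/G/T; `NA` for missing calls gives
#'   `NA`).
#' @param favorable Favorable allele, recycled along the calls.
#' @param other Optional vector of the SNP's other allele; when supplied,
#'   genotypes containing any third allele raise an error.
#' @return Integer vector in \{0, 1, 2\} (`NA` for missing calls).
#' @export
#' @examples
#' score_genotype("G", "G", "G") # 2
#' score_genotype("G", "T", "G") # 1
#' score_genotype("T", "T", "G") # 0
score_genotype <- function(a1, a2, favorable, other = NULL) {
  if (any(is.na(favorable))) stop("favorable allele missing", call. = FALSE)
  if (!is.null(other)) {
    ok <- is.na(a1) |
      ((a1 == favorable | a1 == other) & (a2 == favorable | a2 == other))
    if (any(!ok)) {
      stop("Genotype '", a1[!ok][1], a2[!ok][1],
           "' contains an allele outside the SNP's pair", call. = FALSE)
    }
  }
  out <- (a1 == favorable) + (a2 == favorable)
  as.integer(out)
}

#' Sum favorable-allele scores per participant
#'
#' The total genotype score: for every retained SNP each participant's
#' genotype is scored 0/1/2 by favorable-allele copies and the scores are
#' summed. Missing genotypes are handled per `missing_policy`: with
#' `"zero"` (default) the SNP contributes 0 and is counted in `n_missing`;
#' with `"drop"` participants with any missing retained SNP are removed
#' from the result.
#'
#' @param panel A [genotype_panel()].
#' @param favorable Tibble `rsid`, `favorable_allele` for the retained
#'   SNPs (rows with `NA` favorable allele are ignored).
#' @param missing_policy `"zero"` or `"drop"`.
#' @return Tibble `participant_id`, `total`, `n_missing`, plus one 0/1/2
#'   column per retained rsid.
#' @export
sum_scores <- function(panel, favorable,
                       missing_policy = c("zero", "drop")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(panel, "genotype_panel"))
  favorable <- favorable[!is.na(favorable$favorable_allele), ]
  if (nrow(favorable) == 0) stop("No scorable SNPs", call. = FALSE)
  unknown <- setdiff(favorable$rsid, panel$meta$rsid)
  if (length(unknown) > 0) {
    stop("Favorable-allele table names SNP(s) absent from the panel: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  calls <- panel$calls[panel$calls$rsid %in% favorable$rsid, ]
  meta <- panel$meta[, c("rsid", "ref", "alt")]
  df <- dplyr::left_join(calls, favorable, by = "rsid")
  df <- dplyr::left_join(df, meta, by = "rsid")
  df$other <- ifelse(df$favorable_allele == df$ref, df$alt, df$ref)
  df$score <- score_genotype(df$a1, df$a2, df$favorable_allele, df$other)
  per_part <- df |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      total = sum(.data$score, na.rm = TRUE),
      n_missing = sum(is.na(.data$score)),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(df[, c("participant_id", "rsid", "score")],
                             names_from = "rsid", values_from = "score")
  out <- dplyr::left_join(per_part, wide, by = "participant_id")
  out <- out[match(intersect(panel$participants, out$participant_id),
                   out$participant_id), ]
  if (missing_policy == "drop") out <- out[out$n_missing == 0, ]
  tibble::as_tibble(out)
}

new_tgs_regression <- function(fit, predictor, n) {
  coefs <- stats::coef(summary(fit))
  r <- sqrt(summary(fit)$r.squared) * sign(coefs[2, 1])
  structure(
    list(
      slope = unname(coefs[2, 1]),
      intercept = unname(coefs[1, 1]),
      r = r,
      r2 = summary(fit)$r.squared,
      p_value = unname(coefs[2, 4]),
      n = n,
      predictor = predictor,
      fit = fit
    ),
    class = "tgs_regression"
  )
}

#' @export
print.tgs_regression <- function(x, ...) {
  cat("<tgs_regression> ", x$predictor, " vs percent change (n = ", x$n,
      ")\n", sep = "")
  cat(sprintf("  slope = %.3f, intercept = %.3f\n", x$slope, x$intercept))
  cat(sprintf("  r = %.3f, R^2 = %.3f, p = %.3g\n", x$r, x$r2, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy tgs_regression
#' @export
tidy.tgs_regression <- function(x, ...) {
  coefs <- stats::coef(summary(x$fit))
  tibble::tibble(
    term = rownames(coefs),
    estimate = coefs[, 1],
    std.error = coefs[, 2],
    statistic = coefs[, 3],
    p.value = coefs[, 4]
  )
}

#' @method glance tgs_regression
#' @export
glance.tgs_regression <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r2, p.value = x$p_value,
                 slope = x$slope, intercept = x$intercept, n = x$n)
}

#' Regress training response on the total genotype score
#'
#' Ordinary least squares of the individual percentage improvement on the
#' summed favorable-allele score, with the Pearson correlation, coefficient
#' of determination and the two-sided t-test p-value on the slope. This is
#' the headline test of whether trainability is additively related to the
#' number of favorable alleles possessed.
#'
#' @param scores Tibble from [sum_scores()] (`participant_id`, `total`).
#' @param responses Tibble from [cooper_responses()] (`participant_id`,
#'   `pct_change`); only participants present in both are used.
#' @return A `tgs_regression` object (fields `slope`, `intercept`, `r`,
#'   `r2`, `p_value`, `n`; methods [print()], [tidy()], [glance()],
#'   [ggplot2::autoplot()]).
#' @export
score_regression <- function(scores, responses) {
  df <- dplyr::inner_join(scores[, c("participant_id", "total")],
                          responses[, c("participant_id", "pct_change")],
                          by = "participant_id")
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3) stop("Need at least 3 paired observations", call. = FALSE)
  if (stats::var(df$total) == 0) {
    stop("Zero variance in total score; regression undefined", call. = FALSE)
  }
  fit <- stats::lm(pct_change ~ total, data = df)
  out <- new_tgs_regression(fit, "total genotype score", nrow(df))
  out$data <- df
  out
}

#' Regress training response on baseline fitness
#'
#' As [score_regression()] but with baseline Cooper distance as the
#' predictor, quantifying the dependence of relative improvement on
#' starting fitness (untrained participants have more headroom, so the
#' expected slope is negative).
#'
#' @param responses Tibble from [cooper_responses()] restricted to the
#'   rows to analyse (typically the training arm).
#' @return A `tgs_regression` object.
#' @export
baseline_regression <- function(responses) {
  df <- responses[stats::complete.cases(
    responses[, c("baseline_km", "pct_change")]), ]
  if (nrow(df) < 3) stop("Need at least 3 paired observations", call. = FALSE)
  if (stats::var(df$baseline_km) == 0) {
    stop("Zero variance in baseline; regression undefined", call. = FALSE)
  }
  fit <- stats::lm(pct_change ~ baseline_km, data = df)
  out <- new_tgs_regression(fit, "baseline Cooper distance (km)", nrow(df))
  out$data <- df
  out
}
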