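#' Hardy-Weinberg expected genotype frequencies
#'
#' Expected genotype proportions and counts under Hardy-Weinberg
#' equilibrium given the reference-allele proportion `p`: homozygous
#' reference `p^2`, heterozygous `2p(1-p)`, homozygous alternate `(1-p)^2`,
#' scaled to a cohort of `n` individuals.
#'
#' @param p Reference-allele proportion in \[0, 1\].
#' @param n Cohort size (>= 1).
#' @return Tibble with columns `genotype` (`hom_ref`, `het`, `hom_alt`),
#'   `proportion` and `count` (`n * proportion`, unrounded).
#' @export
#' @examples
#' hwe_expected(0.5, 100) # 25 / 50 / 25
hwe_expected <- function(p, n) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  q <- 1 - p
  props <- c(hom_ref = p^2, het = 2 * p * q, hom_alt = q^2)
  tibble::tibble(
    genotype = names(props),
    proportion = unname(props),
    count = n * unname(props)
  )
}

#' Fisher's exact comparison of observed vs expected genotype counts
#'
#' Compares observed cohort genotype (or allele) counts with expected
#' counts using Fisher's exact test on the 2 x k table of the two count
#' vectors. Expected counts are rounded to the nearest integer first (the
#' exact test is defined on integer tables). When any genotype class has a
#' rounded expected count of zero the comparison falls back to the 2 x 2
#' allele-count table (reference vs alternate allele copies), which is
#' robust to empty genotype classes at small sample sizes. The p-value is
#' two-sided, summing the probability of all tables with the fixed margins
#' whose probability does not exceed the observed table's.
#'
#' @param observed Named or ordered integer vector of observed counts
#'   (`hom_ref`, `het`, `hom_alt` for the genotype model; length 2 for an
#'   allele model).
#' @param expected Numeric vector of expected counts, same classes.
#' @param alpha Exclusion threshold on the p-value (default 0.05).
#' @return Tibble with `p_value`, `excluded` (`p_value <= alpha`), `model`
#'   (`"genotype"` or `"allele"`); the tested table is attached as
#'   attribute `"table"`.
#' @export
fisher_exact_counts <- function(observed, expected, alpha = 0.05) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length", call. = FALSE)
  }
  if (any(observed < 0) || any(round(observed) != observed)) {
    stop("observed counts must be non-negative integers", call. = FALSE)
  }
  expected_int <- round(expected)
  model <- if (length(observed) == 2) "allele" else "genotype"
  if (length(observed) == 3 && any(expected_int == 0)) {
    # genotype classes expected empty: compare allele copies instead
    observed <- c(2 * observed[1] + observed[2], 2 * observed[3] + observed[2])
    expected_int <- c(2 * expected_int[1] + expected_int[2],
                      2 * expected_int[3] + expected_int[2])
    model <- "allele"
  }
  tab <- rbind(observed = as.numeric(observed),
               expected = as.numeric(expected_int))
  empty_col <- colSums(tab) == 0
  tab_test <- tab[, !empty_col, drop = FALSE]
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || ncol(tab_test) < 2) {
    warning("Degenerate count table; p set to 1", call. = FALSE)
    p <- 1
  } else {
    p <- stats::fisher.test(tab_test)$p.value
  }
  out <- tibble::tibble(p_value = p, excluded = p <= alpha, model = model)
  attr(out, "table") <- tab
  out
}

genotype_counts <- function(panel, rsid) {
  meta <- panel$meta[panel$meta$rsid == rsid, ]
  calls <- panel$calls[panel$calls$rsid == rsid & !is.na(panel$calls$a1), ]
  n_ref <- (calls$a1 == meta$ref) + (calls$a2 == meta$ref)
  c(hom_ref = sum(n_ref == 2), het = sum(n_ref == 1),
    hom_alt = sum(n_ref == 0))
}

#' Flag SNPs whose cohort frequencies deviate from the population
#'
#' For every SNP with a known population alternate-allele frequency,
#' compares the cohort's observed genotype counts with the Hardy-Weinberg
#' expectation at that frequency using [fisher_exact_counts()]. SNPs with
#' exact p <= `alpha` are flagged for exclusion from scoring; SNPs lacking
#' a population frequency are skipped with a warning. Exclusion guards the
#' favorable-allele score against SNPs whose cohort allele distribution is
#' unrepresentative of the reference population (e.g. genotyping artefacts
#' or cohort stratification).
#'
#' @param panel A [genotype_panel()] (metadata column `pop_alt_freq` holds
#'   the population alternate-allele proportion).
#' @param alpha Exclusion threshold (default 0.05).
#' @param rsids Optional subset of SNPs to test (default: all with
#'   frequency metadata).
#' @return Tibble `rsid`, `p_value`, `excluded`, `reason`, sorted by
#'   `p_value`.
#' @export
flag_population_outliers <- function(panel, alpha = 0.05, rsids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  meta <- panel$meta
  if (!is.null(rsids)) meta <- meta[meta$rsid %in% rsids, ]
  skipped <- meta$rsid[is.na(meta$pop_alt_freq)]
  if (length(skipped) > 0) {
    warning(length(skipped), " SNP(s) lack pop_alt_freq and were skipped",
            call. = FALSE)
  }
  meta <- meta[!is.na(meta$pop_alt_freq), ]
  rows <- purrr::map(meta$rsid, function(rs) {
    obs <- genotype_counts(panel, rs)
    n <- sum(obs)
    if (n == 0) {
      return(tibble::tibble(rsid = rs, p_value = NA_real_, excluded = FALSE,
                            reason = "no non-missing calls"))
    }
    p_ref <- 1 - meta$pop_alt_freq[meta$rsid == rs]
    expected <- hwe_expected(p_ref, n)$count
    res <- suppressWarnings(fisher_exact_counts(obs, expected, alpha))
    tibble::tibble(
      rsid = rs, p_value = res$p_value, excluded = res$excluded,
      reason = ifelse(res$excluded,
                      "cohort frequencies deviate from population (HWE)", "")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(rsid = character(), p_value = numeric(),
                          excluded = logical(), reason = character()))
  }
  dplyr::arrange(out, .data$p_value, .data$rsid)
}
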