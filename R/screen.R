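#' Build a responder-by-allele contingency table for one SNP
#'
#' Cross-tabulates responder class against alleles (each participant
#' contributes two allele counts) or genotypes (one count per participant)
#' among classified training-arm participants. Participants with a missing
#' genotype at the SNP are excluded from that SNP's table only.
#'
#' @param panel A [genotype_panel()].
#' @param classes Tibble from [dichotomize_responders()]
#'   (`participant_id`, `responder`).
#' @param rsid SNP to tabulate.
#' @param model `"allele"` (2 x 2, default) or `"genotype"` (2 x up-to-3).
#' @return Integer matrix with rows `responder`, `non_responder`; columns
#'   named by allele (ref, alt order) or genotype.
#' @export
build_contingency <- function(panel, classes, rsid,
                              model = c("allele", "genotype")) {
  model <- match.arg(model)
  stopifnot(inherits(panel, "genotype_panel"))
  meta <- panel$meta[panel$meta$rsid == rsid, ]
  if (nrow(meta) == 0) stop("Unknown rsid: ", rsid, call. = FALSE)
  cls <- classes[!is.na(classes$responder),
                 c("participant_id", "responder")]
  calls <- panel$calls[panel$calls$rsid == rsid, ]
  df <- dplyr::inner_join(cls, calls, by = "participant_id")
  df <- df[!is.na(df$a1), ]
  if (nrow(df) < 2) {
    stop("Fewer than 2 classified participants with calls at ", rsid,
         call. = FALSE)
  }
  row_lab <- factor(ifelse(df$responder, "responder", "non_responder"),
                    levels = c("responder", "non_responder"))
  if (model == "allele") {
    alleles <- factor(c(df$a1, df$a2), levels = c(meta$ref, meta$alt))
    tab <- table(rep(row_lab, 2), alleles)
  } else {
    ref <- meta$ref
    alt <- meta$alt
    lv <- c(paste0(ref, ref), genotype_string(ref, alt), paste0(alt, alt))
    n_ref <- (df$a1 == ref) + (df$a2 == ref)
    gts <- factor(lv[3 - n_ref], levels = lv)
    tab <- table(row_lab, gts)
  }
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(rownames(tab), colnames(tab)))
  rownames(m) <- c("responder", "non_responder")
  m
}

pearson_chisq <- function(tab) {
  # Pearson chi-square without continuity correction; degenerate margins
  # yield statistic 0, p 1
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (any(rowSums(tab) == 0) || ncol(tab) < 2) {
    return(list(stat = 0, p = 1, df = NA_integer_))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(stat = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

#' Chi-square screen of a SNP panel against responder class
#'
#' Screens every SNP in the panel for association between its alleles (or
#' genotypes) and responder class using Pearson's chi-square test without
#' continuity correction. SNPs are banded by p-value: `primary`
#' (p <= `alpha`), `secondary` (`alpha` < p <= `secondary_max`, a
#' near-significance band carried forward to confirmation), or `none`.
#' No multiple-testing correction is applied by default — on a null panel
#' the primary band is expected to capture a fraction `alpha` of SNPs, and
#' the count of screen hits grows linearly with panel size; downstream
#' confirmation and the additive-structure check are the intended guards.
#' An optional Bonferroni/Benjamini-Hochberg switch supports sensitivity
#' analysis.
#'
#' @param panel A [genotype_panel()] (polymorphic SNPs).
#' @param classes Tibble from [dichotomize_responders()].
#' @param alpha Primary-band threshold (default 0.05).
#' @param secondary_max Upper edge of the secondary band (default 0.075).
#' @param model Contingency model passed to [build_contingency()].
#' @param correction `"none"` (default), `"bonferroni"` or `"bh"`; applied
#'   to the banding p-values when requested.
#' @return Tibble `rsid`, `chi2_stat`, `chi2_p`, `band`, sorted by
#'   `chi2_p` ascending with lexicographic rsid tie-break.
#' @export
chi_square_screen <- function(panel, classes, alpha = 0.05,
                              secondary_max = 0.075,
                              model = c("allele", "genotype"),
                              correction = c("none", "bonferroni", "bh")) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  stopifnot(inherits(panel, "genotype_panel"))
  rsids <- panel$meta$rsid
  if (length(rsids) == 0) stop("Empty panel", call. = FALSE)
  rows <- purrr::map(rsids, function(rs) {
    tab <- tryCatch(build_contingency(panel, classes, rs, model),
                    error = function(e) NULL)
    if (is.null(tab)) {
      return(tibble::tibble(rsid = rs, chi2_stat = NA_real_, chi2_p = 1))
    }
    cs <- pearson_chisq(tab)
    tibble::tibble(rsid = rs, chi2_stat = cs$stat, chi2_p = cs$p)
  })
  out <- dplyr::bind_rows(rows)
  p_band <- switch(correction,
    none = out$chi2_p,
    bonferroni = stats::p.adjust(out$chi2_p, "bonferroni"),
    bh = stats::p.adjust(out$chi2_p, "BH")
  )
  out$band <- dplyr::case_when(
    p_band <= alpha ~ "primary",
    p_band <= secondary_max ~ "secondary",
    TRUE ~ "none"
  )
  dplyr::arrange(out, .data$chi2_p, .data$rsid)
}

#' One-way ANOVA confirmation of screened SNPs
#'
#' For each candidate SNP, fits a one-way ANOVA of training-arm percentage
#' improvement across genotype groups, recording Levene's test for
#' homogeneity of variance alongside. Genotype groups with fewer than
#' `min_group` members are dropped (default) or merged into the
#' heterozygote group. A SNP is confirmed when the ANOVA p-value is at most
#' `alpha` and Levene's p exceeds `alpha` (the variance gate the screen's
#' parametric assumption requires). SNPs with fewer than two genotype
#' groups after the size rule get `anova_p = 1` and are not confirmed.
#'
#' @param panel A [genotype_panel()].
#' @param responses Tibble from [cooper_responses()] (training arm rows
#'   are used).
#' @param candidates Character vector of rsids to confirm (typically the
#'   primary + secondary bands of [chi_square_screen()]).
#' @param alpha Confirmation threshold (default 0.05).
#' @param min_group Minimum genotype-group size (default 2).
#' @param small_groups `"drop"` (default) or `"merge"` into the
#'   heterozygote group.
#' @return Tibble `rsid`, `anova_F`, `anova_p`, `levene_p`, `confirmed`.
#' @export
anova_confirm <- function(panel, responses, candidates, alpha = 0.05,
                          min_group = 2,
                          small_groups = c("drop", "merge")) {
  small_groups <- match.arg(small_groups)
  stopifnot(inherits(panel, "genotype_panel"))
  if (length(candidates) == 0) {
    return(tibble::tibble(rsid = character(), anova_F = numeric(),
                          anova_p = numeric(), levene_p = numeric(),
                          confirmed = logical()))
  }
  eg <- responses[responses$group == "EG" & !is.na(responses$pct_change),
                  c("participant_id", "pct_change")]
  gts <- panel_genotypes(panel)
  rows <- purrr::map(candidates, function(rs) {
    df <- dplyr::inner_join(eg, gts[gts$rsid == rs, ], by = "participant_id")
    df <- df[!is.na(df$genotype), ]
    counts <- table(df$genotype)
    small <- names(counts)[counts < min_group]
    if (length(small) > 0) {
      if (small_groups == "merge") {
        meta <- panel$meta[panel$meta$rsid == rs, ]
        het <- genotype_string(meta$ref, meta$alt)
        if (het %in% names(counts)) {
          df$genotype[df$genotype %in% small] <- het
        } else {
          df <- df[!df$genotype %in% small, ]
        }
      } else {
        df <- df[!df$genotype %in% small, ]
      }
    }
    if (dplyr::n_distinct(df$genotype) < 2 || nrow(df) < 3) {
      return(tibble::tibble(rsid = rs, anova_F = NA_real_, anova_p = 1,
                            levene_p = NA_real_, confirmed = FALSE))
    }
    df$genotype <- factor(df$genotype)
    fit <- stats::aov(pct_change ~ genotype, data = df)
    an <- summary(fit)[[1]]
    f_val <- an[["F value"]][1]
    p_val <- an[["Pr(>F)"]][1]
    if (is.na(p_val)) { f_val <- 0; p_val <- 1 }
    # tiny genotype groups can make the deviation fit degenerate; the
    # resulting NaN is treated as "no evidence of heterogeneity"
    lev <- tryCatch(
      suppressWarnings(
        car::leveneTest(pct_change ~ genotype, data = df,
                        center = mean)[["Pr(>F)"]][1]
      ),
      error = function(e) NA_real_
    )
    tibble::tibble(
      rsid = rs, anova_F = f_val, anova_p = p_val, levene_p = lev,
      confirmed = p_val <= alpha & (is.na(lev) | lev > alpha)
    )
  })
  dplyr::bind_rows(rows)
}

#' Assign the favorable allele of a screened SNP
#'
#' The favorable (positive) allele is the one whose relative frequency is
#' higher among responders than among non-responders. An exact tie leaves
#' the SNP unresolved (`NA`) with a warning; such SNPs are dropped from
#' scoring.
#'
#' @param table 2 x 2 allele-model contingency matrix from
#'   [build_contingency()] (rows `responder`, `non_responder`; columns
#'   named by allele). Genotype-model tables are collapsed to allele
#'   counts first.
#' @return Single character: the favorable allele, or `NA` on a tie.
#' @export
#' @examples
#' tab <- matrix(c(3, 0, 1, 4), 2,
#'               dimnames = list(c("responder", "non_responder"), c("C", "T")))
#' assign_favorable_allele(tab) # "C"
assign_favorable_allele <- function(table) {
  if (ncol(table) == 3) {
    # genotype columns (e.g. CC | CT | TT) -> allele copies
    ref <- substr(colnames(table)[1], 1, 1)
    alt <- substr(colnames(table)[3], 1, 1)
    table <- cbind(2 * table[, 1] + table[, 2], 2 * table[, 3] + table[, 2])
    colnames(table) <- c(ref, alt)
  }
  tot <- rowSums(table)
  if (any(tot == 0)) {
    warning("Empty responder class; favorable allele unresolved",
            call. = FALSE)
    return(NA_character_)
  }
  f_resp <- table["responder", ] / tot["responder"]
  f_non <- table["non_responder", ] / tot["non_responder"]
  diff <- f_resp - f_non
  if (isTRUE(all.equal(max(diff), min(diff)))) {
    warning("Allele frequencies tied between classes; unresolved",
            call. = FALSE)
    return(NA_character_)
  }
  colnames(table)[which.max(diff)]
}
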