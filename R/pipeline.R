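#' Run the discovery pipeline end to end
#'
#' Orchestrates the full genotype-to-trainability analysis:
#'
#' 1. consistency filtering of replicate probe calls and high-missingness
#'    participants ([filter_inconsistent()]);
#' 2. monomorphic SNP removal ([remove_monomorphic()]);
#' 3. response phenotypes and responder dichotomisation
#'    ([cooper_responses()], [dichotomize_responders()]);
#' 4. chi-square screen with p-value banding ([chi_square_screen()]);
#' 5. one-way ANOVA confirmation of banded SNPs with Levene gating
#'    ([anova_confirm()]);
#' 6. Fisher's exact comparison of confirmed SNPs' cohort frequencies
#'    against population expectations, excluding deviating SNPs
#'    ([flag_population_outliers()]);
#' 7. favorable-allele assignment ([assign_favorable_allele()]);
#' 8. additive 0/1/2 scoring and regression of percentage improvement on
#'    the total score ([sum_scores()], [score_regression()]), plus the
#'    baseline-fitness regression.
#'
#' A SNP is retained for scoring when its screen band is primary or
#' secondary, its ANOVA confirms at `confirm_alpha` with homogeneous
#' variance, it is not population-excluded, and its favorable allele is
#' resolved.
#'
#' @param cohort A `tgs_cohort` (from [simulate_cohort()] /
#'   [read_cohort()]), or a list with elements `panel` (a
#'   [genotype_panel()]) and `cooper` (long Cooper-test tibble).
#' @param screen_alpha Primary-band threshold for the screen (default
#'   0.05).
#' @param secondary_max Upper edge of the secondary screen band (default
#'   0.075).
#' @param confirm_alpha ANOVA confirmation threshold (default 0.05).
#' @param fisher_alpha Population-frequency exclusion threshold (default
#'   0.05).
#' @param model Contingency model, `"allele"` (default) or `"genotype"`.
#' @param correction Multiplicity handling in the screen: `"none"`
#'   (default), `"bonferroni"`, `"bh"`.
#' @param missing_policy Missing-genotype policy for scoring (see
#'   [sum_scores()]).
#' @param max_missing Participant missingness ceiling (see
#'   [filter_inconsistent()]).
#' @return A `tgs_run`: list with `counts`, `screen` (per-SNP results
#'   table), `scores`, `regression`, `baseline_reg`, `responses`,
#'   `audit`, `panel`.
#' @export
run_discovery <- function(cohort,
                          screen_alpha = 0.05, secondary_max = 0.075,
                          confirm_alpha = 0.05, fisher_alpha = 0.05,
                          model = c("allele", "genotype"),
                          correction = c("none", "bonferroni", "bh"),
                          missing_policy = c("zero", "drop"),
                          max_missing = 0.2) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  missing_policy <- match.arg(missing_policy)
  panel <- cohort$panel
  cooper <- tibble::as_tibble(cohort$cooper)
  stopifnot(inherits(panel, "genotype_panel"))

  orphans <- setdiff(panel$participants, unique(cooper$participant_id))
  if (length(orphans) > 0) {
    stop("Participant(s) genotyped but missing from phenotypes: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }

  n_input <- nrow(panel$meta)
  fi <- filter_inconsistent(panel, max_missing = max_missing)
  panel <- fi$panel
  rm <- remove_monomorphic(panel)
  panel <- rm$panel

  responses <- cooper_responses(cooper)
  responses <- responses[responses$participant_id %in% panel$participants, ]
  classes <- dichotomize_responders(responses)

  screen <- chi_square_screen(panel, classes, alpha = screen_alpha,
                              secondary_max = secondary_max, model = model,
                              correction = correction)
  candidates <- screen$rsid[screen$band != "none"]
  confirm <- anova_confirm(panel, responses, candidates,
                           alpha = confirm_alpha)
  confirmed <- confirm$rsid[confirm$confirmed]
  fisher <- if (length(confirmed) > 0) {
    suppressWarnings(
      flag_population_outliers(panel, alpha = fisher_alpha,
                               rsids = confirmed)
    )
  } else {
    tibble::tibble(rsid = character(), p_value = numeric(),
                   excluded = logical(), reason = character())
  }

  tab <- dplyr::left_join(screen, confirm, by = "rsid")
  tab <- dplyr::left_join(
    tab, fisher[, c("rsid", "p_value", "excluded")], by = "rsid"
  )
  names(tab)[names(tab) == "p_value"] <- "fisher_p"
  tab$excluded[is.na(tab$excluded)] <- FALSE
  tab$confirmed[is.na(tab$confirmed)] <- FALSE
  tab$retained <- tab$band != "none" & tab$confirmed & !tab$excluded

  fav <- purrr::map_chr(tab$rsid, function(rs) {
    if (!tab$retained[tab$rsid == rs]) return(NA_character_)
    ct <- build_contingency(panel, classes, rs, model = "allele")
    suppressWarnings(assign_favorable_allele(ct))
  })
  tab$favorable_allele <- fav
  tab$retained <- tab$retained & !is.na(tab$favorable_allele)
  tab <- dplyr::left_join(
    tab,
    panel$meta[, c("rsid", "gene", "ref", "alt", "consequence", "chrom",
                   "pos")],
    by = "rsid"
  )

  retained <- tab[tab$retained, ]
  scores <- NULL
  regression <- NULL
  if (nrow(retained) > 0) {
    fav_tab <- retained[, c("rsid", "favorable_allele")]
    eg_ids <- classes$participant_id[!is.na(classes$responder)]
    sc_panel <- panel
    sc_panel$calls <- sc_panel$calls[
      sc_panel$calls$participant_id %in% eg_ids, ]
    sc_panel$participants <- intersect(sc_panel$participants, eg_ids)
    scores <- sum_scores(sc_panel, fav_tab, missing_policy = missing_policy)
    regression <- tryCatch(score_regression(scores, responses),
                           error = function(e) NULL)
  }
  baseline_reg <- tryCatch(
    baseline_regression(responses[responses$group == "EG", ]),
    error = function(e) NULL
  )

  counts <- list(
    input_snps = n_input,
    monomorphic_removed = rm$n_removed,
    polymorphic = nrow(panel$meta),
    participants_dropped =
      sum(fi$audit$type == "participant_dropped"),
    chi2_primary = sum(screen$band == "primary"),
    chi2_secondary = sum(screen$band == "secondary"),
    anova_confirmed = length(confirmed),
    population_excluded = sum(tab$excluded),
    final_snps = sum(tab$retained),
    scored_participants = if (is.null(scores)) 0L else nrow(scores)
  )
  structure(
    list(counts = counts, screen = tab, scores = scores,
         regression = regression, baseline_reg = baseline_reg,
         responses = classes, audit = fi$audit, panel = panel),
    class = "tgs_run"
  )
}

#' @export
print.tgs_run <- function(x, ...) {
  c <- x$counts
  cat("<tgs_run>\n")
  cat("  SNPs: ", c$input_snps, " input, ", c$monomorphic_removed,
      " monomorphic removed, ", c$polymorphic, " screened\n", sep = "")
  cat("  Screen: ", c$chi2_primary, " primary + ", c$chi2_secondary,
      " secondary; ", c$anova_confirmed, " ANOVA-confirmed; ",
      c$population_excluded, " population-excluded; ", c$final_snps,
      " retained\n", sep = "")
  if (!is.null(x$regression)) {
    cat(sprintf("  Score regression (n = %d): r = %.3f, R^2 = %.3f, p = %.3g\n",
                x$regression$n, x$regression$r, x$regression$r2,
                x$regression$p_value))
  } else {
    cat("  Score regression: not computed (no retained SNPs)\n")
  }
  invisible(x)
}

#' Candidate-SNP report table
#'
#' Formats a run's screened SNPs as a candidate-gene report: one row per
#' SNP in the screen bands, sorted by chi-square p-value, with the Fisher
#' exact p, ANOVA p, favorable (positive) allele and coding status.
#' Population-excluded SNPs stay listed, annotated in the `excluded`
#' column, rather than being silently dropped.
#'
#' @param run A `tgs_run` from [run_discovery()].
#' @param path Optional path; when given the table is also written as CSV.
#' @return Tibble with columns `SNP`, `Gene`, `Alleles`, `Type`,
#'   `Position`, `FisherExact`, `p_chi2`, `p_ANOVA`, `PositiveAllele`,
#'   `Coding`, `excluded`.
#' @export
render_table1 <- function(run, path = NULL) {
  stopifnot(inherits(run, "tgs_run"))
  tab <- run$screen
  tab <- tab[tab$retained | tab$excluded, ]
  out <- tibble::tibble(
    SNP = tab$rsid,
    Gene = tab$gene,
    Alleles = paste0(tab$ref, ">", tab$alt),
    Type = tab$consequence,
    Position = paste0(tab$chrom, ":", tab$pos),
    FisherExact = tab$fisher_p,
    p_chi2 = tab$chi2_p,
    p_ANOVA = tab$anova_p,
    PositiveAllele = tab$favorable_allele,
    Coding = ifelse(
      tab$consequence %in% c("missense", "synonymous", "stop-gain"),
      "Yes", "No"),
    excluded = tab$excluded
  )
  out <- dplyr::arrange(out, .data$p_chi2, .data$SNP)
  if (!is.null(path)) readr::write_csv(out, path, progress = FALSE)
  out
}
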