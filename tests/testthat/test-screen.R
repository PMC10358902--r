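# 4 classified participants at one SNP: responders CC, CT;
# non-responders TT, TT (ref C, alt T)
screen_fixture <- function() {
  meta <- tibble::tibble(rsid = "rs1", gene = "G1", ref = "C", alt = "T",
                         consequence = "intron variant", chrom = "chr1",
                         pos = 1L, pop_alt_freq = 0.4)
  gs <- c("CC", "CT", "TT", "TT")
  calls <- tibble::tibble(
    participant_id = paste0("E", 1:4), rsid = "rs1",
    a1 = substr(gs, 1, 1), a2 = substr(gs, 2, 2)
  )
  classes <- tibble::tibble(
    participant_id = paste0("E", 1:4), group = "EG",
    pct_change = c(20, 18, 2, 4),
    responder = c(TRUE, TRUE, FALSE, FALSE)
  )
  list(panel = genotype_panel(calls, meta), classes = classes)
}

test_that("contingency tables count alleles and genotypes by hand", {
  fx <- screen_fixture()
  tab_a <- build_contingency(fx$panel, fx$classes, "rs1", model = "allele")
  expect_equal(unname(tab_a), matrix(c(3, 0, 1, 4), 2))
  expect_equal(colnames(tab_a), c("C", "T"))
  # allele column totals are twice the classified participants
  expect_equal(sum(tab_a), 2 * 4)

  tab_g <- build_contingency(fx$panel, fx$classes, "rs1", model = "genotype")
  expect_equal(unname(tab_g), matrix(c(1, 0, 1, 0, 0, 2), 2))

  # a missing call drops that participant from this SNP's table only
  panel2 <- fx$panel
  panel2$calls$a1[1] <- NA
  panel2$calls$a2[1] <- NA
  tab2 <- build_contingency(panel2, fx$classes, "rs1")
  expect_equal(sum(tab2), 2 * 3)
})

test_that("Pearson chi-square matches the closed 2x2 form", {
  # perfect separation example
  tab <- matrix(c(10, 0, 0, 10), 2,
                dimnames = list(c("responder", "non_responder"), c("A", "B")))
  cs <- tgscore:::pearson_chisq(tab)
  expect_equal(cs$stat, 20, tolerance = 1e-12)
  expect_equal(cs$p, stats::pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # independence
  cs2 <- tgscore:::pearson_chisq(matrix(c(5, 5, 5, 5), 2))
  expect_equal(cs2$stat, 0)
  expect_equal(cs2$p, 1)
  # random tables against the closed form
  set.seed(5)
  for (i in 1:30) {
    tab <- matrix(stats::rpois(4, 8) + 1, 2)
    expect_equal(tgscore:::pearson_chisq(tab)$stat, chisq_2x2_closed(tab),
                 tolerance = 1e-9)
  }
})

test_that("screen bands, sorts deterministically, and honours correction", {
  set.seed(41)
  cfg <- sim_config(n_train = 40, n_control = 10, n_snps = 60,
                    monomorphic_fraction = 0, n_causal = 6,
                    effect_per_allele = 8, noise_sd = 4, seed = 41)
  co <- simulate_cohort(cfg, artifacts = FALSE)
  classes <- dichotomize_responders(cooper_responses(co$cooper))
  sc <- chi_square_screen(co$panel, classes)
  # deterministic ordering: p ascending, rsid tie-break
  expect_equal(sc, dplyr::arrange(sc, chi2_p, rsid))
  expect_true(all(sc$band[sc$chi2_p <= 0.05] == "primary"))
  expect_true(all(sc$band[sc$chi2_p > 0.075] == "none"))
  # Bonferroni never enlarges the primary band
  sc_b <- chi_square_screen(co$panel, classes, correction = "bonferroni")
  expect_lte(sum(sc_b$band == "primary"), sum(sc$band == "primary"))
  expect_true(all(sc_b$rsid[sc_b$band == "primary"] %in%
                    sc$rsid[sc$band == "primary"]))
})

test_that("null screens capture about alpha in the primary band", {
  set.seed(57)
  fracs <- vapply(1:8, function(i) {
    cfg <- sim_config(n_train = 21, n_control = 5, n_snps = 80,
                      monomorphic_fraction = 0, n_causal = 2,
                      effect_per_allele = 0, noise_sd = 9.09,
                      seed = 57 + i)
    co <- simulate_cohort(cfg, artifacts = FALSE)
    classes <- dichotomize_responders(cooper_responses(co$cooper))
    sc <- chi_square_screen(co$panel, classes)
    mean(sc$band == "primary")
  }, numeric(1))
  # discrete small-sample chi-square is conservative-to-nominal; the
  # primary fraction should sit near alpha, not far above
  expect_lt(mean(fracs), 0.09)
  expect_gt(mean(fracs), 0.005)
})

test_that("ANOVA confirmation reproduces the sum-of-squares oracle", {
  meta <- tibble::tibble(rsid = "rs1", gene = "G1", ref = "C", alt = "T",
                         consequence = "intron variant", chrom = "chr1",
                         pos = 1L, pop_alt_freq = NA_real_)
  gs <- c("CC", "CC", "TT", "TT")
  calls <- tibble::tibble(participant_id = paste0("E", 1:4), rsid = "rs1",
                          a1 = substr(gs, 1, 1), a2 = substr(gs, 2, 2))
  panel <- genotype_panel(calls, meta)
  responses <- tibble::tibble(
    participant_id = paste0("E", 1:4), group = "EG",
    pct_change = c(10, 12, 20, 22)
  )
  res <- anova_confirm(panel, responses, "rs1")
  oracle <- anova_f_hand(list(c(10, 12), c(20, 22)))
  expect_equal(res$anova_F, oracle$f, tolerance = 1e-12)
  expect_equal(res$anova_p, oracle$p, tolerance = 1e-12)
  expect_true(res$confirmed)

  # identical group means: F = 0, p = 1
  responses2 <- responses
  responses2$pct_change <- c(10, 12, 10, 12)
  res2 <- anova_confirm(panel, responses2, "rs1")
  expect_equal(res2$anova_F, 0)
  expect_equal(res2$anova_p, 1)
  expect_false(res2$confirmed)

  # fewer than two groups after the size rule: p 1, not confirmed
  gs3 <- c("CC", "CC", "CC", "CT")
  panel3 <- genotype_panel(
    tibble::tibble(participant_id = paste0("E", 1:4), rsid = "rs1",
                   a1 = substr(gs3, 1, 1), a2 = substr(gs3, 2, 2)), meta)
  res3 <- anova_confirm(panel3, responses, "rs1", min_group = 2)
  expect_equal(res3$anova_p, 1)
  expect_false(res3$confirmed)
})

test_that("a planted additive SNP is confirmed with high probability", {
  set.seed(73)
  hits <- vapply(1:15, function(i) {
    copies <- stats::rbinom(100, 2, 0.5)
    pct <- 2 + 6 * copies + stats::rnorm(100, 0, 6)
    gs <- c("TT", "CT", "CC")[copies + 1]
    meta <- tibble::tibble(rsid = "rs1", gene = "G", ref = "C", alt = "T",
                           consequence = "intron variant", chrom = "chr1",
                           pos = 1L, pop_alt_freq = NA_real_)
    panel <- genotype_panel(
      tibble::tibble(participant_id = sprintf("E%03d", 1:100), rsid = "rs1",
                     a1 = substr(gs, 1, 1), a2 = substr(gs, 2, 2)), meta)
    responses <- tibble::tibble(participant_id = sprintf("E%03d", 1:100),
                                group = "EG", pct_change = pct)
    anova_confirm(panel, responses, "rs1")$confirmed
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("favorable allele is the one enriched among responders", {
  fx <- screen_fixture()
  tab <- build_contingency(fx$panel, fx$classes, "rs1")
  expect_equal(assign_favorable_allele(tab), "C")
  # symmetric table is unresolved
  tie <- matrix(c(2, 2, 2, 2), 2,
                dimnames = list(c("responder", "non_responder"), c("C", "T")))
  expect_warning(fa <- assign_favorable_allele(tie), "tie")
  expect_true(is.na(fa))
  # genotype-model table collapses to allele counts
  tab_g <- build_contingency(fx$panel, fx$classes, "rs1", model = "genotype")
  expect_equal(assign_favorable_allele(tab_g), "C")
})
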