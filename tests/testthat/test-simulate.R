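test_that("simulation is fully determined by config and seed", {
  cfg <- sim_config(n_train = 8, n_control = 8, n_snps = 40,
                    probe_inconsistency_rate = 0.02, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$panel$calls, b$panel$calls)
  expect_identical(a$panel$probes, b$panel$probes)
  expect_identical(a$cooper, b$cooper)
  expect_identical(a$diaries, b$diaries)
  c <- simulate_cohort(sim_config(n_train = 8, n_control = 8, n_snps = 40,
                                  probe_inconsistency_rate = 0.02,
                                  seed = 124))
  expect_false(identical(a$panel$calls, c$panel$calls))
})

test_that("derived config calibration hits the planted moments", {
  cfg <- sim_config()
  # genetic variance + noise variance = target response variance
  score_var <- cfg$n_causal * 2 * cfg$causal_freq * (1 - cfg$causal_freq)
  expect_equal(cfg$effect_per_allele^2 * score_var + cfg$noise_sd^2,
               cfg$response_sd^2, tolerance = 1e-9)
  # planted R^2
  expect_equal(cfg$effect_per_allele^2 * score_var / cfg$response_sd^2,
               cfg$target_r2, tolerance = 1e-9)
  # planted mean
  expect_equal(cfg$train_intercept +
                 cfg$effect_per_allele * cfg$n_causal * 2 * cfg$causal_freq,
               cfg$response_mean, tolerance = 1e-9)
})

test_that("genotype draws follow Hardy-Weinberg proportions", {
  set.seed(1)
  cfg <- sim_config(n_train = 5000, n_control = 5000, n_snps = 3,
                    monomorphic_fraction = 0, n_causal = 1,
                    causal_freq = 0.5, seed = 1)
  g <- simulate_genotypes(cfg)
  rs <- g$causal$rsid[1]
  meta <- g$panel$meta[g$panel$meta$rsid == rs, ]
  calls <- g$panel$calls[g$panel$calls$rsid == rs, ]
  n_alt <- (calls$a1 == meta$alt) + (calls$a2 == meta$alt)
  props <- table(factor(n_alt, levels = 0:2)) / length(n_alt)
  # binomial sampling error bound: 3 SE at n = 10,000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(props[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(props[2] - 0.50), 3 * sqrt(0.5 * 0.5 / 10000))
  expect_lt(abs(props[3] - 0.25), 3 * se)
})

test_that("monomorphic fraction and removal counts are exact", {
  co <- simulate_cohort(sim_config(seed = 5), artifacts = FALSE)
  res <- remove_monomorphic(co$panel)
  expect_equal(res$n_removed, 285)
  expect_equal(nrow(res$panel$meta), 715)
})

test_that("planted truth equals the score recomputed from the panel", {
  co <- simulate_cohort(sim_config(n_train = 10, n_control = 5,
                                   n_snps = 30, monomorphic_fraction = 0.2,
                                   seed = 9), artifacts = FALSE)
  sc <- sum_scores(co$panel,
                   co$truth$causal[, c("rsid", "favorable_allele")])
  truth <- co$truth$scores
  expect_equal(sc$total[match(truth$participant_id, sc$participant_id)],
               truth$true_score)
})

test_that("artifact injection plants recoverable defects", {
  # zero rate: the consistency filter removes nothing
  co0 <- simulate_cohort(sim_config(n_train = 5, n_control = 5,
                                    n_snps = 20, monomorphic_fraction = 0,
                                    probe_inconsistency_rate = 0, seed = 3),
                         artifacts = TRUE)
  f0 <- filter_inconsistent(co0$panel)
  expect_equal(nrow(f0$audit), 0)

  # named corrupt participants are dropped downstream
  co1 <- simulate_cohort(
    sim_config(n_train = 8, n_control = 8, n_snps = 30,
               monomorphic_fraction = 0,
               corrupt_participants = c("EG06", "EG08"), seed = 4),
    artifacts = TRUE)
  f1 <- filter_inconsistent(co1$panel)
  dropped <- f1$audit$participant_id[f1$audit$type == "participant_dropped"]
  expect_setequal(dropped, c("EG06", "EG08"))

  # rate r at m SNPs x k participants: blanked-call count within 3 SE
  rate <- 0.05
  co2 <- simulate_cohort(
    sim_config(n_train = 20, n_control = 20, n_snps = 100,
               monomorphic_fraction = 0,
               probe_inconsistency_rate = rate, seed = 6),
    artifacts = TRUE)
  f2 <- filter_inconsistent(co2$panel, max_missing = 1)
  n_cells <- 100 * 40
  n_blanked <- sum(f2$audit$type == "call_set_missing")
  expect_lt(abs(n_blanked - rate * n_cells),
            3 * sqrt(n_cells * rate * (1 - rate)))
})

test_that("written cohorts round-trip exactly", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_train = 6, n_control = 6, n_snps = 15,
                                   monomorphic_fraction = 0.2, n_causal = 5,
                                   seed = 12), artifacts = FALSE)
  write_cohort(co, file.path(dir, "c1"))
  co2 <- read_cohort(file.path(dir, "c1"))
  write_cohort(co2, file.path(dir, "c2"))
  for (f in c("genotypes.tsv", "snp_meta.csv", "phenotypes.csv",
              "diary.csv", "truth.json")) {
    expect_identical(readLines(file.path(dir, "c1", f)),
                     readLines(file.path(dir, "c2", f)),
                     label = f)
  }
  # truth scores still match a recomputation after the round trip
  sc <- sum_scores(co2$panel,
                   co2$truth$causal[, c("rsid", "favorable_allele")])
  expect_equal(sc$total[match(co2$truth$scores$participant_id,
                              sc$participant_id)],
               co2$truth$scores$true_score)
})

test_that("favorable-allele recovery is far above chance at n = 100 per arm", {
  set.seed(33)
  accs <- vapply(1:10, function(i) {
    cfg <- sim_config(n_train = 100, n_control = 100, n_snps = 18,
                      monomorphic_fraction = 0, n_causal = 18,
                      effect_per_allele = 4, noise_sd = 4,
                      seed = 33000 + i)
    co <- simulate_cohort(cfg, artifacts = FALSE)
    resp <- dichotomize_responders(cooper_responses(co$cooper))
    truth <- co$truth$causal
    fav <- vapply(truth$rsid, function(rs) {
      tab <- build_contingency(co$panel, resp, rs)
      suppressWarnings(assign_favorable_allele(tab))
    }, character(1))
    mean(fav == truth$favorable_allele, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(accs), 0.9)
})
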