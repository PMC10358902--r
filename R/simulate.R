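#' Simulation configuration for a synthetic training cohort
#'
#' Defines the generative model for a synthetic cohort with the
#' statistical structure the analysis pipeline assumes: a biallelic SNP
#' panel with a fixed monomorphic fraction and Hardy-Weinberg genotypes, a
#' set of causal SNPs with equal additive effects on the percentage
#' training response, and Gaussian noise calibrated so that the planted
#' score-response coefficient of determination, response mean and response
#' SD hit their targets.
#'
#' Derived quantities (when not supplied explicitly): with `m` causal SNPs
#' at favorable-allele frequency `f` and equal per-allele effect `b`, the
#' genetic variance of the response is `b^2 * m * 2 f (1 - f)`; `b` is
#' chosen so this equals `target_r2 * response_sd^2`, the residual SD is
#' `sqrt((1 - target_r2)) * response_sd`, and the intercept shifts the
#' mean response to `response_mean` given the expected score `2 m f`.
#'
#' @param n_train,n_control Arm sizes (defaults 21 and 24).
#' @param n_snps Panel size (default 1000).
#' @param monomorphic_fraction Fraction of panel SNPs fixed for one allele
#'   (default 0.285).
#' @param n_causal Number of causal SNPs (default 18).
#' @param causal_freq Favorable-allele population frequency of causal SNPs
#'   (default 0.5).
#' @param response_mean,response_sd Target mean and SD of the training-arm
#'   percentage improvement (defaults 11.51 and 9.09).
#' @param target_r2 Planted score-response R^2 (default 0.85).
#' @param effect_per_allele,noise_sd,train_intercept Override the derived
#'   per-allele effect (% points), residual SD (%), and intercept.
#' @param control_mean,control_sd Control-arm percentage change
#'   distribution (defaults 1.55 and 6.98).
#' @param baseline_eg_mean,baseline_eg_sd,baseline_cg_mean,baseline_cg_sd
#'   Baseline Cooper distance distributions, km (defaults 2.22/0.48 and
#'   2.06/0.37).
#' @param week4_fraction Fraction of the week-8 change expressed at week 4
#'   (default 0.6).
#' @param baseline_effect Coefficient of (baseline - mean baseline) on the
#'   training response, % per km; 0 (default) plants no
#'   baseline-dependence.
#' @param freq_range Range of alternate-allele frequencies for non-causal
#'   polymorphic SNPs (default c(0.1, 0.9)).
#' @param probe_replicates Replicate probe readings fabricated per call by
#'   [inject_artifacts()] (default 3).
#' @param probe_inconsistency_rate Probability a call's probe replicates
#'   disagree (default 0).
#' @param missing_rate Probability a call is missing outright (default 0).
#' @param corrupt_participants Participant ids whose probe readings are
#'   corrupted wholesale so that consistency filtering drops them
#'   (default none).
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_train = 21, n_control = 24, n_snps = 1000,
                       monomorphic_fraction = 0.285,
                       n_causal = 18, causal_freq = 0.5,
                       response_mean = 11.51, response_sd = 9.09,
                       target_r2 = 0.85,
                       effect_per_allele = NULL, noise_sd = NULL,
                       train_intercept = NULL,
                       control_mean = 1.55, control_sd = 6.98,
                       baseline_eg_mean = 2.22, baseline_eg_sd = 0.48,
                       baseline_cg_mean = 2.06, baseline_cg_sd = 0.37,
                       week4_fraction = 0.6, baseline_effect = 0,
                       freq_range = c(0.1, 0.9),
                       probe_replicates = 3,
                       probe_inconsistency_rate = 0, missing_rate = 0,
                       corrupt_participants = NULL, seed = 1L) {
  stopifnot(monomorphic_fraction >= 0, monomorphic_fraction <= 1,
            causal_freq > 0, causal_freq < 1,
            target_r2 >= 0, target_r2 < 1,
            response_sd > 0, control_sd > 0,
            probe_inconsistency_rate >= 0, probe_inconsistency_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  score_var <- n_causal * 2 * causal_freq * (1 - causal_freq)
  if (is.null(effect_per_allele)) {
    effect_per_allele <- sqrt(target_r2 * response_sd^2 / score_var)
  }
  if (is.null(noise_sd)) {
    noise_sd <- sqrt((1 - target_r2)) * response_sd
  }
  if (is.null(train_intercept)) {
    train_intercept <- response_mean -
      effect_per_allele * n_causal * 2 * causal_freq
  }
  structure(
    list(
      n_train = n_train, n_control = n_control, n_snps = n_snps,
      monomorphic_fraction = monomorphic_fraction,
      n_causal = n_causal, causal_freq = causal_freq,
      response_mean = response_mean, response_sd = response_sd,
      target_r2 = target_r2,
      effect_per_allele = effect_per_allele, noise_sd = noise_sd,
      train_intercept = train_intercept,
      control_mean = control_mean, control_sd = control_sd,
      baseline_eg_mean = baseline_eg_mean, baseline_eg_sd = baseline_eg_sd,
      baseline_cg_mean = baseline_cg_mean, baseline_cg_sd = baseline_cg_sd,
      week4_fraction = week4_fraction, baseline_effect = baseline_effect,
      freq_range = freq_range,
      probe_replicates = probe_replicates,
      probe_inconsistency_rate = probe_inconsistency_rate,
      missing_rate = missing_rate,
      corrupt_participants = corrupt_participants,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# non-palindromic ref/alt pairs only: strand orientation of A/T and C/G
# SNPs is unresolvable, and genotyping panels avoid them by design
ALLELE_PAIRS <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))

#' Simulate a genotype panel
#'
#' Draws Hardy-Weinberg genotypes for a biallelic panel. The configured
#' monomorphic fraction of SNPs is fixed for the reference allele
#' (alternate-allele frequency 0), emulating panel content whose minor
#' alleles are absent from a small cohort; the remainder draw alternate
#' frequencies uniformly from `freq_range`, except the causal SNPs which
#' use `causal_freq`. Intended-polymorphic SNPs that come out monomorphic
#' in-cohort by sampling chance are redrawn (the panel is conditioned on
#' in-cohort polymorphism). The generated metadata's `pop_alt_freq` is the
#' true sampling frequency, so population-frequency comparisons are
#' correctly calibrated by construction.
#'
#' @param config A [sim_config()]. Callers are responsible for seeding
#'   ([simulate_cohort()] seeds once from `config$seed`).
#' @return A list: `panel` (a [genotype_panel()]) and `causal` (tibble
#'   `rsid`, `favorable_allele`, `effect`, `freq`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_part <- config$n_train + config$n_control
  participants <- c(sprintf("EG%02d", seq_len(config$n_train)),
                    sprintf("CG%02d", seq_len(config$n_control)))
  n_mono <- round(config$monomorphic_fraction * config$n_snps)
  n_poly <- config$n_snps - n_mono
  if (config$n_causal > n_poly) {
    stop("More causal SNPs than polymorphic SNPs", call. = FALSE)
  }
  rsids <- sprintf("rs%06d", seq_len(config$n_snps))
  pairs <- ALLELE_PAIRS[sample.int(4, config$n_snps, replace = TRUE)]
  ref <- vapply(pairs, `[`, character(1), 1)
  alt <- vapply(pairs, `[`, character(1), 2)

  status <- rep("poly", config$n_snps)
  mono_idx <- if (n_mono > 0) {
    sample.int(config$n_snps, n_mono)
  } else integer(0)
  status[mono_idx] <- "mono"
  poly_idx <- which(status == "poly")
  causal_idx <- sort(sample(poly_idx, config$n_causal))

  alt_freq <- numeric(config$n_snps)
  alt_freq[mono_idx] <- 0
  alt_freq[poly_idx] <- stats::runif(n_poly, config$freq_range[1],
                                     config$freq_range[2])
  alt_freq[causal_idx] <- config$causal_freq

  draw_copies <- function(freq) stats::rbinom(n_part, 2, freq)
  copies <- matrix(0L, nrow = config$n_snps, ncol = n_part)
  for (i in poly_idx) {
    cp <- draw_copies(alt_freq[i])
    tries <- 0
    while (length(unique(cp)) < 2 && tries < 50) {
      cp <- draw_copies(alt_freq[i])
      tries <- tries + 1
    }
    copies[i, ] <- cp
  }

  calls <- tibble::tibble(
    participant_id = rep(participants, times = config$n_snps),
    rsid = rep(rsids, each = n_part),
    a1 = as.vector(vapply(seq_len(config$n_snps), function(i) {
      ifelse(copies[i, ] >= 1, alt[i], ref[i])
    }, character(n_part))),
    a2 = as.vector(vapply(seq_len(config$n_snps), function(i) {
      ifelse(copies[i, ] == 2, alt[i], ref[i])
    }, character(n_part)))
  )
  consequences <- c("intron variant", "downstream", "upstream", "3'UTR",
                    "missense", "synonymous", "stop-gain")
  meta <- tibble::tibble(
    rsid = rsids,
    gene = sprintf("GENE%04d", seq_len(config$n_snps)),
    ref = ref, alt = alt,
    consequence = sample(consequences, config$n_snps, replace = TRUE,
                         prob = c(0.45, 0.15, 0.15, 0.1, 0.1, 0.04, 0.01)),
    chrom = paste0("chr", sample(c(1:22, "X"), config$n_snps,
                                 replace = TRUE)),
    pos = sample.int(2e8, config$n_snps),
    pop_alt_freq = alt_freq
  )
  panel <- genotype_panel(calls, meta, participants = participants)
  causal <- tibble::tibble(
    rsid = rsids[causal_idx],
    favorable_allele = alt[causal_idx],
    effect = config$effect_per_allele,
    freq = config$causal_freq
  )
  list(panel = panel, causal = causal)
}

true_scores <- function(panel, causal) {
  calls <- panel$calls[panel$calls$rsid %in% causal$rsid, ]
  df <- dplyr::left_join(calls, causal, by = "rsid")
  df$copies <- (df$a1 == df$favorable_allele) + (df$a2 == df$favorable_allele)
  df |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(true_score = sum(.data$copies, na.rm = TRUE),
                     genetic_effect = sum(.data$copies * .data$effect,
                                          na.rm = TRUE),
                     .groups = "drop")
}

#' Simulate Cooper-test phenotypes from a genotype panel
#'
#' Training-arm percentage improvement is an additive function of the true
#' favorable-allele score plus Gaussian noise:
#' `pct = intercept + effect * score + baseline_effect * (baseline - mean)
#' + N(0, noise_sd)`. Control-arm change is pure noise around the control
#' mean. Week-4 distances interpolate a configurable fraction of the
#' week-8 change; week-0/4/8 distances are reconstructed from the drawn
#' baselines. Draws that would imply a non-positive distance are resampled.
#'
#' @param panel A [genotype_panel()] from [simulate_genotypes()].
#' @param causal Causal-SNP tibble from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @return List: `cooper` (long tibble `participant_id`, `group`, `week`,
#'   `distance_km`, `srpe`) and `truth` (list with per-participant
#'   `scores`, the planted `slope`, `intercept`, `noise_sd`, and the
#'   `causal` table).
#' @export
simulate_phenotypes <- function(panel, causal, config) {
  stopifnot(inherits(config, "sim_config"))
  scores <- true_scores(panel, causal)
  eg_ids <- grep("^EG", panel$participants, value = TRUE)
  cg_ids <- grep("^CG", panel$participants, value = TRUE)

  draw_baseline <- function(n, m, s) {
    x <- stats::rnorm(n, m, s)
    while (any(x <= 0.5)) x[x <= 0.5] <- stats::rnorm(sum(x <= 0.5), m, s)
    x
  }
  base_eg <- draw_baseline(length(eg_ids), config$baseline_eg_mean,
                           config$baseline_eg_sd)
  base_cg <- draw_baseline(length(cg_ids), config$baseline_cg_mean,
                           config$baseline_cg_sd)

  eg_scores <- scores$genetic_effect[match(eg_ids, scores$participant_id)]
  pct_eg <- config$train_intercept + eg_scores +
    config$baseline_effect * (base_eg - config$baseline_eg_mean) +
    stats::rnorm(length(eg_ids), 0, config$noise_sd)
  pct_cg <- stats::rnorm(length(cg_ids), config$control_mean,
                         config$control_sd)
  # guard against (never realistically drawn) sub--100% changes
  for (v in c("pct_eg", "pct_cg")) {
    x <- get(v)
    while (any(x <= -95)) {
      x[x <= -95] <- stats::rnorm(sum(x <= -95),
                                  if (v == "pct_eg") config$response_mean
                                  else config$control_mean,
                                  config$noise_sd)
    }
    assign(v, x)
  }

  build_rows <- function(ids, group, base, pct) {
    tibble::tibble(
      participant_id = rep(ids, 3),
      group = group,
      week = rep(c(0, 4, 8), each = length(ids)),
      distance_km = round(c(base,
                            base * (1 + config$week4_fraction * pct / 100),
                            base * (1 + pct / 100)), 4),
      srpe = round(stats::runif(3 * length(ids), 8, 10), 1)
    )
  }
  cooper <- dplyr::bind_rows(
    build_rows(eg_ids, "EG", base_eg, pct_eg),
    build_rows(cg_ids, "CG", base_cg, pct_cg)
  )
  truth <- list(
    scores = scores[, c("participant_id", "true_score")],
    slope = config$effect_per_allele,
    intercept = config$train_intercept,
    noise_sd = config$noise_sd,
    causal = causal
  )
  list(cooper = cooper, truth = truth)
}

#' Simulate training diaries
#'
#' Training-arm participants log three weekly runs whose duration ramps
#' about 10% per week from 20 minutes (capped at 30) at sRPE 6-7; control
#' participants log sporadic self-directed sessions at lower intensity.
#'
#' @param config A [sim_config()].
#' @return Tibble `participant_id`, `week`, `session_index`,
#'   `duration_min`, `srpe`.
#' @export
simulate_diaries <- function(config) {
  eg_ids <- sprintf("EG%02d", seq_len(config$n_train))
  cg_ids <- sprintf("CG%02d", seq_len(config$n_control))
  eg <- tidyr::expand_grid(participant_id = eg_ids, week = 1:8,
                           session_index = 1:3)
  eg$duration_min <- round(pmin(20 * 1.1^(eg$week - 1), 30) *
                             stats::runif(nrow(eg), 0.95, 1.05), 2)
  eg$srpe <- round(stats::runif(nrow(eg), 6, 7), 1)
  cg_rows <- purrr::map(cg_ids, function(id) {
    weeks <- sample(1:8, sample(0:8, 1))
    if (length(weeks) == 0) return(NULL)
    tibble::tibble(
      participant_id = id, week = weeks,
      session_index = 1L,
      duration_min = round(stats::runif(length(weeks), 15, 40), 2),
      srpe = round(stats::runif(length(weeks), 3, 7), 1)
    )
  })
  dplyr::bind_rows(eg, dplyr::bind_rows(cg_rows))
}

#' Inject genotyping artifacts into a panel
#'
#' Fabricates replicate probe readings (mixed forward/reverse orientations)
#' for every call, then plants artifacts: with probability
#' `probe_inconsistency_rate` one replicate of a call is replaced by a
#' different genotype (so consistency filtering will blank the call);
#' participants named in `corrupt_participants` get a high disagreement
#' rate across their whole profile (so they exceed the missingness ceiling
#' and are dropped); with probability `missing_rate` a call is missing
#' outright.
#'
#' @param panel A [genotype_panel()].
#' @param config A [sim_config()].
#' @return The panel with a `probes` tibble attached (and `missing_rate`
#'   blanking applied to calls).
#' @export
inject_artifacts <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  calls <- panel$calls
  if (config$missing_rate > 0) {
    blank <- stats::runif(nrow(calls)) < config$missing_rate
    calls$a1[blank] <- NA_character_
    calls$a2[blank] <- NA_character_
    panel$calls <- calls
  }
  n_rep <- config$probe_replicates
  present <- calls[!is.na(calls$a1), ]
  rate <- rep(config$probe_inconsistency_rate, nrow(present))
  rate[present$participant_id %in% config$corrupt_participants] <- 0.5
  meta <- panel$meta[, c("rsid", "ref", "alt")]
  present <- dplyr::left_join(present, meta, by = "rsid")
  idx <- rep(seq_len(nrow(present)), each = n_rep)
  probes <- tibble::tibble(
    participant_id = present$participant_id[idx],
    rsid = present$rsid[idx],
    a1 = present$a1[idx],
    a2 = present$a2[idx],
    orientation = sample(c("F", "R"), length(idx), replace = TRUE)
  )
  # one replicate per flagged call swapped to a different genotype
  flagged <- which(stats::runif(nrow(present)) < rate)
  if (length(flagged) > 0) {
    swap_row <- (flagged - 1) * n_rep +
      sample.int(n_rep, length(flagged), replace = TRUE)
    ref_f <- present$ref[flagged]
    alt_f <- present$alt[flagged]
    cur <- genotype_string(probes$a1[swap_row], probes$a2[swap_row])
    other <- ifelse(cur == genotype_string(ref_f, ref_f),
                    genotype_string(ref_f, alt_f),
                    genotype_string(ref_f, ref_f))
    sp <- split_genotype(other)
    probes$a1[swap_row] <- sp$a1
    probes$a2[swap_row] <- sp$a2
  }
  # reverse-orientation probes are stored complemented, as read
  rev_rows <- probes$orientation == "R"
  probes$a1[rev_rows] <- complement_allele(probes$a1[rev_rows])
  probes$a2[rev_rows] <- complement_allele(probes$a2[rev_rows])
  panel$probes <- probes
  panel
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_genotypes()], [simulate_phenotypes()],
#' [simulate_diaries()] and [inject_artifacts()] under a single seed.
#' Identical config and seed give an identical cohort.
#'
#' @param config A [sim_config()].
#' @param artifacts Fabricate replicate probe readings and artifacts
#'   (default TRUE only when the config sets a nonzero artifact rate or
#'   names corrupt participants; pass explicitly to force).
#' @return A `tgs_cohort`: list with `panel`, `cooper`, `diaries`,
#'   `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            artifacts = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(artifacts)) {
    artifacts <- config$probe_inconsistency_rate > 0 ||
      config$missing_rate > 0 || length(config$corrupt_participants) > 0
  }
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g$panel, g$causal, config)
  diaries <- simulate_diaries(config)
  panel <- if (artifacts) inject_artifacts(g$panel, config) else g$panel
  structure(
    list(panel = panel, cooper = ph$cooper, diaries = diaries,
         truth = ph$truth, config = config),
    class = "tgs_cohort"
  )
}

#' @export
print.tgs_cohort <- function(x, ...) {
  cat("<tgs_cohort> ", x$config$n_train, " training + ", x$config$n_control,
      " control participants, ", x$config$n_snps, " SNPs (",
      nrow(x$truth$causal), " causal), seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `genotypes.tsv` (matrix dialect), `snp_meta.csv`,
#' `phenotypes.csv`, `diary.csv` and `truth.json` into a directory.
#' [read_cohort()] reads them back; a write-read-write cycle is
#' byte-identical.
#'
#' @param cohort A `tgs_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tgs_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genotype_matrix(cohort$panel, file.path(dir, "genotypes.tsv"))
  readr::write_csv(cohort$panel$meta, file.path(dir, "snp_meta.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$cooper, file.path(dir, "phenotypes.csv"),
                   progress = FALSE)
  readr::write_csv(cohort$diaries, file.path(dir, "diary.csv"),
                   progress = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      scores = truth$scores, slope = truth$slope,
      intercept = truth$intercept, noise_sd = truth$noise_sd,
      causal = truth$causal
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return A `tgs_cohort` (without probes or config; `truth` restored from
#'   `truth.json`).
#' @export
read_cohort <- function(dir) {
  meta <- read_snp_meta(file.path(dir, "snp_meta.csv"))
  panel <- read_genotypes(file.path(dir, "genotypes.tsv"), meta = meta)
  cooper <- readr::read_csv(file.path(dir, "phenotypes.csv"),
                            show_col_types = FALSE, progress = FALSE)
  diaries <- readr::read_csv(file.path(dir, "diary.csv"),
                             show_col_types = FALSE, progress = FALSE)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  truth <- list(
    scores = tibble::as_tibble(tr$scores), slope = tr$slope,
    intercept = tr$intercept, noise_sd = tr$noise_sd,
    causal = tibble::as_tibble(tr$causal)
  )
  structure(
    list(panel = panel, cooper = cooper, diaries = diaries, truth = truth,
         config = NULL),
    class = "tgs_cohort"
  )
}
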