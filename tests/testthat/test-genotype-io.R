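test_that("matrix dialect parses a toy panel and validates cells", {
  dir <- withr::local_tempdir()
  meta <- toy_meta()[1:3, ]
  writeLines(c(
    "rsid\tP1\tP2",
    "rs1\tCC\tCT",
    "rs2\tAG\tAA",
    "rs3\tGG\t"
  ), file.path(dir, "g.tsv"))
  panel <- read_genotypes(file.path(dir, "g.tsv"), meta = meta)
  expect_s3_class(panel, "genotype_panel")
  expect_equal(nrow(panel$calls), 6)
  expect_equal(panel$participants, c("P1", "P2"))
  gts <- panel_genotypes(panel)
  expect_equal(gts$genotype[gts$participant_id == "P1" & gts$rsid == "rs1"],
               "CC")
  # missing preserved, not imputed
  expect_true(is.na(gts$genotype[gts$participant_id == "P2" &
                                   gts$rsid == "rs3"]))

  # malformed genotype names the offending cell
  writeLines(c("rsid,P1", "rs1,CX"), file.path(dir, "bad.csv"))
  expect_error(read_genotypes(file.path(dir, "bad.csv"), meta = meta),
               "CX.*P1|P1.*CX")

  # calls without metadata are a hard error
  writeLines(c("rsid\tP1", "rs99\tCC"), file.path(dir, "orphan.tsv"))
  expect_error(read_genotypes(file.path(dir, "orphan.tsv"), meta = meta),
               "rs99")
})

test_that("comma and tab dialects are sniffed to the same panel", {
  dir <- withr::local_tempdir()
  meta <- toy_meta()[1:2, ]
  writeLines(c("rsid\tP1\tP2", "rs1\tCT\tCC", "rs2\tAG\tGG"),
             file.path(dir, "g.tsv"))
  writeLines(c("rsid,P1,P2", "rs1,CT,CC", "rs2,AG,GG"),
             file.path(dir, "g.csv"))
  p1 <- read_genotypes(file.path(dir, "g.tsv"), meta = meta)
  p2 <- read_genotypes(file.path(dir, "g.csv"), meta = meta)
  expect_equal(p1$calls, p2$calls)
})

test_that("VCF GT input matches the equivalent matrix input", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  meta <- toy_meta()[1:2, ]
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2",
    "chr1\t100\trs1\tC\tT\t.\t.\t.\tGT\t0/1\t0/0",
    "chr2\t200\trs2\tA\tG\t.\t.\t.\tGT\t0/1\t1/1"
  )
  writeLines(vcf, file.path(dir, "g.vcf"))
  writeLines(c("rsid\tP1\tP2", "rs1\tCT\tCC", "rs2\tAG\tGG"),
             file.path(dir, "g.tsv"))
  pv <- read_genotypes(file.path(dir, "g.vcf"), meta = meta, format = "vcf")
  pm <- read_genotypes(file.path(dir, "g.tsv"), meta = meta)
  gv <- dplyr::arrange(panel_genotypes(pv), participant_id, rsid)
  gm <- dplyr::arrange(panel_genotypes(pm), participant_id, rsid)
  expect_equal(gv, gm)

  # multi-allelic records rejected
  vcf_multi <- sub("C\tT", "C\tT,G", vcf[4])
  writeLines(c(vcf[1:3], vcf_multi, vcf[5]), file.path(dir, "multi.vcf"))
  expect_error(
    read_genotypes(file.path(dir, "multi.vcf"), meta = meta, format = "vcf"),
    "iallelic"
  )
})

test_that("matrix write/read round-trips bit-identically", {
  dir <- withr::local_tempdir()
  panel <- toy_panel()
  f1 <- file.path(dir, "a.tsv")
  f2 <- file.path(dir, "b.tsv")
  write_genotype_matrix(panel, f1)
  panel2 <- read_genotypes(f1, meta = toy_meta())
  write_genotype_matrix(panel2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("orientation normalization flips reverse probes and is idempotent", {
  # T>C SNP read as "GA" on the reverse strand is forward "CT"
  meta <- tibble::tibble(rsid = "rs10", gene = "G", ref = "T", alt = "C",
                         consequence = "intron variant", chrom = "chr1",
                         pos = 1L, pop_alt_freq = NA_real_)
  calls <- tibble::tibble(participant_id = "P1", rsid = "rs10",
                          a1 = "C", a2 = "T")
  probes <- tibble::tibble(
    participant_id = "P1", rsid = "rs10",
    a1 = c("G", "C"), a2 = c("A", "T"),
    orientation = c("R", "F")
  )
  panel <- genotype_panel(calls, meta, probes = probes)
  norm <- normalize_orientation(panel)
  expect_equal(gt_str(norm$probes$a1, norm$probes$a2)[1], "CT")
  expect_equal(gt_str(norm$probes$a1, norm$probes$a2)[2], "CT")
  expect_true(all(norm$probes$orientation == "F"))
  # idempotent
  expect_identical(normalize_orientation(norm)$probes, norm$probes)
})

test_that("complementing every probe reading leaves the forward panel invariant", {
  set.seed(404)
  cfg <- sim_config(n_train = 5, n_control = 5, n_snps = 12,
                    monomorphic_fraction = 0, n_causal = 3,
                    probe_inconsistency_rate = 0, seed = 404)
  co <- simulate_cohort(cfg, artifacts = TRUE)
  norm1 <- normalize_orientation(co$panel)
  # flip the recorded orientation of every probe and complement the reading:
  # the same physical observation reported on the other strand
  flipped <- co$panel
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped$probes$a1 <- unname(comp[flipped$probes$a1])
  flipped$probes$a2 <- unname(comp[flipped$probes$a2])
  flipped$probes$orientation <-
    ifelse(flipped$probes$orientation == "F", "R", "F")
  norm2 <- normalize_orientation(flipped)
  expect_equal(
    gt_str(norm1$probes$a1, norm1$probes$a2),
    gt_str(norm2$probes$a1, norm2$probes$a2)
  )
})

test_that("palindromic SNPs with reverse probes are flagged, not flipped", {
  meta <- tibble::tibble(rsid = "rsAT", gene = "G", ref = "A", alt = "T",
                         consequence = "intron variant", chrom = "chr1",
                         pos = 1L, pop_alt_freq = NA_real_)
  calls <- tibble::tibble(participant_id = "P1", rsid = "rsAT",
                          a1 = "A", a2 = "T")
  probes <- tibble::tibble(participant_id = "P1", rsid = "rsAT",
                           a1 = "A", a2 = "T", orientation = "R")
  panel <- genotype_panel(calls, meta, probes = probes)
  expect_warning(norm <- normalize_orientation(panel), "alindromic")
  # reading trusted as supplied
  expect_equal(norm$probes$a1, "A")
  expect_equal(norm$probes$a2, "T")
})

test_that("consistency filter blanks disagreeing calls and drops noisy participants", {
  meta <- toy_meta()[1, ]
  calls <- tibble::tibble(
    participant_id = c("P1", "P2"), rsid = "rs1",
    a1 = c("C", "C"), a2 = c("T", "T")
  )
  probes <- tibble::tibble(
    participant_id = rep(c("P1", "P2"), each = 3),
    rsid = "rs1",
    a1 = c("C", "C", "C",  "C", "C", "C"),
    a2 = c("T", "T", "T",  "T", "C", "T"),
    orientation = "F"
  )
  panel <- genotype_panel(calls, meta, probes = probes)
  res <- filter_inconsistent(panel, max_missing = 1)
  gts <- panel_genotypes(res$panel)
  # full agreement retained
  expect_equal(gts$genotype[gts$participant_id == "P1"], "CT")
  # {CT, CC, CT} blanked
  expect_true(is.na(gts$genotype[gts$participant_id == "P2"]))
  expect_equal(res$audit$type, "call_set_missing")

  # with a 1-SNP panel the blanked call is 100% missingness: dropped
  res2 <- filter_inconsistent(panel, max_missing = 0.2)
  expect_false("P2" %in% res2$panel$participants)
  expect_true("participant_dropped" %in% res2$audit$type)
})

test_that("monomorphic removal matches the brute-force definition", {
  panel <- toy_panel()
  res <- remove_monomorphic(panel)
  expect_equal(res$n_removed, 1)
  expect_setequal(res$panel$meta$rsid, c("rs1", "rs2", "rs3"))

  # monomorphic among non-missing but with missing calls: still removed
  meta <- toy_meta()[1, ]
  calls <- tibble::tibble(
    participant_id = c("P1", "P2", "P3"), rsid = "rs1",
    a1 = c("C", "C", NA), a2 = c("C", "C", NA)
  )
  expect_warning(res2 <- remove_monomorphic(genotype_panel(calls, meta)),
                 "polymorphic")
  expect_equal(res2$n_removed, 1)
  expect_equal(nrow(res2$panel$meta), 0)

  # brute-force cross-check on random small panels: retained iff >= 2
  # distinct non-missing genotype strings
  set.seed(99)
  for (i in 1:10) {
    gs <- sample(c("CC", "CT", "TT", NA), 8, replace = TRUE)
    calls <- tibble::tibble(
      participant_id = paste0("P", 1:8), rsid = "rs1",
      a1 = substr(gs, 1, 1), a2 = substr(gs, 2, 2)
    )
    p <- genotype_panel(calls, toy_meta()[1, ])
    kept <- nrow(remove_monomorphic(p)$panel$meta) == 1
    expect_equal(kept, length(unique(gs[!is.na(gs)])) >= 2)
  }

  # idempotent
  res3 <- remove_monomorphic(res$panel)
  expect_equal(res3$n_removed, 0)
  expect_equal(res3$panel$meta, res$panel$meta)
})
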