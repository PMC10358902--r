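# Small in-code fixtures shared across tests.

toy_meta <- function() {
  tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    gene = paste0("G", 1:4),
    ref = c("C", "A", "G", "C"),
    alt = c("T", "G", "T", "A"),
    consequence = c("intron variant", "missense", "upstream", "3'UTR"),
    chrom = c("chr1", "chr2", "chr3", "chr4"),
    pos = c(100L, 200L, 300L, 400L),
    pop_alt_freq = c(0.3, 0.5, 0.2, NA)
  )
}

# 4 SNPs x 4 participants; rs4 monomorphic (all CC)
toy_panel <- function() {
  gts <- tibble::tribble(
    ~participant_id, ~rs1, ~rs2, ~rs3, ~rs4,
    "P1", "CC", "AG", "GG", "CC",
    "P2", "CT", "AA", "GT", "CC",
    "P3", "TT", "GG", "GG", "CC",
    "P4", "CT", "AG", NA,   "CC"
  )
  long <- tidyr::pivot_longer(gts, -participant_id,
                              names_to = "rsid", values_to = "genotype")
  a1 <- substr(long$genotype, 1, 1)
  a2 <- substr(long$genotype, 2, 2)
  calls <- tibble::tibble(
    participant_id = long$participant_id, rsid = long$rsid,
    a1 = ifelse(is.na(long$genotype), NA_character_, a1),
    a2 = ifelse(is.na(long$genotype), NA_character_, a2)
  )
  genotype_panel(calls, toy_meta())
}

# deterministic Cooper table: two arms, weeks 0/4/8
toy_cooper <- function() {
  tibble::tibble(
    participant_id = rep(c("E1", "E2", "E3", "C1", "C2"), each = 3),
    group = rep(c("EG", "EG", "EG", "CG", "CG"), each = 3),
    week = rep(c(0, 4, 8), 5),
    distance_km = c(2.0, 2.06, 2.10,   # +5%
                    2.0, 2.12, 2.20,   # +10%
                    2.0, 2.18, 2.30,   # +15%
                    2.5, 2.5, 2.5,
                    2.0, 2.02, 2.02)
  )
}

# local genotype-string helper (unordered pair, alphabetical)
gt_str <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), NA_character_,
         paste0(pmin(a1, a2), pmax(a1, a2)))
}
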