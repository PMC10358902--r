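#' Construct a genotype panel
#'
#' A genotype panel bundles biallelic SNP calls for a cohort with per-SNP
#' metadata. Calls are held in long (tidy) form, one row per
#' (participant, SNP) pair, with the two alleles in separate columns.
#' Allele order within a call carries no meaning; missing genotypes are
#' explicit `NA`s and are never imputed anywhere downstream.
#'
#' @param calls Tibble with columns `participant_id`, `rsid`, `a1`, `a2`.
#'   Alleles must be one of A, C, G, T, or `NA` (both alleles `NA` for a
#'   missing call).
#' @param meta Tibble with columns `rsid`, `gene`, `ref`, `alt`,
#'   `consequence`, `chrom`, `pos` and optionally `pop_alt_freq` (population
#'   alternate-allele proportion in \[0, 1\], `NA` when unknown). Every rsid
#'   appearing in `calls` must be present here.
#' @param probes Optional tibble of replicate probe readings with columns
#'   `participant_id`, `rsid`, `a1`, `a2`, `orientation` (`"F"` forward or
#'   `"R"` reverse). Used by [filter_inconsistent()].
#' @param participants Optional character vector fixing participant order;
#'   defaults to order of first appearance in `calls`.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `calls`, `meta`, `probes`, `participants`.
#' @export
#' @examples
#' meta <- tibble::tibble(
#'   rsid = "rs1", gene = "GENE1", ref = "C", alt = "T",
#'   consequence = "intron variant", chrom = "chr1", pos = 100L,
#'   pop_alt_freq = 0.3
#' )
#' calls <- tibble::tibble(
#'   participant_id = c("P1", "P2"), rsid = "rs1",
#'   a1 = c("C", "C"), a2 = c("T", "C")
#' )
#' genotype_panel(calls, meta)
genotype_panel <- function(calls, meta, probes = NULL, participants = NULL) {
  calls <- tibble::as_tibble(calls)
  meta <- tibble::as_tibble(meta)
  required_call_cols <- c("participant_id", "rsid", "a1", "a2")
  if (!all(required_call_cols %in% names(calls))) {
    stop("`calls` must have columns ", paste(required_call_cols, collapse = ", "),
         call. = FALSE)
  }
  required_meta_cols <- c("rsid", "ref", "alt")
  if (!all(required_meta_cols %in% names(meta))) {
    stop("`meta` must have columns ", paste(required_meta_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"pop_alt_freq" %in% names(meta)) meta$pop_alt_freq <- NA_real_
  for (col in c("gene", "consequence", "chrom")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_character_
  }
  if (!"pos" %in% names(meta)) meta$pos <- NA_integer_

  bad_nuc <- function(x) !is.na(x) & !x %in% c("A", "C", "G", "T")
  if (any(bad_nuc(calls$a1) | bad_nuc(calls$a2))) {
    bad <- calls[bad_nuc(calls$a1) | bad_nuc(calls$a2), ]
    stop("Invalid allele(s) in calls, e.g. participant ", bad$participant_id[1],
         " at ", bad$rsid[1], ": '", bad$a1[1], bad$a2[1], "'", call. = FALSE)
  }
  if (any(bad_nuc(meta$ref) | bad_nuc(meta$alt) | is.na(meta$ref) | is.na(meta$alt))) {
    stop("SNP metadata ref/alt alleles must be A, C, G or T", call. = FALSE)
  }
  if (any(meta$ref == meta$alt)) {
    stop("SNP metadata has ref == alt for ",
         meta$rsid[meta$ref == meta$alt][1], call. = FALSE)
  }
  ok_freq <- is.na(meta$pop_alt_freq) |
    (meta$pop_alt_freq >= 0 & meta$pop_alt_freq <= 1)
  if (!all(ok_freq)) {
    stop("pop_alt_freq outside [0, 1] for ",
         meta$rsid[!ok_freq][1], call. = FALSE)
  }
  orphan <- setdiff(unique(calls$rsid), meta$rsid)
  if (length(orphan) > 0) {
    stop("Calls reference rsid(s) with no metadata: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(calls[, c("participant_id", "rsid")]) > 0) {
    dup <- calls[duplicated(calls[, c("participant_id", "rsid")]), ]
    stop("Duplicate call for participant ", dup$participant_id[1],
         " at ", dup$rsid[1], call. = FALSE)
  }
  if (anyDuplicated(meta$rsid) > 0) {
    stop("Duplicate rsid in metadata", call. = FALSE)
  }
  if (is.null(participants)) participants <- unique(calls$participant_id)
  if (!is.null(probes)) probes <- tibble::as_tibble(probes)

  structure(
    list(calls = calls, meta = meta, probes = probes,
         participants = participants),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  n_missing <- sum(is.na(x$calls$a1))
  cat("<genotype_panel> ", length(x$participants), " participants x ",
      nrow(x$meta), " SNPs (", nrow(x$calls), " calls, ",
      n_missing, " missing",
      if (!is.null(x$probes)) paste0("; ", nrow(x$probes), " probe readings"),
      ")\n", sep = "")
  invisible(x)
}

#' Genotypes as two-character strings
#'
#' Collapses the two allele columns of a panel's calls into sorted
#' two-character genotype strings (`"CT"`, alphabetical within the pair so
#' that heterozygotes have a single representation). Missing calls give `NA`.
#'
#' @param panel A [genotype_panel()].
#' @return Tibble `participant_id`, `rsid`, `genotype`.
#' @export
panel_genotypes <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  dplyr::mutate(
    panel$calls,
    genotype = genotype_string(.data$a1, .data$a2)
  )[, c("participant_id", "rsid", "genotype")]
}

genotype_string <- function(a1, a2) {
  out <- ifelse(is.na(a1) | is.na(a2), NA_character_,
                paste0(pmin(a1, a2), pmax(a1, a2)))
  out
}

split_genotype <- function(g) {
  a1 <- ifelse(is.na(g), NA_character_, substr(g, 1, 1))
  a2 <- ifelse(is.na(g), NA_character_, substr(g, 2, 2))
  list(a1 = a1, a2 = a2)
}
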