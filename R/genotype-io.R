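#' Read SNP metadata sidecar
#'
#' Reads the per-SNP metadata table accompanying a genotype matrix:
#' `rsid,gene,ref,alt,consequence,chrom,pos,pop_alt_freq` (comma or tab
#' separated, sniffed from the header line).
#'
#' @param path Path to the metadata CSV/TSV.
#' @return Tibble of SNP metadata.
#' @export
read_snp_meta <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  meta <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  needed <- c("rsid", "ref", "alt")
  if (!all(needed %in% names(meta))) {
    stop("SNP metadata must contain columns rsid, ref, alt", call. = FALSE)
  }
  tibble::as_tibble(meta)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a genotype panel
#'
#' Reads biallelic genotype calls into a [genotype_panel()]. Two dialects are
#' supported:
#'
#' * `"matrix"` — one row per SNP, first column `rsid`, one column per
#'   participant, genotypes as two-character strings (`"CT"`); empty cells,
#'   `"NN"`, `"--"` or `NA` denote missing calls. Tab or comma separated
#'   (sniffed). This mirrors the spreadsheet export convention of genotyping
#'   services.
#' * `"vcf"` — a VCF with per-sample `GT` fields; biallelic records only
#'   (multi-allelic records are rejected). Requires the `vcfR` package.
#'
#' @param path Path to the genotype file.
#' @param meta SNP metadata tibble (see [read_snp_meta()]); for `"matrix"`
#'   it is required and every rsid in the file must be present in it. For
#'   `"vcf"` it may be `NULL`, in which case metadata is built from the VCF
#'   records themselves.
#' @param format `"matrix"` or `"vcf"`.
#' @return A [genotype_panel()]. Missing calls are preserved, never imputed.
#' @export
read_genotypes <- function(path, meta = NULL, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (format == "matrix") {
    read_genotypes_matrix(path, meta)
  } else {
    read_genotypes_vcf(path, meta)
  }
}

read_genotypes_matrix <- function(path, meta) {
  if (is.null(meta)) {
    stop("`meta` is required for matrix-format genotypes", call. = FALSE)
  }
  delim <- sniff_delim(path)
  wide <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (names(wide)[1] != "rsid") names(wide)[1] <- "rsid"
  long <- tidyr::pivot_longer(wide, -"rsid",
                              names_to = "participant_id",
                              values_to = "genotype")
  long$genotype[long$genotype %in% c("", "NN", "--", "..")] <- NA_character_
  bad <- !is.na(long$genotype) &
    !grepl("^[ACGT]{2}$", long$genotype)
  if (any(bad)) {
    b <- long[bad, ][1, ]
    stop("Malformed genotype '", b$genotype, "' for participant ",
         b$participant_id, " at ", b$rsid, call. = FALSE)
  }
  al <- split_genotype(long$genotype)
  calls <- tibble::tibble(
    participant_id = long$participant_id,
    rsid = long$rsid,
    a1 = al$a1, a2 = al$a2
  )
  genotype_panel(calls, meta,
                 participants = setdiff(names(wide), "rsid"))
}

read_genotypes_vcf <- function(path, meta) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stop("Multi-allelic VCF record at ", fix$ID[multi][1],
         "; only biallelic records are supported", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rsids <- fix$ID
  rownames(gt) <- rsids
  long <- tibble::as_tibble(gt, rownames = "rsid")
  long <- tidyr::pivot_longer(long, -"rsid",
                              names_to = "participant_id", values_to = "gt")
  lookup_allele <- function(code, ref, alt) {
    dplyr::case_when(code == "0" ~ ref, code == "1" ~ alt,
                     TRUE ~ NA_character_)
  }
  ra <- tibble::tibble(rsid = rsids, ref = fix$REF, alt = fix$ALT)
  long <- dplyr::left_join(long, ra, by = "rsid")
  parts <- stringr::str_split_fixed(ifelse(is.na(long$gt), "./.", long$gt),
                                    "[/|]", 2)
  calls <- tibble::tibble(
    participant_id = long$participant_id,
    rsid = long$rsid,
    a1 = lookup_allele(parts[, 1], long$ref, long$alt),
    a2 = lookup_allele(parts[, 2], long$ref, long$alt)
  )
  # half-calls are treated as missing
  half <- xor(is.na(calls$a1), is.na(calls$a2))
  calls$a1[half] <- NA_character_
  calls$a2[half] <- NA_character_
  if (is.null(meta)) {
    meta <- tibble::tibble(
      rsid = rsids, gene = NA_character_, ref = fix$REF, alt = fix$ALT,
      consequence = NA_character_, chrom = fix$CHROM,
      pos = suppressWarnings(as.integer(fix$POS)), pop_alt_freq = NA_real_
    )
  }
  genotype_panel(calls, meta, participants = colnames(gt))
}

#' Write a genotype panel as a matrix TSV
#'
#' Inverse of [read_genotypes()] matrix dialect: one row per SNP, first
#' column `rsid`, one column per participant, sorted two-character genotype
#' strings, missing calls as empty cells. Reading the written file back
#' round-trips the panel's calls exactly.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  gts <- panel_genotypes(panel)
  wide <- tidyr::pivot_wider(gts, names_from = "participant_id",
                             values_from = "genotype")
  wide <- wide[match(panel$meta$rsid, wide$rsid),
               c("rsid", panel$participants)]
  readr::write_tsv(wide, path, na = "", progress = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(x) {
  out <- unname(COMPLEMENT[x])
  out[is.na(x)] <- NA_character_
  if (any(!is.na(x) & is.na(out))) {
    stop("Cannot complement allele '", x[!is.na(x) & is.na(out)][1], "'",
         call. = FALSE)
  }
  out
}

is_palindromic <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Normalise probe readings to the forward strand
#'
#' Genotyping probes read each SNP in forward or reverse orientation.
#' Reverse-orientation readings are complemented (A<->T, C<->G) so that all
#' alleles are expressed forward-forward; forward readings pass through
#' unchanged, so the operation is idempotent. Palindromic SNPs (A/T or C/G)
#' cannot be strand-resolved from sequence alone: their reverse-orientation
#' readings are left as read (trusting the input orientation label is
#' already resolved upstream) and a warning names them.
#'
#' @param panel A [genotype_panel()] carrying a `probes` tibble (see
#'   [genotype_panel()]); panels without probes are returned unchanged.
#' @return The panel with all probe readings forward-oriented (orientation
#'   column set to `"F"`).
#' @export
normalize_orientation <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(panel$probes) || nrow(panel$probes) == 0) return(panel)
  probes <- panel$probes
  meta <- panel$meta
  pal <- meta$rsid[is_palindromic(meta$ref, meta$alt)]
  rev_rows <- probes$orientation == "R"
  pal_rev <- rev_rows & probes$rsid %in% pal
  if (any(pal_rev)) {
    warning("Palindromic SNP(s) with reverse-orientation probes left as ",
            "read: ", paste(unique(probes$rsid[pal_rev]), collapse = ", "),
            call. = FALSE)
  }
  flip <- rev_rows & !probes$rsid %in% pal
  probes$a1[flip] <- complement_allele(probes$a1[flip])
  probes$a2[flip] <- complement_allele(probes$a2[flip])
  probes$orientation <- "F"
  panel$probes <- probes
  panel
}

#' Filter internally inconsistent calls
#'
#' Applies the replicate-probe consistency rule: after orientation
#' normalisation, a (participant, SNP) call whose replicate probe readings do
#' not all agree (as unordered allele pairs) is set to missing. Participants
#' whose resulting missingness exceeds `max_missing` (as a fraction of the
#' panel's SNPs) are dropped from the panel entirely. Every removal is listed
#' in the audit table with its reason.
#'
#' @param panel A [genotype_panel()]. If it carries probe readings the
#'   consensus of consistent readings replaces the stored call; without
#'   probes only the participant-missingness rule applies.
#' @param max_missing Missingness ceiling above which a participant is
#'   dropped (default 0.2).
#' @return List with elements `panel` (filtered) and `audit` (tibble
#'   `type`, `participant_id`, `rsid`, `reason`).
#' @export
filter_inconsistent <- function(panel, max_missing = 0.2) {
  stopifnot(inherits(panel, "genotype_panel"))
  panel <- normalize_orientation(panel)
  audit <- tibble::tibble(type = character(), participant_id = character(),
                          rsid = character(), reason = character())

  if (!is.null(panel$probes) && nrow(panel$probes) > 0) {
    probes <- panel$probes
    probes$genotype <- genotype_string(probes$a1, probes$a2)
    consensus <- probes |>
      dplyr::filter(!is.na(.data$genotype)) |>
      dplyr::group_by(.data$participant_id, .data$rsid) |>
      dplyr::summarise(
        n_distinct_gt = dplyr::n_distinct(.data$genotype),
        genotype = .data$genotype[1],
        .groups = "drop"
      )
    bad <- consensus[consensus$n_distinct_gt > 1, ]
    if (nrow(bad) > 0) {
      audit <- dplyr::bind_rows(audit, tibble::tibble(
        type = "call_set_missing",
        participant_id = bad$participant_id,
        rsid = bad$rsid,
        reason = "replicate probe readings disagree"
      ))
    }
    consensus$genotype[consensus$n_distinct_gt > 1] <- NA_character_
    al <- split_genotype(consensus$genotype)
    upd <- tibble::tibble(participant_id = consensus$participant_id,
                          rsid = consensus$rsid,
                          new_a1 = al$a1, new_a2 = al$a2)
    calls <- dplyr::left_join(panel$calls, upd,
                              by = c("participant_id", "rsid"))
    has_upd <- paste(calls$participant_id, calls$rsid) %in%
      paste(upd$participant_id, upd$rsid)
    calls$a1[has_upd] <- calls$new_a1[has_upd]
    calls$a2[has_upd] <- calls$new_a2[has_upd]
    calls$new_a1 <- NULL
    calls$new_a2 <- NULL
    panel$calls <- calls
  }

  n_snps <- nrow(panel$meta)
  miss <- panel$calls |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(frac = sum(is.na(.data$a1)) / n_snps, .groups = "drop")
  dropped <- miss$participant_id[miss$frac > max_missing]
  if (length(dropped) > 0) {
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      type = "participant_dropped",
      participant_id = dropped,
      rsid = NA_character_,
      reason = sprintf("missingness %.1f%% exceeds ceiling %.1f%%",
                       100 * miss$frac[match(dropped, miss$participant_id)],
                       100 * max_missing)
    ))
    panel$calls <- panel$calls[!panel$calls$participant_id %in% dropped, ]
    if (!is.null(panel$probes)) {
      panel$probes <- panel$probes[!panel$probes$participant_id %in% dropped, ]
    }
    panel$participants <- setdiff(panel$participants, dropped)
  }
  list(panel = panel, audit = audit)
}

#' Remove monomorphic SNPs
#'
#' Drops every SNP showing fewer than two distinct genotypes among
#' non-missing calls (including SNPs with no non-missing calls at all).
#' Such SNPs carry no between-participant information and would produce
#' degenerate contingency tables downstream.
#'
#' @param panel A [genotype_panel()].
#' @return List with elements `panel` (polymorphic SNPs only) and
#'   `n_removed` (count of SNPs dropped).
#' @export
remove_monomorphic <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  gts <- panel_genotypes(panel)
  keep <- gts |>
    dplyr::filter(!is.na(.data$genotype)) |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(n_gt = dplyr::n_distinct(.data$genotype),
                     .groups = "drop") |>
    dplyr::filter(.data$n_gt >= 2)
  keep_ids <- keep$rsid
  n_removed <- nrow(panel$meta) - length(keep_ids)
  panel$meta <- panel$meta[panel$meta$rsid %in% keep_ids, ]
  panel$calls <- panel$calls[panel$calls$rsid %in% keep_ids, ]
  if (!is.null(panel$probes)) {
    panel$probes <- panel$probes[panel$probes$rsid %in% keep_ids, ]
  }
  if (length(keep_ids) == 0) {
    warning("No polymorphic SNPs remain after filtering", call. = FALSE)
  }
  list(panel = panel, n_removed = n_removed)
}
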