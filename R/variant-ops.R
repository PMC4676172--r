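# Somatic vs germline classification, donor masking, identity checks and
# variant summary statistics on per-specimen allele-count tables.

NONSILENT_CLASSES <- c("nonsynonymous", "stop-gain", "stop-loss", "frameshift")

add_vaf <- function(df) {
  dplyr::mutate(df,
                depth = .data$ref_reads + .data$alt_reads,
                vaf = ifelse(.data$depth > 0, .data$alt_reads / .data$depth,
                             NA_real_))
}

#' Check whether two genotype panels come from the same individual
#'
#' Compares genotype calls at loci covered to at least `min_depth` in both
#' panels; the fraction of concordant genotypes is compared with `threshold`
#' to produce a same-individual verdict. Two unrelated individuals genotyped
#' on a common-SNP panel concord at roughly the sum of squared Hardy-Weinberg
#' genotype frequencies (about 40-50 % at intermediate allele frequencies),
#' far below the default threshold.
#'
#' @param panel_a,panel_b Tibbles with columns `chrom`, `pos`, `genotype`,
#'   `depth` (e.g. from [simulate_panel_reads()]).
#' @param min_depth Minimum depth in both panels for a locus to count.
#' @param threshold Concordance at or above which the verdict is
#'   same-individual.
#' @return One-row tibble: `n_loci`, `concordance`, `same_individual`.
#' @export
check_identity <- function(panel_a, panel_b, min_depth = 20,
                           threshold = 0.95) {
  m <- dplyr::inner_join(
    dplyr::select(panel_a, "chrom", "pos", ga = "genotype", da = "depth"),
    dplyr::select(panel_b, "chrom", "pos", gb = "genotype", db = "depth"),
    by = c("chrom", "pos")) |>
    dplyr::filter(.data$da >= min_depth, .data$db >= min_depth,
                  !is.na(.data$ga), !is.na(.data$gb))
  if (nrow(m) < 50) {
    stop("fewer than 50 co-covered loci pass `min_depth`", call. = FALSE)
  }
  conc <- mean(m$ga == m$gb)
  tibble::tibble(n_loci = nrow(m), concordance = conc,
                 same_individual = conc >= threshold)
}

#' Call somatic variants from a tumor/normal pair
#'
#' A variant is called somatic when it is well supported in the tumor and
#' absent from the matched normal: tumor VAF at or above `min_vaf`, tumor alt
#' reads at or above `min_alt`, normal VAF at or below `max_normal_vaf`, and
#' both depths at or above `min_depth`. An optional second normal (`nat`,
#' the adjacent normal tissue) excludes any variant it carries above
#' `nat_max_vaf`.
#'
#' @param tumor,matched_normal Variant tables (tibbles with `chrom`, `pos`,
#'   `ref`, `alt`, `ref_reads`, `alt_reads` and optional annotation columns).
#' @param nat Optional secondary-normal variant table.
#' @param min_vaf,min_alt,max_normal_vaf,min_depth,nat_max_vaf Filter
#'   thresholds; see Details above for the rule each enforces.
#' @return A somatic call set: tibble keyed by `(chrom, pos, ref, alt)` with
#'   `vaf`, `alt_reads`, `depth` and any annotation columns of `tumor`.
#' @export
call_somatic <- function(tumor, matched_normal, nat = NULL,
                         min_vaf = 0.05, min_alt = 4,
                         max_normal_vaf = 0.01, min_depth = 20,
                         nat_max_vaf = 0.05) {
  if (nrow(tumor) == 0 || nrow(matched_normal) == 0) {
    stop("empty variant table", call. = FALSE)
  }
  key <- c("chrom", "pos", "ref", "alt")
  t <- add_vaf(tumor)
  n <- add_vaf(matched_normal) |>
    dplyr::select(dplyr::all_of(key), n_depth = "depth", n_vaf = "vaf")
  calls <- dplyr::inner_join(t, n, by = key) |>
    dplyr::filter(
      .data$vaf >= min_vaf,
      .data$alt_reads >= min_alt,
      .data$n_vaf <= max_normal_vaf,
      .data$depth >= min_depth,
      .data$n_depth >= min_depth
    )
  if (!is.null(nat)) {
    hot <- add_vaf(nat) |>
      dplyr::filter(.data$vaf > nat_max_vaf) |>
      dplyr::select(dplyr::all_of(key))
    calls <- dplyr::anti_join(calls, hot, by = key)
  }
  calls |>
    dplyr::select(-"n_depth", -"n_vaf") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Remove donor/recipient germline differences from recurrent-tumor calls
#'
#' A somatic call in the recurrent tumor is discarded when the donor
#' (`R_NAT`) genotype differs from the recipient (`P_B`) genotype at that
#' locus — such sites are donor germline leaking through the contamination
#' mixture, not tumor mutations. Loci absent from both panels are retained
#' with `mask_warn = TRUE`.
#'
#' @param calls A somatic call set from [call_somatic()].
#' @param r_nat_panel,p_b_panel Genotype panels (tibbles with `chrom`, `pos`,
#'   `genotype`) for the donor tissue and the recipient blood.
#' @return The filtered call set (never larger than the input), with a
#'   `mask_warn` column.
#' @export
mask_donor_differences <- function(calls, r_nat_panel, p_b_panel) {
  gd <- dplyr::select(r_nat_panel, "chrom", "pos", g_donor = "genotype")
  gr <- dplyr::select(p_b_panel, "chrom", "pos", g_recipient = "genotype")
  out <- calls |>
    dplyr::left_join(gd, by = c("chrom", "pos")) |>
    dplyr::left_join(gr, by = c("chrom", "pos")) |>
    dplyr::mutate(mask_warn = is.na(.data$g_donor) & is.na(.data$g_recipient))
  out |>
    dplyr::filter(.data$mask_warn |
                    dplyr::coalesce(.data$g_donor == .data$g_recipient, TRUE)) |>
    dplyr::select(-"g_donor", -"g_recipient")
}

#' Partition somatic calls into shared and tumor-unique sets
#'
#' Variants are matched between the primary-tumor and recurrent-tumor call
#' sets on the `(chrom, pos, ref, alt)` key and labeled `shared`,
#' `P-unique` or `R-unique`. Shared variants are expected to be enriched for
#' clonal (driver) mutations, so their primary-tumor VAFs are compared with
#' the P-unique VAFs by a Welch two-sample t-test (reported on the percent
#' scale).
#'
#' @param p_t,r_t Somatic call sets from [call_somatic()].
#' @return A list with `partition` (the labeled union) and `vaf_test`
#'   (one-row tibble: group mean VAFs in percent, Welch `p_value`,
#'   `flag_small` when a compared group has fewer than 2 variants).
#' @export
partition_shared_unique <- function(p_t, r_t) {
  if (nrow(p_t) == 0) stop("empty primary-tumor call set", call. = FALSE)
  key <- c("chrom", "pos", "ref", "alt")
  pk <- dplyr::select(p_t, dplyr::all_of(key), vaf_pt = "vaf")
  rk <- dplyr::select(r_t, dplyr::all_of(key), vaf_rt = "vaf")
  part <- dplyr::full_join(pk, rk, by = key) |>
    dplyr::mutate(class = dplyr::case_when(
      !is.na(.data$vaf_pt) & !is.na(.data$vaf_rt) ~ "shared",
      !is.na(.data$vaf_pt) ~ "P-unique",
      TRUE ~ "R-unique"))
  sh <- 100 * part$vaf_pt[part$class == "shared"]
  un <- 100 * part$vaf_pt[part$class == "P-unique"]
  small <- length(sh) < 2 || length(un) < 2
  p <- if (small) NA_real_ else t.test(sh, un)$p.value
  list(partition = part,
       vaf_test = tibble::tibble(
         n_shared = length(sh), n_p_unique = length(un),
         n_r_unique = sum(part$class == "R-unique"),
         mean_vaf_shared = if (length(sh)) mean(sh) else NA_real_,
         mean_vaf_p_unique = if (length(un)) mean(un) else NA_real_,
         p_value = p, flag_small = small))
}

#' Strand-collapsed single-base substitution spectrum
#'
#' Counts SNVs in the six pyrimidine-reference classes
#' `C>A, C>G, C>T, T>A, T>C, T>G`; purine-reference substitutions are
#' reverse-complemented first (so `G>A` counts as `C>T`). Proportions sum
#' to 1.
#'
#' @param calls A somatic call set; indels (multi-base alleles or
#'   `type == "indel"`) are excluded.
#' @return Tibble: `class`, `n`, `proportion` over the six classes.
#' @export
substitution_spectrum <- function(calls) {
  snv <- calls |>
    dplyr::filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1,
                  .data$ref != .data$alt)
  if ("type" %in% names(snv)) snv <- dplyr::filter(snv, .data$type == "snv")
  if (nrow(snv) == 0) stop("no SNVs in call set", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- snv$ref %in% c("A", "G")
  ref <- ifelse(flip, comp[snv$ref], snv$ref)
  alt <- ifelse(flip, comp[snv$alt], snv$alt)
  cls <- paste0(ref, ">", alt)
  lev <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  n <- table(factor(cls, levels = lev))
  tibble::tibble(class = lev, n = as.integer(n),
                 proportion = as.numeric(n) / sum(n))
}

#' Nonsilent-to-silent variant ratio
#'
#' Ratio of nonsilent calls (nonsynonymous, stop-gain, stop-loss,
#' frameshift) to silent calls; `Inf` with `flag_infinite = TRUE` when no
#' silent variant is present.
#'
#' @param calls A somatic call set with an `effect` column.
#' @return One-row tibble: `n_nonsilent`, `n_silent`, `ratio`,
#'   `flag_infinite`.
#' @export
nonsilent_silent_ratio <- function(calls) {
  ns <- sum(calls$effect %in% NONSILENT_CLASSES)
  s <- sum(calls$effect == "silent")
  tibble::tibble(n_nonsilent = ns, n_silent = s,
                 ratio = if (s == 0) Inf else ns / s,
                 flag_infinite = s == 0)
}
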