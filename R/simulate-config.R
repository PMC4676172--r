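#' Simulation configuration for a synthetic transplant cohort
#'
#' Builds the parameter set that drives the synthetic cohort generator. The
#' defaults emulate the transplant study design this package targets: 21
#' patients of whom 9 experience tumor recurrence within the 24-month
#' follow-up window, with the full five-specimen set (primary tumor `P_T`,
#' its normal adjacent tissue `P_NAT`, recurrent tumor `R_T`, donor-liver
#' normal adjacent tissue `R_NAT`, and recipient blood `P_B`) available for 4
#' of the 9 recurrent patients. Donor-cell contamination defaults are the
#' midpoints of the per-patient ranges reported for that design
#' (0.80, 0.06, 0.55, 0).
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_recurrent Number of patients with post-transplant recurrence;
#'   must not exceed `n_patients`.
#' @param n_wes Number of recurrent patients with the full five-specimen set
#'   (exome-style data: germline panels, variant tables, coverage bins).
#' @param panel_size Number of germline SNP loci on the genotyping panel.
#' @param maf_range Length-2 numeric, bounds of the uniform minor-allele
#'   frequency distribution for panel loci; must lie in (0, 0.5].
#' @param n_somatic_per_clone Somatic variants carried by each tumor clone.
#' @param clone_fractions Cancer-cell fraction of each (nested) clone in the
#'   primary tumor, each in (0, 1]. The first clone is truncal.
#' @param shared_clone_fraction Fraction of primary clones retained in the
#'   recurrent tumor (truncal clone first; at least one clone is retained
#'   whenever the fraction is positive).
#' @param n_somatic_private Somatic variants private to the recurrent tumor.
#' @param private_clone_fraction Cancer-cell fraction of the recurrent
#'   tumor's private clone.
#' @param n_germline_background Number of germline panel sites carried into
#'   the per-specimen variant tables as background rows (true negatives for
#'   somatic calling; donor-only sites among them exercise donor masking).
#' @param alpha Donor-cell contamination fraction of each full-specimen
#'   recurrent tumor biopsy, recycled to `n_wes` patients; each in \[0, 1\].
#' @param purity_pt,purity_rt Tumor purity of the primary tumor and of the
#'   recipient compartment of the recurrent tumor, in (0, 1].
#' @param depth_mean Mean sequencing depth (reads) per site and per
#'   coverage bin.
#' @param seq_error Per-base sequencing error rate; alt/ref flips are applied
#'   symmetrically at this rate.
#' @param n_genes Number of genes in the expression matrix and gene model.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi} (variance
#'   \eqn{\mu + \phi\mu^2}); scalar or length `n_genes`.
#' @param gene_mean_meanlog,gene_mean_sdlog Log-normal parameters of the
#'   per-gene baseline expression means.
#' @param libsize_sdlog Log-normal sd of per-sample library-size factors.
#' @param planted_gene_log2fc Planted log2 fold change applied to the planted
#'   gene in the `P_T` of recurrent patients.
#' @param planted_region Named list `(chrom, start, end)`: genomic interval
#'   carrying a hemizygous deletion shared by `P_T` and `R_T` in
#'   `planted_in_patients` of the full-specimen patients (0-based half-open).
#' @param planted_in_patients How many of the `n_wes` patients carry the
#'   planted deletion (the spec's "3 of 4" regime by default).
#' @param bin_size Coverage bin width in bp.
#' @param chrom_lengths Named integer vector of chromosome lengths defining
#'   the synthetic genome.
#' @param hazard_ratio True hazard ratio of the low- vs high-expression group
#'   for the planted gene.
#' @param baseline_hazard Baseline recurrence hazard per month for the
#'   high-expression group. The default 0.008 makes the expected number of
#'   events over the follow-up window match the 9-of-21 recurrence rate of
#'   the emulated design.
#' @param censor_time Administrative censoring time in months.
#' @param p_male,p_hbv Marginal frequencies of male sex and HBV positivity.
#' @param age_mean,age_sd Normal parameters for patient age.
#' @param seed Integer seed used by [simulate_cohort()].
#'
#' @return A list of class `oltseq_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 6, n_recurrent = 3, n_wes = 2)
#' cfg$alpha
sim_config <- function(n_patients = 21,
                       n_recurrent = 9,
                       n_wes = 4,
                       panel_size = 2000,
                       maf_range = c(0.1, 0.5),
                       n_somatic_per_clone = 60,
                       clone_fractions = c(1, 0.55),
                       shared_clone_fraction = 0.5,
                       n_somatic_private = 25,
                       private_clone_fraction = 0.6,
                       n_germline_background = 300,
                       alpha = c(0.80, 0.06, 0.55, 0),
                       purity_pt = 0.8,
                       purity_rt = 0.8,
                       depth_mean = 100,
                       seq_error = 0.001,
                       n_genes = 1000,
                       nb_dispersion = 0.1,
                       gene_mean_meanlog = log(300),
                       gene_mean_sdlog = 1,
                       libsize_sdlog = 0.15,
                       planted_gene_log2fc = -1.5,
                       planted_region = list(chrom = "chr4", start = 30e6, end = 60e6),
                       planted_in_patients = 3,
                       bin_size = 5e5,
                       chrom_lengths = c(chr1 = 100e6, chr2 = 100e6,
                                         chr3 = 100e6, chr4 = 100e6),
                       hazard_ratio = 7,
                       baseline_hazard = 0.008,
                       censor_time = 24,
                       p_male = 0.9,
                       p_hbv = 0.8,
                       age_mean = 50,
                       age_sd = 9,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "oltseq_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_recurrent <= cfg$n_patients,
            cfg$n_wes <= cfg$n_recurrent, cfg$panel_size >= 1,
            cfg$depth_mean > 0)
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("`maf_range` must be increasing and lie in (0, 0.5]", call. = FALSE)
  }
  if (any(cfg$clone_fractions <= 0) || any(cfg$clone_fractions > 1)) {
    stop("clone fractions must lie in (0, 1]", call. = FALSE)
  }
  if (any(cfg$alpha < 0) || any(cfg$alpha > 1)) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  frac1 <- c(cfg$purity_pt, cfg$purity_rt, cfg$private_clone_fraction)
  if (any(frac1 <= 0) || any(frac1 > 1)) {
    stop("purities and clone fractions must lie in (0, 1]", call. = FALSE)
  }
  if (any(cfg$nb_dispersion <= 0)) {
    stop("`nb_dispersion` must be positive", call. = FALSE)
  }
  if (cfg$hazard_ratio <= 0) stop("`hazard_ratio` must be positive", call. = FALSE)
  if (cfg$seq_error < 0 || cfg$seq_error >= 0.5) {
    stop("`seq_error` must lie in [0, 0.5)", call. = FALSE)
  }
  invisible(cfg)
}

#' Synthetic genome layout: coverage bins and gene model
#'
#' Deterministically lays out the binned genome and an evenly spaced gene
#' model over the chromosomes in `config`, and identifies the planted gene as
#' the gene nearest the midpoint of the planted deletion. Coordinates are
#' 0-based half-open throughout.
#'
#' @param config An [sim_config()] object.
#' @return A list with `bins` (tibble: chrom, start, end), `genes` (tibble:
#'   gene, chrom, start, end) and `planted_gene` (character scalar).
#' @export
cohort_genome <- function(config) {
  bins <- purrr::map_dfr(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = config$bin_size)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + config$bin_size, len))
  })
  glen <- sum(config$chrom_lengths)
  # evenly spaced 50 kb genes across the concatenated genome
  gpos <- floor(seq(0, glen - 5e4, length.out = config$n_genes))
  offsets <- cumsum(c(0, unname(config$chrom_lengths)))
  idx <- findInterval(gpos, offsets, rightmost.closed = FALSE)
  genes <- tibble::tibble(
    gene = sprintf("G%04d", seq_len(config$n_genes)),
    chrom = names(config$chrom_lengths)[idx],
    start = gpos - offsets[idx]
  ) |>
    dplyr::mutate(end = pmin(.data$start + 5e4,
                             unname(config$chrom_lengths[.data$chrom])))
  pr <- config$planted_region
  mid <- (pr$start + pr$end) / 2
  cand <- genes |>
    dplyr::filter(.data$chrom == pr$chrom,
                  .data$start < pr$end, .data$end > pr$start)
  if (nrow(cand) == 0) stop("planted region overlaps no gene", call. = FALSE)
  planted <- cand$gene[which.min(abs((cand$start + cand$end) / 2 - mid))]
  list(bins = bins, genes = genes, planted_gene = planted)
}
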