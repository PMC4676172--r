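# Tumor-origin determination and donor-cell contamination estimation.
#
# Two independent estimators of the donor fraction alpha in the
# recurrent-tumor biopsy: a binomial maximum-likelihood estimator on
# germline-SNP allele fractions at informative loci (recipient genotype !=
# donor genotype), and a somatic VAF-dilution estimator on clonal variants
# shared between the primary and recurrent tumors.

#' Clonal-relationship statistic between two somatic call sets
#'
#' Quantifies whether two tumors share a clonal origin: the CR value is the
#' Jaccard index of their somatic variant keys, and the chance-sharing null
#' treats the number of shared variants as Poisson with mean
#' `|P| * |R| / callable_bases` (independent placement over the callable
#' territory). The origin call is `recipient` when sharing is both
#' statistically impossible by chance (`p <= p_threshold`) and substantial
#' (`cr >= cr_threshold`).
#'
#' @param p_t,r_t Somatic call sets (tibbles keyed by `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param callable_bases Size of the jointly callable territory in bases.
#' @param p_threshold,cr_threshold Decision thresholds for the origin call.
#' @return One-row tibble: `n_pt`, `n_rt`, `n_shared`, `cr_value`,
#'   `expected_shared_by_chance`, `p_value`, `origin_call`.
#' @export
clonal_relationship <- function(p_t, r_t, callable_bases,
                                p_threshold = 1e-6, cr_threshold = 0.05) {
  if (nrow(p_t) == 0 || nrow(r_t) == 0) {
    stop("empty somatic call set", call. = FALSE)
  }
  if (callable_bases < max(nrow(p_t), nrow(r_t))) {
    stop("`callable_bases` smaller than a call set", call. = FALSE)
  }
  key <- c("chrom", "pos", "ref", "alt")
  a <- dplyr::distinct(dplyr::select(p_t, dplyr::all_of(key)))
  b <- dplyr::distinct(dplyr::select(r_t, dplyr::all_of(key)))
  shared <- nrow(dplyr::inner_join(a, b, by = key))
  union_n <- nrow(a) + nrow(b) - shared
  cr <- shared / union_n
  e_chance <- nrow(a) * nrow(b) / callable_bases
  p <- ppois(shared - 1, e_chance, lower.tail = FALSE)
  tibble::tibble(
    n_pt = nrow(a), n_rt = nrow(b), n_shared = shared,
    cr_value = cr, expected_shared_by_chance = e_chance, p_value = p,
    origin_call = if (p <= p_threshold && cr >= cr_threshold)
      "recipient" else "not-established")
}

germline_loglik <- function(alpha, alt, depth, g_r, g_d, eps) {
  f <- ((1 - alpha) * g_r + alpha * g_d) / 2
  sum(dbinom(alt, depth, err_adjust(f, eps), log = TRUE))
}

#' Germline-SNP maximum-likelihood estimate of donor contamination
#'
#' At an informative locus (recipient genotype `g_R` differs from donor
#' genotype `g_D`) the alt-allele fraction of a mixed biopsy has expectation
#' `f(alpha) = ((1 - alpha) g_R + alpha g_D) / 2`, observed through a
#' symmetric sequencing-error channel `f' = f (1 - eps) + (1 - f) eps`. The
#' estimator maximizes the binomial log-likelihood of the observed alt
#' counts over `alpha` in \[0, 1\] (0.001 grid, then golden-section
#' refinement, with the boundaries compared explicitly so exact 0 or 1 can
#' be returned), and reports the profile-likelihood 95 % interval
#' `{alpha : logL >= logL_max - 1.92}`.
#'
#' Loci falling inside copy-number-aberrant segments of the recurrent tumor
#' violate the two-copies-per-cell assumption and are excluded via
#' `excluded_regions`.
#'
#' @param rt_counts Allele counts over the panel for the recurrent-tumor
#'   biopsy: tibble with `chrom`, `pos`, `depth`, `alt_reads`.
#' @param p_b,r_nat Genotype panels (tibbles with `chrom`, `pos`,
#'   `genotype`) for recipient blood and donor tissue.
#' @param excluded_regions Optional tibble of 0-based half-open intervals
#'   (`chrom`, `start`, `end`) to exclude.
#' @param eps Per-base sequencing error rate.
#' @param min_depth Minimum recurrent-tumor depth per locus.
#' @param min_informative Minimum number of informative loci required.
#' @return One-row tibble: `alpha`, `ci_low`, `ci_high`, `n_informative`,
#'   `loglik`, `estimable`, `reason`.
#' @export
estimate_contamination_germline <- function(rt_counts, p_b, r_nat,
                                            excluded_regions = NULL,
                                            eps = 0.001, min_depth = 20,
                                            min_informative = 30) {
  not_est <- function(reason, n = 0L) {
    tibble::tibble(alpha = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   n_informative = n, loglik = NA_real_,
                   estimable = FALSE, reason = reason)
  }
  loci <- rt_counts |>
    dplyr::inner_join(dplyr::select(p_b, "chrom", "pos", g_r = "genotype"),
                      by = c("chrom", "pos")) |>
    dplyr::inner_join(dplyr::select(r_nat, "chrom", "pos", g_d = "genotype"),
                      by = c("chrom", "pos")) |>
    dplyr::filter(.data$depth >= min_depth)
  if (!is.null(excluded_regions) && nrow(excluded_regions) > 0) {
    drop <- loci |>
      dplyr::inner_join(
        dplyr::transmute(excluded_regions, chrom = .data$chrom,
                         s1 = .data$start + 1, e = .data$end),
        by = dplyr::join_by("chrom", dplyr::between(x$pos, y$s1, y$e))) |>
      dplyr::distinct(.data$chrom, .data$pos)
    loci <- dplyr::anti_join(loci, drop, by = c("chrom", "pos"))
  }
  inf <- dplyr::filter(loci, .data$g_r != .data$g_d)
  if (nrow(inf) == 0) {
    return(not_est("no informative loci (donor and recipient genotypes agree)"))
  }
  if (nrow(inf) < min_informative) {
    stop("only ", nrow(inf), " informative loci; need >= ", min_informative,
         call. = FALSE)
  }
  ll <- function(a) germline_loglik(a, inf$alt_reads, inf$depth,
                                    inf$g_r, inf$g_d, eps)
  grid <- seq(0, 1, by = 0.001)
  llg <- vapply(grid, ll, numeric(1))
  i <- which.max(llg)
  lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-9)
  cand <- c(0, 1, opt$maximum, grid[i])
  cll <- vapply(cand, ll, numeric(1))
  best <- which.max(cll)
  alpha_hat <- cand[best]; ll_max <- cll[best]
  qual <- grid[!is.na(llg) & llg >= ll_max - 1.92]
  tibble::tibble(alpha = alpha_hat,
                 ci_low = min(c(qual, alpha_hat)),
                 ci_high = max(c(qual, alpha_hat)),
                 n_informative = nrow(inf), loglik = ll_max,
                 estimable = TRUE, reason = NA_character_)
}

#' Somatic VAF-dilution estimate of donor contamination
#'
#' Donor-cell contamination dilutes every somatic VAF in the recurrent tumor
#' by the same factor `1 - alpha` (equal purity of the two tumors'
#' recipient compartments, copy-number-neutral loci). Restricting to clonal
#' shared variants — primary-tumor VAF at least `0.8 * purity_pt / 2` — the
#' estimator is `clamp(1 - median(VAF_RT / VAF_PT), 0, 1)`, with a seeded
#' percentile bootstrap over loci for the 95 % interval.
#'
#' @param partition The `partition` tibble from [partition_shared_unique()]
#'   (columns `class`, `vaf_pt`, `vaf_rt`).
#' @param purity_pt Primary-tumor purity in (0, 1].
#' @param min_clonal Minimum number of clonal shared variants.
#' @param n_boot Bootstrap resamples.
#' @param boot_seed Seed for the bootstrap.
#' @return One-row tibble: `alpha`, `ci_low`, `ci_high`, `n_clonal`,
#'   `estimable`, `reason`.
#' @export
estimate_contamination_somatic <- function(partition, purity_pt,
                                           min_clonal = 10, n_boot = 1000,
                                           boot_seed = 1L) {
  cl <- partition |>
    dplyr::filter(.data$class == "shared",
                  .data$vaf_pt >= 0.8 * purity_pt / 2,
                  .data$vaf_pt > 0)
  if (nrow(cl) < min_clonal) {
    return(tibble::tibble(
      alpha = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      n_clonal = nrow(cl), estimable = FALSE,
      reason = sprintf("only %d clonal shared variants; need >= %d",
                       nrow(cl), min_clonal)))
  }
  ratio <- cl$vaf_rt / cl$vaf_pt
  est <- function(r) min(max(1 - median(r), 0), 1)
  boot <- with_seed(boot_seed, {
    vapply(seq_len(n_boot), function(b) {
      est(ratio[sample.int(length(ratio), replace = TRUE)])
    }, numeric(1))
  })
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  tibble::tibble(alpha = est(ratio), ci_low = ci[1], ci_high = ci[2],
                 n_clonal = nrow(cl), estimable = TRUE,
                 reason = NA_character_)
}

#' Combine the germline and somatic contamination estimates
#'
#' The combined range spans the available point estimates, mirroring the
#' two-method reporting style (e.g. "72-86 %"); with a single successful
#' estimator the range collapses to a point.
#'
#' @param germline_est,somatic_est One-row tibbles from
#'   [estimate_contamination_germline()] and
#'   [estimate_contamination_somatic()].
#' @return One-row tibble of class `oltseq_contamination`:
#'   per-method estimates and intervals, `combined_low`, `combined_high`.
#' @export
combine_contamination <- function(germline_est, somatic_est) {
  pts <- c(if (isTRUE(germline_est$estimable)) germline_est$alpha,
           if (isTRUE(somatic_est$estimable)) somatic_est$alpha)
  if (length(pts) == 0) {
    stop("both contamination estimators failed: ",
         germline_est$reason, " / ", somatic_est$reason, call. = FALSE)
  }
  out <- tibble::tibble(
    alpha_germline = germline_est$alpha,
    germline_ci_low = germline_est$ci_low,
    germline_ci_high = germline_est$ci_high,
    alpha_somatic = somatic_est$alpha,
    somatic_ci_low = somatic_est$ci_low,
    somatic_ci_high = somatic_est$ci_high,
    combined_low = min(pts), combined_high = max(pts),
    n_informative_loci = germline_est$n_informative,
    n_clonal_variants = somatic_est$n_clonal)
  class(out) <- c("oltseq_contamination", class(out))
  out
}

#' @export
print.oltseq_contamination <- function(x, ...) {
  cat(sprintf("Donor-cell contamination: %s %%\n",
              if (isTRUE(all.equal(x$combined_low, x$combined_high)))
                sprintf("%.0f", 100 * x$combined_low)
              else sprintf("%.0f-%.0f", 100 * x$combined_low,
                           100 * x$combined_high)))
  NextMethod()
}

#' Crude tumor-purity estimate from somatic VAFs
#'
#' `min(1, 2 * 95th percentile of somatic VAF)` — a rough stand-in when an
#' external purity call is unavailable; clonal heterozygous variants at
#' purity `pi` sit near VAF `pi / 2`.
#'
#' @param calls A somatic call set with a `vaf` column.
#' @return Purity estimate in (0, 1].
#' @export
estimate_purity_crude <- function(calls) {
  stopifnot(nrow(calls) > 0)
  min(1, 2 * quantile(calls$vaf, 0.95, names = FALSE))
}
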