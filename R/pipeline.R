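# End-to-end analysis of a transplant cohort: origin and contamination per
# full-specimen patient, cross-patient copy-number regions, the
# recurrent-vs-non-recurrent expression contrast, candidate-gene
# integration, and the prognostic survival models.

#' Run the integrated recurrence analysis on a cohort
#'
#' Executes the full pipeline on a synthetic cohort (or any object with the
#' same slots): per full-specimen patient, somatic calling with
#' donor-difference masking, the clonal-relationship origin test and both
#' contamination estimators; copy-number segmentation of P_T and R_T with
#' purity-aware state calls (the recurrent tumor's effective aberrant-cell
#' fraction uses the germline contamination estimate); the k-of-n shared
#' deletion/amplification catalog and its genes; the cohort fold-change
#' contrast and its under-expressed set; the deletion-by-under-expression
#' candidate list; and, per candidate gene, median-dichotomized
#' Kaplan-Meier, log-rank, and multivariate Cox models on the clinical
#' table.
#'
#' @param cohort An `oltseq_cohort` from [simulate_cohort()].
#' @param k Cross-patient region vote threshold.
#' @param covariates Clinical covariates for the multivariate Cox model.
#' @param candidate_genes Optional character vector to use instead of the
#'   integrated candidate list (e.g. to force evaluation of a known gene).
#' @return Object of class `oltseq_pipeline`: a list with `origin`,
#'   `contamination`, `segments`, `regions`, `region_genes`, `contrast`,
#'   `underexpressed`, `candidates` and `survival` (one row per candidate:
#'   log-rank p, Cox HR and p for the low-expression group, flags), plus
#'   `km` fits per candidate.
#' @export
run_recurrence_pipeline <- function(cohort, k = 3,
                                    covariates = c("hbv", "grade", "age", "sex"),
                                    candidate_genes = NULL) {
  stopifnot(inherits(cohort, "oltseq_cohort"))
  cfg <- cohort$config
  callable <- sum(cfg$chrom_lengths)

  origin <- list(); contamination <- list(); per_patient <- list()
  segments <- list()
  for (p in cohort$wes_patients) {
    v <- cohort$variants |> dplyr::filter(.data$patient == p)
    tab <- function(spec) dplyr::filter(v, .data$specimen == spec)
    pan <- cohort$panels[[p]]

    pt_calls <- call_somatic(tab("P_T"), tab("P_B"), nat = tab("P_NAT"))
    rt_calls <- call_somatic(tab("R_T"), tab("P_B")) |>
      mask_donor_differences(pan$rnat, pan$pb)

    cr <- clonal_relationship(pt_calls, rt_calls, callable)
    part <- partition_shared_unique(pt_calls, rt_calls)

    # copy number: tumor vs matched normal tissue
    cov <- cohort$coverage |> dplyr::filter(.data$patient == p)
    cov_of <- function(spec) dplyr::filter(cov, .data$specimen == spec)
    pt_track <- bin_log2_ratios(cov_of("P_T"), cov_of("P_NAT"))
    rt_track <- bin_log2_ratios(cov_of("R_T"), cov_of("R_NAT"))
    pt_seg_own <- segment_binary(pt_track)
    rt_seg_own <- segment_binary(rt_track)
    # joint breakpoints: change points found in either specimen are imposed
    # on both, so the contamination-diluted R_T only has to estimate states
    pt_seg <- impose_breakpoints(pt_track, pt_seg_own, rt_seg_own) |>
      call_states(cfg$purity_pt)
    rt_seg_raw <- impose_breakpoints(rt_track, pt_seg_own, rt_seg_own)

    # exclude CN-aberrant R_T territory from the germline MLE
    excl <- rt_seg_raw |> dplyr::filter(abs(.data$mean_l) > 0.1)
    germ <- estimate_contamination_germline(pan$rt, pan$pb, pan$rnat,
                                            excluded_regions = excl,
                                            eps = cfg$seq_error)
    som <- estimate_contamination_somatic(part$partition, cfg$purity_pt)
    contamination[[p]] <- combine_contamination(germ, som) |>
      dplyr::mutate(patient = p, .before = 1)

    alpha_hat <- if (isTRUE(germ$estimable)) germ$alpha else
      if (isTRUE(som$estimable)) som$alpha else 0
    eff_purity <- max(cfg$purity_rt * (1 - alpha_hat), 0.02)
    rt_seg <- call_states(rt_seg_raw, eff_purity)

    origin[[p]] <- cr |> dplyr::mutate(patient = p, .before = 1)
    per_patient[[p]] <- list(pt = pt_seg, rt = rt_seg)
    segments[[p]] <- dplyr::bind_rows(
      pt_seg |> dplyr::mutate(patient = p, specimen = "P_T", .before = 1),
      rt_seg |> dplyr::mutate(patient = p, specimen = "R_T", .before = 1))
  }

  regions <- cross_patient_regions(per_patient, cohort$genome$bins, k = k)
  del_regions <- regions |> dplyr::filter(.data$category == "shared-del")
  region_genes <- if (nrow(del_regions) > 0) {
    unique(genes_in_regions(del_regions, cohort$genome$genes)$gene)
  } else character(0)

  folds <- per_patient_fold_changes(cohort$counts, cohort$samples)
  labels <- cohort$samples |>
    dplyr::distinct(.data$patient, .data$recurrence)
  contrast <- group_contrast(folds, labels)
  under <- underexpressed_genes(contrast)$gene

  candidates <- candidate_genes %||% {
    if (length(region_genes) > 0 && length(under) > 0) {
      candidate_integration(region_genes, under, cohort$genome$genes)
    } else character(0)
  }

  covs <- encode_covariates(cohort$clinical, covariates)
  covs <- covs[, vapply(covs, function(x) var(x) > 0, logical(1)),
               drop = FALSE]
  km <- list()
  surv <- purrr::map_dfr(candidates, function(g) {
    f <- folds |> dplyr::filter(.data$gene == g)
    f <- f[match(cohort$clinical$patient, f$patient), ]
    cut <- dichotomize_median(f$log2fc)
    if (cut$flag_degenerate) return(tibble::tibble())
    km[[g]] <<- km_fit(cohort$clinical$time, cohort$clinical$event,
                       cut$group)
    lr <- logrank_test(cohort$clinical$time, cohort$clinical$event,
                       cut$group)
    fit <- tryCatch(
      cox_fit(cohort$clinical$time, cohort$clinical$event,
              dplyr::bind_cols(
                tibble::tibble(low = as.numeric(cut$group == "low")), covs)),
      error = function(e) NULL)
    co <- if (!is.null(fit))
      fit$coefficients[fit$coefficients$term == "low", ] else
        tibble::tibble(hr = NA_real_, p_value = NA_real_)
    tibble::tibble(gene = g, n_low = sum(cut$group == "low"),
                   n_high = sum(cut$group == "high"),
                   logrank_p = lr$p_value, cox_hr = co$hr,
                   cox_p = co$p_value,
                   flag_monotone = if (!is.null(fit)) fit$flag_monotone
                   else NA)
  })

  structure(list(
    origin = dplyr::bind_rows(origin),
    contamination = dplyr::bind_rows(contamination),
    segments = dplyr::bind_rows(segments),
    regions = regions,
    region_genes = region_genes,
    contrast = contrast,
    underexpressed = under,
    candidates = candidates,
    survival = surv,
    km = km
  ), class = "oltseq_pipeline")
}

#' @export
print.oltseq_pipeline <- function(x, ...) {
  cat("<oltseq_pipeline>\n")
  cat(sprintf("  origin calls: %s\n",
              paste(x$origin$origin_call, collapse = ", ")))
  cat(sprintf("  contamination (combined range): %s\n",
              paste(sprintf("%s %.0f-%.0f%%", x$contamination$patient,
                            100 * x$contamination$combined_low,
                            100 * x$contamination$combined_high),
                    collapse = "; ")))
  cat(sprintf("  %d catalog regions; %d shared-del genes; %d under-expressed; candidates: %s\n",
              nrow(x$regions), length(x$region_genes),
              length(x$underexpressed),
              if (length(x$candidates)) paste(x$candidates, collapse = ", ")
              else "(none)"))
  if (nrow(x$survival) > 0) {
    cat("  survival per candidate:\n")
    print(x$survival)
  }
  invisible(x)
}

#' Plot a copy-number bin track with its segments
#'
#' @param track A bin track from [bin_log2_ratios()].
#' @param segments Optional called segment set to overlay.
#' @return A ggplot object.
#' @export
plot_cnv_track <- function(track, segments = NULL) {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes((.data$start + .data$end) / 2,
                                    .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "Position (bp)", y = "log2 tumor/normal") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_l, yend = .data$mean_l,
                   color = .data$state),
      linewidth = 1.1, inherit.aes = FALSE)
  }
  p
}
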