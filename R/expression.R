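# Counts normalization (median-of-ratios), per-patient tumor/normal log2
# fold changes, a sum-conditioned negative-binomial exact test for
# replicate-free patient pairs, and the recurrent vs non-recurrent group
# contrast on per-patient fold changes.

counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene")])
  rownames(m) <- counts$gene
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio of the sample's
#' count to the gene's geometric mean across samples.
#'
#' @param counts Tibble with a `gene` column and one column of non-negative
#'   integer counts per sample.
#' @return Tibble: `sample`, `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- counts_matrix(counts)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) stop("no gene has nonzero counts in all samples", call. = FALSE)
  geo <- exp(rowMeans(log(m[ok, , drop = FALSE])))
  sf <- apply(m[ok, , drop = FALSE], 2, function(col) median(col / geo))
  tibble::tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Per-patient tumor/normal log2 fold changes
#'
#' Normalized P_T counts are scaled by the matched P_NAT within each
#' patient: `F = log2((K_PT/s_PT + c) / (K_PNAT/s_PNAT + c))` with
#' pseudocount `c`.
#'
#' @param counts Counts tibble (see [estimate_size_factors()]).
#' @param samples Sample sheet tibble: `sample`, `patient`, `role`
#'   (`"P_T"`/`"P_NAT"`), and optionally `recurrence`.
#' @param size_factors Optional precomputed size factors; estimated from
#'   `counts` when `NULL`.
#' @param pseudocount Pseudocount `c` on the normalized-count scale.
#' @return Long tibble: `gene`, `patient`, `log2fc`.
#' @export
per_patient_fold_changes <- function(counts, samples, size_factors = NULL,
                                     pseudocount = 0.5) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  m <- counts_matrix(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample)
  pairs <- samples |>
    dplyr::filter(.data$role %in% c("P_T", "P_NAT")) |>
    dplyr::select("sample", "patient", "role") |>
    tidyr::pivot_wider(names_from = "role", values_from = "sample")
  if (!all(c("P_T", "P_NAT") %in% names(pairs)) ||
      any(is.na(pairs$P_T)) || any(is.na(pairs$P_NAT))) {
    stop("every patient needs matched P_T and P_NAT samples", call. = FALSE)
  }
  purrr::map2_dfr(pairs$patient, seq_len(nrow(pairs)), function(p, i) {
    t_col <- pairs$P_T[i]; n_col <- pairs$P_NAT[i]
    tibble::tibble(
      gene = rownames(m), patient = p,
      log2fc = unname(log2((m[, t_col] / sf[t_col] + pseudocount) /
                             (m[, n_col] / sf[n_col] + pseudocount))))
  })
}

#' Fit a mean-dispersion trend by method of moments
#'
#' Per-gene dispersions are estimated from normalized counts of the given
#' sample group by moments, `phi = (var - mu) / mu^2`, and regressed on the
#' reciprocal mean by least squares: `phi(mu) = a0 + a1 / mu`. Fitted values
#' are floored at 1e-8. Used to lend a dispersion to the replicate-free
#' per-patient exact test, pooled across the cohort's normal samples.
#'
#' @param counts Counts tibble.
#' @param group Character vector of sample names forming the group (at least
#'   2).
#' @return An object of class `oltseq_disp_trend` with coefficients `a0`,
#'   `a1`.
#' @export
fit_dispersion_trend <- function(counts, group) {
  if (length(group) < 2) stop("need at least 2 samples", call. = FALSE)
  m <- counts_matrix(counts)[, group, drop = FALSE]
  sf <- estimate_size_factors(counts[, c("gene", group)])$size_factor
  norm <- sweep(m, 2, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, var)
  keep <- mu > 0
  phi <- (v[keep] - mu[keep]) / mu[keep]^2
  x <- 1 / mu[keep]
  fit <- stats::lm(phi ~ x)
  structure(list(a0 = unname(coef(fit)[1]), a1 = unname(coef(fit)[2]),
                 n_genes = sum(keep)),
            class = "oltseq_disp_trend")
}

#' @export
print.oltseq_disp_trend <- function(x, ...) {
  cat(sprintf("<oltseq_disp_trend> phi(mu) = %.4g + %.4g/mu (%d genes)\n",
              x$a0, x$a1, x$n_genes))
  invisible(x)
}

#' Evaluate a dispersion trend at given means
#'
#' @param trend An `oltseq_disp_trend` object.
#' @param mu Numeric vector of means.
#' @return Fitted dispersions, floored at 1e-8.
#' @export
dispersion_at <- function(trend, mu) {
  stopifnot(inherits(trend, "oltseq_disp_trend"))
  pmax(trend$a0 + trend$a1 / mu, 1e-8)
}

nb_exact_p <- function(k_a, k_b, s_a, s_b, phi) {
  total <- k_a + k_b
  if (total == 0) return(1)
  q <- total / (s_a + s_b)
  mu_a <- q * s_a; mu_b <- q * s_b
  size_a <- 1 / phi; size_b <- 1 / phi
  a <- 0:total
  pr <- dnbinom(a, mu = mu_a, size = size_a) *
    dnbinom(total - a, mu = mu_b, size = size_b)
  obs <- pr[k_a + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr))
}

#' Negative-binomial exact test for one tumor/normal pair
#'
#' For each gene, conditions on the total count of the two samples and
#' computes the two-sided exact p-value: the probability, under independent
#' NB marginals with a common concentration fitted from `trend` and means
#' proportional to the size factors, of all splits of the total as likely
#' or less likely than the observed one. With equal size factors and equal
#' counts the observed split is modal and `p = 1`; a zero total gives
#' `p = 1` by convention.
#'
#' @param counts Counts tibble.
#' @param sample_t,sample_n Column names of the tumor and normal samples.
#' @param trend An `oltseq_disp_trend` dispersion trend.
#' @param size_factors Optional size-factor tibble (estimated from `counts`
#'   when `NULL`).
#' @param pseudocount Pseudocount for the reported log2 fold change.
#' @param p_threshold,lfc_threshold Pass thresholds: `p < p_threshold` and
#'   `|log2 fold| > lfc_threshold`.
#' @return Tibble: `gene`, `k_t`, `k_n`, `effect` (log2), `p_value`,
#'   `pass`, `direction`.
#' @export
nb_pair_test <- function(counts, sample_t, sample_n, trend,
                         size_factors = NULL, pseudocount = 0.5,
                         p_threshold = 0.01, lfc_threshold = 1) {
  stopifnot(inherits(trend, "oltseq_disp_trend"))
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample)
  m <- counts_matrix(counts)
  k_t <- unname(m[, sample_t]); k_n <- unname(m[, sample_n])
  s_t <- sf[sample_t]; s_n <- sf[sample_n]
  q <- (k_t + k_n) / (s_t + s_n)
  phi <- dispersion_at(trend, pmax(q, 1e-8))
  p <- vapply(seq_along(k_t), function(g) {
    nb_exact_p(k_t[g], k_n[g], s_t, s_n, phi[g])
  }, numeric(1))
  eff <- log2((k_t / s_t + pseudocount) / (k_n / s_n + pseudocount))
  tibble::tibble(
    gene = rownames(m), k_t = as.integer(k_t), k_n = as.integer(k_n),
    effect = eff, p_value = p,
    pass = p < p_threshold & abs(eff) > lfc_threshold,
    direction = dplyr::case_when(eff > 0 ~ "up", eff < 0 ~ "down",
                                 TRUE ~ "none"))
}

welch_stats <- function(m1, m2, v1, v2, n1, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  # degenerate zero-variance groups: limiting p is 0 (effect) or 1 (none)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  list(t = t, df = df, p = p, degenerate = degen)
}

#' Contrast per-patient fold changes between recurrent and non-recurrent
#' patients
#'
#' Per gene, a Welch two-sample t-test (or Wilcoxon rank-sum) compares the
#' per-patient log2 fold changes between the two recurrence groups. The
#' effect is the difference of group means (log2 units); a gene passes when
#' `|effect| >= lfc_threshold` and the raw `p < p_threshold` — no multiple
#' testing adjustment is applied, by design: the screen feeds a downstream
#' intersection with deleted regions, not a standalone discovery list.
#'
#' @param folds Long fold-change tibble from [per_patient_fold_changes()].
#' @param labels Tibble: `patient`, `recurrence` (logical).
#' @param lfc_threshold,p_threshold Pass thresholds (the default pair
#'   corresponds to |fold| > 2 at p < 0.01).
#' @param method `"welch"` or `"wilcoxon"`.
#' @return Tibble: `gene`, `effect` (mean recurrent minus mean
#'   non-recurrent), `p_value`, `pass`, `direction`, `flag_degenerate`.
#' @export
group_contrast <- function(folds, labels, lfc_threshold = 1,
                           p_threshold = 0.01,
                           method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  d <- dplyr::inner_join(folds, labels, by = "patient")
  ngrp <- d |> dplyr::distinct(.data$patient, .data$recurrence) |>
    dplyr::count(.data$recurrence)
  if (nrow(ngrp) < 2 || any(ngrp$n < 2)) {
    stop("need at least 2 patients per recurrence group", call. = FALSE)
  }
  if (method == "welch") {
    st <- d |>
      dplyr::group_by(.data$gene, .data$recurrence) |>
      dplyr::summarise(m = mean(.data$log2fc), v = var(.data$log2fc),
                       n = dplyr::n(), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "recurrence", values_from = c("m", "v", "n"))
    w <- welch_stats(st$m_TRUE, st$m_FALSE, st$v_TRUE, st$v_FALSE,
                     st$n_TRUE, st$n_FALSE)
    res <- tibble::tibble(gene = st$gene, effect = st$m_TRUE - st$m_FALSE,
                          p_value = w$p, flag_degenerate = w$degenerate)
  } else {
    res <- d |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(
        effect = mean(.data$log2fc[.data$recurrence]) -
          mean(.data$log2fc[!.data$recurrence]),
        p_value = stats::wilcox.test(.data$log2fc[.data$recurrence],
                                     .data$log2fc[!.data$recurrence],
                                     exact = FALSE)$p.value,
        .groups = "drop") |>
      dplyr::mutate(flag_degenerate = FALSE)
  }
  res |>
    dplyr::mutate(
      pass = abs(.data$effect) >= lfc_threshold & .data$p_value < p_threshold,
      direction = dplyr::case_when(.data$effect > 0 ~ "up",
                                   .data$effect < 0 ~ "down",
                                   TRUE ~ "none")) |>
    dplyr::select("gene", "effect", "p_value", "pass", "direction",
                  "flag_degenerate")
}

#' Under-expressed subset of a group contrast
#'
#' @param contrast Result of [group_contrast()].
#' @return The passing, negative-effect rows.
#' @export
underexpressed_genes <- function(contrast) {
  dplyr::filter(contrast, .data$pass, .data$effect < 0)
}
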