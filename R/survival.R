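# Expression dichotomization, Kaplan-Meier / log-rank, Cox proportional
# hazards (Newton-Raphson on the partial likelihood, Efron ties), candidate
# integration and the region-wide prognostic screen.

#' Dichotomize values at the median
#'
#' Labels each value `low` when it is at or below the median (for even n the
#' median is the mean of the central pair). The median value itself falls in
#' the low group, so 21 distinct values split 11 low / 10 high.
#'
#' @param values Numeric vector (length at least 4).
#' @return List: `group` (character vector `"low"`/`"high"`), `cut` (the
#'   median), `flag_degenerate` (`TRUE` when all values tie, leaving a
#'   single group).
#' @export
#' @examples
#' dichotomize_median(1:21)$group |> table()
dichotomize_median <- function(values) {
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  cut <- median(values)
  degen <- length(unique(values)) == 1
  if (degen) warning("all values tied; single group", call. = FALSE)
  list(group = ifelse(values <= cut, "low", "high"), cut = cut,
       flag_degenerate = degen)
}

#' Dichotomize against a reference (normal-tissue) distribution
#'
#' The cut point is `mean(reference) - k_sd * sd(reference)`; values
#' strictly below the cut are `low`. This is the normal-liver
#' mean-minus-2-SD rule used when an external reference distribution is
#' available.
#'
#' @param values Numeric vector of patient values.
#' @param reference Numeric vector of reference values (n >= 10).
#' @param k_sd Number of reference SDs below the reference mean.
#' @return List: `group`, `cut`, `flag_empty_low` (`TRUE` when no value
#'   falls below the cut).
#' @export
dichotomize_reference_sd <- function(values, reference, k_sd = 2) {
  if (length(reference) < 10) stop("reference needs >= 10 values", call. = FALSE)
  s <- sd(reference)
  if (s == 0) stop("reference distribution has zero variance", call. = FALSE)
  cut <- mean(reference) - k_sd * s
  group <- ifelse(values < cut, "low", "high")
  list(group = group, cut = cut, flag_empty_low = !any(group == "low"))
}

#' Kaplan-Meier product-limit fit
#'
#' Computes `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` per group, with the
#' median survival as the smallest time at which the curve reaches 0.5 or
#' below (undefined when never reached).
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups Optional group labels (single group when `NULL`).
#' @return Object of class `oltseq_km`: `curves` (tibble: group, time,
#'   n_risk, n_event, n_censor, survival) and `medians` (tibble: group, n,
#'   n_events, median).
#' @export
km_fit <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("negative times", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", length(times))
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  d <- tibble::tibble(time = times, event = as.integer(events),
                      group = as.character(groups))
  curves <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(g, key) {
      tt <- sort(unique(g$time))
      n_risk <- vapply(tt, function(t) sum(g$time >= t), integer(1))
      n_event <- vapply(tt, function(t) sum(g$time == t & g$event == 1),
                        integer(1))
      n_censor <- vapply(tt, function(t) sum(g$time == t & g$event == 0),
                         integer(1))
      tibble::tibble(time = tt, n_risk = n_risk, n_event = n_event,
                     n_censor = n_censor,
                     survival = cumprod(1 - n_event / n_risk))
    }) |>
    dplyr::ungroup()
  medians <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      median = if (any(.data$survival <= 0.5))
        min(.data$time[.data$survival <= 0.5]) else NA_real_,
      .groups = "drop") |>
    dplyr::left_join(
      d |> dplyr::group_by(.data$group) |>
        dplyr::summarise(n = dplyr::n(), n_events = sum(.data$event),
                         .groups = "drop"),
      by = "group") |>
    dplyr::select("group", "n", "n_events", "median")
  structure(list(curves = curves, medians = medians), class = "oltseq_km")
}

#' @export
print.oltseq_km <- function(x, ...) {
  cat("<oltseq_km> Kaplan-Meier fit\n")
  print(x$medians)
  invisible(x)
}

#' @rdname km_fit
#' @param x An `oltseq_km` object.
#' @param ... Unused.
#' @export
autoplot.oltseq_km <- function(x, ...) {
  d <- x$curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over event times, referred to chi-square with 1 df. Invariant to
#' swapping the group labels.
#'
#' @inheritParams km_fit
#' @return One-row tibble: `chisq`, `df`, `p_value`, `n_events`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- as.character(groups)
  lev <- unique(g)
  if (length(lev) != 2) stop("log-rank test needs exactly 2 groups", call. = FALSE)
  if (sum(events) < 1) stop("no events", call. = FALSE)
  tt <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in tt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == lev[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == lev[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  tibble::tibble(chisq = chisq, df = 1L,
                 p_value = pchisq(chisq, 1, lower.tail = FALSE),
                 n_events = as.integer(sum(events)))
}

# Efron (or Breslow) partial log-likelihood, score and information at beta
cox_partial <- function(beta, times, events, x, ties = "efron") {
  n <- length(times); p <- ncol(x)
  ord <- order(-times, -events)  # decreasing time
  tt <- times[ord]; ev <- events[ord]; xx <- x[ord, , drop = FALSE]
  eta <- drop(xx %*% beta); w <- exp(eta)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  s0 <- 0; s1 <- numeric(p); s2 <- matrix(0, p, p)
  i <- 1
  while (i <= n) {
    t_cur <- tt[i]
    j <- i
    while (j <= n && tt[j] == t_cur) j <- j + 1
    idx <- i:(j - 1)
    for (k in idx) {
      s0 <- s0 + w[k]
      s1 <- s1 + w[k] * xx[k, ]
      s2 <- s2 + w[k] * tcrossprod(xx[k, ])
    }
    dset <- idx[ev[idx] == 1]
    d <- length(dset)
    if (d > 0) {
      sd0 <- sum(w[dset])
      sd1 <- colSums(xx[dset, , drop = FALSE] * w[dset])
      sd2 <- matrix(0, p, p)
      for (k in dset) sd2 <- sd2 + w[k] * tcrossprod(xx[k, ])
      ll <- ll + sum(eta[dset])
      U <- U + colSums(xx[dset, , drop = FALSE])
      frac <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
      for (f in frac) {
        den <- s0 - f * sd0
        z <- (s1 - f * sd1) / den
        ll <- ll - log(den)
        U <- U - z
        I <- I + (s2 - f * sd2) / den - tcrossprod(z)
      }
    }
    i <- j
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards regression
#'
#' Fits the Cox model by Newton-Raphson on the partial log-likelihood with
#' Efron's tie correction (Breslow optional), with step-halving; convergence
#' when the log-likelihood change drops below 1e-8 (at most 50 iterations).
#' Reports per-term hazard ratios with Wald 95 % intervals and p-values,
#' and the likelihood-ratio test against the null model. Monotone
#' likelihood (separation — e.g. one group with no events) is detected from
#' diverging coefficients and flagged rather than suppressed; the hazard
#' ratio and interval are then unstable and very wide.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (at least one event).
#' @param covariates Data frame or matrix of numeric covariates (no
#'   constant columns).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `oltseq_cox`; see [tidy()] and [glance()]
#'   methods.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(events) < 1) stop("no events", call. = FALSE)
  const <- apply(x, 2, function(col) var(col) == 0)
  if (any(const)) {
    stop("constant covariate(s): ", paste(colnames(x)[const], collapse = ", "),
         call. = FALSE)
  }
  # center for numerical stability; leaves beta unchanged
  xc <- sweep(x, 2, colMeans(x))
  beta <- numeric(ncol(xc))
  f0 <- cox_partial(beta, times, events, xc, ties)
  ll_null <- f0$loglik
  ll_old <- ll_null
  cur <- f0
  converged <- FALSE; iter <- 0
  for (iter in seq_len(50)) {
    step <- tryCatch(solve(cur$info, cur$score),
                     error = function(e) cur$score / (diag(cur$info) + 1e-8))
    halve <- 0
    repeat {
      beta_new <- beta + step
      f_new <- cox_partial(beta_new, times, events, xc, ties)
      if (is.finite(f_new$loglik) && f_new$loglik >= ll_old - 1e-12) break
      step <- step / 2
      halve <- halve + 1
      if (halve > 30) break
    }
    beta <- beta_new; cur <- f_new
    if (abs(cur$loglik - ll_old) < 1e-8) { converged <- TRUE; break }
    ll_old <- cur$loglik
  }
  se <- sqrt(diag(tryCatch(solve(cur$info),
                           error = function(e)
                             matrix(NA_real_, ncol(xc), ncol(xc)))))
  flag_monotone <- any(abs(beta) > 10) || !converged
  lrt_stat <- 2 * (cur$loglik - ll_null)
  coefs <- tibble::tibble(
    term = colnames(x), estimate = beta, hr = exp(beta), se = se,
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)))
  structure(list(
    coefficients = coefs,
    loglik = c(null = ll_null, full = cur$loglik),
    lrt = tibble::tibble(statistic = lrt_stat, df = ncol(xc),
                         p_value = pchisq(lrt_stat, ncol(xc),
                                          lower.tail = FALSE)),
    n = length(times), n_events = as.integer(sum(events)),
    iterations = iter, converged = converged,
    flag_monotone = flag_monotone, ties = ties),
    class = "oltseq_cox")
}

#' @export
print.oltseq_cox <- function(x, ...) {
  cat(sprintf("<oltseq_cox> n = %d, events = %d (%s ties)%s\n",
              x$n, x$n_events, x$ties,
              if (x$flag_monotone) " [monotone likelihood]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x An `oltseq_cox` object.
#' @param ... Unused.
#' @return Tibble of per-term estimates: `term`, `estimate` (log hazard
#'   ratio), `hr`, `se`, `ci_low`, `ci_high`, `p_value`.
#' @export
tidy.oltseq_cox <- function(x, ...) x$coefficients

#' Model-level summary of a Cox fit
#'
#' @param x An `oltseq_cox` object.
#' @param ... Unused.
#' @return One-row tibble: sample size, events, log-likelihoods, LRT
#'   statistic and p-value, convergence and separation flags.
#' @export
glance.oltseq_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 loglik_null = x$loglik[["null"]],
                 loglik = x$loglik[["full"]],
                 lrt_statistic = x$lrt$statistic, lrt_df = x$lrt$df,
                 lrt_p_value = x$lrt$p_value,
                 converged = x$converged,
                 flag_monotone = x$flag_monotone)
}

#' Intersect deleted-region genes with under-expressed genes
#'
#' The candidate list is the intersection of the genes inside recurrent
#' shared-deletion regions with the genes under-expressed in recurrent
#' patients, ordered deterministically by genomic position when a gene
#' model is supplied (alphabetically otherwise).
#'
#' @param region_genes,underexpressed Character vectors of gene symbols
#'   (both non-empty).
#' @param gene_model Optional tibble (`gene`, `chrom`, `start`) for
#'   positional ordering.
#' @return Character vector of candidate genes (possibly empty).
#' @export
candidate_integration <- function(region_genes, underexpressed,
                                  gene_model = NULL) {
  if (length(region_genes) == 0 || length(underexpressed) == 0) {
    stop("both gene sets must be non-empty", call. = FALSE)
  }
  cand <- intersect(region_genes, underexpressed)
  if (length(cand) == 0) return(character(0))
  if (is.null(gene_model)) return(sort(cand))
  gm <- gene_model |>
    dplyr::filter(.data$gene %in% cand) |>
    dplyr::arrange(.data$chrom, .data$start)
  c(gm$gene, sort(setdiff(cand, gm$gene)))
}

#' Encode clinical covariates for Cox regression
#'
#' Standard encodings for the covariates this screen adjusts for: sex as
#' female indicator, age binarized at `age_cut`, HBV as a 0/1/2 ordinal
#' when three levels exist (active replication carrier / carrier / none)
#' and 0/1 otherwise, grade and stage as ordinals taken numerically.
#'
#' @param clinical Clinical tibble with a subset of the columns `sex`,
#'   `age`, `grade`, `hbv`, `stage`, `cirrhosis`.
#' @param covariates Character vector naming the columns to encode.
#' @param age_cut Age threshold for the binary age indicator.
#' @return Numeric tibble with one column per requested covariate.
#' @export
encode_covariates <- function(clinical, covariates, age_cut = 49) {
  out <- purrr::map(covariates, function(v) {
    col <- clinical[[v]]
    if (is.null(col)) stop("missing clinical column: ", v, call. = FALSE)
    switch(v,
           sex = as.numeric(col %in% c("F", "female")),
           age = as.numeric(col < age_cut),
           as.numeric(col))
  })
  tibble::as_tibble(setNames(out, covariates))
}

#' Region-wide prognostic survival screen
#'
#' For every gene in a region, patients are dichotomized by the
#' reference-distribution rule ([dichotomize_reference_sd()]), a
#' multivariate Cox model (low-group indicator plus the configured clinical
#' covariates) is fitted, and genes are ranked by ascending coefficient
#' p-value. Genes whose smaller group holds under 5 % of patients are
#' flagged as unbalanced — their top ranks are driven by a handful of
#' patients.
#'
#' @param expression Long tibble: `gene`, `patient`, `value`.
#' @param clinical Tibble with `patient`, `time`, `event` and covariate
#'   columns.
#' @param reference Long tibble of reference values: `gene`, `value`.
#' @param covariates Clinical covariate names passed to
#'   [encode_covariates()].
#' @param k_sd Reference-rule SD multiplier.
#' @param age_cut Age threshold for the binary age covariate.
#' @return Tibble ranked by `p_value`: `gene`, `hr`, `p_value`,
#'   `low_fraction`, `flag_balance`, `flag_monotone`, `rank`.
#' @export
region_survival_screen <- function(expression, clinical, reference,
                                   covariates = c("hbv", "grade", "age", "sex"),
                                   k_sd = 2, age_cut = 49) {
  genes <- unique(expression$gene)
  covs <- encode_covariates(clinical, covariates, age_cut)
  covs <- covs[, vapply(covs, function(x) var(x) > 0, logical(1)),
               drop = FALSE]
  rows <- purrr::map_dfr(genes, function(g) {
    ex <- expression |> dplyr::filter(.data$gene == g)
    ex <- ex[match(clinical$patient, ex$patient), ]
    ref <- reference$value[reference$gene == g]
    if (length(ref) < 10 || sd(ref) == 0) return(tibble::tibble())
    cut <- dichotomize_reference_sd(ex$value, ref, k_sd)
    low <- as.numeric(cut$group == "low")
    if (length(unique(low)) < 2) return(tibble::tibble())
    fit <- tryCatch(
      cox_fit(clinical$time, clinical$event,
              dplyr::bind_cols(tibble::tibble(low = low), covs)),
      error = function(e) NULL)
    if (is.null(fit)) return(tibble::tibble())
    co <- fit$coefficients[fit$coefficients$term == "low", ]
    lf <- mean(low)
    tibble::tibble(gene = g, hr = co$hr, p_value = co$p_value,
                   low_fraction = lf,
                   flag_balance = min(lf, 1 - lf) < 0.05,
                   flag_monotone = fit$flag_monotone)
  })
  if (nrow(rows) == 0) stop("no gene passed dichotomization", call. = FALSE)
  rows |>
    dplyr::arrange(.data$p_value) |>
    dplyr::mutate(rank = dplyr::row_number())
}
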