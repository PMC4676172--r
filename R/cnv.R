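# Copy-number analysis: binned log2 tumor/normal coverage ratios, recursive
# binary segmentation, purity-aware five-state calling, and cross-patient
# recurrent-region discovery. Coordinates are 0-based half-open throughout.

CN_STATES <- c("homo-del", "hemi-del", "neutral", "hemi-amp", "homo-amp")

#' Binned log2 tumor/normal coverage ratios
#'
#' Computes `L_b = log2((t_b * S_n / S_t + c) / (n_b + c))` per bin, where
#' `S_t`, `S_n` are total depths (so a global library-size difference
#' cancels) and `c` is a count-scale pseudocount guarding empty bins.
#'
#' @param tumor_cov,normal_cov Coverage tibbles on the same bin grid
#'   (`chrom`, `start`, `end`, `depth`).
#' @param pseudocount Count-scale pseudocount `c`.
#' @return A bin track tibble: `chrom`, `start`, `end`, `tumor_depth`,
#'   `normal_depth`, `log2_ratio`.
#' @export
bin_log2_ratios <- function(tumor_cov, normal_cov, pseudocount = 0.5) {
  key <- c("chrom", "start", "end")
  if (nrow(tumor_cov) != nrow(normal_cov) ||
      !identical(tumor_cov[key], normal_cov[key])) {
    stop("tumor and normal coverage are on different bin grids", call. = FALSE)
  }
  s_t <- sum(tumor_cov$depth); s_n <- sum(normal_cov$depth)
  tumor_cov |>
    dplyr::select(dplyr::all_of(key)) |>
    dplyr::mutate(
      tumor_depth = tumor_cov$depth,
      normal_depth = normal_cov$depth,
      log2_ratio = log2((.data$tumor_depth * s_n / s_t + pseudocount) /
                          (.data$normal_depth + pseudocount)))
}

# Welch t p-value for a two-group comparison given sufficient statistics
welch_p_from_stats <- function(n1, n2, sum1, sum2, ss1, ss2) {
  m1 <- sum1 / n1; m2 <- sum2 / n2
  v1 <- pmax(ss1 - n1 * m1^2, 0) / pmax(n1 - 1, 1)
  v2 <- pmax(ss2 - n2 * m2^2, 0) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / pmax(n1 - 1, 1) +
                          (v2 / n2)^2 / pmax(n2 - 1, 1)),
               1)
  ifelse(n1 > 1 & n2 > 1, 2 * pt(-abs(t), df), 1)
}

# Best change-point candidate for x among single breakpoints and
# breakpoint pairs (an interior segment against its combined flanks, the
# circular-binary-segmentation refinement that recovers weak centered
# events). Every resulting part must keep >= min_bins bins. Returns
# list(breaks, p) or NULL.
best_split <- function(x, min_bins) {
  n <- length(x)
  if (n < 2 * min_bins) return(NULL)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  best <- list(breaks = NULL, p = Inf)
  # single breakpoints
  k <- seq(min_bins, n - min_bins)
  p1 <- welch_p_from_stats(k, n - k, cs[k + 1], cs[n + 1] - cs[k + 1],
                           cs2[k + 1], cs2[n + 1] - cs2[k + 1])
  i1 <- which.min(p1)
  if (p1[i1] < best$p) best <- list(breaks = k[i1], p = p1[i1])
  # breakpoint pairs: interior run [i, j] vs both flanks
  if (n >= 3 * min_bins) {
    for (i in seq(min_bins + 1, n - 2 * min_bins + 1)) {
      j <- seq(i + min_bins - 1, n - min_bins)
      n1 <- j - i + 1
      s1 <- cs[j + 1] - cs[i]
      q1 <- cs2[j + 1] - cs2[i]
      p2 <- welch_p_from_stats(n1, n - n1, s1, cs[n + 1] - s1,
                               q1, cs2[n + 1] - q1)
      i2 <- which.min(p2)
      if (p2[i2] < best$p) {
        best <- list(breaks = c(i - 1, j[i2]), p = p2[i2])
      }
    }
  }
  if (is.null(best$breaks)) NULL else best
}

segment_chrom <- function(l, min_bins, alpha_split) {
  # returns integer vector of segment start indices
  rec <- function(lo, hi) {
    x <- l[lo:hi]
    sp <- best_split(x, min_bins)
    if (is.null(sp) || is.na(sp$p) || sp$p >= alpha_split) return(lo)
    starts <- lo + c(0, sp$breaks)
    ends <- c(lo + sp$breaks - 1, hi)
    unlist(purrr::map2(starts, ends, rec))
  }
  rec(1L, length(l))
}

#' Recursive binary segmentation of a log2-ratio track
#'
#' Within each chromosome, recursively splits at the breakpoint maximizing
#' the two-sample Welch t-statistic of the log2 ratios; a split is accepted
#' when its p-value is below `alpha_split` and both sides keep at least
#' `min_seg_bins` bins. Segments tile the binned territory exactly.
#'
#' @param track A bin track from [bin_log2_ratios()].
#' @param min_seg_bins Minimum bins per segment.
#' @param alpha_split Split acceptance threshold on the Welch p-value.
#' @return A segment set tibble: `chrom`, `start`, `end`, `n_bins`,
#'   `mean_l`, `state` (unset, `NA`).
#' @export
segment_binary <- function(track, min_seg_bins = 5, alpha_split = 0.001) {
  track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2 * min_seg_bins) {
        stop("chromosome ", key$chrom, " has fewer than ", 2 * min_seg_bins,
             " bins", call. = FALSE)
      }
      starts <- segment_chrom(d$log2_ratio, min_seg_bins, alpha_split)
      ends <- c(starts[-1] - 1L, nrow(d))
      purrr::map2_dfr(starts, ends, function(a, b) {
        tibble::tibble(start = d$start[a], end = d$end[b],
                       n_bins = b - a + 1L,
                       mean_l = mean(d$log2_ratio[a:b]),
                       state = NA_character_)
      })
    }) |>
    dplyr::ungroup()
}

#' Re-average a bin track over a fixed set of segment boundaries
#'
#' Computes per-segment mean log2 ratios of `track` over the union of the
#' boundaries of the supplied segment sets. Matched specimens (e.g. a
#' primary and a recurrent tumor of the same patient) are best compared on
#' joint breakpoints: a change point detected in the cleaner specimen is
#' imposed on the noisier one, whose own role is then only to estimate the
#' segment state, not to re-detect it.
#'
#' @param track A bin track from [bin_log2_ratios()].
#' @param ... One or more segment sets whose boundaries are pooled.
#' @return A segment set tiling the track on the pooled boundaries.
#' @export
impose_breakpoints <- function(track, ...) {
  segs <- dplyr::bind_rows(...)
  track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      b <- segs[segs$chrom == key$chrom, ]
      cuts <- sort(unique(c(min(d$start), b$start, b$end, max(d$end))))
      cuts <- cuts[cuts >= min(d$start) & cuts <= max(d$end)]
      idx <- findInterval(d$start, cuts, rightmost.closed = FALSE)
      d |>
        dplyr::mutate(.seg = idx) |>
        dplyr::group_by(.data$.seg) |>
        dplyr::summarise(start = min(.data$start), end = max(.data$end),
                         n_bins = dplyr::n(),
                         mean_l = mean(.data$log2_ratio),
                         .groups = "drop") |>
        dplyr::mutate(state = NA_character_) |>
        dplyr::select(-".seg")
    }) |>
    dplyr::ungroup() |>
    dplyr::select("chrom", "start", "end", "n_bins", "mean_l", "state")
}

#' Purity-parameterized copy-number state means
#'
#' Expected log2 ratio of each of the five CN states for a tumor of purity
#' `pi`: a hemizygous deletion in a fraction-`pi` tumor shifts the average
#' copy number from 2 to `2 - pi`, hence `log2(1 - pi/2)`, and so on; the
#' homozygous-deletion mean is floored at copy fraction 0.05 to avoid
#' `log(0)`.
#'
#' @param purity Tumor purity in (0, 1].
#' @return Named numeric vector over the five states.
#' @export
cn_state_means <- function(purity) {
  stopifnot(purity > 0, purity <= 1)
  c("homo-del" = log2(max(1 - purity, 0.05)),
    "hemi-del" = log2(1 - purity / 2),
    "neutral" = 0,
    "hemi-amp" = log2(1 + purity / 2),
    "homo-amp" = log2(1 + purity))
}

#' Assign copy-number states to segments
#'
#' Each segment takes the state whose purity-adjusted model mean (see
#' [cn_state_means()]) is nearest its mean log2 ratio; exact ties break
#' toward `neutral`.
#'
#' @param segments A segment set from [segment_binary()].
#' @param purity Tumor purity in (0, 1] (for a contaminated recurrent tumor,
#'   pass the effective aberrant-cell fraction `purity * (1 - alpha)`).
#' @return The segment set with `state` filled in.
#' @export
call_states <- function(segments, purity) {
  mu <- cn_state_means(purity)
  states <- vapply(segments$mean_l, function(l) {
    d <- abs(l - mu)
    hit <- which(d == min(d))
    if (length(hit) > 1 && "neutral" %in% names(mu)[hit]) return("neutral")
    names(mu)[hit[1]]
  }, character(1))
  dplyr::mutate(segments, state = states)
}

bin_states <- function(segments, bins) {
  # state of each bin of `bins` under `segments` (bin midpoint membership)
  bins |>
    dplyr::mutate(.mid = (.data$start + .data$end) / 2) |>
    dplyr::left_join(
      dplyr::select(segments, "chrom", seg_start = "start",
                    seg_end = "end", "state"),
      by = dplyr::join_by("chrom", closest(x$.mid >= y$seg_start))) |>
    dplyr::mutate(state = ifelse(.data$.mid < .data$seg_end, .data$state,
                                 NA_character_)) |>
    dplyr::select(-".mid", -"seg_start", -"seg_end")
}

#' Recurrent copy-number regions across patients
#'
#' For each bin of the common grid and each patient, the primary/recurrent
#' state pair is reduced to categories (`amp` = hemi- or homo-amplified,
#' `del` = hemi- or homo-deleted): `shared-amp`/`shared-del` when both
#' tumors agree, `P-only-*` / `R-only-*` when only one is aberrant. A bin
#' enters the catalog under a category when at least `k` of the patients
#' share it; adjacent qualifying bins merge into regions.
#'
#' @param per_patient Named list; each element a list with `pt` and `rt`
#'   called segment sets for one patient.
#' @param bins The common bin grid (tibble `chrom`, `start`, `end`).
#' @param k Minimum number of patients sharing a bin-level category.
#' @return Region catalog tibble: `category`, `chrom`, `start`, `end`,
#'   `n_bins`.
#' @export
cross_patient_regions <- function(per_patient, bins, k = 3) {
  if (length(per_patient) < k) {
    stop("fewer patients than `k`", call. = FALSE)
  }
  amp <- c("hemi-amp", "homo-amp"); del <- c("hemi-del", "homo-del")
  cats <- c("shared-amp", "shared-del", "P-only-amp", "P-only-del",
            "R-only-amp", "R-only-del")
  votes <- matrix(0L, nrow(bins), length(cats),
                  dimnames = list(NULL, cats))
  for (p in per_patient) {
    sp <- bin_states(p$pt, bins)$state
    sr <- bin_states(p$rt, bins)$state
    votes[, "shared-amp"] <- votes[, "shared-amp"] + (sp %in% amp & sr %in% amp)
    votes[, "shared-del"] <- votes[, "shared-del"] + (sp %in% del & sr %in% del)
    votes[, "P-only-amp"] <- votes[, "P-only-amp"] + (sp %in% amp & !sr %in% amp)
    votes[, "P-only-del"] <- votes[, "P-only-del"] + (sp %in% del & !sr %in% del)
    votes[, "R-only-amp"] <- votes[, "R-only-amp"] + (!sp %in% amp & sr %in% amp)
    votes[, "R-only-del"] <- votes[, "R-only-del"] + (!sp %in% del & sr %in% del)
  }
  empty <- tibble::tibble(category = character(), chrom = character(),
                          start = double(), end = double(),
                          n_bins = integer())
  out <- purrr::map_dfr(cats, function(cat) {
    hit <- votes[, cat] >= k
    if (!any(hit)) return(empty)
    bins |>
      dplyr::mutate(hit = hit) |>
      dplyr::filter(.data$hit) |>
      dplyr::group_by(.data$chrom) |>
      # merge runs of adjacent qualifying bins
      dplyr::mutate(run = cumsum(.data$start != dplyr::lag(.data$end,
                                                           default = -1))) |>
      dplyr::group_by(.data$chrom, .data$run) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       n_bins = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(category = cat, .before = 1) |>
      dplyr::select("category", "chrom", "start", "end", "n_bins")
  })
  if (nrow(out) == 0) empty else out
}

#' Genes overlapping catalog regions
#'
#' A gene is reported for a region when their half-open intervals overlap by
#' at least one base (`gene_start < region_end` and
#' `gene_end > region_start`); a gene abutting a region boundary is
#' excluded.
#'
#' @param regions Region catalog (tibble with `chrom`, `start`, `end` and
#'   optionally `category`).
#' @param gene_model Tibble with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open, unique symbols).
#' @return Tibble: one row per (region, gene) overlap, carrying the region
#'   columns plus `gene`, `gene_start`, `gene_end`.
#' @export
genes_in_regions <- function(regions, gene_model) {
  if (nrow(gene_model) == 0) stop("empty gene model", call. = FALSE)
  stopifnot(!anyDuplicated(gene_model$gene))
  if (nrow(regions) == 0) return(tibble::tibble())
  gm <- dplyr::select(gene_model, "gene", "chrom", gene_start = "start",
                      gene_end = "end")
  regions |>
    dplyr::inner_join(gm,
                      by = dplyr::join_by("chrom", x$start < y$gene_end,
                                          x$end > y$gene_start)) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_start)
}
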