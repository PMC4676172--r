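# Log2 ratio construction, segmentation, state calling, cross-patient
# regions and gene overlap.

flat_bins <- function(n, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 1000,
                 end = seq_len(n) * 1000)
}

track_from <- function(l, chrom = "chr1") {
  flat_bins(length(l), chrom) |>
    dplyr::mutate(tumor_depth = 100, normal_depth = 100, log2_ratio = l)
}

test_that("log2 ratios: identity, global-scaling cancellation, deletions", {
  b <- flat_bins(50)
  t_cov <- b |> dplyr::mutate(depth = 200L)
  expect_true(all(bin_log2_ratios(t_cov, t_cov)$log2_ratio == 0))

  # uniformly doubled tumor library: normalization cancels, L = 0
  t2 <- b |> dplyr::mutate(depth = 400L)
  expect_equal(max(abs(bin_log2_ratios(t2, t_cov)$log2_ratio)), 0,
               tolerance = 1e-12)

  # planted hemizygous deletion at purity 1, depth 200
  withr::with_seed(3, {
    del <- c(rep(FALSE, 20), rep(TRUE, 15), rep(FALSE, 15))
    tc <- b |> dplyr::mutate(depth = rpois(50, ifelse(del, 100, 200)))
    nc <- b |> dplyr::mutate(depth = rpois(50, 200))
    tr <- bin_log2_ratios(tc, nc)
    expect_equal(mean(tr$log2_ratio[del]) - mean(tr$log2_ratio[!del]), -1,
                 tolerance = 0.1)
  })
  expect_error(bin_log2_ratios(t_cov, t_cov[1:10, ]), "grids")
})

test_that("segmentation: constant tracks stay whole, steps are localized", {
  expect_equal(nrow(segment_binary(track_from(rep(0.01, 40)))), 1)
  expect_error(segment_binary(track_from(rep(0, 6)), min_seg_bins = 5),
               "fewer")

  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      l <- c(rnorm(50, 0, 0.2), rnorm(50, -1, 0.2))
      seg <- segment_binary(track_from(l))
      any(abs(seg$start / 1000 - 50) <= 2)
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

# independent exhaustive oracle: recursion over {no split, best single
# breakpoint, best interior pair} scored with stats::t.test
oracle_segment <- function(l, min_bins = 5, alpha_split = 0.001) {
  rec <- function(lo, hi) {
    x <- l[lo:hi]; n <- length(x)
    best <- list(p = Inf, parts = NULL)
    if (n >= 2 * min_bins) {
      for (k in min_bins:(n - min_bins)) {
        p <- tryCatch(stats::t.test(x[1:k], x[(k + 1):n])$p.value,
                      error = function(e) 1)
        if (p < best$p) best <- list(p = p, parts = list(c(lo, lo + k - 1),
                                                         c(lo + k, hi)))
      }
    }
    if (n >= 3 * min_bins) {
      for (i in (min_bins + 1):(n - 2 * min_bins + 1)) {
        for (j in (i + min_bins - 1):(n - min_bins)) {
          p <- tryCatch(stats::t.test(x[i:j], x[-(i:j)])$p.value,
                        error = function(e) 1)
          if (p < best$p) {
            best <- list(p = p, parts = list(c(lo, lo + i - 2),
                                             c(lo + i - 1, lo + j - 1),
                                             c(lo + j, hi)))
          }
        }
      }
    }
    if (!is.finite(best$p) || best$p >= alpha_split) return(lo)
    unlist(lapply(best$parts, function(pr) rec(pr[1], pr[2])))
  }
  sort(rec(1, length(l)))
}

test_that("segmentation equals the exhaustive split-search oracle", {
  cases <- list(
    c(rnorm2 <- NULL, withr::with_seed(1, c(rnorm(25, 0, 0.2),
                                            rnorm(20, -1, 0.2),
                                            rnorm(15, 0, 0.2)))),
    withr::with_seed(2, c(rnorm(30, 0.5, 0.2), rnorm(30, -0.5, 0.2))),
    withr::with_seed(3, rnorm(50, 0, 0.2)),
    withr::with_seed(4, c(rnorm(12, 0, 0.1), rnorm(10, 1, 0.1),
                          rnorm(14, 0, 0.1), rnorm(12, -1, 0.1)))
  )
  for (l in cases) {
    seg <- segment_binary(track_from(l))
    got_starts <- sort(seg$start / 1000 + 1)
    expect_equal(got_starts, oracle_segment(l))
    # tiling invariant
    expect_equal(sum(seg$n_bins), length(l))
    expect_true(all(seg$end[-nrow(seg)] == seg$start[-1]))
  }
})

test_that("state calling is nearest-mean with purity-adjusted centers", {
  seg <- function(m) tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                                    n_bins = 10, mean_l = m,
                                    state = NA_character_)
  expect_equal(call_states(seg(-1), purity = 1)$state, "hemi-del")
  expect_equal(call_states(seg(0.58), purity = 1)$state, "hemi-amp")
  expect_equal(call_states(seg(0), purity = 0.5)$state, "neutral")
  expect_error(call_states(seg(0), purity = 0), "purity")

  withr::with_seed(9, {
    ms <- runif(200, -2.5, 1.5)
    for (pur in c(0.3, 0.7, 1)) {
      got <- call_states(seg(0) |> dplyr::slice(rep(1, 200)) |>
                           dplyr::mutate(mean_l = ms), pur)$state
      mu <- cn_state_means(pur)
      oracle <- names(mu)[apply(abs(outer(ms, mu, "-")), 1, which.min)]
      expect_equal(got, oracle)
    }
  })
})

test_that("lower purity never flips hemi-del calls to homo-del", {
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1, n_bins = 10,
                        mean_l = -0.6, state = NA_character_)
  states <- vapply(seq(1, 0.2, by = -0.1), function(p)
    call_states(seg, p)$state, character(1))
  # as purity falls, all model means shrink toward 0, so a fixed negative
  # mean can only move deeper-ward: hemi-del may become homo-del, never the
  # reverse
  hit_homo <- which(states == "homo-del")
  hit_hemi <- which(states == "hemi-del")
  if (length(hit_homo) && length(hit_hemi)) {
    expect_true(max(hit_hemi) < min(hit_homo))
  }
  expect_true(all(states %in% c("hemi-del", "homo-del", "neutral")))
})

test_that("cross-patient regions follow the k-of-n vote rule", {
  bins <- flat_bins(30)
  seg_del <- function(from, to) tibble::tibble(
    chrom = "chr1",
    start = c(0, (from - 1) * 1000, to * 1000),
    end = c((from - 1) * 1000, to * 1000, 30000),
    n_bins = c(from - 1, to - from + 1, 30 - to),
    mean_l = c(0, -1, 0), state = c("neutral", "hemi-del", "neutral"))
  seg_flat <- tibble::tibble(chrom = "chr1", start = 0, end = 30000,
                             n_bins = 30, mean_l = 0, state = "neutral")
  del_both <- list(pt = seg_del(10, 20), rt = seg_del(10, 20))
  flat <- list(pt = seg_flat, rt = seg_flat)

  three <- list(a = del_both, b = del_both, c = del_both, d = flat)
  cat3 <- cross_patient_regions(three, bins, k = 3)
  expect_equal(nrow(cat3[cat3$category == "shared-del", ]), 1)
  expect_equal(cat3$start[cat3$category == "shared-del"], 9000)
  expect_equal(cat3$end[cat3$category == "shared-del"], 20000)

  two <- list(a = del_both, b = del_both, c = flat, d = flat)
  cat2 <- cross_patient_regions(two, bins, k = 3)
  expect_equal(nrow(cat2[cat2$category == "shared-del", ]), 0)

  none <- cross_patient_regions(list(a = flat, b = flat, c = flat), bins,
                                k = 3)
  expect_equal(nrow(none), 0)
  expect_error(cross_patient_regions(list(a = flat), bins, k = 3), "fewer")
})

test_that("region logic equals brute-force per-bin vote counting", {
  withr::with_seed(31, {
    bins <- flat_bins(40)
    states <- c("neutral", "hemi-del", "homo-del", "hemi-amp", "homo-amp")
    rand_seg <- function() {
      s <- sample(states, 40, TRUE, prob = c(0.6, 0.1, 0.1, 0.1, 0.1))
      runs <- rle(s)
      ends <- cumsum(runs$lengths)
      tibble::tibble(chrom = "chr1", start = (c(0, head(ends, -1))) * 1000,
                     end = ends * 1000, n_bins = runs$lengths,
                     mean_l = 0, state = runs$values) |>
        (\(d) {d$.s <- runs$values; d})()
    }
    pats <- lapply(1:4, function(i) list(pt = rand_seg(), rt = rand_seg()))
    got <- cross_patient_regions(pats, bins, k = 2)

    # brute-force oracle on the bin grid
    bin_state <- function(seg) rep(seg$state, seg$n_bins)
    amp <- c("hemi-amp", "homo-amp"); del <- c("hemi-del", "homo-del")
    votes <- sapply(pats, function(p) {
      sp <- bin_state(p$pt); sr <- bin_state(p$rt)
      rbind(`shared-amp` = sp %in% amp & sr %in% amp,
            `shared-del` = sp %in% del & sr %in% del,
            `P-only-amp` = sp %in% amp & !sr %in% amp,
            `P-only-del` = sp %in% del & !sr %in% del,
            `R-only-amp` = !sp %in% amp & sr %in% amp,
            `R-only-del` = !sp %in% del & sr %in% del)
    }, simplify = "array")
    tot <- apply(votes, c(1, 2), sum)
    for (cat in rownames(tot)) {
      want_bins <- which(tot[cat, ] >= 2)
      got_bins <- integer(0)
      gr <- got[got$category == cat, ]
      if (nrow(gr) > 0) {
        got_bins <- unlist(lapply(seq_len(nrow(gr)), function(i)
          seq(gr$start[i] / 1000 + 1, gr$end[i] / 1000)))
      }
      expect_equal(sort(got_bins), want_bins, ignore_attr = TRUE)
    }
  })
})

test_that("imposed breakpoints re-average a track on pooled boundaries", {
  l <- c(rep(0, 10), rep(-1, 10), rep(0, 10))
  tr <- track_from(l)
  seg_a <- tibble::tibble(chrom = "chr1", start = c(0, 10000),
                          end = c(10000, 30000), n_bins = c(10, 20),
                          mean_l = c(0, -0.5), state = NA)
  seg_b <- tibble::tibble(chrom = "chr1", start = c(0, 20000),
                          end = c(20000, 30000), n_bins = c(20, 10),
                          mean_l = c(-0.5, 0), state = NA)
  out <- impose_breakpoints(tr, seg_a, seg_b)
  expect_equal(nrow(out), 3)
  expect_equal(out$mean_l, c(0, -1, 0))
  expect_equal(sum(out$n_bins), 30)
})

test_that("gene overlap is half-open with at least one shared base", {
  gm <- tibble::tibble(gene = c("A", "B", "C"), chrom = "chr1",
                       start = c(500, 2000, 5000), end = c(1500, 3000, 6000))
  reg <- tibble::tibble(category = "shared-del", chrom = "chr1",
                        start = 1000, end = 2000)
  hit <- genes_in_regions(reg, gm)
  expect_equal(hit$gene, "A")  # B abuts at 2000: zero overlap, excluded
  expect_error(genes_in_regions(reg, gm[0, ]), "empty gene model")

  withr::with_seed(17, {
    gm2 <- tibble::tibble(gene = sprintf("g%03d", 1:100), chrom = "chr1",
                          start = sample.int(1e5, 100)) |>
      dplyr::mutate(end = start + sample.int(5000, 100))
    reg2 <- tibble::tibble(chrom = "chr1",
                           start = sample.int(1e5, 15)) |>
      dplyr::mutate(end = start + sample.int(8000, 15), category = "x")
    got <- genes_in_regions(reg2, gm2)
    # quadratic all-pairs oracle
    want <- 0L
    for (i in seq_len(nrow(reg2))) for (j in seq_len(nrow(gm2))) {
      if (reg2$start[i] < gm2$end[j] && reg2$end[i] > gm2$start[j])
        want <- want + 1L
    }
    expect_equal(nrow(got), want)
  })
})
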