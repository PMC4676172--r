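# Dichotomization rules, product-limit estimation, log-rank, Cox PH and the
# prognostic screen. The survival package serves as the independent
# cross-check for the in-package implementations.

test_that("median dichotomization splits 21 distinct values 11/10", {
  withr::with_seed(2, v <- sample(seq(-3, 3, length.out = 21)))
  d <- dichotomize_median(v)
  expect_equal(sum(d$group == "low"), 11)
  expect_equal(sum(d$group == "high"), 10)
  expect_true(all(v[d$group == "low"] <= d$cut))

  d4 <- dichotomize_median(c(1, 2, 3, 4))
  expect_equal(d4$cut, 2.5)
  expect_setequal(which(d4$group == "low"), 1:2)

  expect_error(dichotomize_median(c(1, 2, 3)), "at least 4")
  expect_warning(dt <- dichotomize_median(rep(2, 6)), "tied")
  expect_true(dt$flag_degenerate)
})

test_that("reference-SD dichotomization uses mean minus k SDs", {
  withr::with_seed(3, ref <- rnorm(50, 10, 1))
  cut <- mean(ref) - 2 * sd(ref)
  d <- dichotomize_reference_sd(c(cut - 0.1, cut + 0.1, 15), ref)
  expect_equal(d$cut, cut)
  expect_equal(d$group, c("low", "high", "high"))
  expect_false(d$flag_empty_low)

  d2 <- dichotomize_reference_sd(c(9, 10, 11), ref)
  expect_true(d2$flag_empty_low)
  expect_error(dichotomize_reference_sd(1:5, rep(1, 20)), "variance")
  expect_error(dichotomize_reference_sd(1:5, rnorm(5)), "10")

  # enumeration: group counts equal brute-force threshold counting
  withr::with_seed(4, vals <- rnorm(100, 9, 2))
  d3 <- dichotomize_reference_sd(vals, ref, k_sd = 1.5)
  expect_equal(sum(d3$group == "low"), sum(vals < mean(ref) - 1.5 * sd(ref)))
})

test_that("KM estimator matches hand computation and survfit", {
  none <- km_fit(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(none$curves$survival == 1))
  expect_true(is.na(none$medians$median))

  all_ev <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(all_ev$curves$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(all_ev$medians$median, 2)

  withr::with_seed(8, {
    t <- round(rexp(60, 0.1), 1)
    ev <- rbinom(60, 1, 0.6)
    g <- sample(c("a", "b"), 60, TRUE)
    fit <- km_fit(t, ev, g)
    ref <- survival::survfit(survival::Surv(t, ev) ~ g)
    sm <- summary(ref)
    for (lev in c("a", "b")) {
      mine <- fit$curves[fit$curves$group == lev & fit$curves$n_event > 0, ]
      theirs <- sm$surv[sm$strata == paste0("g=", lev)]
      expect_equal(mine$survival, theirs, tolerance = 1e-12)
    }
  })
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM equals the empirical survival function without censoring", {
  withr::with_seed(10, t <- sample(1:40, 25, TRUE))
  fit <- km_fit(t, rep(1, 25))
  for (i in seq_len(nrow(fit$curves))) {
    expect_equal(fit$curves$survival[i], mean(t > fit$curves$time[i]))
  }
})

test_that("log-rank: symmetry, hand toy, survdiff agreement", {
  t <- c(1, 2, 3, 1, 2, 3); ev <- rep(1, 6)
  g <- rep(c("a", "b"), each = 3)
  sym <- logrank_test(t, ev, g)
  expect_equal(sym$chisq, 0)
  expect_equal(sym$p_value, 1)

  # 6-subject toy, hand-computed O-E and hypergeometric variance
  t2 <- c(1, 3, 5, 2, 4, 6); ev2 <- c(1, 1, 0, 1, 1, 1)
  g2 <- rep(c("a", "b"), each = 3)
  ref <- survival::survdiff(survival::Surv(t2, ev2) ~ g2)
  mine <- logrank_test(t2, ev2, g2)
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-12)
  # label-swap invariance
  swapped <- logrank_test(t2, ev2, rev(g2))
  expect_equal(swapped$chisq,
               logrank_test(t2, ev2, ifelse(g2 == "a", "b", "a"))$chisq)

  withr::with_seed(14, {
    for (i in 1:20) {
      tt <- round(rexp(50, 0.1), 1)
      ee <- rbinom(50, 1, 0.7)
      gg <- sample(c("x", "y"), 50, TRUE)
      if (sum(ee) == 0 || length(unique(gg)) < 2) next
      expect_equal(logrank_test(tt, ee, gg)$chisq,
                   survival::survdiff(survival::Surv(tt, ee) ~ gg)$chisq,
                   tolerance = 1e-10)
    }
  })
  expect_error(logrank_test(t, ev, rep("a", 6)), "2 groups")
  expect_error(logrank_test(t, rep(0, 6), g), "events")
})

test_that("Cox fit matches coxph (Efron ties) and the grid-search oracle", {
  withr::with_seed(21, {
    n <- 80
    x <- rbinom(n, 1, 0.5)
    t <- round(rexp(n, 0.05 * exp(0.8 * x)), 0) + 1
    ev <- rbinom(n, 1, 0.8)
    fit <- cox_fit(t, ev, data.frame(x = x))
    ref <- survival::coxph(survival::Surv(t, ev) ~ x, ties = "efron")
    expect_equal(fit$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(fit$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(fit$loglik[["full"]], ref$loglik[2], tolerance = 1e-8,
                 ignore_attr = TRUE)
    # LRT against the null model
    expect_equal(fit$lrt$statistic,
                 2 * (ref$loglik[2] - ref$loglik[1]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  })

  # small-n grid oracle: independently coded Efron partial likelihood
  efron_ll <- function(beta, t, ev, x) {
    ll <- 0
    for (tt in sort(unique(t[ev == 1]))) {
      risk <- which(t >= tt)
      dset <- which(t == tt & ev == 1)
      d <- length(dset)
      s0 <- sum(exp(beta * x[risk]))
      sd0 <- sum(exp(beta * x[dset]))
      ll <- ll + sum(beta * x[dset]) -
        sum(log(s0 - (seq_len(d) - 1) / d * sd0))
    }
    ll
  }
  withr::with_seed(22, {
    for (i in 1:4) {
      n <- 8
      x <- rbinom(n, 1, 0.5)
      if (var(x) == 0) x[1] <- 1 - x[1]
      t <- sample(1:6, n, TRUE)
      ev <- pmax(rbinom(n, 1, 0.7), c(1, rep(0, n - 1)))
      fit <- cox_fit(t, ev, data.frame(x = x))
      grid <- seq(-5, 5, by = 1e-4)
      llg <- vapply(grid, efron_ll, numeric(1), t = t, ev = ev, x = x)
      best <- grid[which.max(llg)]
      if (abs(best) < 4.9) {  # interior maximum, no separation
        expect_lt(abs(fit$coefficients$estimate - best), 1e-3)
        expect_gte(fit$loglik[["full"]], max(llg) - 1e-8)
      } else {
        expect_true(fit$flag_monotone)
      }
    }
  })
  expect_error(cox_fit(c(1, 2), c(0, 0), data.frame(x = c(0, 1))), "events")
  expect_error(cox_fit(c(1, 2), c(1, 1), data.frame(x = c(1, 1))),
               "constant")
})

test_that("Cox null recovery and Wald CI coverage at a large effect", {
  withr::with_seed(30, {
    n <- 8000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1)
    ev <- rep(1, n)
    fit <- cox_fit(t, ev, data.frame(x = x))
    expect_lte(abs(fit$coefficients$estimate), 0.05)
    expect_equal(fit$coefficients$hr, 1, tolerance = 0.06)
  })

  covered <- vapply(1:50, function(s) {
    withr::with_seed(400 + s, {
      n <- 400
      x <- rep(0:1, each = n / 2)
      t <- pmin(rexp(n, 0.02 * 7^x), 60)
      ev <- as.integer(t < 60)
      fit <- cox_fit(t, ev, data.frame(x = x))
      co <- fit$coefficients
      log(7) >= log(co$ci_low) && log(7) <= log(co$ci_high)
    })
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("tidy and glance expose the model summaries", {
  withr::with_seed(33, {
    n <- 60
    x <- data.frame(a = rbinom(n, 1, 0.5), b = rnorm(n))
    fit <- cox_fit(rexp(n, 0.1), rbinom(n, 1, 0.8), x)
    td <- tidy(fit)
    expect_equal(td$term, c("a", "b"))
    expect_true(all(c("hr", "ci_low", "ci_high", "p_value") %in% names(td)))
    gl <- glance(fit)
    expect_equal(gl$n, n)
    expect_true(gl$converged)
    expect_s3_class(autoplot(km_fit(rexp(20, 0.1), rbinom(20, 1, 0.7),
                                    rep(c("a", "b"), 10))), "ggplot")
  })
})

test_that("candidate integration intersects and orders genomically", {
  expect_equal(candidate_integration(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(candidate_integration(c("A", "B"), c("C", "D")), character(0))
  gm <- tibble::tibble(gene = c("C", "B"), chrom = "chr4",
                       start = c(100, 900))
  expect_equal(candidate_integration(c("A", "B", "C"), c("B", "C"), gm),
               c("C", "B"))
  expect_error(candidate_integration(character(0), "A"), "non-empty")
})

test_that("region screen ranks a planted prognostic gene near the top", {
  top3 <- vapply(1:10, function(s) {
    withr::with_seed(500 + s, {
      n <- 200; n_genes <- 50
      genes <- c("target", sprintf("null%02d", 1:(n_genes - 1)))
      ref <- tidyr::expand_grid(gene = genes, i = 1:40) |>
        dplyr::mutate(value = rnorm(dplyr::n(), 10, 1)) |>
        dplyr::select(gene, value)
      expr <- tidyr::expand_grid(gene = genes,
                                 patient = sprintf("p%03d", 1:n)) |>
        dplyr::mutate(value = rnorm(dplyr::n(), 10, 1))
      # push ~15 % of patients below the mean-2SD cut for the target gene
      low_pat <- sprintf("p%03d", 1:30)
      expr$value[expr$gene == "target" & expr$patient %in% low_pat] <-
        rnorm(30, 7, 0.3)
      low <- expr$gene == "target" & expr$patient %in% low_pat
      is_low <- sprintf("p%03d", 1:n) %in% low_pat
      cl <- tibble::tibble(
        patient = sprintf("p%03d", 1:n),
        time = pmin(rexp(n, 0.02 * 2.5^is_low), 36),
        event = as.integer(pmin(rexp(n, 0.02 * 2.5^is_low), 36) < 36),
        sex = sample(c("M", "F"), n, TRUE),
        age = round(rnorm(n, 55, 8)), grade = sample(1:3, n, TRUE),
        hbv = rbinom(n, 1, 0.5))
      cl$time <- pmin(rexp(n, 0.02 * 2.5^is_low), 36)
      cl$event <- as.integer(cl$time < 36)
      screen <- region_survival_screen(expr, cl, ref)
      which(screen$gene == "target") <= 3
    })
  }, logical(1))
  expect_gte(sum(top3), 8)
})

test_that("region screen flags unbalanced dichotomizations", {
  withr::with_seed(61, {
    n <- 100
    ref <- tibble::tibble(gene = "g", value = rnorm(40, 10, 1))
    vals <- rnorm(n, 10, 1)
    cut <- mean(ref$value) - 2 * sd(ref$value)
    vals[1:3] <- cut - 1  # 3 % low group
    vals[4:n] <- pmax(vals[4:n], cut + 0.1)
    expr <- tibble::tibble(gene = "g", patient = sprintf("p%03d", 1:n),
                           value = vals)
    cl <- tibble::tibble(patient = sprintf("p%03d", 1:n),
                         time = rexp(n, 0.05), event = rbinom(n, 1, 0.7),
                         sex = sample(c("M", "F"), n, TRUE),
                         age = round(rnorm(n, 55, 8)),
                         grade = sample(1:3, n, TRUE),
                         hbv = rbinom(n, 1, 0.5))
    screen <- region_survival_screen(expr, cl, ref)
    expect_equal(nrow(screen), 1)
    expect_true(screen$flag_balance)
    expect_equal(screen$low_fraction, 0.03)
  })
})
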