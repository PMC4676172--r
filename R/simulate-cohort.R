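# Synthetic transplant cohort generator.
#
# Every input the analysis pipeline consumes (genotype panels, variant
# tables, coverage bins, counts matrices, clinical tables) can be generated
# here with a ground-truth record, under the five-specimen design:
# P_T / P_NAT / R_T / R_NAT / P_B per patient.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# symmetric alt<->ref flip at rate eps
err_adjust <- function(f, eps) f * (1 - eps) + (1 - f) * eps

# expected VAF of a somatic variant in a cell mixture:
#  (1 - alpha) recipient cells (purity-weighted tumor + stroma) + alpha donor
#  normal cells. cn is local copy number in tumor cells, mut_copies the
#  number of mutated copies they retain, cf the clone's cancer-cell fraction.
vaf_expect <- function(purity, cf, cn = 2, mut_copies = 1, alpha = 0) {
  num <- (1 - alpha) * purity * cf * mut_copies
  den <- (1 - alpha) * (purity * cn + (1 - purity) * 2) + alpha * 2
  num / den
}

draw_reads <- function(f, config, n = length(f)) {
  f <- rep_len(f, n)
  depth <- rpois(n, config$depth_mean)
  alt <- rbinom(n, depth, err_adjust(f, config$seq_error))
  tibble::tibble(depth = depth, alt_reads = alt, ref_reads = depth - alt)
}

random_loci <- function(n, config) {
  lens <- config$chrom_lengths
  ch <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(runif(n, 1, unname(lens[ch])))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tibble::tibble(chrom = ch, pos = as.integer(pos), ref = ref,
                 alt = unname(alt))
}

in_planted <- function(chrom, pos, config, carries = TRUE) {
  pr <- config$planted_region
  carries & chrom == pr$chrom & (pos - 1) >= pr$start & (pos - 1) < pr$end
}

#' Simulate recipient and donor germlines at a SNP panel
#'
#' Draws `panel_size` biallelic loci with minor-allele frequencies uniform on
#' `maf_range`, then genotypes (alt-allele dosage 0/1/2) for the recipient and
#' the donor independently from Hardy-Weinberg proportions at each locus MAF.
#'
#' @param config An [sim_config()] object.
#' @param seed Optional integer; if given, the draw is made under this seed
#'   without disturbing the ambient RNG state.
#' @return A tibble with one row per locus: `chrom`, `pos`, `ref`, `alt`,
#'   `maf`, `g_recipient`, `g_donor`.
#' @export
#' @examples
#' g <- simulate_germlines(sim_config(panel_size = 100), seed = 1)
#' table(g$g_recipient)
simulate_germlines <- function(config, seed = NULL) {
  validate_sim_config(config)
  with_seed(seed, {
    loci <- random_loci(config$panel_size, config)
    maf <- runif(config$panel_size, config$maf_range[1], config$maf_range[2])
    loci |>
      dplyr::mutate(
        maf = maf,
        g_recipient = rbinom(dplyr::n(), 2, maf),
        g_donor = rbinom(dplyr::n(), 2, maf)
      )
  })
}

#' Draw sequencing reads over a genotype panel
#'
#' Produces panel-style allele counts (depth, alt reads) at each locus for a
#' specimen whose true alt-allele fraction per locus is `fraction` — e.g.
#' `g_recipient / 2` for recipient blood, or the donor/recipient mixture
#' expectation for a contaminated recurrent-tumor biopsy. Depth is Poisson
#' with mean `config$depth_mean`; alt reads are binomial after symmetric
#' sequencing-error adjustment.
#'
#' @param germlines Output of [simulate_germlines()] (or any tibble with
#'   `chrom`, `pos`, `ref`, `alt` columns).
#' @param fraction Numeric vector of true alt-allele fractions, one per locus.
#' @param config An [sim_config()] object.
#' @param genotype Optional integer vector of genotypes to carry along.
#' @inheritParams simulate_germlines
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `genotype`, `depth`,
#'   `alt_reads`, `ref_reads`.
#' @export
simulate_panel_reads <- function(germlines, fraction, config,
                                 genotype = NA_integer_, seed = NULL) {
  stopifnot(length(fraction) %in% c(1L, nrow(germlines)))
  with_seed(seed, {
    reads <- draw_reads(rep_len(fraction, nrow(germlines)), config)
    germlines |>
      dplyr::select("chrom", "pos", "ref", "alt") |>
      dplyr::mutate(genotype = rep_len(genotype, nrow(germlines))) |>
      dplyr::bind_cols(reads)
  })
}

sample_effects <- function(n) {
  # nonsilent:silent = 2.8, the observed exome-wide ratio in this design
  classes <- c("nonsynonymous", "stop-gain", "stop-loss", "frameshift",
               "silent", "noncoding")
  probs <- c(0.50, 0.03, 0.01, 0.02, 0.20, 0.24)
  sample(classes, n, replace = TRUE, prob = probs)
}

annotate_genes <- function(df, genes) {
  genes1 <- genes |>
    dplyr::transmute(gene_symbol = .data$gene, chrom = .data$chrom,
                     gstart1 = .data$start + 1, gend = .data$end)
  df |>
    dplyr::left_join(genes1,
                     by = dplyr::join_by("chrom",
                                         dplyr::between(x$pos, y$gstart1, y$gend)),
                     multiple = "first") |>
    dplyr::mutate(gene = .data$gene_symbol) |>
    dplyr::select(-"gene_symbol", -"gstart1", -"gend")
}

#' Simulate primary-tumor somatic variants with matched normals
#'
#' Assigns each somatic variant to a clone, computes its expected variant
#' allele fraction in the primary tumor under the heterozygous copy-number
#' neutral model `purity * clone_fraction / 2` (with copy-number-aware
#' algebra inside the planted hemizygous deletion, where the mutated allele
#' sits on the retained haplotype with probability 0.5), and draws binomial
#' read counts at Poisson depth for the P_T, P_NAT and P_B specimens. A
#' seeded sample of germline panel loci is carried into the tables as
#' background rows.
#'
#' @inheritParams simulate_panel_reads
#' @param germlines Output of [simulate_germlines()] for this patient.
#' @param genome Optional [cohort_genome()] result (computed if `NULL`).
#' @param carries_deletion Does this patient's tumor carry the planted
#'   deletion?
#' @return A list with `variants` (tibble: specimen, chrom, pos, ref, alt,
#'   ref_reads, alt_reads, gene, effect, type), `truth` (one row per somatic
#'   variant: clone, clone fraction, deletion status, expected VAF) and
#'   `background` (the germline loci used).
#' @export
simulate_tumor_variants <- function(config, germlines, genome = NULL,
                                    carries_deletion = TRUE, seed = NULL) {
  validate_sim_config(config)
  if (is.null(genome)) genome <- cohort_genome(config)
  with_seed(seed, {
    nclone <- length(config$clone_fractions)
    nsom <- nclone * config$n_somatic_per_clone
    som <- random_loci(nsom, config) |>
      dplyr::mutate(
        clone = rep(seq_len(nclone), each = config$n_somatic_per_clone),
        clone_fraction = config$clone_fractions[.data$clone],
        effect = sample_effects(nsom),
        type = ifelse(.data$effect == "frameshift", "indel", "snv"),
        in_deletion = in_planted(.data$chrom, .data$pos, config,
                                 carries_deletion),
        retained_copy = ifelse(.data$in_deletion,
                               rbinom(nsom, 1, 0.5), 1L),
        expected_vaf_pt = vaf_expect(
          config$purity_pt, .data$clone_fraction,
          cn = ifelse(.data$in_deletion, 1, 2),
          mut_copies = ifelse(.data$in_deletion, .data$retained_copy, 1)
        )
      ) |>
      annotate_genes(genome$genes)
    # indel alleles: extend ref or alt by one base
    idx <- som$type == "indel"
    som$alt[idx] <- paste0(som$ref[idx], som$alt[idx])

    nbg <- min(config$n_germline_background, nrow(germlines))
    bg <- germlines[sample.int(nrow(germlines), nbg), ]

    emit <- function(spec, f_som, f_bg) {
      dplyr::bind_rows(
        som |>
          dplyr::select("chrom", "pos", "ref", "alt", "gene", "effect",
                        "type") |>
          dplyr::bind_cols(draw_reads(f_som, config, nrow(som))),
        bg |>
          dplyr::select("chrom", "pos", "ref", "alt") |>
          dplyr::mutate(gene = NA_character_, effect = "noncoding",
                        type = "snv") |>
          dplyr::bind_cols(draw_reads(f_bg, config, nrow(bg)))
      ) |>
        dplyr::mutate(specimen = spec, .before = 1) |>
        dplyr::select("specimen", "chrom", "pos", "ref", "alt",
                      "ref_reads", "alt_reads", "gene", "effect", "type")
    }
    variants <- dplyr::bind_rows(
      emit("P_T", som$expected_vaf_pt, bg$g_recipient / 2),
      emit("P_NAT", 0, bg$g_recipient / 2),
      emit("P_B", 0, bg$g_recipient / 2)
    )
    list(variants = variants, truth = som, background = bg)
  })
}

#' Simulate the recurrent tumor as a recipient-tumor / donor-normal mixture
#'
#' The recurrent-tumor biopsy is modeled as a cell mixture: fraction
#' `1 - alpha` recipient cells (a retained subset of the primary clones plus
#' a private clone, at purity `purity_rt`) and fraction `alpha` donor normal
#' cells carrying the donor germline. At a germline locus the alt-read
#' fraction therefore has expectation `((1 - alpha) g_R + alpha g_D) / 2`;
#' somatic VAFs are diluted by the same mixture. Also emits R_NAT (pure donor
#' tissue) rows, supplemental P_B coverage at private loci, and panel-style
#' read counts for R_T and R_NAT.
#'
#' @inheritParams simulate_tumor_variants
#' @param primary Output of [simulate_tumor_variants()] for the same patient.
#' @param alpha Donor-cell contamination fraction in \[0, 1\].
#' @return A list with `variants` (R_T, R_NAT and supplemental P_B rows),
#'   `truth` (per somatic variant: retention in R_T, expected R_T VAF),
#'   `rt_panel` and `rnat_panel`.
#' @export
simulate_recurrent_mixture <- function(config, primary, germlines,
                                       alpha = config$alpha[1],
                                       genome = NULL,
                                       carries_deletion = TRUE, seed = NULL) {
  validate_sim_config(config)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (is.null(genome)) genome <- cohort_genome(config)
  with_seed(seed, {
    nclone <- length(config$clone_fractions)
    n_keep <- if (config$shared_clone_fraction <= 0) 0L else
      max(1L, round(config$shared_clone_fraction * nclone))
    som <- primary$truth |>
      dplyr::mutate(
        in_rt = .data$clone <= n_keep,
        expected_vaf_rt = ifelse(
          .data$in_rt,
          vaf_expect(config$purity_rt, .data$clone_fraction,
                     cn = ifelse(.data$in_deletion, 1, 2),
                     mut_copies = ifelse(.data$in_deletion,
                                         .data$retained_copy, 1),
                     alpha = alpha),
          0)
      )
    priv <- random_loci(config$n_somatic_private, config) |>
      dplyr::mutate(
        clone = 0L, clone_fraction = config$private_clone_fraction,
        effect = sample_effects(config$n_somatic_private),
        type = ifelse(.data$effect == "frameshift", "indel", "snv"),
        in_deletion = in_planted(.data$chrom, .data$pos, config,
                                 carries_deletion),
        retained_copy = ifelse(.data$in_deletion,
                               rbinom(config$n_somatic_private, 1, 0.5), 1L),
        expected_vaf_pt = 0,
        in_rt = TRUE,
        expected_vaf_rt = vaf_expect(
          config$purity_rt, .data$clone_fraction,
          cn = ifelse(.data$in_deletion, 1, 2),
          mut_copies = ifelse(.data$in_deletion, .data$retained_copy, 1),
          alpha = alpha)
      ) |>
      annotate_genes(genome$genes)
    idx <- priv$type == "indel"
    priv$alt[idx] <- paste0(priv$ref[idx], priv$alt[idx])
    truth_rt <- dplyr::bind_rows(som, priv)

    bg <- primary$background
    f_bg_rt <- ((1 - alpha) * bg$g_recipient + alpha * bg$g_donor) / 2
    emit <- function(spec, df, f) {
      df |>
        dplyr::select("chrom", "pos", "ref", "alt", dplyr::any_of(c("gene")),
                      dplyr::any_of(c("effect", "type"))) |>
        dplyr::mutate(
          gene = if ("gene" %in% names(df)) .data$gene else NA_character_,
          effect = if ("effect" %in% names(df)) .data$effect else "noncoding",
          type = if ("type" %in% names(df)) .data$type else "snv"
        ) |>
        dplyr::bind_cols(draw_reads(f, config, nrow(df))) |>
        dplyr::mutate(specimen = spec, .before = 1) |>
        dplyr::select("specimen", "chrom", "pos", "ref", "alt",
                      "ref_reads", "alt_reads", "gene", "effect", "type")
    }
    variants <- dplyr::bind_rows(
      emit("R_T", truth_rt, truth_rt$expected_vaf_rt),
      emit("R_T", bg, f_bg_rt),
      emit("R_NAT", truth_rt, 0),
      emit("R_NAT", bg, bg$g_donor / 2),
      emit("P_B", priv, 0)  # matched-normal coverage at private loci
    )
    f_panel <- ((1 - alpha) * germlines$g_recipient +
                  alpha * germlines$g_donor) / 2
    list(
      variants = variants,
      truth = truth_rt,
      rt_panel = simulate_panel_reads(germlines, f_panel, config),
      rnat_panel = simulate_panel_reads(germlines, germlines$g_donor / 2,
                                        config,
                                        genotype = germlines$g_donor)
    )
  })
}

#' Simulate binned sequencing coverage for one patient's specimens
#'
#' Per-bin depth is Poisson with mean `depth_mean * C / 2`, where `C` is the
#' average copy number of the cell mixture in that bin: hemizygous deletion
#' in the planted region of P_T and R_T when the patient carries it
#' (attenuated in R_T by donor contamination and purity), diploid elsewhere
#' and in the normal specimens.
#'
#' @inheritParams simulate_recurrent_mixture
#' @return Tibble: `specimen`, `chrom`, `start`, `end`, `depth`,
#'   `true_state` (CN state label per bin).
#' @export
simulate_coverage_bins <- function(config, genome = NULL, alpha = 0,
                                   carries_deletion = TRUE, seed = NULL) {
  validate_sim_config(config)
  if (is.null(genome)) genome <- cohort_genome(config)
  with_seed(seed, {
    bins <- genome$bins
    pr <- config$planted_region
    del <- carries_deletion & bins$chrom == pr$chrom &
      bins$start < pr$end & bins$end > pr$start
    cn_tumor <- ifelse(del, 1, 2)
    mix_cn <- function(purity, alpha) {
      (1 - alpha) * (purity * cn_tumor + (1 - purity) * 2) + alpha * 2
    }
    emit <- function(spec, cn) {
      bins |>
        dplyr::mutate(
          specimen = spec, .before = 1) |>
        dplyr::mutate(
          depth = rpois(nrow(bins), config$depth_mean * cn / 2),
          true_state = ifelse(spec %in% c("P_T", "R_T") & del,
                              "hemi-del", "neutral"))
    }
    dplyr::bind_rows(
      emit("P_T", mix_cn(config$purity_pt, 0)),
      emit("P_NAT", 2),
      emit("R_T", mix_cn(config$purity_rt, alpha)),
      emit("R_NAT", 2)
    )
  })
}

#' Simulate a gene-by-sample RNA counts matrix
#'
#' Counts are negative-binomial with per-gene log-normal baseline means,
#' per-sample log-normal library-size factors, and dispersion
#' `nb_dispersion` (variance \eqn{\mu + \phi \mu^2}). The planted gene's P_T
#' mean is multiplied by `2^planted_gene_log2fc` in recurrent patients only.
#'
#' @inheritParams simulate_tumor_variants
#' @return A list with `counts` (tibble: `gene` column plus one column per
#'   sample), `samples` (tibble: sample, patient, role, recurrence) and
#'   `gene_means` (true baseline means).
#' @export
simulate_counts_matrix <- function(config, genome = NULL, seed = NULL) {
  validate_sim_config(config)
  if (config$n_genes < 10) stop("`n_genes` must be >= 10", call. = FALSE)
  if (is.null(genome)) genome <- cohort_genome(config)
  with_seed(seed, {
    patients <- cohort_patient_ids(config)
    recurrent <- patient_is_recurrent(config)
    samples <- tidyr::expand_grid(patient = patients,
                                  role = c("P_T", "P_NAT")) |>
      dplyr::mutate(sample = paste(.data$patient, .data$role, sep = "_"),
                    recurrence = rep(recurrent, each = 2)) |>
      dplyr::select("sample", "patient", "role", "recurrence")
    mu <- exp(rnorm(config$n_genes, config$gene_mean_meanlog,
                    config$gene_mean_sdlog))
    phi <- rep_len(config$nb_dispersion, config$n_genes)
    sf <- exp(rnorm(nrow(samples), 0, config$libsize_sdlog))
    planted <- genome$planted_gene
    gidx <- match(planted, genome$genes$gene)
    cnt <- matrix(0L, config$n_genes, nrow(samples),
                  dimnames = list(genome$genes$gene, samples$sample))
    for (j in seq_len(nrow(samples))) {
      m <- mu * sf[j]
      if (samples$role[j] == "P_T" && samples$recurrence[j]) {
        m[gidx] <- m[gidx] * 2^config$planted_gene_log2fc
      }
      cnt[, j] <- rnbinom(config$n_genes, mu = m, size = 1 / phi)
    }
    counts <- tibble::as_tibble(cnt, rownames = "gene")
    list(counts = counts, samples = samples,
         gene_means = tibble::tibble(gene = genome$genes$gene, mu = mu,
                                     phi = phi))
  })
}

cohort_patient_ids <- function(config) sprintf("HCC%02d", seq_len(config$n_patients))
patient_is_recurrent <- function(config) {
  seq_len(config$n_patients) <= config$n_recurrent
}

#' Simulate per-patient recurrence times under proportional hazards
#'
#' Recurrence times are exponential with hazard
#' `baseline_hazard * hazard_ratio^(group == "low")`, administratively
#' censored at `censor_time` months. Clinical covariates (sex, age, grade,
#' HBV status) are drawn from the configured marginal frequencies.
#'
#' @inheritParams simulate_tumor_variants
#' @param gene_groups Tibble with columns `patient` and `group`
#'   (`"low"`/`"high"`), the true expression group of the planted gene.
#' @return Tibble: `patient`, `time` (months), `event` (0/1), `sex`, `age`,
#'   `grade`, `hbv`, `group`.
#' @export
simulate_clinical_survival <- function(config, gene_groups, seed = NULL) {
  validate_sim_config(config)
  stopifnot(all(c("patient", "group") %in% names(gene_groups)),
            all(gene_groups$group %in% c("low", "high")))
  with_seed(seed, {
    n <- nrow(gene_groups)
    rate <- config$baseline_hazard *
      config$hazard_ratio^(gene_groups$group == "low")
    t_true <- rexp(n, rate)
    gene_groups |>
      dplyr::mutate(
        time = pmin(t_true, config$censor_time),
        event = as.integer(t_true <= config$censor_time),
        sex = ifelse(rbinom(n, 1, config$p_male) == 1, "M", "F"),
        age = round(rnorm(n, config$age_mean, config$age_sd)),
        grade = sample(1:3, n, replace = TRUE, prob = c(0.3, 0.45, 0.25)),
        hbv = rbinom(n, 1, config$p_hbv)
      ) |>
      dplyr::select("patient", "time", "event", "sex", "age", "grade",
                    "hbv", "group")
  })
}

#' Simulate a complete synthetic transplant cohort with ground truth
#'
#' Orchestrates all the generators under `config$seed`: germlines, primary
#' and recurrent variant tables and genotype panels for the full-specimen
#' patients, coverage bins, the cohort counts matrix, and the clinical table
#' (true low/high groups taken as recurrent/non-recurrent, matching the
#' planted under-expression).
#'
#' @param config An [sim_config()] object.
#' @return An object of class `oltseq_cohort`: a list with `config`,
#'   `genome`, `patients`, `variants` (tibble over all specimens of the
#'   full-specimen patients), `panels` (per patient: germline truth, `pb`,
#'   `rnat`, `rt`), `coverage`, `counts`, `samples`, `clinical`, and `truth`
#'   (per-patient alpha, per-variant clone assignments, CN states, planted
#'   gene, survival parameters).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_patients = 8, n_recurrent = 4,
#'                                      n_wes = 2, panel_size = 300,
#'                                      n_genes = 50))
#' cohort
#' }
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  genome <- cohort_genome(config)
  patients <- cohort_patient_ids(config)
  wes <- patients[seq_len(config$n_wes)]
  alphas <- rep_len(config$alpha, config$n_wes)

  panels <- list(); variants <- list(); coverage <- list()
  truth_var <- list()
  for (i in seq_along(wes)) {
    p <- wes[i]
    carries <- i <= config$planted_in_patients
    g <- simulate_germlines(config)
    prim <- simulate_tumor_variants(config, g, genome, carries_deletion = carries)
    rec <- simulate_recurrent_mixture(config, prim, g, alpha = alphas[i],
                                      genome = genome,
                                      carries_deletion = carries)
    pb <- simulate_panel_reads(g, g$g_recipient / 2, config,
                               genotype = g$g_recipient)
    cov <- simulate_coverage_bins(config, genome, alpha = alphas[i],
                                  carries_deletion = carries)
    variants[[p]] <- dplyr::bind_rows(prim$variants, rec$variants) |>
      dplyr::mutate(patient = p, .before = 1)
    panels[[p]] <- list(germline = g, pb = pb, rnat = rec$rnat_panel,
                        rt = rec$rt_panel)
    coverage[[p]] <- cov |> dplyr::mutate(patient = p, .before = 1)
    truth_var[[p]] <- rec$truth |> dplyr::mutate(patient = p, .before = 1)
  }

  expr <- simulate_counts_matrix(config, genome)
  groups <- tibble::tibble(
    patient = patients,
    group = ifelse(patient_is_recurrent(config), "low", "high"))
  clinical <- simulate_clinical_survival(config, groups)

  structure(list(
    config = config,
    genome = genome,
    patients = patients,
    wes_patients = wes,
    variants = dplyr::bind_rows(variants),
    panels = panels,
    coverage = dplyr::bind_rows(coverage),
    counts = expr$counts,
    samples = expr$samples,
    clinical = clinical,
    truth = list(alpha = setNames(alphas, wes),
                 carries_deletion = setNames(
                   seq_along(wes) <= config$planted_in_patients, wes),
                 variants = dplyr::bind_rows(truth_var),
                 planted_gene = genome$planted_gene,
                 planted_region = config$planted_region,
                 hazard_ratio = config$hazard_ratio,
                 groups = groups,
                 gene_means = expr$gene_means)
  ), class = "oltseq_cohort")
}

#' @export
print.oltseq_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<oltseq_cohort>\n")
  cat(sprintf("  %d patients (%d recurrent, %d with full specimen sets)\n",
              cfg$n_patients, cfg$n_recurrent, cfg$n_wes))
  cat(sprintf("  donor contamination alpha: %s\n",
              paste(signif(x$truth$alpha, 3), collapse = ", ")))
  cat(sprintf("  planted gene %s (log2FC %.2f) in %s:%s-%s\n",
              x$truth$planted_gene, cfg$planted_gene_log2fc,
              cfg$planted_region$chrom,
              format(cfg$planted_region$start, big.mark = ","),
              format(cfg$planted_region$end, big.mark = ",")))
  cat(sprintf("  %d somatic truth variants; %d x %d counts matrix\n",
              nrow(x$truth$variants), nrow(x$counts),
              ncol(x$counts) - 1L))
  invisible(x)
}
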