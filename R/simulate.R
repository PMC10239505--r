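#' Configuration for the synthetic cohort generator
#'
#' Returns the default simulation configuration, emulating the structure
#' of the study cohort: four subject groups (controls and Parkinson's
#' disease with normal cognition, mild cognitive impairment, dementia),
#' two brain regions with unequal coverage (no dementia putamen samples),
#' cortex split over two plates with multiplicative batch effects, QC
#' replicates on every plate, blanks defining limits of detection,
#' log-normal analyte abundances with group-specific residual variances,
#' an acute-levodopa DOPA marker, covariates drawn near the cohort
#' characteristics table, and optional planted effects expressed in
#' control-SD units on the log scale (so that Box-Cox with lambda near 0
#' linearizes them and downstream coefficient recovery is interpretable).
#'
#' @param n_per_group named list of per-region group counts.
#' @param n_analytes_lc,n_analytes_fia analyte counts per acquisition arm
#'   (the LC arm includes the named analytes \code{Hcy} and \code{DOPA}).
#' @param n_plates named integer vector of plates per region.
#' @param plate_sigma log-normal SD of per-plate multiplicative factors.
#' @param group_effects data frame (analyte, group, effect) of planted
#'   group shifts in control-SD units.
#' @param levodopa_effects data frame (analyte, pd_class, effect) with
#'   pd_class in PD-ND / PD-D; applied to acutely levodopa-positive (L+)
#'   samples of that class only.
#' @param covariate_effects named numeric vector of per-SD covariate
#'   effects applied to all analytes (default all zero).
#' @param score_effects data frame (analyte, score, slope) of planted
#'   two-way standardized progression-score slopes among PD subjects.
#' @param frac_levodopa_positive probability a PD subject is L+.
#' @param dopa_separation L+ DOPA shift in units of the control DOPA
#'   log-SD (default 4, giving near-complete separation at the 95\%
#'   control quantile threshold).
#' @param dopa_pd_deficit downward DOPA shift (control log-SD units) of
#'   PD subjects without acute medication: endogenous DOPA is reduced by
#'   nigrostriatal degeneration, which keeps L- subjects below the
#'   control quantile threshold (default 1).
#' @param group_sigma_scale named per-group residual-SD multipliers.
#' @param lod_censor_quantile fraction of an analyte's values falling
#'   below the simulated LOD.
#' @param n_qc_per_plate,n_blanks QC replicates per plate; blank count.
#' @param seed default RNG seed for \code{\link{simulate_cohort}}.
#' @param ... overrides merged over the defaults.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_per_group = list(
      cortex = c(CTRL = 36, `PD-CN` = 14, `PD-MCI` = 19, `PD-D` = 32),
      putamen = c(CTRL = 35, `PD-CN` = 14, `PD-MCI` = 19, `PD-D` = 0)
    ),
    n_analytes_lc = 30,
    n_analytes_fia = 70,
    n_plates = c(cortex = 2, putamen = 1),
    plate_sigma = 0.15,
    group_effects = NULL,
    levodopa_effects = NULL,
    covariate_effects = NULL,
    score_effects = NULL,
    frac_levodopa_positive = 0.5,
    dopa_separation = 4,
    dopa_pd_deficit = 1,
    group_sigma_scale = c(CTRL = 1, `PD-CN` = 1, `PD-MCI` = 1, `PD-D` = 1),
    lod_censor_quantile = 0.02,
    n_qc_per_plate = 3,
    n_blanks = 3,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  .assert(length(unknown) == 0,
          paste("unknown sim_config field(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  .assert(all(unlist(cfg$n_per_group) >= 0), "group counts must be >= 0")
  .assert(cfg$frac_levodopa_positive >= 0 && cfg$frac_levodopa_positive <= 1,
          "frac_levodopa_positive must lie in [0, 1]")
  .assert(cfg$plate_sigma >= 0, "plate_sigma must be >= 0")
  structure(cfg, class = "sim_config")
}

# truncated normal by resampling (vectorized rejection)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- x < lower | x > upper
  }
  x
}

# per-group covariate/score distributions drawn near the cohort table
.group_params <- list(
  age = list(mean = c(82, 85, 82, 80), sd = c(10, 6, 6, 5), lim = c(60, 105)),
  education = list(mean = c(14, 16, 14, 16), sd = c(3, 3, 3, 3), lim = c(8, 22)),
  bmi = list(mean = c(25, 22, 25, 27), sd = c(5, 4, 8, 9), lim = c(15, 45)),
  pmci = list(mean = c(3.2, 3.3, 3.4, 3.4), sd = c(1, 0.9, 1.2, 0.9),
              lim = c(1, 8)),
  storage = list(mean = c(10, 8, 6, 8), sd = c(4, 4, 4, 4), lim = c(1, 20)),
  updrs_m = list(mean = c(7, 32, 31, 50), sd = c(5, 15, 15, 16),
                 lim = c(0, 100)),
  usslb = list(mean = c(0, 3, 3.7, 3.4), sd = c(0.01, 0.5, 0.5, 0.6),
               lim = c(0, 5)),
  mmse = list(mean = c(28, 28, 25, 20), sd = c(1, 1, 3, 6), lim = c(0, 30)),
  plaque_density = list(mean = c(2.7, 4.6, 5.1, 1.8), sd = c(3.9, 4.7, 6, 3.3),
                        lim = c(0, 15)),
  tangle_density = list(mean = c(2.9, 5.3, 5.2, 4.8),
                        sd = c(1.6, 2.6, 1.6, 2.1), lim = c(0, 12)),
  pd_duration = list(mean = c(NA, 11, 12, 18), sd = c(NA, 7, 6, 9),
                     lim = c(1, 40))
)
.sex_p_male <- c(0.61, 0.57, 0.74, 0.75)
.comorbidity_p <- list(hyperlipidemia = c(0.36, 0.50, 0.47, 0.34),
                       diabetes = c(0.33, 0.07, 0.16, 0.25),
                       renal_insufficiency = c(0.14, 0.21, 0.11, 0.16),
                       hypothyroidism = c(0.25, 0.21, 0.26, 0.16))
.sim_groups <- c("CTRL", "PD-CN", "PD-MCI", "PD-D")

.effect_lookup <- function(df, analyte, key_col, key) {
  if (is.null(df)) return(0)
  hit <- df$analyte == analyte & df[[key_col]] == key
  if (any(hit)) sum(df$effect[hit]) else 0
}

#' Simulate a synthetic brain metabolomics cohort
#'
#' Generates the four tables the analysis pipeline consumes (analyte
#' table including QC samples, sample metadata, blank signals) together
#' with a truth record of every planted quantity, reproducible
#' bit-for-bit from the configuration and seed. Analyte values are drawn
#' log-normal; on the log scale the mean is shifted by planted group,
#' levodopa-interaction, covariate and progression-score effects (all in
#' control-SD units, i.e. multiples of the analyte's control log-SD), the
#' residual SD is scaled per group, and the resulting abundance is
#' multiplied by the plate factor of the sample's plate. The DOPA analyte
#' is generated so that acutely levodopa-positive (L+) subjects exceed the
#' controls' 95\% quantile and L- subjects fall below it. Blanks are
#' placed so that twice their median (the LOD) sits at the configured
#' censoring quantile of each analyte's values.
#'
#' Each analyte is drawn from its own deterministic RNG sub-stream derived
#' from the cohort seed, so any single analyte can be regenerated without
#' replaying the whole cohort.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return list of class \code{sim_cohort} with elements \code{analytes}
#'   (\code{analyte_table}), \code{meta}, \code{blanks} (matrix) and
#'   \code{truth}.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .assert(sum(unlist(config$n_per_group)) > 0,
          "zero samples in every group")

  n_lc <- config$n_analytes_lc
  n_fia <- config$n_analytes_fia
  lc_ids <- if (n_lc >= 1) c("Hcy", if (n_lc > 1) sprintf("LC%03d", 2:n_lc))
            else character(0)
  fia_ids <- if (n_fia >= 1) sprintf("FIA%03d", seq_len(n_fia))
             else character(0)
  analyte_ids <- c(lc_ids, fia_ids, "DOPA")
  ann <- data.frame(
    analyte_id = analyte_ids,
    method = c(rep("LC", length(lc_ids)), rep("FIA", length(fia_ids)), "LC"),
    analyte_type = "measured",
    class = c(rep("amino acid", length(lc_ids)),
              rep("lipid", length(fia_ids)), "biogenic amine"),
    stringsAsFactors = FALSE)

  for (df in list(config$group_effects, config$levodopa_effects,
                  config$score_effects)) {
    if (!is.null(df)) {
      .assert(all(df$analyte %in% analyte_ids),
              "planted effect references an unknown analyte")
    }
  }

  # --- stream 0: subjects, covariates, plates, L+ assignment, scores ----
  set.seed(derive_seed(seed, 0))
  meta_rows <- list()
  for (rg in names(config$n_per_group)) {
    counts <- config$n_per_group[[rg]]
    counts <- counts[counts > 0]
    if (length(counts) == 0) next
    n_subj <- sum(counts)
    group <- rep(names(counts), counts)
    gi <- match(group, .sim_groups)
    pre <- toupper(substr(rg, 1, 3))
    sid <- sprintf("%s_S%03d", pre, seq_len(n_subj))
    m <- data.frame(sample_id = sid,
                    subject_id = sprintf("%s_subj%03d", pre, seq_len(n_subj)),
                    group = group, region = rg, stringsAsFactors = FALSE)
    m$sex <- ifelse(stats::runif(n_subj) < .sex_p_male[gi], "M", "F")
    for (f in c("age", "education", "bmi", "pmci", "storage")) {
      pp <- .group_params[[f]]
      m[[f]] <- .rtnorm(n_subj, pp$mean[gi], pp$sd[gi], pp$lim[1], pp$lim[2])
    }
    for (f in names(.comorbidity_p)) {
      m[[f]] <- as.integer(stats::runif(n_subj) < .comorbidity_p[[f]][gi])
    }
    for (f in c("updrs_m", "usslb", "mmse", "plaque_density",
                "tangle_density", "pd_duration")) {
      pp <- .group_params[[f]]
      v <- rep(NA_real_, n_subj)
      ok <- !is.na(pp$mean[gi])
      if (any(ok)) {
        v[ok] <- .rtnorm(sum(ok), pp$mean[gi][ok], pp$sd[gi][ok],
                         pp$lim[1], pp$lim[2])
      }
      m[[f]] <- v
    }
    m$usslb[m$group == "CTRL"] <- 0
    # plates: stratified assignment of subjects across the region's plates
    np <- config$n_plates[[rg]]
    plate <- integer(n_subj)
    for (g in names(counts)) {
      ix <- which(group == g)
      plate[ix] <- sample(rep_len(seq_len(np), length(ix)))
    }
    m$plate_id <- sprintf("%s_P%d", pre, plate)
    # acute levodopa assignment: random among PD, independent of scores
    is_pd <- m$group != "CTRL"
    m$l_positive <- FALSE
    m$l_positive[is_pd] <-
      stats::runif(sum(is_pd)) < config$frac_levodopa_positive
    meta_rows[[rg]] <- m
    # QC replicates on each plate
    qc <- data.frame(
      sample_id = sprintf("%s_QC_P%d_%d", pre,
                          rep(seq_len(np), each = config$n_qc_per_plate),
                          rep(seq_len(config$n_qc_per_plate), np)),
      subject_id = "QC", group = "QC", region = rg, sex = NA_character_,
      age = NA_real_, education = NA_real_, bmi = NA_real_,
      pmci = NA_real_, storage = NA_real_,
      hyperlipidemia = NA_integer_, diabetes = NA_integer_,
      renal_insufficiency = NA_integer_, hypothyroidism = NA_integer_,
      updrs_m = NA_real_, usslb = NA_real_, mmse = NA_real_,
      plaque_density = NA_real_, tangle_density = NA_real_,
      pd_duration = NA_real_,
      plate_id = sprintf("%s_P%d", pre,
                         rep(seq_len(np), each = config$n_qc_per_plate)),
      l_positive = FALSE, stringsAsFactors = FALSE)
    meta_rows[[paste0(rg, "_qc")]] <- qc
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  subj <- meta$group != "QC"
  is_pd <- subj & meta$group != "CTRL"

  # standardized covariates for planted covariate effects
  cov_z <- list()
  if (!is.null(config$covariate_effects)) {
    for (f in names(config$covariate_effects)) {
      raw <- if (f == "sexM") as.numeric(meta$sex == "M") else meta[[f]]
      mu <- mean(raw[subj], na.rm = TRUE)
      sd_ <- stats::sd(raw[subj], na.rm = TRUE)
      cov_z[[f]] <- ifelse(subj, (raw - mu) / sd_, 0)
    }
  }
  score_z <- list()
  if (!is.null(config$score_effects)) {
    for (f in unique(config$score_effects$score)) {
      raw <- meta[[f]]
      mu <- mean(raw[is_pd], na.rm = TRUE)
      sd_ <- stats::sd(raw[is_pd], na.rm = TRUE)
      z <- rep(0, nrow(meta))
      z[is_pd] <- (raw[is_pd] - mu) / sd_
      z[is.na(z)] <- 0
      score_z[[f]] <- z
    }
  }

  # --- per-analyte sub-streams -----------------------------------------
  n_samp <- nrow(meta)
  values <- matrix(NA_real_, n_samp, length(analyte_ids),
                   dimnames = list(meta$sample_id, analyte_ids))
  truth_mu <- truth_sigma <- stats::setNames(numeric(length(analyte_ids)),
                                             analyte_ids)
  plate_levels <- unique(meta$plate_id)
  plate_factors <- matrix(NA_real_, length(plate_levels), length(analyte_ids),
                          dimnames = list(plate_levels, analyte_ids))
  pd_class <- ifelse(meta$group == "PD-D", "PD-D",
                     ifelse(is_pd, "PD-ND", NA_character_))
  sigma_scale <- ifelse(subj, config$group_sigma_scale[meta$group], 0.1)
  sigma_scale[is.na(sigma_scale)] <- 1

  for (j in seq_along(analyte_ids)) {
    m_id <- analyte_ids[j]
    set.seed(derive_seed(seed, j))
    if (m_id == "DOPA") {
      mu_m <- log(1)
      sig_m <- 0.4
    } else {
      mu_m <- stats::runif(1, log(0.1), log(100))
      sig_m <- stats::runif(1, 0.2, 0.6)
    }
    truth_mu[j] <- mu_m
    truth_sigma[j] <- sig_m
    pf <- exp(stats::rnorm(length(plate_levels), 0, config$plate_sigma))
    if (config$plate_sigma == 0) pf[] <- 1
    plate_factors[, j] <- pf

    shift <- rep(0, n_samp)
    if (m_id == "DOPA") {
      shift[subj & meta$l_positive] <- config$dopa_separation * sig_m
      shift[is_pd & !meta$l_positive] <- -config$dopa_pd_deficit * sig_m
    } else {
      for (g in setdiff(.sim_groups, "CTRL")) {
        e <- .effect_lookup(config$group_effects, m_id, "group", g)
        if (e != 0) shift[meta$group == g] <- shift[meta$group == g] + e * sig_m
      }
      for (klass in c("PD-ND", "PD-D")) {
        e <- .effect_lookup(config$levodopa_effects, m_id, "pd_class", klass)
        if (e != 0) {
          hit <- !is.na(pd_class) & pd_class == klass & meta$l_positive
          shift[hit] <- shift[hit] + e * sig_m
        }
      }
      for (f in names(cov_z)) {
        shift <- shift + config$covariate_effects[[f]] * cov_z[[f]] * sig_m
      }
      if (!is.null(config$score_effects)) {
        se_m <- config$score_effects[config$score_effects$analyte == m_id, ,
                                     drop = FALSE]
        for (k in seq_len(nrow(se_m))) {
          shift <- shift + se_m$slope[k] * score_z[[se_m$score[k]]] * sig_m
        }
      }
    }
    logx <- mu_m + shift + stats::rnorm(n_samp, 0, sig_m * sigma_scale)
    values[, j] <- exp(logx) * pf[match(meta$plate_id, plate_levels)]
  }

  # --- blanks: LOD (= 2 x blank median) at the censoring quantile ------
  lod_target <- apply(values[subj, , drop = FALSE], 2, .quantile7,
                      probs = config$lod_censor_quantile)
  mult <- seq(0.9, 1.1, length.out = config$n_blanks)
  blanks <- t(vapply(seq_len(config$n_blanks),
                     function(b) lod_target / 2 * mult[b],
                     numeric(length(analyte_ids))))
  if (config$n_blanks == 1) blanks <- matrix(lod_target / 2, 1,
                                             length(analyte_ids))
  dimnames(blanks) <- list(sprintf("BLANK_%d", seq_len(config$n_blanks)),
                           analyte_ids)
  censor_mask <- sweep(values, 2, 2 * apply(blanks, 2, stats::median), "<")

  meta$dopa_level <- values[, "DOPA"]
  l_pos <- stats::setNames(meta$l_positive, meta$sample_id)
  meta_out <- meta[, setdiff(names(meta), "l_positive"), drop = FALSE]
  validate_sample_meta(meta_out)

  truth <- list(mu = truth_mu, sigma = truth_sigma,
                plate_factors = plate_factors,
                l_positive = l_pos[subj],
                group_effects = config$group_effects,
                levodopa_effects = config$levodopa_effects,
                covariate_effects = config$covariate_effects,
                score_effects = config$score_effects,
                censor_mask = censor_mask,
                lod = 2 * apply(blanks, 2, stats::median),
                seed = seed)
  structure(list(analytes = analyte_table(values, ann), meta = meta_out,
                 blanks = blanks, truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic brain metabolomics cohort\n")
  tab <- table(x$meta$region, x$meta$group)
  print(tab)
  cat(sprintf("%d analytes (incl. DOPA), %d blanks, seed %s\n",
              ncol(x$analytes$values), nrow(x$blanks), x$truth$seed))
  invisible(x)
}

#' Simulate i.i.d. uniform null p-values
#'
#' Testing harness for FDR and enrichment calibration.
#'
#' @param n_tests number of p-values (>= 1).
#' @param seed RNG seed.
#' @return vector of p-values in (0, 1].
#' @export
simulate_null_pvalues <- function(n_tests, seed = 1L) {
  .assert(n_tests >= 1, "n_tests must be >= 1")
  set.seed(seed)
  1 - stats::runif(n_tests)
}

#' Generate synthetic metabolite set definitions
#'
#' Draws random sets over the given analytes (emulating pathway
#' membership, many-to-many allowed) and optionally one designated set
#' containing specified member analytes, for power studies of the set
#' enrichment stage.
#'
#' @param analyte_ids available analytes.
#' @param n_sets number of random sets.
#' @param size_range inclusive range of set sizes.
#' @param planted optional named list: set name -> member analyte ids.
#' @param seed RNG seed.
#' @return a \code{metabolite_set_db}.
#' @export
simulate_sets <- function(analyte_ids, n_sets = 20, size_range = c(5, 15),
                          planted = NULL, seed = 1L) {
  set.seed(seed)
  sets <- list()
  for (i in seq_len(n_sets)) {
    k <- sample(size_range[1]:size_range[2], 1)
    sets[[sprintf("SET%03d", i)]] <- sample(analyte_ids,
                                            min(k, length(analyte_ids)))
  }
  desc <- stats::setNames(rep("synthetic set", length(sets)), names(sets))
  if (!is.null(planted)) {
    for (nm in names(planted)) {
      sets[[nm]] <- unique(planted[[nm]])
      desc[nm] <- "planted set"
    }
  }
  structure(list(sets = sets, descriptions = desc),
            class = "metabolite_set_db")
}
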