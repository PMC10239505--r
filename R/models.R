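# covariates entering every analyte model, in design order
.model_covariates <- c("age", "sexM", "education", "bmi", "hyperlipidemia",
                       "diabetes", "renal_insufficiency", "hypothyroidism",
                       "log_pmci", "log_storage")

# assemble the per-sample regression frame for one region
.design_frame <- function(prep, region) {
  r <- prep$regions[[region]]
  .assert(!is.null(r), sprintf("region '%s' not present", region))
  ids <- rownames(r$values)
  meta <- prep$meta[match(ids, prep$meta$sample_id), , drop = FALSE]
  d <- data.frame(sample_id = ids, group = meta$group,
                  stringsAsFactors = FALSE)
  d$age <- meta$age
  d$sexM <- as.numeric(meta$sex == "M")
  d$education <- meta$education
  d$bmi <- meta$bmi
  d$hyperlipidemia <- meta$hyperlipidemia
  d$diabetes <- meta$diabetes
  d$renal_insufficiency <- meta$renal_insufficiency
  d$hypothyroidism <- meta$hypothyroidism
  d$log_pmci <- log(meta$pmci)
  d$log_storage <- log(meta$storage)
  for (f in c("pd_duration", "updrs_m", "usslb", "mmse", "plaque_density",
              "tangle_density")) {
    d[[f]] <- meta[[f]]
  }
  if (!is.null(prep$levodopa)) {
    st <- prep$levodopa$status
    d$l_positive <- st$status[match(ids, st$sample_id)] == "L+"
    d$l_positive[is.na(d$l_positive)] <- FALSE
  } else d$l_positive <- FALSE
  d$grp_pd <- as.numeric(d$group != "CTRL")
  d$grp_pd_cn <- as.numeric(d$group == "PD-CN")
  d$grp_pd_mci <- as.numeric(d$group == "PD-MCI")
  d$grp_pd_d <- as.numeric(d$group == "PD-D")
  d$ldopa_pd_nd <- as.numeric(d$l_positive & d$group %in% c("PD-CN", "PD-MCI"))
  d$ldopa_pd_d <- as.numeric(d$l_positive & d$group == "PD-D")
  d
}

# terms of interest for a region/mode (groups present in the data decide)
.differential_terms <- function(d, mode) {
  has <- function(g) any(d$group == g)
  grp_terms <- if (mode == "all_pd") {
    "grp_pd"
  } else {
    c(if (has("PD-CN")) "grp_pd_cn", if (has("PD-MCI")) "grp_pd_mci",
      if (has("PD-D")) "grp_pd_d")
  }
  ld_terms <- c(
    if (any(d$ldopa_pd_nd == 1)) "ldopa_pd_nd",
    if (has("PD-D") && any(d$ldopa_pd_d == 1)) "ldopa_pd_d")
  list(group = grp_terms, levodopa = ld_terms)
}

.fit_one <- function(d, response, terms, level = 0.95) {
  fml <- stats::as.formula(paste(
    "y ~", paste(c(terms, .model_covariates), collapse = " + ")))
  d$y <- response
  fit <- hetlm(fml, d, variance_groups = "group")
  ci <- confint(fit, level = level)
  keep <- intersect(terms, names(coef(fit)))
  data.frame(term = keep, beta = unname(coef(fit)[keep]),
             se = unname(fit$se[keep]),
             ci_low = unname(ci[keep, 1]), ci_high = unname(ci[keep, 2]),
             p = unname(fit$p_values[keep]),
             n_effective = fit$nobs, converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Differential analysis: per-analyte group and levodopa effects
#'
#' Fits one heteroscedastic linear model (\code{\link{hetlm}}) per
#' analysis-ready analyte and region: standardized analyte value against
#' subject-group indicators (each PD cognitive group vs controls, or a
#' single all-PD indicator), acute levodopa presence indicators separately
#' for non-demented and demented PD, and the fixed covariate set (age,
#' sex, education, BMI, four comorbidity flags, log post-mortem interval,
#' log storage time). Residual variances are group-specific. Putamen
#' models structurally lack the dementia rows and the corresponding
#' levodopa term. Coefficients are in control-SD units. Two-tailed
#' p-values of each term family are converted to Storey q-values
#' separately within each acquisition-method x analyte-type stratum.
#'
#' @param prep a \code{\link{preprocess}} result.
#' @param mode \code{"by_cognition"} (PD-CN / PD-MCI / PD-D vs controls)
#'   or \code{"all_pd"} (single PD indicator).
#' @param regions regions to analyse (default: all present).
#' @return data frame of per-analyte, per-term fit results with q-values.
#' @export
run_differential <- function(prep, mode = c("by_cognition", "all_pd"),
                             regions = names(prep$regions)) {
  mode <- match.arg(mode)
  stopifnot(inherits(prep, "neurometab_prep"))
  out <- list()
  for (rg in regions) {
    d <- .design_frame(prep, rg)
    terms <- .differential_terms(d, mode)
    all_terms <- c(terms$group, terms$levodopa)
    vals <- prep$regions[[rg]]$values
    ann <- prep$regions[[rg]]$annotations
    for (m in colnames(vals)) {
      rows <- tryCatch(.fit_one(d, vals[, m], all_terms),
                       error = function(e) NULL)
      if (is.null(rows)) next
      rows$analyte_id <- m
      rows$region <- rg
      ai <- match(m, ann$analyte_id)
      rows$method <- ann$method[ai]
      rows$analyte_type <- ann$analyte_type[ai]
      out[[paste(rg, m)]] <- rows
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- add_stratified_qvalues(res)
  res[, c("analyte_id", "region", "term", "beta", "se", "ci_low", "ci_high",
          "p", "q", "n_effective", "converged", "method", "analyte_type")]
}

#' Stratified Storey q-values for a fit-result table
#'
#' Adds a \code{q} column: within each coefficient family (term) and
#' region, p-values are FDR-adjusted separately for each combination of
#' acquisition method (LC/FIA) and analyte type (measured/calculated),
#' the four disjoint strata whose union is the full analyte set.
#'
#' @param res fit-result data frame with columns \code{p}, \code{term},
#'   \code{region}, \code{method}, \code{analyte_type}.
#' @return the table with a \code{q} column.
#' @export
add_stratified_qvalues <- function(res) {
  res$q <- NA_real_
  key <- interaction(res$term, res$region, res$method, res$analyte_type,
                     drop = TRUE)
  for (k in levels(key)) {
    ix <- which(key == k & !is.na(res$p))
    if (length(ix) == 0) next
    res$q[ix] <- suppressMessages(qvalues(res$p[ix]))
  }
  res
}

#' Progression analysis: score associations among PD subjects
#'
#' For each analyte, fits the same covariate-adjusted heteroscedastic
#' model with the subject groups and levodopa indicators replaced by a PD
#' membership indicator plus one regressor per progression score, equal to
#' the PD-standardized score for PD subjects and zero for controls: the
#' controls inform the covariate estimates but not the score effect. The
#' reported coefficient is therefore two-way standardized (control SDs of
#' the analyte per PD-subject SD of the score) and invariant to affine
#' rescaling of the raw score. PD subjects missing the score are dropped
#' from that score's models only.
#'
#' @param prep a \code{\link{preprocess}} result.
#' @param scores character vector of score columns; several scores give a
#'   combined model with one regressor each.
#' @param regions regions to analyse.
#' @param min_pd minimum PD subjects with the score observed.
#' @return data frame of per-analyte score coefficients with q-values.
#' @export
run_progression <- function(prep, scores, regions = names(prep$regions),
                            min_pd = 10) {
  stopifnot(inherits(prep, "neurometab_prep"))
  out <- list()
  for (rg in regions) {
    d <- .design_frame(prep, rg)
    is_pd <- d$group != "CTRL"
    keep <- rep(TRUE, nrow(d))
    score_terms <- character(0)
    for (sc in scores) {
      raw <- d[[sc]]
      .assert(!is.null(raw), sprintf("unknown score '%s'", sc))
      obs_pd <- is_pd & !is.na(raw)
      if (sum(obs_pd) < min_pd) next
      sd_pd <- stats::sd(raw[obs_pd])
      if (!is.finite(sd_pd) || sd_pd == 0) {
        stop(sprintf("score '%s' is constant among PD subjects", sc),
             call. = FALSE)
      }
      zc <- paste0("score_", sc)
      z <- rep(0, nrow(d))
      z[obs_pd] <- (raw[obs_pd] - mean(raw[obs_pd])) / sd_pd
      d[[zc]] <- z
      keep <- keep & (!is_pd | !is.na(raw))
      score_terms <- c(score_terms, zc)
    }
    if (length(score_terms) == 0) next
    dd <- d[keep, , drop = FALSE]
    vals <- prep$regions[[rg]]$values[keep, , drop = FALSE]
    ann <- prep$regions[[rg]]$annotations
    for (m in colnames(vals)) {
      rows <- tryCatch(
        .fit_one(dd, vals[, m], c("grp_pd", score_terms)),
        error = function(e) NULL)
      if (is.null(rows)) next
      rows <- rows[rows$term %in% score_terms, , drop = FALSE]
      rows$term <- sub("^score_", "", rows$term)
      rows$analyte_id <- m
      rows$region <- rg
      ai <- match(m, ann$analyte_id)
      rows$method <- ann$method[ai]
      rows$analyte_type <- ann$analyte_type[ai]
      out[[paste(rg, m)]] <- rows
    }
  }
  .assert(length(out) > 0, "no score had enough observed PD subjects")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- add_stratified_qvalues(res)
  res[, c("analyte_id", "region", "term", "beta", "se", "ci_low", "ci_high",
          "p", "q", "n_effective", "converged", "method", "analyte_type")]
}

#' Collinearity report: pairwise correlations and adjusted GVIF
#'
#' Screens a model design for collinearity by (i) pairwise Pearson
#' correlations among non-constant regressors and (ii) the generalized
#' variance inflation factor per term,
#' \eqn{GVIF = \det(R_{11}) \det(R_{22}) / \det(R)} on the correlation
#' matrix of the design columns, reported on the adjusted scale
#' \eqn{GVIF^{1/(2\,df)}}. Flags any \eqn{|r| \ge 0.6} or adjusted GVIF
#' \eqn{\ge 1.5}.
#'
#' @param x a \code{\link{hetlm}} fit or a numeric design matrix
#'   (an intercept column is dropped).
#' @param terms optional integer assignment of columns to terms (as
#'   \code{attr(model.matrix, "assign")}); default one term per column.
#' @param r_limit,gvif_limit flag thresholds.
#' @return list with \code{correlations} (data frame of pairs),
#'   \code{gvif} (data frame per term) and \code{flagged} (logical).
#' @export
collinearity_check <- function(x, terms = NULL, r_limit = 0.6,
                               gvif_limit = 1.5) {
  if (inherits(x, "hetlm")) {
    stop("pass the design matrix (model.matrix) for a hetlm fit",
         call. = FALSE)
  }
  X <- as.matrix(x)
  ic <- which(colnames(X) %in% "(Intercept)" |
                apply(X, 2, function(c) stats::sd(c) == 0))
  if (length(ic)) {
    if (!is.null(terms)) terms <- terms[-ic]
    X <- X[, -ic, drop = FALSE]
  }
  p <- ncol(X)
  .assert(p >= 1, "no non-constant regressors")
  if (is.null(terms)) terms <- seq_len(p)
  R <- suppressWarnings(stats::cor(X))
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  cor_df <- data.frame(var1 = colnames(X)[pairs[, 1]],
                       var2 = colnames(X)[pairs[, 2]],
                       r = R[pairs], stringsAsFactors = FALSE)
  cor_df$flag <- abs(cor_df$r) >= r_limit
  detR <- det(R)
  gvif_rows <- lapply(unique(terms), function(tt) {
    ix <- which(terms == tt)
    g <- if (detR <= .Machine$double.eps) {
      Inf
    } else {
      det(R[ix, ix, drop = FALSE]) *
        det(R[-ix, -ix, drop = FALSE]) / detR
    }
    df_t <- length(ix)
    adj <- g^(1 / (2 * df_t))
    data.frame(term = paste(colnames(X)[ix], collapse = "+"),
               df = df_t, gvif = g, adjusted_gvif = adj,
               flag = !is.finite(adj) | adj >= gvif_limit,
               stringsAsFactors = FALSE)
  })
  gvif_df <- do.call(rbind, gvif_rows)
  list(correlations = cor_df, gvif = gvif_df,
       flagged = any(cor_df$flag) || any(gvif_df$flag))
}

#' Cohort characteristics table with group comparison tests
#'
#' Summarizes subject characteristics per group: mean (SD) for continuous
#' variables with a heteroscedastic analysis of variance p-value (joint
#' Wald test of the group terms in a group-variance \code{\link{hetlm}}),
#' and count (percent) for binary variables with a two-tailed Fisher
#' exact test on the 2 x k table. Both an all-groups and a PD-groups-only
#' comparison are reported. Characteristics with no observed values are
#' omitted (recorded in the \code{"omitted"} attribute).
#'
#' @param meta sample metadata (one row per subject sample; QC ignored).
#' @param continuous,binary characteristic column names.
#' @return data frame, one row per characteristic.
#' @export
cohort_table <- function(meta,
                         continuous = c("age", "education", "bmi", "pmci",
                                        "storage", "pd_duration", "updrs_m",
                                        "usslb", "mmse", "plaque_density",
                                        "tangle_density"),
                         binary = c("sexM", "hyperlipidemia", "diabetes",
                                    "renal_insufficiency",
                                    "hypothyroidism")) {
  meta <- meta[meta$group != "QC", , drop = FALSE]
  meta <- meta[!duplicated(meta$subject_id), , drop = FALSE]
  meta$sexM <- as.numeric(meta$sex == "M")
  groups <- intersect(.sim_groups, unique(meta$group))
  pd_groups <- setdiff(groups, "CTRL")
  omitted <- character(0)
  test_cont <- function(d) {
    d <- d[!is.na(d$value), , drop = FALSE]
    if (length(unique(d$group)) < 2 || stats::sd(d$value) == 0) {
      return(NA_real_)
    }
    d$group <- factor(d$group)
    fit <- tryCatch(hetlm(value ~ group, d, variance_groups = "group"),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    parm <- grep("^group", names(coef(fit)), value = TRUE)
    wald_test(fit, parm)$p.value
  }
  test_bin <- function(d) {
    d <- d[!is.na(d$value), , drop = FALSE]
    if (length(unique(d$group)) < 2 || length(unique(d$value)) < 2) {
      return(NA_real_)
    }
    stats::fisher.test(table(d$value, d$group))$p.value
  }
  rows <- list()
  for (ch in c(continuous, binary)) {
    v <- meta[[ch]]
    if (is.null(v) || all(is.na(v))) {
      omitted <- c(omitted, ch)
      next
    }
    is_cont <- ch %in% continuous
    cells <- vapply(groups, function(g) {
      x <- v[meta$group == g]
      x <- x[!is.na(x)]
      if (length(x) == 0) return("-")
      if (is_cont) sprintf("%.1f (%.1f)", mean(x), stats::sd(x))
      else sprintf("%d (%.0f%%)", sum(x == 1), 100 * mean(x == 1))
    }, "")
    d_all <- data.frame(value = v, group = meta$group)
    d_pd <- d_all[d_all$group %in% pd_groups, , drop = FALSE]
    p_all <- if (is_cont) test_cont(d_all) else test_bin(d_all)
    p_pd <- if (length(pd_groups) >= 2) {
      if (is_cont) test_cont(d_pd) else test_bin(d_pd)
    } else NA_real_
    row <- data.frame(characteristic = ch, t(cells),
                      p_all_groups = p_all, p_pd_groups = p_pd,
                      stringsAsFactors = FALSE, check.names = FALSE)
    rows[[ch]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Welch t-tests of progression scores by acute levodopa state
#'
#' Verifies the assumption that acute levodopa presence at death is a
#' random process unrelated to disease progression: within each PD class
#' (demented / non-demented), each score is compared between L+ and L-
#' subjects with a two-tailed Welch t-test (Welch-Satterthwaite degrees
#' of freedom), and the p-values are FDR-adjusted.
#'
#' @param meta sample metadata.
#' @param levodopa a \code{levodopa_status}.
#' @param scores score columns to test.
#' @param region brain region whose samples are tested.
#' @return data frame: pd_class, score, mean difference, p, q.
#' @export
welch_by_levodopa <- function(meta, levodopa,
                              scores = c("pd_duration", "updrs_m", "usslb",
                                         "mmse", "plaque_density",
                                         "tangle_density"),
                              region = "cortex") {
  st <- levodopa$status[levodopa$status$region == region, , drop = FALSE]
  meta <- meta[match(st$sample_id, meta$sample_id), , drop = FALSE]
  meta$l_positive <- st$status == "L+"
  meta$pd_class <- ifelse(meta$group == "PD-D", "PD-D", "PD-ND")
  rows <- list()
  for (klass in unique(meta$pd_class)) {
    sub <- meta[meta$pd_class == klass, , drop = FALSE]
    for (sc in scores) {
      x <- sub[[sc]][sub$l_positive]
      y <- sub[[sc]][!sub$l_positive]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) next
      if (stats::sd(c(x, y)) == 0) next
      tt <- stats::t.test(x, y)
      rows[[paste(klass, sc)]] <- data.frame(
        pd_class = klass, score = sc, mean_diff = mean(x) - mean(y),
        p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  .assert(length(rows) > 0, "no score had enough L+ and L- subjects")
  out <- do.call(rbind, rows)
  out$q <- suppressMessages(qvalues(out$p))
  rownames(out) <- NULL
  out
}
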