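#' Linear quantification from quality control medians
#'
#' Converts internal-standard area ratios to concentrations by linear
#' scaling through the kit quality control sample: for each analyte with a
#' known expected QC concentration,
#' \code{conc = ratio * expected / median(QC ratios)}. Analytes without an
#' expected concentration (or with a zero/missing QC median) pass through
#' unchanged and are flagged as unquantified.
#'
#' @param table an \code{\link{analyte_table}} of area ratios.
#' @param qc_ids sample ids of the QC replicates (>= 1 per plate expected).
#' @param expected_qc_conc named numeric vector, analyte id -> expected
#'   concentration in the QC sample (uM); must be positive.
#' @return list with \code{table} (quantified \code{analyte_table}) and
#'   \code{unquantified} (character vector of analytes left as ratios).
#' @export
quantify_linear <- function(table, qc_ids, expected_qc_conc) {
  stopifnot(inherits(table, "analyte_table"))
  .assert(length(qc_ids) >= 1 && all(qc_ids %in% rownames(table$values)),
          "qc_ids must identify >= 1 sample in the table")
  .assert(all(expected_qc_conc > 0, na.rm = TRUE),
          "expected QC concentrations must be positive")
  v <- table$values
  unquantified <- character(0)
  for (m in colnames(v)) {
    exp_c <- expected_qc_conc[m]
    if (is.na(exp_c) || is.null(exp_c) || !m %in% names(expected_qc_conc)) {
      unquantified <- c(unquantified, m)
      next
    }
    qc_med <- stats::median(v[qc_ids, m], na.rm = TRUE)
    if (!is.finite(qc_med) || qc_med == 0) {
      unquantified <- c(unquantified, m)
      next
    }
    v[, m] <- v[, m] * exp_c / qc_med
  }
  list(table = analyte_table(v, table$annotations),
       unquantified = unquantified)
}

#' Limits of detection from blank signals
#'
#' LOD per analyte is twice the median signal observed in blank samples.
#' Analytes absent from the blank table get a missing LOD and are exempt
#' from LOD-based filtering.
#'
#' @param blanks numeric matrix (blank samples x analytes) or an
#'   \code{analyte_table} restricted to blanks.
#' @return named numeric vector of LODs.
#' @export
compute_lod <- function(blanks) {
  v <- if (inherits(blanks, "analyte_table")) blanks$values else blanks
  .assert(is.matrix(v) && !is.null(colnames(v)),
          "blanks must be a matrix with analyte column names")
  lod <- apply(v, 2, function(x) 2 * stats::median(x, na.rm = TRUE))
  lod[!is.finite(lod)] <- NA_real_
  lod
}

#' Filter analytes undetectable in every subject group
#'
#' Removes an analyte if and only if, in every subject group (QC samples
#' excluded), strictly more than \code{frac} of its values lie below the
#' LOD. Values below LOD that survive the filter are kept unadjusted: they
#' remain the best available estimate of the true level.
#'
#' @param table an \code{analyte_table}.
#' @param lod named LOD vector from \code{\link{compute_lod}}; analytes
#'   with missing LOD are never removed.
#' @param meta sample metadata (defines the subject groups).
#' @param frac below-LOD fraction threshold (default 0.5, strict).
#' @return list with \code{table} (filtered), \code{removed} (ids) and
#'   \code{below_lod} (logical matrix over the retained analytes).
#' @export
filter_below_lod <- function(table, lod, meta, frac = 0.5) {
  stopifnot(inherits(table, "analyte_table"))
  meta <- meta[match(rownames(table$values), meta$sample_id), , drop = FALSE]
  .assert(!anyNA(meta$sample_id), "metadata missing for some samples")
  subj <- meta$group != "QC"
  groups <- unique(meta$group[subj])
  v <- table$values
  removed <- character(0)
  for (m in colnames(v)) {
    if (!m %in% names(lod) || is.na(lod[m])) next
    frac_below <- vapply(groups, function(g) {
      x <- v[subj & meta$group == g, m]
      x <- x[!is.na(x)]
      if (length(x) == 0) return(0)
      mean(x < lod[m])
    }, 0)
    if (length(frac_below) > 0 && all(frac_below > frac)) {
      removed <- c(removed, m)
    }
  }
  keep <- setdiff(colnames(v), removed)
  out <- at_subset(table, analytes = keep)
  bl <- matrix(FALSE, nrow(out$values), ncol(out$values),
               dimnames = dimnames(out$values))
  for (m in colnames(out$values)) {
    if (m %in% names(lod) && !is.na(lod[m])) {
      bl[, m] <- !is.na(out$values[, m]) & out$values[, m] < lod[m]
    }
  }
  list(table = out, removed = removed, below_lod = bl)
}

#' Interpolate exact zeros as half the minimal non-zero value
#'
#' Exact zeros are biologically implausible and break the log-family
#' transformations, so each zero of an analyte is replaced by half of that
#' analyte's minimal non-zero value. Missing values are untouched. An
#' analyte that is entirely zero has no defined replacement: all its
#' values become missing and it is flagged.
#'
#' @param table an \code{analyte_table}.
#' @return list with \code{table}, \code{flagged} (all-zero analytes) and
#'   \code{n_interpolated}.
#' @export
interpolate_zeros <- function(table) {
  stopifnot(inherits(table, "analyte_table"))
  v <- table$values
  flagged <- character(0)
  n_interp <- 0L
  for (m in colnames(v)) {
    x <- v[, m]
    zero <- !is.na(x) & x == 0
    if (!any(zero)) next
    nz <- x[!is.na(x) & x > 0]
    if (length(nz) == 0) {
      v[, m] <- NA_real_
      flagged <- c(flagged, m)
    } else {
      v[zero, m] <- min(nz) / 2
      n_interp <- n_interp + sum(zero)
    }
  }
  list(table = analyte_table(v, table$annotations), flagged = flagged,
       n_interpolated = n_interp)
}

#' Group-median plate normalization
#'
#' Removes multiplicative plate (batch) effects by an extension of median
#' normalization in which every sample serves as a reference after being
#' pre-scaled by its own group median. For each analyte \eqn{m}:
#' \deqn{r_s = x_s / \mathrm{median}_{t \in \mathrm{group}(s)}(x_t)}
#' \deqn{q_p = \mathrm{median}_{t \in \mathrm{plate}\, p}(r_t) /
#'       \mathrm{median}_{t}(r_t)}
#' \deqn{y_s = x_s / q_{p(s)}}
#' QC samples participate as their own group, so the plate quotients are
#' estimated from all samples without being distorted by unequal group
#' allocation across plates. With a single plate \eqn{q \equiv 1} and the
#' table is returned unchanged; a second application is always the
#' identity (idempotence).
#'
#' The caller is responsible for passing samples of a single brain region:
#' group medians are defined within region.
#'
#' @param table an \code{analyte_table}.
#' @param meta sample metadata supplying \code{group} and \code{plate_id}
#'   for every sample of the table.
#' @return list with \code{table} (normalized), \code{quotients}
#'   (data frame analyte_id, plate_id, q) and \code{reference} (matrix of
#'   the pre-normalized reference values \eqn{r}).
#' @export
plate_normalize <- function(table, meta) {
  stopifnot(inherits(table, "analyte_table"))
  meta <- meta[match(rownames(table$values), meta$sample_id), , drop = FALSE]
  .assert(!anyNA(meta$sample_id), "metadata missing for some samples")
  .assert(!anyNA(meta$plate_id) && !anyNA(meta$group),
          "every sample needs a plate and a group")
  v <- table$values
  plates <- unique(as.character(meta$plate_id))
  groups <- as.character(meta$group)
  r_mat <- v * NA_real_
  quot <- expand.grid(analyte_id = colnames(v), plate_id = plates,
                      stringsAsFactors = FALSE)
  quot$q <- NA_real_
  y <- v
  for (m in colnames(v)) {
    x <- v[, m]
    r <- rep(NA_real_, length(x))
    for (g in unique(groups)) {
      ix <- groups == g
      med_g <- stats::median(x[ix], na.rm = TRUE)
      if (!is.finite(med_g)) next
      if (med_g == 0) {
        warning(sprintf("group '%s' median is 0 for analyte '%s'; excluded from reference",
                        g, m), call. = FALSE)
        next
      }
      r[ix] <- x[ix] / med_g
    }
    med_all <- stats::median(r, na.rm = TRUE)
    .assert(is.finite(med_all) && med_all != 0,
            sprintf("no usable reference values for analyte '%s'", m))
    q <- vapply(plates, function(p) {
      rp <- r[as.character(meta$plate_id) == p]
      med_p <- stats::median(rp, na.rm = TRUE)
      if (!is.finite(med_p)) {
        warning(sprintf("plate '%s' has no finite reference for analyte '%s'; q = 1",
                        p, m), call. = FALSE)
        return(1)
      }
      med_p / med_all
    }, 0)
    y[, m] <- x / q[as.character(meta$plate_id)]
    r_mat[, m] <- r
    quot$q[quot$analyte_id == m] <- q[quot$plate_id[quot$analyte_id == m]]
  }
  list(table = analyte_table(y, table$annotations), quotients = quot,
       reference = r_mat)
}

#' Compute metabolic indicators (sums and ratios of analytes)
#'
#' Sum indicators are the sum of their member analytes; ratio indicators
#' are the numerator sum divided by the denominator sum, with zero
#' denominators yielding missing values (ratios with zeros are excluded
#' from analysis rather than inflated). Members lost to earlier filtering
#' are dropped from the formula; an indicator with no surviving numerator
#' member is all-missing and flagged. Indicators inherit \code{FIA} as
#' their method if any constituent is FIA (conservative stratum
#' assignment), else \code{LC}; their type is \code{calculated}.
#'
#' @param table an \code{analyte_table} of measured analytes.
#' @param defs indicator definitions from \code{\link{read_indicator_defs}}
#'   (data frame with list columns \code{numerator}, \code{denominator}).
#' @return list with \code{table} (indicators only) and \code{flagged}.
#' @export
compute_indicators <- function(table, defs) {
  stopifnot(inherits(table, "analyte_table"))
  validate_indicator_defs(defs)
  v <- table$values
  ann <- table$annotations
  n <- nrow(v)
  out <- matrix(NA_real_, n, nrow(defs),
                dimnames = list(rownames(v), defs$indicator_id))
  method <- character(nrow(defs))
  flagged <- character(0)
  for (i in seq_len(nrow(defs))) {
    num <- intersect(defs$numerator[[i]], colnames(v))
    den <- intersect(defs$denominator[[i]], colnames(v))
    members <- c(num, den)
    method[i] <- if (any(ann$method[match(members, ann$analyte_id)] == "FIA"))
      "FIA" else "LC"
    if (length(num) == 0) {
      flagged <- c(flagged, defs$indicator_id[i])
      next
    }
    num_sum <- rowSums(v[, num, drop = FALSE])
    if (defs$kind[i] == "sum") {
      out[, i] <- num_sum
    } else {
      if (length(den) == 0) {
        flagged <- c(flagged, defs$indicator_id[i])
        next
      }
      den_sum <- rowSums(v[, den, drop = FALSE])
      ratio <- num_sum / den_sum
      ratio[!is.na(den_sum) & den_sum == 0] <- NA_real_
      out[, i] <- ratio
    }
  }
  ind_ann <- data.frame(analyte_id = defs$indicator_id, method = method,
                        analyte_type = "calculated",
                        class = "indicator", stringsAsFactors = FALSE)
  list(table = analyte_table(out, ind_ann), flagged = flagged)
}

#' Box-Cox transformation with profile-likelihood lambda
#'
#' Estimates the Box-Cox exponent \eqn{\lambda} maximizing the profile
#' log-likelihood over \eqn{[-3, 3]} (no shift parameter; inputs are
#' positive by construction after zero interpolation) and returns the
#' transformed values \eqn{(v^\lambda - 1)/\lambda} (natural log at
#' \eqn{\lambda = 0}).
#'
#' @param values strictly positive numeric vector with >= 10 finite
#'   values (missing allowed, carried through).
#' @param lambda_range search interval.
#' @param tol optimizer tolerance on lambda.
#' @return list with \code{values} (transformed), \code{lambda} and
#'   \code{flagged} (TRUE for a constant vector, where lambda is
#'   undefined; the transformed values are then all zero).
#' @export
boxcox_fit_transform <- function(values, lambda_range = c(-3, 3),
                                 tol = 1e-4) {
  fin <- is.finite(values)
  v <- values[fin]
  .assert(length(v) >= 10, "need >= 10 finite values for Box-Cox")
  if (any(v <= 0)) {
    stop("non-positive values passed to Box-Cox; pipeline ordering bug",
         call. = FALSE)
  }
  if (stats::sd(v) == 0) {
    out <- values
    out[fin] <- 0
    return(list(values = out, lambda = NA_real_, flagged = TRUE))
  }
  n <- length(v)
  slog <- sum(log(v))
  nll <- function(lambda) {
    tv <- if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
    s2 <- stats::var(tv) * (n - 1) / n
    -(-n / 2 * log(s2) + (lambda - 1) * slog)
  }
  opt <- stats::optimize(nll, interval = lambda_range, tol = tol)
  lambda <- opt$minimum
  out <- values
  out[fin] <- if (abs(lambda) < 1e-12) log(v) else (v^lambda - 1) / lambda
  list(values = out, lambda = lambda, flagged = FALSE)
}

#' Adjust remote outliers to Tukey fences
#'
#' Values beyond \eqn{Q_1 - k \cdot IQR} or \eqn{Q_3 + k \cdot IQR}
#' (quartiles by linear interpolation, type 7) are set to the fence
#' rather than removed, protecting group means from extreme values while
#' retaining the observations. \code{k = 3} targets remote outliers only.
#'
#' @param values numeric vector (>= 4 finite values).
#' @param k fence multiplier.
#' @return list with \code{values}, \code{lower}, \code{upper},
#'   \code{n_adjusted}.
#' @export
tukey_fence <- function(values, k = 3) {
  fin <- is.finite(values)
  .assert(sum(fin) >= 4, "need >= 4 finite values for Tukey fencing")
  q <- .quantile7(values[fin], c(0.25, 0.75))
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  out <- values
  n_adj <- sum(fin & (values < lower | values > upper))
  out[fin & values < lower] <- lower
  out[fin & values > upper] <- upper
  list(values = out, lower = lower, upper = upper, n_adjusted = n_adj)
}

#' Standardize values to the control distribution
#'
#' Centers and scales by the mean and SD of control samples so that model
#' coefficients are expressed in units of one control standard deviation.
#'
#' @param values numeric vector.
#' @param control_mask logical vector marking control samples (>= 3 finite
#'   control values required).
#' @return list with \code{values} (z-scores), \code{center}, \code{scale},
#'   \code{flagged} (TRUE when the control SD is zero; values then NA).
#' @export
standardize_to_controls <- function(values, control_mask) {
  .assert(length(control_mask) == length(values),
          "control mask length mismatch")
  cv <- values[control_mask]
  cv <- cv[is.finite(cv)]
  .assert(length(cv) >= 3, "need >= 3 finite control values")
  mu <- mean(cv)
  sdv <- stats::sd(cv)
  if (sdv == 0) {
    return(list(values = rep(NA_real_, length(values)), center = mu,
                scale = 0, flagged = TRUE))
  }
  list(values = (values - mu) / sdv, center = mu, scale = sdv,
       flagged = FALSE)
}

#' Impute missing BMI and education conditionally on group and sex
#'
#' The regression models require complete covariates; the only analyte-free
#' covariates that may be missing (BMI, years of education) are imputed by
#' the mean over subjects of the same group and sex, falling back to the
#' group mean and then the overall mean for empty cells (each fallback is
#' reported). No other field is ever imputed.
#'
#' @param meta sample metadata data frame.
#' @param fields covariates eligible for imputation.
#' @return list with \code{meta} (imputed) and \code{log} (data frame of
#'   imputed cells: sample_id, field, value, source).
#' @export
impute_covariates <- function(meta, fields = c("bmi", "education")) {
  log_rows <- list()
  subj <- meta$group != "QC"
  for (f in intersect(fields, names(meta))) {
    miss <- which(subj & is.na(meta[[f]]))
    for (i in miss) {
      g <- meta$group[i]; s <- meta$sex[i]
      pool <- meta[[f]][subj & meta$group == g & meta$sex %in% s]
      src <- "group_sex"
      if (all(is.na(pool))) {
        pool <- meta[[f]][subj & meta$group == g]
        src <- "group"
      }
      if (all(is.na(pool))) {
        pool <- meta[[f]][subj]
        src <- "overall"
      }
      val <- mean(pool, na.rm = TRUE)
      meta[[f]][i] <- val
      log_rows[[length(log_rows) + 1]] <-
        data.frame(sample_id = meta$sample_id[i], field = f, value = val,
                   source = src, stringsAsFactors = FALSE)
    }
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(sample_id = character(0), field = character(0),
               value = numeric(0), source = character(0))
  list(meta = meta, log = log_df)
}

#' Classify acute levodopa presence from brain DOPA levels
#'
#' All PD subjects of the cohort were on chronic levodopa medication;
#' whether the drug was acutely present at death is inferred from the
#' brain DOPA level. Per brain region, the physiological threshold is the
#' 95\% quantile (type 7) of the controls' DOPA values; a PD sample is
#' L+ when its DOPA strictly exceeds the threshold (ties go to L-).
#' Controls are never flagged.
#'
#' @param dopa named numeric vector of (normalized) DOPA values, names =
#'   sample ids.
#' @param meta sample metadata.
#' @param quantile control quantile defining the threshold.
#' @param min_controls minimum finite control values required per region.
#' @return object of class \code{levodopa_status}: list with
#'   \code{status} (data frame sample_id, region, status) and
#'   \code{thresholds} (named per region).
#' @export
classify_levodopa <- function(dopa, meta, quantile = 0.95,
                              min_controls = 10) {
  .assert(!is.null(names(dopa)), "dopa vector must be named by sample id")
  meta <- meta[match(names(dopa), meta$sample_id), , drop = FALSE]
  .assert(!anyNA(meta$sample_id), "metadata missing for some dopa samples")
  regions <- unique(meta$region[meta$group != "QC"])
  thresholds <- stats::setNames(numeric(0), character(0))
  rows <- list()
  for (rg in regions) {
    in_rg <- meta$region == rg
    ctrl <- dopa[in_rg & meta$group == "CTRL"]
    ctrl <- ctrl[is.finite(ctrl)]
    if (length(ctrl) == 0) {
      stop(sprintf("region '%s' has no control DOPA values; cannot classify",
                   rg), call. = FALSE)
    }
    .assert(length(ctrl) >= min_controls,
            sprintf("region '%s' has < %d control DOPA values", rg,
                    min_controls))
    thr <- .quantile7(ctrl, quantile)
    thresholds[rg] <- thr
    pd <- in_rg & meta$group %in% c("PD-CN", "PD-MCI", "PD-D")
    if (any(pd)) {
      rows[[rg]] <- data.frame(
        sample_id = meta$sample_id[pd], region = rg,
        status = ifelse(!is.na(dopa[pd]) & dopa[pd] > thr, "L+", "L-"),
        stringsAsFactors = FALSE)
    }
  }
  status <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), region = character(0),
               status = character(0))
  rownames(status) <- NULL
  structure(list(status = status, thresholds = thresholds,
                 quantile = quantile),
            class = "levodopa_status")
}

#' @export
print.levodopa_status <- function(x, ...) {
  cat("Acute levodopa classification\n")
  for (rg in names(x$thresholds)) {
    st <- x$status$status[x$status$region == rg]
    cat(sprintf("  %s: threshold %.4g (%.0f%% control quantile); L+ %d / L- %d\n",
                rg, x$thresholds[rg], 100 * x$quantile,
                sum(st == "L+"), sum(st == "L-")))
  }
  invisible(x)
}
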