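#' Run the full preprocessing pipeline
#'
#' Applies the fixed preprocessing order to a raw analyte table:
#' quantification (optional) -> LOD computation and group-wise filtering ->
#' zero interpolation -> indicator computation -> plate normalization
#' (metabolites and indicators alike) -> levodopa classification from
#' normalized DOPA -> Box-Cox transformation -> Tukey fencing ->
#' standardization to controls -> covariate imputation. The order is fixed
#' because later stages assume the guarantees of earlier ones (Box-Cox
#' requires the positivity that zero interpolation establishes;
#' standardization defines the control-SD coefficient units).
#'
#' Brain regions are processed separately throughout: group medians,
#' control quantiles and standardization statistics are all within-region,
#' matching the separate per-region model families downstream.
#'
#' @param table raw \code{\link{analyte_table}} (subject and QC samples).
#' @param meta sample metadata covering every sample of \code{table}.
#' @param blanks blank-signal matrix or \code{analyte_table} for LOD.
#' @param indicator_defs optional indicator definitions.
#' @param expected_qc_conc optional named vector for linear quantification.
#' @param lod_frac below-LOD fraction threshold (default 0.5).
#' @param tukey_k Tukey fence multiplier (default 3).
#' @param dopa_quantile control quantile for the levodopa threshold.
#' @param dopa_analyte analyte id holding the DOPA measurement.
#' @param indicators_from \code{"raw"} computes indicators from
#'   pre-normalization values and plate-normalizes them together with the
#'   metabolites (default); \code{"normalized"} computes them from
#'   already-normalized metabolites and then normalizes the indicators.
#' @return object of class \code{neurometab_prep}: per-region standardized
#'   matrices and records, the levodopa status, imputed metadata, LODs.
#' @export
preprocess <- function(table, meta, blanks, indicator_defs = NULL,
                       expected_qc_conc = NULL, lod_frac = 0.5,
                       tukey_k = 3, dopa_quantile = 0.95,
                       dopa_analyte = "DOPA",
                       indicators_from = c("raw", "normalized")) {
  indicators_from <- match.arg(indicators_from)
  stopifnot(inherits(table, "analyte_table"))
  validate_sample_meta(meta)
  meta <- meta[match(rownames(table$values), meta$sample_id), , drop = FALSE]
  .assert(!anyNA(meta$sample_id), "metadata missing for some samples")

  flags <- list()
  if (!is.null(expected_qc_conc)) {
    qc_ids <- meta$sample_id[meta$group == "QC"]
    qres <- quantify_linear(table, qc_ids, expected_qc_conc)
    table <- qres$table
    flags$unquantified <- qres$unquantified
  }
  lod <- compute_lod(blanks)

  imp <- impute_covariates(meta)
  meta <- imp$meta

  regions <- unique(meta$region)
  region_out <- list()
  dopa_all <- numeric(0)
  for (rg in regions) {
    ids <- meta$sample_id[meta$region == rg]
    tab_r <- at_subset(table, samples = ids)
    meta_r <- meta[match(ids, meta$sample_id), , drop = FALSE]

    fl <- filter_below_lod(tab_r, lod, meta_r, frac = lod_frac)
    zi <- interpolate_zeros(fl$table)
    tab_r <- zi$table

    if (!is.null(indicator_defs) && indicators_from == "raw") {
      ind <- compute_indicators(tab_r, indicator_defs)
      tab_r <- analyte_table(cbind(tab_r$values, ind$table$values),
                             rbind(tab_r$annotations,
                                   ind$table$annotations))
      ind_flagged <- ind$flagged
    } else ind_flagged <- character(0)

    nm <- plate_normalize(tab_r, meta_r)
    tab_n <- nm$table

    if (!is.null(indicator_defs) && indicators_from == "normalized") {
      ind <- compute_indicators(tab_n, indicator_defs)
      ind_n <- plate_normalize(ind$table, meta_r)
      tab_n <- analyte_table(cbind(tab_n$values, ind_n$table$values),
                             rbind(tab_n$annotations,
                                   ind_n$table$annotations))
      ind_flagged <- ind$flagged
    }

    if (dopa_analyte %in% colnames(tab_n$values)) {
      dv <- tab_n$values[, dopa_analyte]
      names(dv) <- rownames(tab_n$values)
      dopa_all <- c(dopa_all, dv)
    }

    subj <- meta_r$group != "QC"
    ctrl <- meta_r$group == "CTRL"
    v <- tab_n$values
    z <- matrix(NA_real_, sum(subj), ncol(v),
                dimnames = list(rownames(v)[subj], colnames(v)))
    rec <- data.frame(analyte_id = colnames(v), lambda = NA_real_,
                      fence_lower = NA_real_, fence_upper = NA_real_,
                      k = tukey_k, center = NA_real_, scale = NA_real_,
                      n_adjusted = 0L, flagged = FALSE,
                      stringsAsFactors = FALSE)
    for (j in seq_len(ncol(v))) {
      x <- v[subj, j]
      if (sum(is.finite(x)) < 10 || all(!is.finite(x))) {
        rec$flagged[j] <- TRUE
        next
      }
      bc <- boxcox_fit_transform(x)
      rec$lambda[j] <- bc$lambda
      if (bc$flagged) { rec$flagged[j] <- TRUE; next }
      tf <- tukey_fence(bc$values, k = tukey_k)
      rec$fence_lower[j] <- tf$lower
      rec$fence_upper[j] <- tf$upper
      rec$n_adjusted[j] <- tf$n_adjusted
      st <- standardize_to_controls(tf$values, ctrl[subj])
      rec$center[j] <- st$center
      rec$scale[j] <- st$scale
      if (st$flagged) { rec$flagged[j] <- TRUE; next }
      z[, j] <- st$values
    }
    region_out[[rg]] <- list(
      values = z[, !rec$flagged, drop = FALSE],
      normalized = tab_n,
      annotations = tab_n$annotations,
      transform_record = rec,
      normalization = list(quotients = nm$quotients,
                           reference = nm$reference),
      removed_below_lod = fl$removed,
      below_lod = fl$below_lod,
      zero_flagged = zi$flagged,
      indicator_flagged = ind_flagged
    )
  }

  levodopa <- if (length(dopa_all)) {
    classify_levodopa(dopa_all, meta, quantile = dopa_quantile)
  } else NULL

  structure(list(regions = region_out, levodopa = levodopa, meta = meta,
                 lod = lod, imputation_log = imp$log, flags = flags,
                 options = list(lod_frac = lod_frac, tukey_k = tukey_k,
                                dopa_quantile = dopa_quantile,
                                dopa_analyte = dopa_analyte,
                                indicators_from = indicators_from)),
            class = "neurometab_prep")
}

#' @export
print.neurometab_prep <- function(x, ...) {
  cat("Preprocessed metabolomics cohort\n")
  for (rg in names(x$regions)) {
    r <- x$regions[[rg]]
    cat(sprintf("  %s: %d samples x %d analysis-ready analytes (%d removed below LOD, %d flagged)\n",
                rg, nrow(r$values), ncol(r$values),
                length(r$removed_below_lod), sum(r$transform_record$flagged)))
  }
  if (!is.null(x$levodopa)) print(x$levodopa)
  invisible(x)
}
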