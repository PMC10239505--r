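#' Analyte table: samples x analytes with per-analyte annotations
#'
#' The central data container of the pipeline: a numeric matrix of
#' non-negative analyte values (area ratios or concentrations in uM;
#' missing values allowed) with sample identifiers as row names and
#' analyte identifiers as column names, plus a per-analyte annotation
#' table giving the acquisition method (\code{"LC"} liquid chromatography
#' or \code{"FIA"} flow injection analysis), the analyte type
#' (\code{"measured"} or \code{"calculated"}) and a free-text class label.
#' The method x type combination later defines the strata for false
#' discovery rate control.
#'
#' @param values numeric matrix, samples in rows, analytes in columns,
#'   with complete dimnames. Negative finite values are rejected.
#' @param annotations data frame with columns \code{analyte_id},
#'   \code{method}, \code{analyte_type} and optionally \code{class};
#'   one row per column of \code{values}.
#' @return An object of class \code{analyte_table}: a list with elements
#'   \code{values} and \code{annotations}.
#' @export
analyte_table <- function(values, annotations) {
  .assert(is.matrix(values) && is.numeric(values),
          "`values` must be a numeric matrix")
  .assert(!is.null(rownames(values)) && !is.null(colnames(values)),
          "`values` must have sample row names and analyte column names")
  .assert(!anyDuplicated(rownames(values)), "duplicated sample ids")
  .assert(!anyDuplicated(colnames(values)), "duplicated analyte ids")
  fin <- is.finite(values)
  .assert(!any(values[fin] < 0), "negative analyte values are not allowed")
  .assert(is.data.frame(annotations), "`annotations` must be a data frame")
  .assert(all(c("analyte_id", "method", "analyte_type") %in%
                names(annotations)),
          "annotations need columns analyte_id, method, analyte_type")
  if (is.null(annotations$class)) annotations$class <- NA_character_
  annotations <- annotations[match(colnames(values),
                                   annotations$analyte_id), , drop = FALSE]
  .assert(!anyNA(annotations$analyte_id),
          "annotation missing for at least one analyte")
  .assert(all(annotations$method %in% c("LC", "FIA")),
          "analyte method must be 'LC' or 'FIA'")
  .assert(all(annotations$analyte_type %in% c("measured", "calculated")),
          "analyte_type must be 'measured' or 'calculated'")
  rownames(annotations) <- NULL
  structure(list(values = values, annotations = annotations),
            class = "analyte_table")
}

#' @export
print.analyte_table <- function(x, ...) {
  cat(sprintf("analyte_table: %d samples x %d analytes\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$annotations$method, x$annotations$analyte_type)
  print(tab)
  n_miss <- sum(is.na(x$values))
  cat(sprintf("missing cells: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$values)))
  invisible(x)
}

#' @export
dim.analyte_table <- function(x) dim(x$values)

# subset by sample ids and/or analyte ids, keeping annotations aligned
#' Subset an analyte table
#'
#' @param x an \code{analyte_table}.
#' @param samples,analytes character vectors of ids to keep (default all).
#' @return A new \code{analyte_table}.
#' @export
at_subset <- function(x, samples = NULL, analytes = NULL) {
  stopifnot(inherits(x, "analyte_table"))
  v <- x$values
  if (!is.null(samples)) {
    .assert(all(samples %in% rownames(v)), "unknown sample id in subset")
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(analytes)) {
    .assert(all(analytes %in% colnames(v)), "unknown analyte id in subset")
    v <- v[, analytes, drop = FALSE]
  }
  ann <- x$annotations[match(colnames(v), x$annotations$analyte_id), ,
                       drop = FALSE]
  analyte_table(v, ann)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample metadata contract: required identifier and design
#' columns, valid group and region levels, positive post-mortem collection
#' interval (\code{pmci}, hours) and freezer storage time (years) for
#' subject samples (both enter the models log-transformed), and the
#' structural expectation that the dementia group has no putamen samples
#' (a warning if violated, since that is a fact of the study design rather
#' than a hard invariant of the code).
#'
#' @param meta data frame with columns \code{sample_id}, \code{subject_id},
#'   \code{group} (CTRL, PD-CN, PD-MCI, PD-D or QC), \code{region}
#'   (cortex/putamen), \code{plate_id}, and for subject samples the
#'   covariates \code{age}, \code{sex} (M/F), \code{education}, \code{bmi},
#'   comorbidity flags \code{hyperlipidemia}, \code{diabetes},
#'   \code{renal_insufficiency}, \code{hypothyroidism}, \code{pmci},
#'   \code{storage}; optional progression scores and \code{dopa_level}.
#' @return the validated data frame (invisibly unchanged).
#' @export
validate_sample_meta <- function(meta) {
  req <- c("sample_id", "subject_id", "group", "region", "plate_id")
  .assert(all(req %in% names(meta)),
          paste("sample metadata must contain:", paste(req, collapse = ", ")))
  .assert(!anyDuplicated(meta$sample_id), "duplicated sample ids in metadata")
  .assert(all(meta$group %in% c("CTRL", "PD-CN", "PD-MCI", "PD-D", "QC")),
          "invalid group label")
  .assert(all(meta$region %in% c("cortex", "putamen")),
          "invalid region label")
  subj <- meta$group != "QC"
  if (any(subj)) {
    for (col in c("pmci", "storage")) {
      if (col %in% names(meta)) {
        v <- meta[[col]][subj]
        .assert(all(is.na(v) | v > 0),
                sprintf("%s must be positive (log-transformed in models)", col))
      }
    }
    if ("sex" %in% names(meta)) {
      .assert(all(meta$sex[subj] %in% c("M", "F") | is.na(meta$sex[subj])),
              "sex must be 'M' or 'F'")
    }
  }
  if (any(meta$group == "PD-D" & meta$region == "putamen")) {
    warning("PD-D putamen samples present; the study design has none",
            call. = FALSE)
  }
  invisible(meta)
}
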