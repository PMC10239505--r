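#' Read a wide-format analyte table with its annotation file
#'
#' Reads a CSV or TSV (auto-detected from the header line) whose first
#' column holds sample identifiers and whose remaining columns are
#' analytes, together with an annotation table mapping each analyte to its
#' acquisition method and type. Cells equal to \code{""}, \code{"NA"} or
#' \code{"NaN"} (case-insensitive) become missing values; any other
#' non-numeric cell is treated as corrupt data and raises an error.
#'
#' @param path path to the analyte value table.
#' @param annotation_path path to a CSV/TSV with columns
#'   \code{analyte_id}, \code{method}, \code{analyte_type}
#'   and optionally \code{class}.
#' @return an \code{\link{analyte_table}}.
#' @export
read_analyte_table <- function(path, annotation_path) {
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8")
  .assert(ncol(raw) >= 2, "analyte table needs a sample id column and data")
  sample_ids <- raw[[1]]
  .assert(!anyDuplicated(sample_ids), "duplicated sample ids in file")
  analyte_ids <- colnames(raw)[-1]
  .assert(!anyDuplicated(analyte_ids), "duplicated analyte columns in file")
  vals <- vapply(seq_along(analyte_ids), function(j) {
    .parse_numeric_strict(raw[[j + 1]],
                          sprintf("analyte column '%s'", analyte_ids[j]))
  }, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(sample_ids, analyte_ids))
  ann <- utils::read.table(annotation_path, sep = .detect_sep(annotation_path),
                           header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  missing_ann <- setdiff(analyte_ids, ann$analyte_id)
  .assert(length(missing_ann) == 0,
          paste("annotation missing for analyte(s):",
                paste(utils::head(missing_ann, 5), collapse = ", ")))
  analyte_table(vals, ann)
}

#' Read a sample metadata table
#'
#' @param path CSV/TSV of per-sample metadata; see
#'   \code{\link{validate_sample_meta}} for the expected columns.
#' @return validated data frame.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.table(path, sep = .detect_sep(path), header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            fileEncoding = "UTF-8")
  num_cols <- intersect(names(meta),
                        c("age", "education", "bmi", "pmci", "storage",
                          "hyperlipidemia", "diabetes", "renal_insufficiency",
                          "hypothyroidism", "pd_duration", "updrs_m", "usslb",
                          "mmse", "plaque_density", "tangle_density",
                          "dopa_level"))
  for (col in num_cols) {
    meta[[col]] <- .parse_numeric_strict(meta[[col]],
                                         sprintf("metadata column '%s'", col))
  }
  validate_sample_meta(meta)
  meta
}

#' Read metabolite set definitions in GMT format
#'
#' Standard GMT: one set per line, tab-separated
#' \code{set_id <tab> description <tab> member ...}. Duplicate members
#' within a set are collapsed; members not present in any analyte table are
#' retained here and filtered later at mapping time (one measured analyte
#' may represent several isoforms and so belong to many sets).
#'
#' @param path path to the GMT file.
#' @return a \code{metabolite_set_db}: list with \code{sets} (named list of
#'   member id vectors) and \code{descriptions} (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need set_id, description and >=1 member",
                   i, length(fields)), call. = FALSE)
    }
    id <- fields[1]
    .assert(!id %in% names(sets), sprintf("duplicated set id '%s'", id))
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    sets[[id]] <- members
    desc[id] <- fields[2]
  }
  structure(list(sets = sets, descriptions = desc),
            class = "metabolite_set_db")
}

#' @export
print.metabolite_set_db <- function(x, ...) {
  cat(sprintf("metabolite_set_db: %d sets, median size %s\n",
              length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else "-"))
  invisible(x)
}

#' Read metabolic indicator definitions
#'
#' Indicators are derived analytes defined as sums or ratios of measured
#' metabolites (for instance enzyme-activity or synthesis proxies). The
#' file has columns \code{indicator_id}, \code{kind} (\code{sum} or
#' \code{ratio}), \code{numerator} and \code{denominator}, the latter two
#' being semicolon-separated analyte id lists (denominator empty for sums).
#'
#' @param path CSV/TSV path.
#' @return data frame with list columns \code{numerator}, \code{denominator}.
#' @export
read_indicator_defs <- function(path) {
  df <- utils::read.table(path, sep = .detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", colClasses = "character")
  .assert(all(c("indicator_id", "kind", "numerator") %in% names(df)),
          "indicator file needs indicator_id, kind, numerator[, denominator]")
  if (is.null(df$denominator)) df$denominator <- ""
  split_members <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(m) { m <- trimws(m); m[nzchar(m)] })
  }
  defs <- data.frame(indicator_id = df$indicator_id, kind = df$kind,
                     stringsAsFactors = FALSE)
  defs$numerator <- split_members(df$numerator)
  defs$denominator <- split_members(df$denominator)
  validate_indicator_defs(defs)
  defs
}

#' @rdname read_indicator_defs
#' @param defs indicator definition data frame to validate.
#' @export
validate_indicator_defs <- function(defs) {
  .assert(all(defs$kind %in% c("sum", "ratio")),
          "indicator kind must be 'sum' or 'ratio'")
  .assert(all(lengths(defs$numerator) > 0),
          "indicator numerator must be non-empty")
  bad <- defs$kind == "sum" & lengths(defs$denominator) > 0
  .assert(!any(bad), "sum indicators must have an empty denominator")
  bad <- defs$kind == "ratio" & lengths(defs$denominator) == 0
  .assert(!any(bad), "ratio indicators need a denominator")
  invisible(defs)
}

# stable column order for result files
.result_columns <- function(df) {
  id_col <- intersect(c("analyte_id", "set_id"), names(df))
  lead <- c(id_col, intersect(c("region", "stratum", "term"), names(df)))
  stat <- intersect(c("beta", "se", "ci_low", "ci_high", "p", "q",
                      "n_effective", "D_plus", "n_mapped", "mean_abs_beta",
                      "auc", "n_pos", "n_neg", "converged"), names(df))
  c(lead, stat, setdiff(names(df), c(lead, stat)))
}

#' Write a result table to CSV (12 significant digit round-trip)
#'
#' Writes model fit or set enrichment results with a stable column order.
#' Numeric values are serialized with 12 significant digits so that
#' \code{read_results(write_results(x))} reproduces the values.
#'
#' @param results data frame of results (may be empty, header still written).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  .assert(is.data.frame(results), "`results` must be a data frame")
  results <- results[, .result_columns(results), drop = FALSE]
  out <- results
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           formatC(out[[col]], digits = 12, format = "g"))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop(sprintf("cannot write results to '%s': %s",
                                path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}
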