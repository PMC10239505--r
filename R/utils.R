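# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

# type-7 quantile (linear interpolation between order statistics);
# the single quantile convention used for DOPA thresholds and Tukey quartiles
.quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
}

#' Derive a deterministic sub-seed
#'
#' Deterministic sub-seed derivation: one RNG stream per analyte or
#' pipeline stage, so a single cohort seed reproduces any part of the
#' generation independently. The result stays below 2^31.
#'
#' @param seed base integer seed.
#' @param index stream index (stage number, analyte index, replicate id).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) * 7919 + as.numeric(index)) %% 2147483646
  as.integer(s) + 1L
}

# comma/tab auto-detection from the header line
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return(",")
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

# missing-value tokens accepted in numeric cells; any other non-numeric
# token is corrupt data and raises a hard error at the caller
.na_tokens <- c("", "na", "nan")

.parse_numeric_strict <- function(x, context) {
  x_chr <- trimws(as.character(x))
  is_na_tok <- tolower(x_chr) %in% .na_tokens | is.na(x)
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- !is_na_tok & is.na(out)
  if (any(bad)) {
    stop(sprintf("non-numeric value(s) in %s: %s", context,
                 paste(utils::head(unique(x_chr[bad]), 5), collapse = ", ")),
         call. = FALSE)
  }
  out[is_na_tok] <- NA_real_
  out
}

# tiny FNV-1a hash for run manifests (no external digest dependency)
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
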