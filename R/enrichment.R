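#' Map metabolite sets onto the analysed analytes
#'
#' Restricts each set to members present in the analysed table
#' (membership is many-to-many: one measured analyte may represent
#' several isoforms and belong to several sets), optionally appends a
#' custom microbial-metabolite set, and drops sets with fewer than
#' \code{min_size} mapped members.
#'
#' @param sets a \code{metabolite_set_db}.
#' @param analytes character vector of analysed analyte ids.
#' @param microbial_members optional member ids for the appended custom
#'   \code{"microbial"} set.
#' @param min_size minimum mapped members to retain a set (default 4).
#' @return data frame (set_id, set_name, n_mapped) with list column
#'   \code{members}; dropped-set count in attribute \code{"n_dropped"}.
#' @export
map_sets <- function(sets, analytes, microbial_members = NULL,
                     min_size = 4) {
  stopifnot(inherits(sets, "metabolite_set_db"))
  .assert(length(analytes) > 0, "empty analyte list")
  all_sets <- sets$sets
  desc <- sets$descriptions
  if (!is.null(microbial_members)) {
    all_sets[["microbial"]] <- unique(microbial_members)
    desc["microbial"] <- "custom microbial metabolite set"
  }
  mapped <- lapply(all_sets, function(m) intersect(unique(m), analytes))
  keep <- lengths(mapped) >= min_size
  out <- data.frame(set_id = names(all_sets)[keep],
                    set_name = unname(desc[names(all_sets)[keep]]),
                    n_mapped = unname(lengths(mapped)[keep]),
                    stringsAsFactors = FALSE)
  out$members <- unname(mapped[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# one-sided exact upper tail of D+ (Birnbaum-Tingey / Smirnov formula)
.ks_dplus_exact_p <- function(d, n) {
  if (d <= 0) return(1)
  if (d >= 1) return(0)
  jmax <- floor(n * (1 - d))
  j <- 0:jmax
  # log-space for stability; j = 0 term handled via its closed form
  terms <- vapply(j, function(jj) {
    a <- jj / n + d
    b <- 1 - d - jj / n
    if (b < 0) return(0)
    if (jj == 0) return((1 - d)^n / d)
    exp(lchoose(n, jj) + (jj - 1) * log(a) +
          (n - jj) * ifelse(b == 0, 0, log(b))) * (b > 0 | n == jj)
  }, 0)
  p <- d * sum(terms)
  min(max(p, 0), 1)
}

#' One-sided Kolmogorov-Smirnov test of p-values against uniform
#'
#' Computes \eqn{D^+ = \max_i (i/n - p_{(i)})} over the sorted member
#' p-values (right-continuous empirical CDF, so ties are handled by the
#' highest index) and the one-sided tail probability: the exact
#' Birnbaum-Tingey formula for small sets (\eqn{n \le} \code{exact_max})
#' and the asymptotic tail \eqn{\exp(-2 n D^{+2})} otherwise. Small
#' member p-values push the empirical CDF above the diagonal, giving a
#' large \eqn{D^+} and a small set p-value.
#'
#' @param p_members member p-values in (0, 1]; at least 4.
#' @param method \code{"auto"} (exact up to \code{exact_max}),
#'   \code{"exact"} or \code{"asymptotic"}.
#' @param exact_max largest n using the exact formula under
#'   \code{"auto"}.
#' @return list with \code{D_plus} and \code{p} (clipped to (0, 1]).
#' @export
ks_uniform_test <- function(p_members, method = c("auto", "exact",
                                                  "asymptotic"),
                            exact_max = 10) {
  method <- match.arg(method)
  n <- length(p_members)
  .assert(n >= 4, "need at least 4 member p-values")
  .assert(all(p_members > 0 & p_members <= 1),
          "member p-values must lie in (0, 1]")
  ps <- sort(p_members)
  d_plus <- max(seq_len(n) / n - ps)
  d_plus <- max(d_plus, 0)
  use_exact <- switch(method, exact = TRUE, asymptotic = FALSE,
                      auto = n <= exact_max)
  p <- if (use_exact) {
    .ks_dplus_exact_p(d_plus, n)
  } else {
    exp(-2 * n * d_plus^2)
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  list(D_plus = d_plus, p = p)
}

#' Metabolite-set enrichment over model p-values
#'
#' Covariate-adjusted set enrichment: because the member p-values come
#' from the main regression models, the covariates are already accounted
#' for. For each mapped set the member p-values of the chosen term are
#' tested against uniformity with the one-sided KS statistic, the mean
#' absolute coefficient over members is reported as the set effect size,
#' and set p-values are FDR-adjusted with q-values. Analytes mapped to a
#' set but lacking a p-value (skipped models) are excluded and the mapped
#' size recounted.
#'
#' @param fit fit-result data frame (from \code{\link{run_differential}}
#'   or \code{\link{run_progression}}).
#' @param sets a \code{metabolite_set_db}.
#' @param term coefficient whose p-values are tested (must exist).
#' @param region region whose fits are used (default: the single region
#'   present).
#' @param microbial_members,min_size passed to \code{\link{map_sets}}.
#' @param method KS tail method, see \code{\link{ks_uniform_test}}.
#' @return data frame: set_id, term, D_plus, p, q, n_mapped,
#'   mean_abs_beta.
#' @export
run_enrichment <- function(fit, sets, term, region = NULL,
                           microbial_members = NULL, min_size = 4,
                           method = "auto") {
  .assert(term %in% fit$term,
          sprintf("term '%s' absent from fit results", term))
  sub <- fit[fit$term == term, , drop = FALSE]
  if (!is.null(region)) sub <- sub[sub$region == region, , drop = FALSE]
  sub <- sub[!is.na(sub$p), , drop = FALSE]
  .assert(nrow(sub) > 0, "no usable p-values for the chosen term")
  mapped <- map_sets(sets, sub$analyte_id,
                     microbial_members = microbial_members,
                     min_size = min_size)
  rows <- list()
  for (i in seq_len(nrow(mapped))) {
    members <- intersect(mapped$members[[i]], sub$analyte_id)
    if (length(members) < min_size) next
    mi <- match(members, sub$analyte_id)
    ks <- ks_uniform_test(sub$p[mi], method = method)
    rows[[mapped$set_id[i]]] <- data.frame(
      set_id = mapped$set_id[i], term = term,
      D_plus = ks$D_plus, p = ks$p,
      n_mapped = length(members),
      mean_abs_beta = mean(abs(sub$beta[mi])),
      stringsAsFactors = FALSE)
  }
  .assert(length(rows) > 0, "no set passed the size threshold")
  out <- do.call(rbind, rows)
  out$q <- suppressMessages(qvalues(out$p))
  rownames(out) <- NULL
  out[, c("set_id", "term", "D_plus", "p", "q", "n_mapped",
          "mean_abs_beta")]
}

#' Wide set-by-term enrichment matrix
#'
#' Combines several \code{\link{run_enrichment}} results (for instance
#' the group terms of the differential analysis side by side) into one
#' wide table with p, q and mean absolute effect per set and term.
#'
#' @param ... \code{run_enrichment} result data frames.
#' @return data frame, one row per set.
#' @export
enrichment_matrix <- function(...) {
  parts <- list(...)
  .assert(length(parts) >= 1, "need at least one enrichment result")
  ids <- sort(unique(unlist(lapply(parts, function(d) d$set_id))))
  out <- data.frame(set_id = ids, stringsAsFactors = FALSE)
  for (d in parts) {
    tm <- unique(d$term)
    mi <- match(ids, d$set_id)
    out[[paste0("p_", tm)]] <- d$p[mi]
    out[[paste0("q_", tm)]] <- d$q[mi]
    out[[paste0("mean_abs_beta_", tm)]] <- d$mean_abs_beta[mi]
  }
  out
}
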