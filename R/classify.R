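#' AUC with DeLong confidence interval
#'
#' Computes the area under the ROC curve as the Mann-Whitney probability
#' (ties counted one half) and its standard error with DeLong's
#' placement-value estimator:
#' \eqn{\widehat{var} = s^2_{10}/n_1 + s^2_{01}/n_0}, where the placement
#' value of a positive is its mean pairwise win rate against the
#' negatives and vice versa. The orientation is corrected so that
#' AUC >= 0.5, and the 95\% CI \eqn{AUC \pm 1.96\, SE} is clipped to
#' [0, 1].
#'
#' @param scores numeric vector of finite scores.
#' @param labels binary labels (logical or 0/1; 1 = positive class).
#' @param level confidence level.
#' @return data frame row: auc, se, ci_low, ci_high, n_pos, n_neg,
#'   flipped (TRUE if the orientation was reversed).
#' @export
auc_delong <- function(scores, labels, level = 0.95) {
  labels <- as.integer(as.logical(labels))
  .assert(length(scores) == length(labels), "length mismatch")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  .assert(all(is.finite(scores)), "scores must be finite")
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  .assert(length(x) >= 1 && length(y) >= 1,
          "both classes must be present")
  placements <- function(a, b) {
    # mean over b of win indicator for each element of a, ties count 1/2
    vapply(a, function(ai) mean((ai > b) + 0.5 * (ai == b)), 0)
  }
  v10 <- placements(x, y)
  auc <- mean(v10)
  flipped <- FALSE
  if (auc < 0.5) {
    flipped <- TRUE
    x <- -x; y <- -y
    v10 <- placements(x, y)
    auc <- mean(v10)
  }
  v01 <- 1 - placements(y, x)
  n1 <- length(x); n0 <- length(y)
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(auc = auc, se = se,
             ci_low = max(0, auc - z * se),
             ci_high = min(1, auc + z * se),
             n_pos = n1, n_neg = n0, flipped = flipped)
}

#' Rank analytes by dementia discrimination (AUC)
#'
#' Univariate discrimination of demented (PD-D) versus non-demented
#' (PD-CN and PD-MCI together) PD subjects, per analyte, computed in
#' three strata: all PD subjects, acutely levodopa-positive (L+) only and
#' L- only — the stratified analysis captures the interaction of the
#' discriminator with acute medication presence. Within each stratum
#' analytes are ranked by AUC, ties broken by narrower confidence
#' interval and then analyte id. Strata with fewer than \code{min_class}
#' subjects in either class are skipped with a note.
#'
#' @param prep a \code{\link{preprocess}} result.
#' @param region region analysed (default \code{"cortex"}, the region
#'   with dementia samples).
#' @param min_class minimum per-class size per stratum.
#' @return data frame with analyte_id, stratum, auc, ci_low, ci_high,
#'   n_pos, n_neg, rank; skipped strata in attribute \code{"skipped"}.
#' @export
best_discriminator <- function(prep, region = "cortex", min_class = 3) {
  stopifnot(inherits(prep, "neurometab_prep"))
  r <- prep$regions[[region]]
  .assert(!is.null(r), sprintf("region '%s' not present", region))
  ids <- rownames(r$values)
  meta <- prep$meta[match(ids, prep$meta$sample_id), , drop = FALSE]
  is_pd <- meta$group %in% c("PD-CN", "PD-MCI", "PD-D")
  label <- as.integer(meta$group == "PD-D")
  st <- prep$levodopa$status
  lpos <- st$status[match(ids, st$sample_id)] == "L+"
  lpos[is.na(lpos)] <- FALSE
  strata <- list(`all PD` = is_pd,
                 `L+ only` = is_pd & lpos,
                 `L- only` = is_pd & !lpos)
  rows <- list(); skipped <- character(0)
  for (snm in names(strata)) {
    sel <- strata[[snm]]
    if (sum(label[sel] == 1) < min_class ||
        sum(label[sel] == 0) < min_class) {
      skipped <- c(skipped, snm)
      next
    }
    for (m in colnames(r$values)) {
      sc <- r$values[sel, m]
      ok <- is.finite(sc)
      if (sum(label[sel][ok] == 1) < min_class ||
          sum(label[sel][ok] == 0) < min_class) next
      a <- auc_delong(sc[ok], label[sel][ok])
      a$analyte_id <- m
      a$stratum <- snm
      rows[[paste(snm, m)]] <- a
    }
  }
  .assert(length(rows) > 0, "no stratum had enough subjects per class")
  out <- do.call(rbind, rows)
  out$ci_width <- out$ci_high - out$ci_low
  out <- out[order(out$stratum, -out$auc, out$ci_width, out$analyte_id), ,
             drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$stratum,
                         FUN = seq_along)
  rownames(out) <- NULL
  out <- out[, c("analyte_id", "stratum", "auc", "ci_low", "ci_high",
                 "n_pos", "n_neg", "rank")]
  attr(out, "skipped") <- skipped
  out
}
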