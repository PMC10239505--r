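#' Linear model with group-specific residual variances (iterative FGLS)
#'
#' Fits a multivariable linear model without assuming equal residual
#' variance across subject groups, the working model of the differential
#' and progression analyses. Estimation is by iterative feasible
#' generalized least squares: ordinary least squares residuals give
#' per-group variance estimates, the model is refit by weighted least
#' squares with weights \eqn{1/\hat\sigma^2_g}, and the two steps are
#' iterated until the relative change in coefficients falls below
#' \code{tol} (default 1e-8) or \code{maxit} iterations.
#'
#' Per-group variances are estimated as
#' \eqn{\hat\sigma^2_g = RSS_g / (n_g - \mathrm{tr}(H)_g)}, where
#' \eqn{\mathrm{tr}(H)_g} is the sum of weighted-fit leverages over the
#' group's rows: the model degrees of freedom are charged to the groups
#' that actually absorb them (group indicators and interaction terms
#' consume leverage inside their own group, which a proportional
#' allocation would under-correct). Wald t
#' statistics use Satterthwaite degrees of freedom per coefficient by
#' default: each coefficient's sampling variance is a weighted sum of the
#' group variance estimates, and
#' \eqn{\nu_j = (\sum_g u_{jg})^2 / \sum_g u_{jg}^2/\nu_g} with
#' \eqn{u_{jg}} the variance share contributed by group \eqn{g} and
#' \eqn{\nu_g} that group's variance degrees of freedom. This keeps the
#' extreme tail calibrated for coefficients that lean on small groups,
#' where a global \eqn{n - p} reference is anticonservative. The global
#' residual-df reference and the normal approximation remain available
#' via \code{df_method}.
#'
#' Rows with missing response or regressors are dropped; the number of
#' samples effectively used is recorded as \code{nobs}.
#'
#' @param formula model formula.
#' @param data data frame containing the variables and the variance group
#'   column.
#' @param variance_groups name of a column of \code{data} (or a vector of
#'   labels, recycled against the rows of \code{data}) defining the groups
#'   whose residual variances are estimated separately. \code{NULL}
#'   constrains all variances equal, in which case the fit reduces exactly
#'   to ordinary least squares.
#' @param tol,maxit convergence tolerance on the relative coefficient
#'   change and maximum number of FGLS iterations.
#' @param df_method \code{"satterthwaite"} (per-coefficient df, default),
#'   \code{"residual"} (t with n - p df) or \code{"normal"}.
#' @return an object of class \code{"hetlm"} with the usual accessor
#'   methods (\code{coef}, \code{vcov}, \code{confint}, \code{summary},
#'   \code{predict}, \code{residuals}, \code{fitted}, \code{simulate}).
#' @examples
#' d <- data.frame(y = rnorm(60), g = rep(c("a", "b", "c"), each = 20))
#' fit <- hetlm(y ~ g, d, variance_groups = "g")
#' summary(fit)
#' @export
hetlm <- function(formula, data, variance_groups = NULL,
                  tol = 1e-8, maxit = 50,
                  df_method = c("satterthwaite", "residual", "normal")) {
  df_method <- match.arg(df_method)
  cl <- match.call()
  if (is.character(variance_groups) && length(variance_groups) == 1L &&
      variance_groups %in% names(data)) {
    grp_all <- as.character(data[[variance_groups]])
  } else if (is.null(variance_groups)) {
    grp_all <- rep("all", nrow(data))
  } else {
    .assert(length(variance_groups) == nrow(data),
            "variance_groups must name a column or match nrow(data)")
    grp_all <- as.character(variance_groups)
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  keep <- stats::complete.cases(X) & is.finite(y) & !is.na(grp_all)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  grp <- factor(grp_all[keep])
  n <- nrow(X); p <- ncol(X)
  .assert(n > p, "fewer usable observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tab <- table(grp)
  .assert(all(tab >= 2), "each variance group needs >= 2 usable samples")

  gidx <- split(seq_len(n), grp)
  w <- rep(1, n)
  beta_old <- rep(Inf, p)
  converged <- FALSE
  iter <- 0L
  s2 <- stats::setNames(rep(NA_real_, nlevels(grp)), levels(grp))
  repeat {
    iter <- iter + 1L
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    res <- as.vector(y - X %*% beta)
    # weighted-fit leverages: h_i = w_i x_i' (X'WX)^-1 x_i
    A <- solve(crossprod(X * sqrt(w)))
    h <- rowSums((X %*% A) * X) * w
    for (g in names(gidx)) {
      ix <- gidx[[g]]
      denom <- max(length(ix) - sum(h[ix]), 1)
      s2[g] <- sum(res[ix]^2) / denom
    }
    if (any(s2 <= 0)) stop("degenerate zero residual variance in a group",
                           call. = FALSE)
    # scaled coefficient change: near-zero coefficients move at machine
    # noise and must not block convergence
    delta <- max(abs(beta - beta_old)) / max(1, max(abs(beta)))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= maxit) break
    beta_old <- beta
    w <- 1 / s2[as.character(grp)]
  }

  w <- 1 / s2[as.character(grp)]
  XtWX <- crossprod(X * sqrt(w))
  V <- solve(XtWX)
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  df_res <- n - p
  A <- solve(XtWX)
  h <- rowSums((X %*% A) * X) * w
  nu_g <- vapply(gidx, function(ix) {
    max(length(ix) - sum(h[ix]), 1)
  }, 0)
  df_coef <- if (df_method == "satterthwaite" && length(gidx) > 1) {
    # variance share of group g in coefficient j: [A Xg'Xg A]_jj / s2_g,
    # with A = (X'WX)^-1; shares sum to A_jj
    shares <- vapply(names(gidx), function(g) {
      Xg <- X[gidx[[g]], , drop = FALSE]
      B <- V %*% crossprod(Xg) %*% V
      diag(B) / s2[g]
    }, numeric(p))
    shares <- matrix(shares, nrow = p)
    tot <- rowSums(shares)
    pmin(tot^2 / rowSums(sweep(shares^2, 2, nu_g, "/")), df_res)
  } else {
    rep(df_res, p)
  }
  names(df_coef) <- colnames(X)
  tval <- beta / se
  pval <- if (df_method == "normal") {
    2 * stats::pnorm(-abs(tval))
  } else {
    2 * stats::pt(-abs(tval), df = df_coef)
  }

  structure(list(
    coefficients = beta, se = se, vcov = V,
    sigma_groups = sqrt(s2),
    t_values = tval, p_values = pval,
    df_residual = df_res, df_coef = df_coef, df_method = df_method,
    nobs = n, rank = p,
    fitted.values = as.vector(X %*% beta),
    residuals = as.vector(y - X %*% beta),
    weights = w, groups = grp,
    iterations = iter, converged = converged,
    terms = attr(mf, "terms"), call = cl,
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    used_rows = which(keep)
  ), class = "hetlm")
}

#' @export
coef.hetlm <- function(object, ...) object$coefficients

#' @export
vcov.hetlm <- function(object, ...) object$vcov

#' @export
nobs.hetlm <- function(object, ...) object$nobs

#' @export
fitted.hetlm <- function(object, ...) object$fitted.values

#' @export
df.residual.hetlm <- function(object, ...) object$df_residual

#' @export
residuals.hetlm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "pearson") {
    r <- r / object$sigma_groups[as.character(object$groups)]
  }
  r
}

#' @export
confint.hetlm <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  crit <- if (object$df_method == "normal") {
    stats::qnorm(1 - a)
  } else {
    stats::qt(1 - a, df = object$df_coef[parm])
  }
  out <- cbind(cf[parm] - crit * object$se[parm],
               cf[parm] + crit * object$se[parm])
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  out
}

#' @export
predict.hetlm <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) {
    yhat <- object$fitted.values
    if (!se.fit) return(yhat)
    stop("se.fit requires `newdata`", call. = FALSE)
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  yhat <- as.vector(X %*% object$coefficients)
  if (!se.fit) return(yhat)
  sefit <- sqrt(rowSums((X %*% object$vcov) * X))
  list(fit = yhat, se.fit = sefit)
}

#' @export
simulate.hetlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sg <- object$sigma_groups[as.character(object$groups)]
  out <- replicate(nsim, object$fitted.values +
                     stats::rnorm(object$nobs, 0, sg), simplify = FALSE)
  out <- as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' @export
print.hetlm <- function(x, ...) {
  cat("Heteroscedastic linear model (iterative FGLS)\n")
  cat("Call: "); print(x$call)
  cat("\nCoefficients:\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("\nGroup residual SDs: %s\n",
              paste(sprintf("%s=%.3g", names(x$sigma_groups),
                            x$sigma_groups), collapse = ", ")))
  cat(sprintf("n = %d, iterations = %d, converged = %s\n",
              x$nobs, x$iterations, x$converged))
  invisible(x)
}

#' @export
summary.hetlm <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$t_values,
               `Pr(>|t|)` = object$p_values,
               ci_low = ci[, 1], ci_high = ci[, 2])
  out <- list(call = object$call, coefficients = tab,
              sigma_groups = object$sigma_groups,
              df_residual = object$df_residual, nobs = object$nobs,
              iterations = object$iterations, converged = object$converged)
  class(out) <- "summary.hetlm"
  out
}

#' @export
print.summary.hetlm <- function(x, ...) {
  cat("Heteroscedastic linear model (iterative FGLS)\n")
  cat("Call: "); print(x$call)
  cat("\n")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE],
                      P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nGroup residual SDs: %s\n",
              paste(sprintf("%s=%.3g", names(x$sigma_groups),
                            x$sigma_groups), collapse = ", ")))
  cat(sprintf("Residual df: %d on %d observations; %d FGLS iteration(s)%s\n",
              x$df_residual, x$nobs, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Joint Wald test of a set of coefficients
#'
#' Tests the null that all named coefficients are zero using the FGLS
#' coefficient covariance, referred to an F distribution with
#' (k, n - p) degrees of freedom. Used for the heteroscedastic analysis
#' of variance in the cohort characteristics table.
#'
#' @param object a \code{hetlm} fit.
#' @param parm character vector of coefficient names.
#' @return list with \code{statistic} (F), \code{df1}, \code{df2},
#'   \code{p.value}.
#' @export
wald_test <- function(object, parm) {
  stopifnot(inherits(object, "hetlm"))
  .assert(all(parm %in% names(object$coefficients)),
          "unknown coefficient in `parm`")
  b <- object$coefficients[parm]
  V <- object$vcov[parm, parm, drop = FALSE]
  k <- length(parm)
  stat <- as.numeric(t(b) %*% solve(V, b)) / k
  p <- stats::pf(stat, k, object$df_residual, lower.tail = FALSE)
  list(statistic = stat, df1 = k, df2 = object$df_residual, p.value = p)
}
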