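#' OLS with cluster-robust (CR1) standard errors
#'
#' Fits an ordinary least squares model and computes the CR1 cluster-robust
#' covariance: the sandwich estimator with small-sample factor
#' `G/(G-1) * (N-1)/(N-k)`, where `G` is the number of clusters, `N` the
#' number of observations and `k` the number of coefficients. Inference uses
#' a t reference distribution with `G - 1` degrees of freedom. With one
#' observation per cluster this reduces exactly to the HC1
#' heteroskedasticity-robust estimator.
#'
#' @param formula Model formula.
#' @param data data.frame (e.g. a [mu_alpha_table()]).
#' @param cluster Cluster variable: a column name or a vector of length
#'   `nrow(data)` (typically the participant id).
#' @return Object of class `erd_ols` with `print`, `summary`, `coef`,
#'   `vcov`, `confint` and `predict` methods.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4), x = c(0, 0, 1, 1), id = 1:4)
#' fit <- erd_ols(y ~ x, d, cluster = "id")
#' coef(fit)["x"]  # 2
#' @export
erd_ols <- function(formula, data, cluster) {
  cl_vec <- if (is.character(cluster) && length(cluster) == 1) {
    if (!cluster %in% names(data))
      stop("cluster column '", cluster, "' not found in data", call. = FALSE)
    data[[cluster]]
  } else cluster
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  omitted <- attr(mf, "na.action")
  if (!is.null(omitted)) cl_vec <- cl_vec[-omitted]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- stats::lm.fit(X, y)
    stop("singular design: collinear column(s) ",
         paste(colnames(X)[is.na(fit0$coefficients)], collapse = ", "),
         call. = FALSE)
  }
  cl_vec <- factor(cl_vec)
  G <- nlevels(cl_vec)
  if (G < 2) stop("insufficient clusters: need at least 2", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  u <- fit$residuals
  bread <- chol2inv(chol(crossprod(X)))
  Xu <- X * u
  scores <- rowsum(Xu, cl_vec)                 # G x k cluster score sums
  meat <- crossprod(scores)
  c_adj <- G / (G - 1) * (n - 1) / (n - k)
  V <- c_adj * bread %*% meat %*% bread
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))
  tval <- beta / se
  df <- G - 1
  structure(list(coefficients = beta, vcov = V, se = se, t = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df), n_obs = n,
                 n_clusters = G, formula = formula, terms = attr(mf, "terms"),
                 model = mf, cluster = cl_vec, residuals = u,
                 fitted = fit$fitted.values, xlevels = stats::.getXlevels(
                   attr(mf, "terms"), mf)),
            class = "erd_ols")
}

#' @export
coef.erd_ols <- function(object, ...) object$coefficients

#' @export
vcov.erd_ols <- function(object, ...) object$vcov

#' @export
confint.erd_ols <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) parm <- names(object$coefficients)
  q <- stats::qt(1 - (1 - level) / 2, object$df)
  out <- cbind(object$coefficients[parm] - q * object$se[parm],
               object$coefficients[parm] + q * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
predict.erd_ols <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(object$terms),
                           data = newdata, xlev = object$xlevels)
  drop(X %*% object$coefficients)
}

#' @export
residuals.erd_ols <- function(object, ...) object$residuals

#' @export
print.erd_ols <- function(x, ...) {
  cat(sprintf("OLS with CR1 cluster-robust SEs (%d obs, %d clusters, t(%d))\n",
              x$n_obs, x$n_clusters, x$df))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.erd_ols <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Cluster SE` = object$se,
               `t value` = object$t, `Pr(>|t|)` = object$p)
  structure(list(coefficients = tab, df = object$df, n_obs = object$n_obs,
                 n_clusters = object$n_clusters, formula = object$formula),
            class = "summary.erd_ols")
}

#' @export
print.summary.erd_ols <- function(x, ...) {
  cat("Formula:", deparse(x$formula), "\n")
  cat(sprintf("%d observations, %d clusters; t reference with %d df\n\n",
              x$n_obs, x$n_clusters, x$df))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Condition contrast from a clustered OLS fit
#'
#' Linear contrast `level1 - level2` of a factor's coefficients under the
#' CR1 covariance, with p from t(G-1) and an effect size
#' `d = estimate / pooled within-condition SD` of the outcome over the two
#' contrasted levels (`d_type = "residual"` uses the residual SD instead).
#'
#' @param fit An [erd_ols()] object.
#' @param term Factor name in the model.
#' @param level1,level2 Levels to contrast.
#' @param d_type Denominator of Cohen's d.
#' @return list of class `erd_contrast`: `estimate`, `se`, `t`, `df`, `p`,
#'   `d`, `levels`.
#' @export
erd_contrast <- function(fit, term, level1, level2,
                         d_type = c("pooled", "residual")) {
  d_type <- match.arg(d_type)
  stopifnot(inherits(fit, "erd_ols"))
  lev <- fit$xlevels[[term]]
  if (is.null(lev))
    stop("'", term, "' is not a factor in the fitted model", call. = FALSE)
  if (!all(c(level1, level2) %in% lev))
    stop("unknown level(s): ",
         paste(setdiff(c(level1, level2), lev), collapse = ", "),
         call. = FALSE)
  cn <- names(fit$coefficients)
  L <- stats::setNames(rep(0, length(cn)), cn)
  add <- function(L, level, sign) {
    nm <- paste0(term, level)
    if (nm %in% cn) L[nm] <- L[nm] + sign   # reference level contributes 0
    L
  }
  L <- add(L, level1, 1)
  L <- add(L, level2, -1)
  est <- sum(L * fit$coefficients)
  se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
  tval <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
  p <- 2 * stats::pt(-abs(tval), fit$df)
  y <- stats::model.response(fit$model)
  g <- fit$model[[term]]
  if (d_type == "pooled") {
    ss <- 0; dfree <- 0
    for (l in c(level1, level2)) {
      yi <- y[g == l]
      if (length(yi) > 1) {
        ss <- ss + (length(yi) - 1) * stats::var(yi)
        dfree <- dfree + length(yi) - 1
      }
    }
    sd_d <- if (dfree > 0) sqrt(ss / dfree) else NA_real_
  } else {
    sd_d <- sqrt(sum(fit$residuals^2) / (fit$n_obs - length(cn)))
  }
  d <- if (isTRUE(sd_d > 0)) est / sd_d else 0
  structure(list(estimate = est, se = se, t = tval, df = fit$df, p = p,
                 d = d, levels = c(level1, level2), term = term),
            class = "erd_contrast")
}

#' @export
print.erd_contrast <- function(x, ...) {
  cat(sprintf("%s: %s - %s\n", x$term, x$levels[1], x$levels[2]))
  cat(sprintf("  beta = %.4f, SE = %.4f, t(%d) = %.3f, p = %.4g, d = %.3f\n",
              x$estimate, x$se, x$df, x$t, x$p, x$d))
  invisible(x)
}

#' Paired t-test with Cohen's d
#'
#' Classical paired t (via [stats::t.test()]) plus the paired effect size
#' `d = mean(x - y) / sd(x - y)`. Degenerate inputs are handled explicitly:
#' if all differences are equal and nonzero the t statistic is reported as
#' +/-Inf with `degenerate = TRUE`; if all differences are zero, t = 0 and
#' p = 1.
#'
#' @param x,y Paired numeric vectors of equal length >= 2 (e.g. per-trial
#'   log10 dynamic vs static band PSD).
#' @return list of class `erd_ttest`: `mean_diff`, `t`, `df`, `p`, `d`,
#'   `n`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  dd <- x - y
  md <- mean(dd)
  s <- stats::sd(dd)
  if (s <= 1e-10 * max(1, abs(md))) {
    tval <- if (md == 0) 0 else sign(md) * Inf
    out <- list(mean_diff = md, t = tval, df = n - 1,
                p = if (md == 0) 1 else 0, d = if (md == 0) 0 else
                  sign(md) * Inf, n = n, degenerate = TRUE)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    out <- list(mean_diff = md, t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value, d = md / s,
                n = n, degenerate = FALSE)
  }
  class(out) <- "erd_ttest"
  out
}

#' @export
print.erd_ttest <- function(x, ...) {
  cat(sprintf("paired t: M_dif = %.4f, t(%d) = %.3f, p = %.4g, d = %.3f%s\n",
              x$mean_diff, x$df, x$t, x$p, x$d,
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}

#' Jeffreys-Zellner-Siow Bayes factor for a one-sample / paired t statistic
#'
#' Default-prior Bayes factor for the paired (one-sample) t set-up: Cauchy
#' prior with scale `r_scale` on the standardized effect, evaluated by
#' adaptive quadrature of the g-mixture representation (normal effect prior
#' with inverse-gamma(1/2, r^2/2) mixing) in log space, so arbitrarily large
#' |t| is handled without overflow.
#'
#' @param t Observed t statistic (finite).
#' @param n Number of pairs (>= 2).
#' @param r_scale Cauchy prior scale (default `sqrt(2)/2`).
#' @return list of class `jzs_bf`: `bf10`, `bf01 = 1/bf10`, `log_bf10`
#'   (natural log), `r_scale`.
#' @examples
#' jzs_bf10(t = 0, n = 47)$bf10  # < 1: data favor the null
#' @export
jzs_bf10 <- function(t, n, r_scale = sqrt(2) / 2) {
  if (!is.finite(t)) stop("invalid input: t must be finite", call. = FALSE)
  if (n < 2) stop("invalid input: need n >= 2", call. = FALSE)
  nu <- n - 1
  # log integrand over u = log(g): likelihood ratio term x IG(1/2, r^2/2)
  # prior density x Jacobian g
  log_f <- function(u) {
    g <- exp(u)
    -0.5 * log1p(n * g) -
      ((nu + 1) / 2) * log1p(t^2 / ((1 + n * g) * nu)) +
      0.5 * log(r_scale^2 / 2) - lgamma(0.5) - 1.5 * u -
      r_scale^2 / (2 * g) + u
  }
  opt <- stats::optimize(log_f, c(-25, 25), maximum = TRUE)
  peak <- opt$objective
  I <- stats::integrate(function(u) exp(log_f(u) - peak), -35, 35,
                        rel.tol = 1e-10, subdivisions = 500L)$value
  log_null <- -((nu + 1) / 2) * log1p(t^2 / nu)
  log_bf <- peak + log(I) - log_null
  structure(list(bf10 = exp(log_bf), bf01 = exp(-log_bf),
                 log_bf10 = log_bf, r_scale = r_scale),
            class = "jzs_bf")
}

#' @export
print.jzs_bf <- function(x, ...) {
  cat(sprintf("JZS Bayes factor (Cauchy scale %.3f): BF10 = %.4g, BF01 = %.4g\n",
              x$r_scale, x$bf10, x$bf01))
  invisible(x)
}

#' Pearson correlation with p-value
#'
#' Thin wrapper around [stats::cor.test()] with an explicit zero-variance
#' error (used for the mu-alpha association).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return list: `r`, `t`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = length(x))
}
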