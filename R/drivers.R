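#' Z-score standardization
#'
#' Centres and scales a series over its non-missing values (sample sd,
#' n - 1 denominator), so regression coefficients on standardized variables
#' are standardized effect sizes. Idempotent on already-standardized input.
#'
#' @param x numeric vector (>= 3 non-missing values).
#' @param name series name used in error messages.
#' @return standardized vector (mean 0, sd 1 over non-missing values).
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  v <- x[!is.na(x)]
  if (length(v) < 3L)
    stop("standardize: series '", name, "' has fewer than 3 non-missing values")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("standardize: series '", name, "' has zero variance")
  (x - mean(v)) / s
}

#' Linear interpolation of interior gaps
#'
#' Fills missing values lying strictly between observed values by linear
#' interpolation (the standard gap-fill for irregularly collected driver
#' series such as fuel prices). Leading and trailing gaps are left missing:
#' no extrapolation beyond the record ends.
#'
#' @param x numeric vector (>= 2 non-missing anchor points).
#' @return gap-filled vector.
#' @export
interpolate_gaps <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0L) stop("interpolate_gaps: all values missing")
  if (length(ok) < 2L) return(x)
  filled <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 1)$y
  filled
}

#' Merge an indicator set into a day-by-series data frame
#'
#' Joins the series of an indicator set (and optionally processed driver
#' series) on their dates, one column per series, ready for regression.
#'
#' @param indicators named list of \code{indicator_series}.
#' @return data.frame with a \code{date} column and one column per series.
#' @export
indicator_frame <- function(indicators) {
  stopifnot(length(indicators) > 0, !is.null(names(indicators)))
  out <- NULL
  for (nm in names(indicators)) {
    s <- indicators[[nm]]
    df <- data.frame(date = s$date, value = s$value)
    names(df)[2] <- nm
    out <- if (is.null(out)) df else merge(out, df, by = "date", all = TRUE)
  }
  out[order(out$date), , drop = FALSE]
}

#' Driver-attribution multiple regression
#'
#' Ordinary least squares of one standardized fleet indicator on
#' standardized candidate drivers (same-axis habitat shift, SSTa, fuel
#' price, weather-alert area, price per pound in the standard analysis),
#' over complete-case days. Coefficients are standardized effect sizes
#' (beta) with two-sided p-values; predictors are ranked by |beta|. Both
#' response and predictors are z-scored. An optional heteroskedasticity-
#' and autocorrelation-robust (Newey-West) covariance can be requested for
#' the p-values; the default reports plain OLS inference.
#'
#' @param data day-by-series data.frame (see \code{\link{indicator_frame}}).
#' @param response name of the response column.
#' @param predictors names of predictor columns.
#' @param robust if TRUE, use Newey-West standard errors (requires the
#'   sandwich and lmtest packages).
#' @return object of class \code{driver_fit}: list with \code{coefficients}
#'   (data.frame predictor, beta, se, p_value, rank), \code{n_obs},
#'   \code{r_squared}, \code{response}, \code{model} (the underlying lm).
#' @export
fit_driver_model <- function(data, response, predictors, robust = FALSE) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  cols <- c(response, predictors)
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[cc, cols, drop = FALSE]
  if (nrow(d) < length(predictors) + 2L)
    stop("fit_driver_model: not enough complete-case days")
  for (nm in cols) d[[nm]] <- standardize(d[[nm]], nm)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(sprintf("`%s`", predictors),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  qrr <- fit$qr$rank
  if (qrr < length(predictors) + 1L) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("fit_driver_model: rank-deficient design; collinear predictors: ",
         paste(alias, collapse = ", "))
  }
  if (robust) {
    if (!requireNamespace("sandwich", quietly = TRUE) ||
        !requireNamespace("lmtest", quietly = TRUE))
      stop("fit_driver_model: robust = TRUE requires sandwich and lmtest")
    ct <- lmtest::coeftest(fit, vcov. = sandwich::NeweyWest(fit))
    est <- ct[, 1]; se <- ct[, 2]; pv <- ct[, 4]
  } else {
    sm <- summary(fit)$coefficients
    est <- sm[, 1]; se <- sm[, 2]; pv <- sm[, 4]
  }
  keep <- setdiff(names(est), "(Intercept)")
  coefs <- data.frame(predictor = gsub("`", "", keep),
                      beta = unname(est[keep]), se = unname(se[keep]),
                      p_value = unname(pv[keep]))
  coefs <- coefs[order(-abs(coefs$beta)), , drop = FALSE]
  coefs$rank <- seq_len(nrow(coefs))
  rownames(coefs) <- NULL
  if (any(abs(coefs$beta) > 1.5))
    warning("fit_driver_model: |beta| > 1.5 for ",
            paste(coefs$predictor[abs(coefs$beta) > 1.5], collapse = ", "),
            " (outside the plausible standardized range)")
  structure(list(coefficients = coefs, n_obs = nrow(d),
                 r_squared = summary(fit)$r.squared,
                 response = response, robust = robust, model = fit),
            class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<driver_fit> response: %s (n = %d days, R^2 = %.3f%s)\n",
              x$response, x$n_obs, x$r_squared,
              if (x$robust) ", Newey-West SEs" else ""))
  df <- x$coefficients
  df$beta <- round(df$beta, digits)
  df$se <- round(df$se, digits)
  df$p_value <- signif(df$p_value, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.driver_fit <- function(object, ...) {
  print(object, ...)
  invisible(object$coefficients)
}

#' @export
coef.driver_fit <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$predictor)
}

#' @export
residuals.driver_fit <- function(object, ...) stats::residuals(object$model)

#' @export
predict.driver_fit <- function(object, ...) stats::predict(object$model, ...)

#' @export
plot.driver_fit <- function(x, ...) {
  co <- x$coefficients[order(x$coefficients$beta), ]
  graphics::barplot(co$beta, names.arg = co$predictor, horiz = TRUE,
                    las = 1, xlab = "standardized effect size (beta)", ...)
  graphics::abline(v = 0)
  invisible(x)
}
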