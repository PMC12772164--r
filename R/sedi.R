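#' Binarize a series into extreme events
#'
#' Flags days whose value strictly exceeds the nearest-rank empirical
#' percentile threshold of the full (pooled, multi-year) series. Pooling
#' treats "extreme" as rare over the whole record, so only a few seasons
#' contribute events at high percentiles.
#'
#' @param series an \code{indicator_series} (season-restricted smoothed
#'   anomalies in the standard workflow).
#' @param percentile threshold probability in (0, 1).
#' @return data.frame (date, event) with attribute \code{threshold}; days
#'   with missing values have missing events.
#' @export
binarize_extreme <- function(series, percentile) {
  if (percentile <= 0 || percentile >= 1)
    stop("binarize_extreme: percentile must be in (0, 1)")
  v <- series$value
  if (sum(!is.na(v)) < 10L)
    stop("binarize_extreme: need at least 10 non-missing days")
  thr <- nearest_rank_quantile(v, percentile)
  structure(data.frame(date = series$date, event = v > thr),
            threshold = thr)
}

#' 2x2 contingency table of predicted and observed events
#'
#' Joins two boolean event series on their day index (days missing in
#' either are dropped pairwise) and counts true positives, false positives,
#' false negatives and true negatives.
#'
#' @param pred_events,resp_events data.frames (date, event) from
#'   \code{\link{binarize_extreme}}.
#' @return object of class \code{contingency}: list(tp, fp, fn, tn, n).
#' @export
contingency <- function(pred_events, resp_events) {
  m <- merge(pred_events, resp_events, by = "date",
             suffixes = c("_pred", "_resp"))
  m <- m[!is.na(m$event_pred) & !is.na(m$event_resp), , drop = FALSE]
  if (nrow(m) == 0L) stop("contingency: no jointly observed days")
  tp <- sum(m$event_pred & m$event_resp)
  fp <- sum(m$event_pred & !m$event_resp)
  fn <- sum(!m$event_pred & m$event_resp)
  tn <- sum(!m$event_pred & !m$event_resp)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = nrow(m)),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  invisible(x)
}

#' Symmetric Extremal Dependence Index
#'
#' Rare-event skill score built from the hit ratio H = TP/(TP+FN) and the
#' false-alarm rate F = FP/(FP+TN):
#' \deqn{SEDI = \frac{\log F - \log H - \log(1-F) + \log(1-H)}
#'                   {\log F + \log H + \log(1-F) + \log(1-H)}}
#' SEDI is bounded in [-1, 1]; 0 is random skill, 1 perfect prediction,
#' and it remains meaningful as events become rare. When any of H or F is
#' exactly 0 or 1 the logarithms diverge; the rates are then clamped to
#' [eps, 1-eps] and the result is flagged degenerate (a limit convention
#' that preserves grid cells where extremes are very rare). The score is
#' invariant to the base of the logarithm.
#'
#' @param table a \code{\link{contingency}} table, or NULL if counts are
#'   supplied directly.
#' @param tp,fp,fn,tn counts, used when \code{table} is NULL.
#' @param eps clamping bound for degenerate rates.
#' @return list of class \code{sedi_score}: sedi, H, F, degenerate, table.
#'   \code{sedi} is NA with a \code{reason} attribute when H or F has a
#'   zero denominator.
#' @export
sedi <- function(table = NULL, tp = NULL, fp = NULL, fn = NULL, tn = NULL,
                 eps = 1e-9) {
  if (is.null(table)) table <- structure(list(tp = tp, fp = fp, fn = fn,
                                              tn = tn, n = tp + fp + fn + tn),
                                         class = "contingency")
  if (table$tp + table$fn == 0 || table$fp + table$tn == 0) {
    s <- NA_real_
    attr(s, "reason") <- "undefined: empty event or non-event margin"
    return(structure(list(sedi = s, H = NA_real_, F = NA_real_,
                          degenerate = NA, table = table),
                     class = "sedi_score"))
  }
  H <- table$tp / (table$tp + table$fn)
  F <- table$fp / (table$fp + table$tn)
  degenerate <- any(c(H, F) %in% c(0, 1))
  Hc <- min(max(H, eps), 1 - eps)
  Fc <- min(max(F, eps), 1 - eps)
  num <- log(Fc) - log(Hc) - log(1 - Fc) + log(1 - Hc)
  den <- log(Fc) + log(Hc) + log(1 - Fc) + log(1 - Hc)
  structure(list(sedi = num / den, H = H, F = F, degenerate = degenerate,
                 table = table),
            class = "sedi_score")
}

#' @export
print.sedi_score <- function(x, ...) {
  cat(sprintf("<sedi_score> SEDI = %s (H = %.3f, F = %.3f)%s\n",
              ifelse(is.na(x$sedi), "NA", sprintf("%.4f", x$sedi)),
              x$H, x$F, if (isTRUE(x$degenerate)) " [degenerate, clamped]" else ""))
  invisible(x)
}

#' Year-block bootstrap interval for SEDI
#'
#' Percentile bootstrap of the SEDI score obtained by resampling whole
#' years (seasons) with replacement, respecting the strong within-season
#' autocorrelation of 30-day-smoothed series. Deterministic given
#' \code{seed}.
#'
#' @param pred_events,resp_events event data.frames (date, event).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param conf confidence level, default 0.95.
#' @return list(lower, upper, level, n_boot, replicates).
#' @export
bootstrap_sedi <- function(pred_events, resp_events, n_boot = 1000, seed = 1,
                           conf = 0.95) {
  if (n_boot < 100) stop("bootstrap_sedi: n_boot must be >= 100")
  m <- merge(pred_events, resp_events, by = "date",
             suffixes = c("_pred", "_resp"))
  m <- m[!is.na(m$event_pred) & !is.na(m$event_resp), , drop = FALSE]
  yr <- as.integer(format(m$date, "%Y"))
  years <- unique(yr)
  if (length(years) < 3L) stop("bootstrap_sedi: need at least 3 years")
  idx_by_year <- split(seq_len(nrow(m)), yr)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    pick <- sample(length(years), replace = TRUE)
    i <- unlist(idx_by_year[pick], use.names = FALSE)
    s <- sedi(tp = sum(m$event_pred[i] & m$event_resp[i]),
              fp = sum(m$event_pred[i] & !m$event_resp[i]),
              fn = sum(!m$event_pred[i] & m$event_resp[i]),
              tn = sum(!m$event_pred[i] & !m$event_resp[i]))
    s$sedi
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], level = conf, n_boot = n_boot,
       replicates = reps)
}

#' SEDI skill grid over predictors, responses and percentiles
#'
#' Scores every predictor x response x percentile combination: both series
#' are binarized at the percentile, the contingency table is built on their
#' shared day index, and SEDI is computed; optionally a year-block
#' bootstrap interval is attached. The default six percentile levels
#' (0.70 to 0.95 in 0.05 steps) profile how skill changes as shifts become
#' more extreme. Cells with SEDI <= 0 are flagged worse than random.
#'
#' @param indicators named list of season-restricted smoothed anomaly
#'   \code{indicator_series} (e.g. from \code{\link{build_indicator_set}}).
#' @param predictors names of predictor series.
#' @param responses names of response series.
#' @param percentiles threshold grid, default \code{seq(0.70, 0.95, 0.05)}.
#' @param n_boot bootstrap replicates per cell (0 = none).
#' @param seed bootstrap seed.
#' @return data.frame of class \code{sedi_grid} with columns predictor,
#'   response, percentile, sedi, H, F, tp, fp, fn, tn, degenerate,
#'   worse_than_random and (with bootstrap) ci_lo, ci_hi.
#' @export
sedi_grid <- function(indicators, predictors, responses,
                      percentiles = seq(0.70, 0.95, by = 0.05),
                      n_boot = 0, seed = 1) {
  if (length(predictors) == 0L || length(responses) == 0L)
    stop("sedi_grid: predictors and responses must be non-empty")
  missing_nm <- setdiff(c(predictors, responses), names(indicators))
  if (length(missing_nm))
    stop("sedi_grid: indicators missing series: ",
         paste(missing_nm, collapse = ", "))
  rows <- list()
  for (p in predictors) for (r in responses) for (q in percentiles) {
    pe <- binarize_extreme(indicators[[p]], q)
    re <- binarize_extreme(indicators[[r]], q)
    tab <- contingency(pe, re)
    s <- sedi(tab)
    row <- data.frame(predictor = p, response = r, percentile = q,
                      sedi = s$sedi, H = s$H, F = s$F,
                      tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
                      degenerate = isTRUE(s$degenerate),
                      worse_than_random = !is.na(s$sedi) & s$sedi <= 0)
    if (n_boot > 0) {
      ci <- bootstrap_sedi(pe, re, n_boot = n_boot, seed = seed)
      row$ci_lo <- ci$lower; row$ci_hi <- ci$upper
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sedi_grid", "data.frame")
  out
}

#' @export
print.sedi_grid <- function(x, digits = 3, ...) {
  cat(sprintf("<sedi_grid> %d predictor(s) x %d response(s) x %d percentile(s)\n",
              length(unique(x$predictor)), length(unique(x$response)),
              length(unique(x$percentile))))
  df <- as.data.frame(x)
  df$sedi <- round(df$sedi, digits)
  print(df[, c("predictor", "response", "percentile", "sedi", "tp", "fp",
               "fn", "tn", "degenerate")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.sedi_grid <- function(object, ...) {
  agg <- stats::aggregate(sedi ~ predictor + response, data = object,
                          FUN = function(v) mean(v, na.rm = TRUE))
  names(agg)[3] <- "mean_sedi"
  agg$n_skillful <- stats::aggregate(sedi ~ predictor + response,
                                     data = object,
                                     FUN = function(v) sum(v > 0, na.rm = TRUE))$sedi
  cat("Mean SEDI and number of skillful percentile levels per pair:\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' @export
plot.sedi_grid <- function(x, ...) {
  pairs <- unique(x[, c("predictor", "response")])
  pair_lab <- paste(pairs$predictor, "->", pairs$response)
  pct <- sort(unique(x$percentile))
  z <- matrix(NA_real_, nrow = nrow(pairs), ncol = length(pct))
  for (i in seq_len(nrow(pairs))) {
    sub <- x[x$predictor == pairs$predictor[i] & x$response == pairs$response[i], ]
    z[i, match(sub$percentile, pct)] <- ifelse(sub$sedi > 0, sub$sedi, NA)
  }
  graphics::image(x = seq_len(nrow(pairs)), y = pct, z = z,
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "extreme-event percentile", xaxt = "n",
                  zlim = c(0, 1), ...)
  graphics::axis(1, at = seq_len(nrow(pairs)), labels = pair_lab,
                 las = 2, cex.axis = 0.7)
  invisible(x)
}
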