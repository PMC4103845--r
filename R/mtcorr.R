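#' Estimate the null proportion pi0 (Storey)
#'
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` is evaluated over the
#' lambda grid, smoothed by a cubic polynomial least-squares fit, and read
#' off at the largest lambda. The estimate is clamped to `(0, 1]` (lower
#' bound `1/m`, with a warning when the raw estimate is non-positive).
#' Fewer than 10 p-values fall back to `pi0 = 1`.
#'
#' @param p p-values in \[0, 1\].
#' @param lambda tuning grid (default 0.05, 0.10, ..., 0.95).
#' @return the estimate, with attributes `lambda` and `raw` (the unsmoothed
#'   grid values).
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- p[!is.na(p)]
  m <- length(p)
  if (m < 10L) return(structure(1, lambda = lambda, raw = NULL))
  raw <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::lm(raw ~ poly(lambda, 3))
  est <- unname(stats::predict(fit,
                               newdata = data.frame(lambda = max(lambda))))
  if (est <= 0) {
    warning("pi0 estimate non-positive; clamped to 1/m", call. = FALSE)
    est <- 1 / m
  }
  structure(min(est, 1), lambda = lambda, raw = raw)
}

#' Storey q-values
#'
#' `q_(i) = min_(j >= i) pi0 * m * p_(j) / j` on the sorted scale, mapped
#' back to the input order (stable for ties). With `pi0 = 1` this is exactly
#' the Benjamini-Hochberg adjusted p-value.
#'
#' @param p p-values; `NA`s propagate.
#' @param pi0 null proportion in (0, 1]; estimated with [estimate_pi0()]
#'   when `NULL`.
#' @param lambda grid passed to [estimate_pi0()].
#' @return a list of class `qvalue_result`: `pvalues`, `qvalues` (input
#'   order), `pi0`, `lambda`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)$qvalues
#' @export
qvalues <- function(p, pi0 = NULL, lambda = seq(0.05, 0.95, by = 0.05)) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (is.null(pi0)) pi0 <- as.numeric(estimate_pi0(pv, lambda))
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  m <- length(pv)
  q <- rep(NA_real_, length(p))
  if (m) {
    o <- order(pv)               # stable: ties keep input order
    qs <- pi0 * m * pv[o] / seq_len(m)
    qs <- rev(cummin(rev(qs)))
    qs <- pmin(qs, 1)
    qo <- numeric(m)
    qo[o] <- qs
    q[ok] <- qo
  }
  structure(list(pvalues = p, qvalues = q, pi0 = pi0, lambda = lambda),
            class = "qvalue_result")
}

#' Append q-values to a p-value table
#'
#' @param df data.frame holding a p-value column.
#' @param p_col name of the p-value column.
#' @param by optional grouping column (e.g. trait) within which correction
#'   is applied separately.
#' @param pi0 fixed pi0, or `NULL` to estimate per group.
#' @param threshold significance cutoff for the flag column (default 0.05).
#' @return `df` with columns `<p_col>_q` and `<p_col>_sig` appended.
#' @export
add_qvalues <- function(df, p_col = "p", by = NULL, pi0 = NULL,
                        threshold = 0.05) {
  stopifnot(p_col %in% names(df))
  qcol <- paste0(p_col, "_q")
  scol <- paste0(p_col, "_sig")
  if (is.null(by)) {
    df[[qcol]] <- qvalues(df[[p_col]], pi0 = pi0)$qvalues
  } else {
    stopifnot(by %in% names(df))
    df[[qcol]] <- NA_real_
    for (g in unique(df[[by]])) {
      i <- df[[by]] == g
      df[[qcol]][i] <- qvalues(df[[p_col]][i], pi0 = pi0)$qvalues
    }
  }
  df[[scol]] <- !is.na(df[[qcol]]) & df[[qcol]] < threshold
  df
}
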