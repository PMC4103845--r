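`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-stream seed
#'
#' Each pipeline stage (pedigree, haplotypes, segregation, phenotypes, Monte
#' Carlo ensemble) draws from its own seed derived from the master seed, so a
#' stage can be regenerated without replaying the stages before it.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed in `[1, 2^31 - 20]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # kept well inside 32-bit integer range; doubles are exact here
  as.integer((abs(seed) * 2654435 + h * 97919) %% 2147483609) + 1L
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# cumulative sums along rows of a 0/1 matrix without apply(); U is upper
# triangular so (X %*% U)[, j] = sum_{i <= j} X[, i]
row_cumsum <- function(X) {
  k <- ncol(X)
  if (k == 0L) return(X)
  U <- upper.tri(matrix(0, k, k), diag = TRUE) * 1
  X %*% U
}

assert_in_01 <- function(p, name = "p", open_left = TRUE, open_right = FALSE) {
  bad <- if (open_left) p <= 0 else p < 0
  bad <- bad | if (open_right) p >= 1 else p > 1
  if (any(bad, na.rm = TRUE))
    stop(sprintf("%s must lie in %s0,1%s", name,
                 if (open_left) "(" else "[", if (open_right) ")" else "]"),
         call. = FALSE)
  invisible(p)
}
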