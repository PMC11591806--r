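clip <- function(x, lb, ub) pmin(pmax(x, lb), ub)

#' Truncate a percentage to a fixed number of decimals
#'
#' Truncation (not rounding), the convention used when quoting percentage
#' metrics in result tables: `pct_truncate(98.19959, 3)` is `98.199`.
#'
#' @param x Numeric vector.
#' @param digits Decimal places kept (default 3).
#' @return Truncated numeric vector.
#' @export
pct_truncate <- function(x, digits = 3) trunc(x * 10^digits) / 10^digits

# squared-distance-safe Euclidean cross distances between row sets
euclidean_cross <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
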