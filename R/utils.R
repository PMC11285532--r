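# small shared helpers

# half-up rounding (round() in R is banker's; result tables follow the
# half-up convention used in the printed proportions)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Report a count as a percentage
#'
#' Converts `numerator / denominator` to a percentage with half-up rounding,
#' the convention used when quoting overlap proportions such as "28 of 285
#' GWAS genes (9.8%)".
#'
#' @param numerator,denominator Non-negative counts with
#'   `0 <= numerator <= denominator` and `denominator > 0`.
#' @param digits Decimal places to keep (default 1; use 0 for whole-percent
#'   display).
#' @return A single numeric percentage.
#' @examples
#' proportion_report(28, 285)      # 9.8
#' proportion_report(17, 38, 0)    # 45
#' @export
proportion_report <- function(numerator, denominator, digits = 1) {
  stopifnot(length(numerator) == 1, length(denominator) == 1)
  if (denominator <= 0) abort("`denominator` must be positive.")
  if (numerator < 0 || numerator > denominator) {
    abort("`numerator` must lie in [0, denominator].")
  }
  round_half_up(100 * numerator / denominator, digits)
}

# uppercase gene-symbol normalization; gene identity is the uppercased symbol
norm_symbols <- function(x) toupper(trimws(x))

# deterministic disambiguation of duplicated symbols: second occurrence gets
# ".1", third ".2", ... in file order
disambiguate_symbols <- function(x) {
  dup <- ave(seq_along(x), x, FUN = seq_along) - 1L
  ifelse(dup > 0L, paste0(x, ".", dup), x)
}

# linear-interpolation percentile bounds (quantile type 7)
pctile_bounds <- function(values, pctile) {
  stopifnot(length(pctile) == 2, pctile[1] < pctile[2])
  quantile(values, probs = pctile / 100, type = 7, names = FALSE)
}

# all permutations of seq_len(n); used for exact small-n Spearman p-values
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}
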