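# preranked GSEA: weighted Kolmogorov-Smirnov running sum with a
# gene-label permutation null

# enrichment score from hit positions in a ranking of length n.
# weights = |stat|^w at each position; hits increment by their weight share,
# misses decrement uniformly. Returns the signed extremum of the running sum.
es_from_positions <- function(pos, absw, n) {
  pos <- sort(pos)
  nh <- length(pos)
  wsum <- sum(absw[pos])
  if (wsum == 0) absw[pos] <- 1  # all-zero stats: unweighted fallback
  wsum <- sum(absw[pos])
  miss_step <- 1 / (n - nh)
  # running sum evaluated just before and at each hit is enough to find the
  # extremum: between hits it decreases linearly
  hit_cum <- cumsum(absw[pos]) / wsum
  miss_before <- (pos - seq_len(nh)) * miss_step      # misses before each hit
  at_hit <- hit_cum - miss_before
  before_hit <- c(0, hit_cum[-nh]) - miss_before
  lo <- min(before_hit, at_hit - 0)                   # most negative point
  hi <- max(at_hit)
  # the most negative value can also occur after the last hit, just before
  # the end (running sum returns to 0 at n): min is among before_hit values
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Ranks genes by the supplied statistic in descending order (ties broken
#' deterministically by gene symbol), computes the weighted
#' Kolmogorov-Smirnov enrichment score for each set, and obtains the null by
#' permuting gene labels `nperm` times. `NES = ES / mean(|null ES| of
#' matching sign)`; the permutation p-value has +1 smoothing, so its floor is
#' `1/(nperm + 1)`. Sets are intersected with the ranked universe and size
#' bounds applied.
#'
#' @param stats Named numeric vector: ranking statistic per gene (e.g.
#'   average log2FC).
#' @param sets Named list of gene vectors or an `rv_genesets`.
#' @param nperm Number of label permutations (default 1000).
#' @param weight Exponent on `|stat|` for hit increments (1 = weighted,
#'   0 = classic KS).
#' @param min_size,max_size Set-size bounds after intersection (defaults
#'   5 and 500).
#' @param seed Integer seed for the permutations.
#' @return Tibble `set`, `size`, `es`, `nes`, `p_value`, `adj_p`,
#'   `leading_edge` (list column).
#' @export
gsea_preranked <- function(stats, sets, nperm = 1000, weight = 1,
                           min_size = 5, max_size = 500, seed = 1) {
  if (inherits(sets, "rv_genesets")) sets <- sets$sets
  if (is.null(names(stats))) abort("`stats` must be named by gene")
  ord <- order(-stats, names(stats))
  ranked <- stats[ord]
  genes <- names(ranked)
  n <- length(genes)
  absw <- abs(ranked)^weight

  set.seed(seed)
  out <- lapply(names(sets), function(nm) {
    hits <- which(genes %in% sets[[nm]])
    sz <- length(hits)
    if (sz < min_size || sz > max_size) {
      inform(paste0("set ", nm, " skipped (size ", sz,
                    " outside bounds after intersection)"))
      return(NULL)
    }
    es <- es_from_positions(hits, absw, n)
    null_es <- vapply(seq_len(nperm), function(i) {
      es_from_positions(sample.int(n, sz), absw, n)
    }, 1)
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (nperm + 1)
    # leading edge: hits at or before (after, for negative ES) the extremum
    run_at_hits <- cumsum(absw[sort(hits)]) / sum(absw[hits]) -
      (sort(hits) - seq_len(sz)) / (n - sz)
    le <- if (es >= 0) {
      genes[sort(hits)[seq_len(which.max(run_at_hits))]]
    } else {
      genes[sort(hits)[seq(which.min(run_at_hits), sz)]]
    }
    tibble(set = nm, size = sz, es = es, nes = nes, p_value = p,
           leading_edge = list(le))
  })
  res <- bind_rows(out)
  if (nrow(res)) res$adj_p <- bh_adjust(res$p_value) else res$adj_p <- numeric(0)
  res[, c("set", "size", "es", "nes", "p_value", "adj_p", "leading_edge")]
}
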