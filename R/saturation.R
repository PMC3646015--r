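## Gene-discovery saturation: random read subsets, per-subassembly metrics
## and the coverage-vs-reads linear fit.

## run f under a private RNG stream so callers' RNG state is untouched
withPrivateSeed <- function(seed, f) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  f()
}

#' Draw a random subset of reads
#'
#' Uniform sampling without replacement of `round(fraction * N)` reads
#' (half-up rounding, or `floor`). Sampling is performed over the sorted
#' ids, so the result depends only on the id set, the fraction and the
#' seed -- not on input order.
#'
#' @param read_ids character vector of read ids (any order).
#' @param fraction fraction of reads to keep, in (0, 1].
#' @param seed integer RNG seed.
#' @param rounding `"round"` (half-up, default) or `"floor"`.
#' @return Character vector of sampled ids (sorted).
#' @export
subsetReads <- function(read_ids, fraction, seed,
                        rounding = c("round", "floor")) {
  rounding <- match.arg(rounding)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  ids <- sort(unique(read_ids))
  n <- length(ids)
  k <- if (rounding == "round") floor(fraction * n + 0.5)
       else floor(fraction * n)
  if (fraction == 1) return(ids)
  withPrivateSeed(seed, function() sort(sample(ids, k)))
}

#' Saturation curve over a ladder of subassemblies
#'
#' Computes, per subassembly, the unique-hit count ([countUniqueSubjects()]),
#' N50, and average coverage per bp ([coverageStats()]), then fits ordinary
#' least squares of coverage per bp on the number of reads. The curve never
#' enforces monotone unique-hit counts: discovery can genuinely dip near
#' full depth as previously separate contigs merge.
#'
#' @param bundles list of per-subassembly lists with elements:
#'   `fraction`, `n_reads`, `best_hits` (per-query best-hit data.frame or
#'   named query->subject vector), `lengths` (isotig lengths), `aligned_bp`
#'   and `contig_lengths` (as for [coverageStats()]); optional
#'   `pct_singleton_reads`.
#' @return List with `points` (data.frame fraction, n_reads, unique_hits,
#'   coverage_per_bp, n50, pct_singleton_reads) and `fit` (list slope,
#'   intercept, r_squared; R^2 is `1 - SSres/SStot`, defined as 0 when
#'   SStot is 0).
#' @export
saturationCurve <- function(bundles) {
  if (length(bundles) < 2) stop("need at least 2 subassembly points")
  pts <- do.call(rbind, lapply(bundles, function(b) {
    cov <- coverageStats(b$aligned_bp, b$contig_lengths)
    data.frame(fraction = b$fraction, n_reads = b$n_reads,
               unique_hits = countUniqueSubjects(b$best_hits),
               coverage_per_bp = cov$avg_coverage_per_bp,
               n50 = n50(b$lengths),
               pct_singleton_reads =
                 if (is.null(b$pct_singleton_reads)) NA_real_
                 else b$pct_singleton_reads)
  }))
  rownames(pts) <- NULL
  list(points = pts,
       fit = olsFit(pts$n_reads, pts$coverage_per_bp))
}

## OLS with the R^2 = 0 convention for a constant response
olsFit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  res <- sum(stats::resid(fit)^2)
  tot <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (tot == 0) 0 else 1 - res / tot)
}
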