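## Ortholog hit ratio: assembly-product length over the full length of its
## putative ortholog's transcript -- a transcript-completeness proxy.

#' Compute ortholog hit ratios
#'
#' One record per annotated product: its length divided by the cDNA length
#' of its putative ortholog's transcript. Ratios are not capped at 1 (UTR
#' differences between species can push them above 1). Unannotated products
#' are omitted.
#'
#' @param annotations an [AnnotationTable-class] or a named character vector
#'   product id -> ortholog id.
#' @param product_lengths named numeric vector product id -> length bp.
#' @param transcript_lengths named numeric vector ortholog id -> reference
#'   transcript (cDNA) length bp. When a reference gene has several
#'   isoforms, supply the chosen one (conventionally the longest).
#' @return data.frame with product_id, product_length, ortholog_id,
#'   ortholog_transcript_length, ratio.
#' @export
computeOhr <- function(annotations, product_lengths, transcript_lengths) {
  if (methods::is(annotations, "AnnotationTable")) {
    cl <- orthologyCalls(annotations)
    map <- stats::setNames(cl$protein_id, cl$transcript_id)
  } else map <- annotations
  map <- map[names(map) %in% names(product_lengths)]
  miss <- setdiff(unique(unname(map)), names(transcript_lengths))
  if (length(miss) > 0)
    stop("missing transcript length for ortholog ", miss[1L])
  pl <- product_lengths[names(map)]
  tl <- transcript_lengths[unname(map)]
  data.frame(product_id = names(map), product_length = unname(pl),
             ortholog_id = unname(map),
             ortholog_transcript_length = unname(tl),
             ratio = unname(pl / tl))
}

#' Summarise ortholog hit ratios
#'
#' Fractions of products at or above completeness thresholds (inclusive
#' `>=`) and a histogram over `[0, 1]` in `bin_width` steps with a final
#' open overflow bin for ratios above 1.
#'
#' @param records data.frame from [computeOhr()] (needs a `ratio` column).
#' @param thresholds completeness thresholds (default `c(0.5, 0.8)`).
#' @param bin_width histogram bin width (default 0.1).
#' @return List with `n`, `frac_ge` (named by threshold) and `histogram`
#'   (named counts, bins `[a,b)`, the last regular bin closed at 1, plus
#'   `">1"`; counts sum to `n`).
#' @export
summarizeOhr <- function(records, thresholds = c(0.5, 0.8),
                         bin_width = 0.1) {
  r <- records$ratio
  if (length(r) == 0) stop("no OHR records")
  frac <- vapply(thresholds, function(t) mean(r >= t), numeric(1))
  names(frac) <- format(thresholds)
  nb <- ceiling(1 / bin_width)
  idx <- pmin(floor(r / bin_width), nb - 1)       # ratio 1.0 in last bin
  idx[r > 1] <- nb
  lo <- format(bin_width * seq(0, nb - 1))
  hi <- format(pmin(bin_width * seq(1, nb), 1))
  labs <- c(paste0("[", lo, ",", hi, ")"), ">1")
  labs[nb] <- sub("\\)$", "]", labs[nb])
  counts <- tabulate(idx + 1, nbins = nb + 1)
  list(n = length(r), frac_ge = frac,
       histogram = stats::setNames(counts, labs))
}
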