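## Redundancy filter: remove assembly products contained, at high identity
## and over their full span, inside longer products of the same assembly.

#' Redundancy rule
#'
#' Parameters deciding when a product is redundant with a longer one:
#' an HSP at greater than `min_identity` percent identity whose span covers
#' the query. With `span = "full_query"` the HSP must reach within
#' `end_slack` bp of both query ends (slack accommodates 454 homopolymer
#' end errors); with `span = "fractional"` it must cover at least
#' `min_cover` of the query length.
#'
#' @param min_identity percent identity that must be exceeded (default 95;
#'   strict `>`).
#' @param span `"full_query"` (default) or `"fractional"`.
#' @param end_slack bp allowed unaligned at each query end (default 0).
#' @param min_cover minimum covered fraction for `span = "fractional"`.
#' @return A `redundancy_rule` list.
#' @export
redundancyRule <- function(min_identity = 95, span = c("full_query",
                           "fractional"), end_slack = 0, min_cover = 0.95) {
  span <- match.arg(span)
  stopifnot(min_identity > 0, min_identity <= 100, end_slack >= 0,
            min_cover > 0, min_cover <= 1)
  structure(list(min_identity = min_identity, span = span,
                 end_slack = end_slack, min_cover = min_cover),
            class = "redundancy_rule")
}

#' Remove redundant (contained) assembly products
#'
#' A product q is removed when some self-comparison HSP aligns it, at more
#' than `rule$min_identity` percent identity and over its required span, to
#' a different product s that is longer (or of equal length with a
#' lexicographically smaller id -- the deterministic tie rule for identical
#' twins). Removal is judged in a single pass against the ORIGINAL product
#' set, so a containment chain a < b < c removes a and b and keeps c.
#'
#' @param products an [AssemblyCollection-class].
#' @param self_hits [HitTable-class] from an all-vs-all nucleotide
#'   comparison of the products (self-matches query == subject tolerated).
#' @param rule a [redundancyRule()].
#' @return List with `kept` (character ids, input order) and `removals`
#'   (data.frame removed_id, retained_id, identity, q_cover; the retainer
#'   named is the longest qualifying one, bitscore then id as tie-break).
#' @export
filterRedundant <- function(products, self_hits, rule = redundancyRule()) {
  len <- productLengths(products)
  h <- hits(self_hits)
  unknown <- setdiff(unique(c(h$query_id, h$subject_id)), names(len))
  if (length(unknown) > 0)
    stop("self-hit references unknown id: ", unknown[1L])
  if (nrow(h) > 0) {
    qlo <- pmin(h$q_start, h$q_end)
    qhi <- pmax(h$q_start, h$q_end)
    ql <- len[h$query_id]
    sl <- len[h$subject_id]
    cover <- (qhi - qlo + 1) / ql
    spans <- if (rule$span == "full_query")
      qlo <= 1 + rule$end_slack & qhi >= ql - rule$end_slack
    else cover >= rule$min_cover
    qual <- h$query_id != h$subject_id &
      (sl > ql | (sl == ql & h$subject_id < h$query_id)) &
      h$pct_identity > rule$min_identity & spans
    h <- h[qual, , drop = FALSE]
    cover <- cover[qual]
  } else cover <- numeric()
  if (nrow(h) == 0) {
    return(list(kept = names(len),
                removals = data.frame(removed_id = character(),
                                      retained_id = character(),
                                      identity = numeric(),
                                      q_cover = numeric())))
  }
  ## best retainer per removed query: longest, then bitscore, then id
  o <- order(h$query_id, -len[h$subject_id], -h$bitscore, h$subject_id,
             method = "radix")
  h <- h[o, , drop = FALSE]
  cover <- cover[o]
  first <- !duplicated(h$query_id)
  removals <- data.frame(removed_id = h$query_id[first],
                         retained_id = h$subject_id[first],
                         identity = h$pct_identity[first],
                         q_cover = pmin(cover[first], 1))
  removals <- removals[order(removals$removed_id, method = "radix"), ]
  rownames(removals) <- NULL
  list(kept = setdiff(names(len), removals$removed_id), removals = removals)
}

#' Write a removals table as TSV
#' @param removals data.frame from [filterRedundant()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRemovals <- function(removals, path) {
  writeTsv(removals, path)
}
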