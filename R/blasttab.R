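## BLAST tabular parsing and the hit-selection primitives every downstream
## stage builds on (significance filter, best hit, top-N, unique subjects).

#' Read a BLAST tabular (12-column) hit file
#'
#' Parses the classic tab-separated dialect
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`. Comment lines starting with `#` are skipped. Row order
#' is preserved; coordinates are kept 1-based inclusive as read (translated
#' searches report protein residues on the protein side, nucleotides on the
#' nucleotide side).
#'
#' @param path hit file path.
#' @param program BLAST program label stored as metadata
#'   (blastn/blastx/tblastn/tblastx).
#' @return A [HitTable-class].
#' @export
readBlastTab <- function(path, program = "blastn") {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  keep <- !grepl("^#", ln) & nzchar(ln)
  if (!any(keep)) return(HitTable(program = program))
  fields <- strsplit(ln[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(keep)[which(nf != 12L)[1L]]
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 bad, nf[which(nf != 12L)[1L]]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(keep)[which(is.na(v))[1L]]
      stop(sprintf("line %d: unparseable %s '%s'", bad, what,
                   m[is.na(v), j][1L]))
    }
    v
  }
  h <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                  pct_identity = num(3, "pident"),
                  aln_len = as.integer(num(4, "length")),
                  mismatches = as.integer(num(5, "mismatch")),
                  gap_opens = as.integer(num(6, "gapopen")),
                  q_start = as.integer(num(7, "qstart")),
                  q_end = as.integer(num(8, "qend")),
                  s_start = as.integer(num(9, "sstart")),
                  s_end = as.integer(num(10, "send")),
                  evalue = num(11, "evalue"),
                  bitscore = num(12, "bitscore"),
                  stringsAsFactors = FALSE)
  HitTable(h, program = program)
}

#' Write a HitTable in the 12-column tabular dialect
#' @param x a [HitTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBlastTab <- function(x, path) {
  h <- hits(x)
  ev <- format(h$evalue, scientific = TRUE, trim = TRUE, digits = 6)
  out <- cbind(h[, 1:10, drop = FALSE], evalue = ev,
               bitscore = format(h$bitscore, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Keep significant HSPs
#'
#' Retains HSPs with `evalue <= e_cutoff` (inclusive, the standard BLAST
#' reading of an E-value cutoff); grouping and order are preserved.
#'
#' @param x a [HitTable-class].
#' @param e_cutoff positive E-value cutoff, e.g. `1e-5` for significant
#'   similarity or `1e-10` for the stricter manual-annotation regime.
#' @return A filtered [HitTable-class].
#' @export
filterSignificant <- function(x, e_cutoff) {
  stopifnot(e_cutoff > 0)
  HitTable(hits(x)[hits(x)$evalue <= e_cutoff, , drop = FALSE],
           program = blastProgram(x))
}

## Deterministic candidate ordering: best evalue, then highest bitscore,
## then lexicographically smallest subject id. The file's "top hit" is
## otherwise nondeterministic across row orderings.
hspOrder <- function(h) {
  order(h$evalue, -h$bitscore, h$subject_id, method = "radix")
}

#' Best hit among a query's HSPs
#'
#' The HSP minimising (evalue, -bitscore, subject id); deterministic under
#' ties.
#'
#' @param hsps data.frame of HSPs for one query (rows of [hits()]).
#' @return A single-row data.frame.
#' @export
bestHit <- function(hsps) {
  if (nrow(hsps) == 0) stop("no HSPs for query")
  hsps[hspOrder(hsps)[1L], , drop = FALSE]
}

#' Top-N hits for a query
#'
#' First `n` HSPs under the [bestHit()] ordering; fewer if fewer exist.
#'
#' @param hsps data.frame of HSPs for one query.
#' @param n number of hits to keep (>= 1).
#' @return data.frame of up to `n` rows.
#' @export
topHits <- function(hsps, n) {
  stopifnot(n >= 1)
  hsps[utils::head(hspOrder(hsps), n), , drop = FALSE]
}

#' Best hit per query over a whole table
#'
#' @param x a [HitTable-class] (typically already significance-filtered).
#' @return data.frame, one row per query (its best HSP), ordered by query id.
#' @export
bestHitsByQuery <- function(x) {
  h <- hits(x)
  if (nrow(h) == 0) return(h)
  o <- hspOrder(h)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  h[order(h$query_id, method = "radix"), , drop = FALSE]
}

#' Count distinct subjects among per-query best hits
#'
#' The "number of unique BLAST hits" statistic: distinct subject ids over a
#' one-best-hit-per-query mapping. Optionally strips trailing accession
#' versions (`.N`) before deduplication.
#'
#' @param best_hits data.frame with a `subject_id` column (one best hit per
#'   query, e.g. from [bestHitsByQuery()]) or a named character vector
#'   query id -> subject id.
#' @param strip_versions logical; drop a trailing `.<digits>` from subject
#'   ids before counting.
#' @return Integer count of distinct subjects.
#' @export
countUniqueSubjects <- function(best_hits, strip_versions = FALSE) {
  s <- if (is.data.frame(best_hits)) best_hits$subject_id
       else as.character(best_hits)
  if (strip_versions) s <- sub("\\.[0-9]+$", "", s)
  length(unique(s))
}
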