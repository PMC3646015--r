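## Reciprocal-best-hit orthology annotation with region-aware
## multi-assignment and isoform/paralog classification.

#' Annotator configuration
#'
#' @param e_cutoff significance cutoff applied to both hit directions
#'   (default 1e-5).
#' @param max_nonoverlap_aa residue overlap on the reference protein up to
#'   which two confirmed transcripts are accepted as orthologs of distinct
#'   regions (default 14; strictly more triggers the isoform/paralog
#'   branch).
#' @param top_n_forward candidates considered per reference protein
#'   (default 50).
#' @return A `predictor_config` list.
#' @export
predictorConfig <- function(e_cutoff = 1e-5, max_nonoverlap_aa = 14,
                            top_n_forward = 50) {
  stopifnot(e_cutoff > 0, max_nonoverlap_aa >= 0, top_n_forward >= 1)
  structure(list(e_cutoff = e_cutoff, max_nonoverlap_aa = max_nonoverlap_aa,
                 top_n_forward = top_n_forward), class = "predictor_config")
}

#' Reverse best-hit index: transcript to its best reference protein
#'
#' From a transcriptome-vs-proteome (blastx-style) table, the best
#' significant subject per transcript. Transcripts with no significant hit
#' are absent.
#'
#' @param reverse_hits [HitTable-class], queries are transcripts, subjects
#'   reference proteins.
#' @param cfg a [predictorConfig()].
#' @return Named character vector transcript id -> protein id.
#' @export
reverseBestIndex <- function(reverse_hits, cfg = predictorConfig()) {
  bh <- bestHitsByQuery(filterSignificant(reverse_hits, cfg$e_cutoff))
  stats::setNames(bh$subject_id, bh$query_id)
}

## interval overlap in residues (1-based inclusive); <= 0 means disjoint
aaOverlap <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2) + 1
}

#' Assign orthology by reciprocal best BLAST hit
#'
#' For each reference protein P (lexicographic order), candidate
#' transcripts from P's forward (tblastn-style) hits are visited in
#' (evalue, -bitscore, subject id) order, at most `top_n_forward` of them.
#' A candidate T is confirmed when the reverse index maps T back to P.
#' The first confirmed candidate is recorded as an ortholog. A later
#' confirmed candidate whose forward HSP overlaps every previously accepted
#' call for P by at most `max_nonoverlap_aa` residues (on P's coordinates)
#' is an ortholog of a distinct region; otherwise it is an isoform when it
#' is a singleton or shares an isogroup with any previously accepted call
#' for P, else a paralog. A transcript already assigned to another protein
#' is skipped (first assignment in protein order wins). A transcript that
#' fails reciprocal confirmation for one protein remains available to
#' others.
#'
#' @param forward_hits [HitTable-class], queries are reference proteins,
#'   subjects transcripts; protein residue coordinates on the query side.
#' @param reverse_index named vector from [reverseBestIndex()].
#' @param isogroup_map named character vector isotig id -> isogroup id.
#' @param kinds named character vector transcript id -> kind
#'   ("isotig"/"singleton"/"contig").
#' @param cfg a [predictorConfig()].
#' @return An [AnnotationTable-class].
#' @export
assignOrthology <- function(forward_hits, reverse_index, isogroup_map,
                            kinds, cfg = predictorConfig()) {
  h <- hits(filterSignificant(forward_hits, cfg$e_cutoff))
  unknown <- setdiff(unique(h$subject_id), names(kinds))
  if (length(unknown) > 0)
    stop("forward hit subject with unknown kind: ", unknown[1L])
  ## one representative HSP (the best under the tie rule) per
  ## (protein, transcript) pair
  o <- hspOrder(h)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(paste(h$query_id, h$subject_id, sep = "\r")), ,
         drop = FALSE]
  byProt <- split(h, h$query_id)
  assigned <- character(0)               # transcript -> protein
  out <- vector("list", length(byProt))
  names(out) <- names(byProt)
  for (p in sort(names(byProt))) {
    cand <- byProt[[p]]
    cand <- cand[utils::head(hspOrder(cand), cfg$top_n_forward), ,
                 drop = FALSE]
    acc_t <- character(0); acc_s <- integer(0); acc_e <- integer(0)
    acc_cat <- character(0); acc_ev <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      t <- cand$subject_id[i]
      if (t %in% names(assigned)) next          # first assignment wins
      if (is.na(reverse_index[t]) || reverse_index[t] != p) next
      ps <- min(cand$q_start[i], cand$q_end[i])
      pe <- max(cand$q_start[i], cand$q_end[i])
      if (length(acc_t) == 0) {
        cat <- "ortholog"
      } else {
        ov <- max(aaOverlap(ps, pe, acc_s, acc_e))
        if (ov <= cfg$max_nonoverlap_aa) {
          cat <- "ortholog"
        } else {
          sameGroup <- !is.na(isogroup_map[t]) &&
            any(isogroup_map[t] == isogroup_map[acc_t], na.rm = TRUE)
          cat <- if (identical(unname(kinds[t]), "singleton") || sameGroup)
            "isoform" else "paralog"
        }
      }
      acc_t <- c(acc_t, t); acc_s <- c(acc_s, ps); acc_e <- c(acc_e, pe)
      acc_cat <- c(acc_cat, cat); acc_ev <- c(acc_ev, cand$evalue[i])
      assigned[t] <- p
    }
    if (length(acc_t) > 0)
      out[[p]] <- data.frame(transcript_id = acc_t, protein_id = p,
                             category = acc_cat, p_start = acc_s,
                             p_end = acc_e, evalue = acc_ev)
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(calls))
    calls <- data.frame(transcript_id = character(), protein_id = character(),
                        category = character(), p_start = integer(),
                        p_end = integer(), evalue = numeric())
  AnnotationTable(calls)
}

#' Recovery of known transcript-to-protein pairs
#'
#' Fraction of an externally known mapping (e.g. manually annotated genes)
#' recovered by the annotator: a pair counts as recovered when the table
#' assigns the transcript to the known protein, in any category.
#'
#' @param table an [AnnotationTable-class].
#' @param known_pairs named character vector transcript id -> protein id.
#' @return List with `n_known`, `n_recovered`, `fraction`.
#' @export
evaluateAgainstKnown <- function(table, known_pairs) {
  if (length(known_pairs) == 0) stop("known_pairs is empty")
  cl <- orthologyCalls(table)
  got <- stats::setNames(cl$protein_id, cl$transcript_id)
  hit <- !is.na(got[names(known_pairs)]) &
    got[names(known_pairs)] == known_pairs
  list(n_known = length(known_pairs), n_recovered = sum(hit),
       fraction = sum(hit) / length(known_pairs))
}

#' Write orthology calls as TSV
#' @param table an [AnnotationTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOrthologyCalls <- function(table, path) {
  writeTsv(orthologyCalls(table), path)
}
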