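## Core data model: FASTA I/O, isogroup maps, basic assembly metrics.

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V")

#' Read assembly products from a FASTA file
#'
#' Reads a multi-record FASTA of assembly products and infers each product's
#' kind from its header. Newbler names isotigs `isotig#####` by convention,
#' so the default pattern classes ids matching `^isotig` as isotigs and
#' everything else as singletons; the convention is not guaranteed, hence
#' the pattern is configurable. Sequences are uppercased; `N` and other
#' IUPAC ambiguity codes are allowed and count toward the length.
#'
#' @param path FASTA file path.
#' @param isotig_pattern regex applied to ids; matching products become
#'   isotigs.
#' @param isogroup_map optional named character vector isotig id -> isogroup
#'   id (e.g. from [loadIsogroupMap()]). Required downstream for isotigs.
#' @return An [AssemblyCollection-class]. When no `isogroup_map` is given,
#'   each isotig is placed in its own provisional isogroup (`ig:<id>`).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">isotig00001", "ACGTACGT", ">r1", "TTGACA"), f)
#' readAssemblyFasta(f)
#' @export
readAssemblyFasta <- function(path, isotig_pattern = "^isotig",
                              isogroup_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate id ", ids[duplicated(ids)][1L])
  chs <- toupper(as.character(raw))
  bad <- regexpr(paste0("[^", paste(IUPAC_DNA, collapse = ""), "]"), chs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("non-IUPAC character '%s' in record %s at position %d",
                 substr(chs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  seqs <- Biostrings::DNAStringSet(chs)
  names(seqs) <- ids
  kind <- ifelse(grepl(isotig_pattern, ids), "isotig", "singleton")
  isogroup <- rep(NA_character_, length(ids))
  isIso <- kind == "isotig"
  if (!is.null(isogroup_map)) {
    isogroup[isIso] <- unname(isogroup_map[ids[isIso]])
    if (any(isIso & is.na(isogroup)))
      stop("isotig missing from isogroup map: ",
           ids[isIso & is.na(isogroup)][1L])
  } else {
    isogroup[isIso] <- paste0("ig:", ids[isIso])
  }
  AssemblyCollection(seqs, kind, isogroup)
}

#' Write assembly products to FASTA
#'
#' 60-column wrapped, ids as headers; a read/write round trip is
#' byte-identical on ids and sequences.
#'
#' @param x [AssemblyCollection-class] or named [Biostrings::DNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAssemblyFasta <- function(x, path) {
  seqs <- if (methods::is(x, "AssemblyCollection")) productSequences(x) else x
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Load an isotig-to-isogroup membership table
#'
#' Two-column TSV (isotig id, isogroup id), header line optional (detected
#' when the first field of the first line matches neither data row pattern
#' nor is it consistent; practically: a first line whose fields repeat in no
#' data row is treated as data unless it equals common header names).
#'
#' @param path TSV file path.
#' @return Named character vector isotig id -> isogroup id.
#' @export
loadIsogroupMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(tab) < 2) stop("isogroup map must have two columns")
  if (nrow(tab) > 0 &&
      tolower(tab[1, 1]) %in% c("isotig", "isotig_id", "id"))
    tab <- tab[-1, , drop = FALSE]
  m <- stats::setNames(tab[[2]], tab[[1]])
  dup <- duplicated(names(m))
  if (any(dup)) {
    clash <- names(m)[dup][1L]
    if (length(unique(m[names(m) == clash])) > 1)
      stop("isotig ", clash, " mapped to two isogroups")
    m <- m[!dup]
  }
  m
}

#' Write an isogroup map as 2-column TSV
#' @param map named character vector isotig id -> isogroup id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIsogroupMap <- function(map, path) {
  utils::write.table(data.frame(names(map), unname(map)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L hold at least
#' half the total assembled bases: sort descending, accumulate, take the
#' first length at which the cumulative sum reaches total/2.
#'
#' @param lengths positive integer vector of sequence lengths (bp).
#' @return N50 in bp.
#' @examples
#' n50(c(2, 3, 4, 5, 6))  # total 20; 6 + 5 = 11 >= 10, so 5
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- unname(sort(lengths, decreasing = TRUE))
  ## accumulate in double: totals beyond 2^31 bp overflow integer cumsum
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1L]]
}

#' Length distribution summary
#'
#' Min, max, median and mean; the median of an even-sized sample is the
#' midpoint of the two central values, so half-integral medians occur.
#'
#' @param lengths non-empty numeric vector of lengths (bp).
#' @return List with `n`, `min`, `max`, `median`, `mean`.
#' @export
lengthSummary <- function(lengths) {
  if (length(lengths) == 0) stop("empty length list")
  list(n = length(lengths), min = min(lengths), max = max(lengths),
       median = stats::median(lengths), mean = mean(lengths))
}

#' Per-contig read depth and average coverage
#'
#' Contig depth is total aligned read bp divided by contig length; the
#' assembly-wide average coverage per bp is total aligned bp over total
#' assembly bp (the length-weighted mean of the depths). Also counts
#' contigs at the extremes of the depth distribution.
#'
#' @param aligned_bp named numeric vector contig id -> total read bp aligned.
#' @param contig_lengths named numeric vector contig id -> contig length bp;
#'   same key set as `aligned_bp`.
#' @param low,high depth thresholds for the extreme-contig counts
#'   (defaults 10 and 10000).
#' @return List with `avg_coverage_per_bp`, `contig_depths` (named),
#'   `n_low` (depth <= low), `n_high` (depth >= high).
#' @export
coverageStats <- function(aligned_bp, contig_lengths, low = 10,
                          high = 10000) {
  if (!setequal(names(aligned_bp), names(contig_lengths)))
    stop("aligned_bp and contig_lengths must share the same contig ids")
  contig_lengths <- contig_lengths[names(aligned_bp)]
  if (any(contig_lengths <= 0)) stop("zero-length contig")
  depths <- aligned_bp / contig_lengths
  list(avg_coverage_per_bp = sum(aligned_bp) / sum(contig_lengths),
       contig_depths = depths,
       n_low = sum(depths <= low),
       n_high = sum(depths >= high))
}
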