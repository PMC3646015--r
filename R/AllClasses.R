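#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom stats median pt lm coef setNames rnorm runif
#' @importFrom utils read.delim write.table head
NULL

VALID_KINDS <- c("isotig", "singleton", "contig")

HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' AssemblyCollection: assembly products of a de novo transcriptome
#'
#' Container for the products of a 454/Newbler-style assembly: isotigs
#' (predicted transcripts, each belonging to an isogroup), singletons
#' (unassembled quality reads) and contigs. Sequences are held as an
#' uppercase [Biostrings::DNAStringSet] named by product id; `kind` and
#' `isogroup` run parallel to it. Isogroups -- the assembler's closest proxy
#' for genes -- are recoverable with [isogroupMap()] / [isogroups()].
#'
#' @slot sequences [Biostrings::DNAStringSet] named by unique product ids.
#' @slot kind character vector, one of `"isotig"`, `"singleton"`, `"contig"`.
#' @slot isogroup character vector; isogroup id for isotigs, `NA` otherwise.
#'
#' @section Validity:
#' Ids unique and non-empty; every sequence of length >= 1; every isotig has
#' an isogroup and every singleton has none.
#'
#' @export
setClass("AssemblyCollection",
  slots = c(sequences = "DNAStringSet",
            kind = "character",
            isogroup = "character"))

setValidity("AssemblyCollection", function(object) {
  ids <- names(object@sequences)
  n <- length(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    return("all products must have non-empty ids")
  if (anyDuplicated(ids))
    return(sprintf("duplicate id %s", ids[duplicated(ids)][1L]))
  if (length(object@kind) != n || length(object@isogroup) != n)
    return("kind and isogroup must run parallel to sequences")
  if (!all(object@kind %in% VALID_KINDS))
    return("kind must be one of isotig, singleton, contig")
  if (n > 0 && any(Biostrings::width(object@sequences) < 1))
    return("zero-length sequence present")
  iso <- object@kind == "isotig"
  if (any(iso & is.na(object@isogroup)))
    return("isotig without an isogroup id")
  if (any(object@kind == "singleton" & !is.na(object@isogroup)))
    return("singleton with an isogroup id")
  TRUE
})

#' Construct an AssemblyCollection
#'
#' @param sequences [Biostrings::DNAStringSet] (or named character vector)
#'   of product sequences, named by id.
#' @param kind character vector of product kinds (`"isotig"`, `"singleton"`,
#'   `"contig"`), recycled if length 1.
#' @param isogroup character vector of isogroup ids (`NA` where absent),
#'   recycled if length 1.
#' @return An `AssemblyCollection`.
#' @examples
#' ac <- AssemblyCollection(c(isotig00001 = "ACGTACGT", r1 = "TTTTAA"),
#'                          kind = c("isotig", "singleton"),
#'                          isogroup = c("ig1", NA))
#' productLengths(ac)
#' @export
AssemblyCollection <- function(sequences, kind, isogroup = NA_character_) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  n <- length(sequences)
  kind <- rep_len(as.character(kind), n)
  isogroup <- rep_len(as.character(isogroup), n)
  methods::new("AssemblyCollection", sequences = sequences, kind = kind,
               isogroup = isogroup)
}

#' HitTable: BLAST tabular hits
#'
#' One high-scoring segment pair (HSP) per row, in the 12-column tabular
#' dialect (qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore). File order is preserved within each query;
#' coordinates are kept 1-based inclusive exactly as read.
#'
#' @slot hits data.frame with the 12 canonical columns.
#' @slot program character; one of blastn, blastx, tblastn, tblastx
#'   (metadata only).
#' @export
setClass("HitTable",
  slots = c(hits = "data.frame", program = "character"))

setValidity("HitTable", function(object) {
  if (!identical(colnames(object@hits), HIT_COLUMNS))
    return("hits must have the 12 canonical BLAST tabular columns")
  h <- object@hits
  if (nrow(h) > 0) {
    if (any(h$evalue < 0)) return("negative E-value")
    if (any(h$pct_identity > 100)) return("percent identity above 100")
  }
  if (length(object@program) != 1L)
    return("program must be a single string")
  TRUE
})

#' Construct a HitTable from a data.frame of HSPs
#'
#' @param hits data.frame with the 12 canonical columns (see [HitTable-class]).
#' @param program BLAST program label (metadata).
#' @return A `HitTable`.
#' @export
HitTable <- function(hits = emptyHitFrame(), program = "blastn") {
  hits <- as.data.frame(hits)
  if (ncol(hits) == length(HIT_COLUMNS)) colnames(hits) <- HIT_COLUMNS
  rownames(hits) <- NULL
  methods::new("HitTable", hits = hits, program = program)
}

emptyHitFrame <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' AnnotationTable: orthology calls from the reciprocal-best-hit annotator
#'
#' One row per annotated transcript: the reference protein it is assigned
#' to, the call category (`ortholog`, `isoform`, `paralog`), the residue
#' interval the call occupies on the protein (from the forward HSP) and the
#' forward E-value.
#'
#' @slot calls data.frame with columns transcript_id, protein_id, category,
#'   p_start, p_end, evalue.
#' @export
setClass("AnnotationTable", slots = c(calls = "data.frame"))

setValidity("AnnotationTable", function(object) {
  need <- c("transcript_id", "protein_id", "category",
            "p_start", "p_end", "evalue")
  if (!all(need %in% colnames(object@calls)))
    return("calls must have transcript_id, protein_id, category, p_start, p_end, evalue")
  cl <- object@calls
  if (nrow(cl) > 0) {
    if (anyDuplicated(cl$transcript_id))
      return("a transcript may be assigned to at most one protein")
    if (!all(cl$category %in% c("ortholog", "isoform", "paralog")))
      return("category must be ortholog, isoform or paralog")
    if (any(cl$p_start > cl$p_end)) return("p_start > p_end")
  }
  TRUE
})

#' Construct an AnnotationTable from a data.frame of calls
#' @param calls data.frame with columns transcript_id, protein_id,
#'   category, p_start, p_end, evalue.
#' @return An `AnnotationTable`.
#' @export
AnnotationTable <- function(calls) {
  rownames(calls) <- NULL
  methods::new("AnnotationTable", calls = calls)
}

## ---- generics -------------------------------------------------------------

#' @rdname AssemblyCollection
#' @param x an object.
#' @export
setGeneric("productIds", function(x) standardGeneric("productIds"))
#' @rdname AssemblyCollection
#' @export
setGeneric("productKinds", function(x) standardGeneric("productKinds"))
#' @rdname AssemblyCollection
#' @export
setGeneric("productLengths", function(x) standardGeneric("productLengths"))
#' @rdname AssemblyCollection
#' @export
setGeneric("isogroupMap", function(x) standardGeneric("isogroupMap"))
#' @rdname AssemblyCollection
#' @export
setGeneric("isogroups", function(x) standardGeneric("isogroups"))

#' @rdname HitTable
#' @param x an object.
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @rdname HitTable
#' @export
setGeneric("blastProgram", function(x) standardGeneric("blastProgram"))

#' @rdname AnnotationTable
#' @param x an object.
#' @export
setGeneric("orthologyCalls", function(x) standardGeneric("orthologyCalls"))

setMethod("productIds", "AssemblyCollection",
          function(x) names(x@sequences))
setMethod("productKinds", "AssemblyCollection",
          function(x) stats::setNames(x@kind, names(x@sequences)))
setMethod("productLengths", "AssemblyCollection",
          function(x) stats::setNames(Biostrings::width(x@sequences),
                                      names(x@sequences)))
#' @describeIn AssemblyCollection named character vector isotig id ->
#'   isogroup id (isotigs only).
setMethod("isogroupMap", "AssemblyCollection", function(x) {
  sel <- x@kind == "isotig"
  stats::setNames(x@isogroup[sel], names(x@sequences)[sel])
})
#' @describeIn AssemblyCollection list isogroup id -> character vector of
#'   member isotig ids.
setMethod("isogroups", "AssemblyCollection", function(x) {
  m <- isogroupMap(x)
  split(names(m), m)
})
setMethod("hits", "HitTable", function(x) x@hits)
setMethod("blastProgram", "HitTable", function(x) x@program)
setMethod("orthologyCalls", "AnnotationTable", function(x) x@calls)

#' @describeIn AssemblyCollection number of products.
#' @export
setMethod("length", "AssemblyCollection", function(x) length(x@sequences))

#' Extract sequences of an AssemblyCollection
#' @param x an `AssemblyCollection`.
#' @param i character, integer or logical product index.
#' @param j,drop,... ignored.
#' @return An `AssemblyCollection` restricted to the selected products.
#' @export
setMethod("[", "AssemblyCollection", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  methods::new("AssemblyCollection", sequences = x@sequences[i],
               kind = x@kind[i], isogroup = x@isogroup[i])
})

#' Sequences of an AssemblyCollection
#' @param x an `AssemblyCollection`.
#' @return The underlying [Biostrings::DNAStringSet].
#' @export
productSequences <- function(x) x@sequences

setMethod("show", "AssemblyCollection", function(object) {
  k <- table(factor(object@kind, VALID_KINDS))
  cat("AssemblyCollection with", length(object@sequences), "products (",
      k[["isotig"]], "isotigs in",
      length(unique(stats::na.omit(object@isogroup))), "isogroups,",
      k[["singleton"]], "singletons,", k[["contig"]], "contigs )\n")
  if (length(object@sequences) > 0)
    cat("  length range:", min(Biostrings::width(object@sequences)), "-",
        max(Biostrings::width(object@sequences)), "bp\n")
})

setMethod("show", "HitTable", function(object) {
  cat("HitTable (", object@program, "):", nrow(object@hits), "HSPs,",
      length(unique(object@hits$query_id)), "queries\n")
})

setMethod("show", "AnnotationTable", function(object) {
  tab <- table(factor(object@calls$category,
                      c("ortholog", "isoform", "paralog")))
  cat("AnnotationTable:", nrow(object@calls), "calls to",
      length(unique(object@calls$protein_id)), "proteins (",
      tab[["ortholog"]], "orthologs,", tab[["isoform"]], "isoforms,",
      tab[["paralog"]], "paralogs )\n")
})
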