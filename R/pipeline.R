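## End-to-end orchestration: redundancy filter -> reciprocal-best-hit
## annotation -> ortholog hit ratio -> partitions, with TSV artifacts.

writeTsv <- function(df, path, header = TRUE) {
  if (header)
    cat("#", paste(colnames(df), collapse = "\t"), "\n", sep = "",
        file = path)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE,
                       append = header))
  invisible(path)
}

#' Read a 2-column id/length TSV
#' @param path TSV path (id, length; '#' comments skipped).
#' @return Named numeric vector.
#' @export
readLengthTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = c("character", "numeric"))
  stats::setNames(tab[[2]], tab[[1]])
}

#' Run configuration for the annotation pipeline
#'
#' @param fasta assembly FASTA path.
#' @param isogroups isogroup map TSV path (optional when the assembly has
#'   no isotigs).
#' @param self_hits,forward_hits,reverse_hits BLAST tabular paths
#'   (self: assembly vs itself, blastn; forward: proteome vs assembly,
#'   tblastn; reverse: assembly vs proteome, blastx).
#' @param ref_lengths reference transcript length TSV (id, length).
#' @param out_dir output directory.
#' @param e_cutoff,min_identity,max_overlap_aa,top_n thresholds (defaults
#'   1e-5, 95, 14, 50).
#' @param ohr_thresholds completeness thresholds for the OHR summary.
#' @return A `run_config` list.
#' @export
runConfig <- function(fasta, isogroups = NULL, self_hits = NULL,
                      forward_hits = NULL, reverse_hits = NULL,
                      ref_lengths = NULL, out_dir = ".",
                      e_cutoff = 1e-5, min_identity = 95,
                      max_overlap_aa = 14, top_n = 50,
                      ohr_thresholds = c(0.5, 0.8)) {
  stopifnot(e_cutoff > 0, min_identity > 0, min_identity <= 100,
            max_overlap_aa >= 0, top_n >= 1)
  structure(list(fasta = fasta, isogroups = isogroups,
                 self_hits = self_hits, forward_hits = forward_hits,
                 reverse_hits = reverse_hits, ref_lengths = ref_lengths,
                 out_dir = out_dir, e_cutoff = e_cutoff,
                 min_identity = min_identity,
                 max_overlap_aa = max_overlap_aa, top_n = top_n,
                 ohr_thresholds = ohr_thresholds), class = "run_config")
}

pipelineStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the annotation pipeline
#'
#' Orchestrates the post-assembly stages in order: load the assembly,
#' remove redundant products, build the reverse best-hit index, assign
#' orthology, compute ortholog hit ratios and the hit/no-hit partition,
#' and write the artifact set (non-redundant FASTA, removals TSV, calls
#' TSV, OHR TSVs, labels TSV, summary TSV). Output is a pure function of
#' the inputs and thresholds; every threshold used is echoed in the
#' summary.
#'
#' @param config a [runConfig()].
#' @return List with `collection` (non-redundant
#'   [AssemblyCollection-class]), `removals`, `annotation`
#'   ([AnnotationTable-class] or NULL), `ohr` (records or NULL),
#'   `ohr_summary`, `nr_partition`, and `files` (written paths).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  ig <- NULL
  if (!is.null(config$isogroups))
    ig <- pipelineStage("isogroups", loadIsogroupMap(config$isogroups))
  ac <- pipelineStage("fasta",
    readAssemblyFasta(config$fasta, isogroup_map = ig))
  if (is.null(config$isogroups) && any(productKinds(ac) == "isotig"))
    stop("[isogroups] isotigs present but no isogroup file given")

  removals <- NULL
  if (!is.null(config$self_hits)) {
    self <- pipelineStage("self_hits", readBlastTab(config$self_hits))
    nr <- pipelineStage("redundancy",
      filterRedundant(ac, self, redundancyRule(config$min_identity)))
    removals <- nr$removals
    ac <- ac[nr$kept]
    writeTsv(removals, out("removals.tsv"))
    files["removals"] <- out("removals.tsv")
  }
  writeAssemblyFasta(ac, out("nonredundant.fa"))
  files["nonredundant"] <- out("nonredundant.fa")

  ann <- NULL
  if (!is.null(config$forward_hits) && !is.null(config$reverse_hits)) {
    cfg <- predictorConfig(config$e_cutoff, config$max_overlap_aa,
                           config$top_n)
    fwd <- pipelineStage("forward_hits",
                         readBlastTab(config$forward_hits, "tblastn"))
    rev <- pipelineStage("reverse_hits",
                         readBlastTab(config$reverse_hits, "blastx"))
    ## restrict homology evidence to retained products
    fwd <- HitTable(hits(fwd)[hits(fwd)$subject_id %in% productIds(ac), ],
                    blastProgram(fwd))
    rev <- HitTable(hits(rev)[hits(rev)$query_id %in% productIds(ac), ],
                    blastProgram(rev))
    ann <- pipelineStage("orthology",
      assignOrthology(fwd, reverseBestIndex(rev, cfg), isogroupMap(ac),
                      productKinds(ac), cfg))
    writeOrthologyCalls(ann, out("calls.tsv"))
    files["calls"] <- out("calls.tsv")
  }

  ohr <- NULL; ohr_sum <- NULL
  if (!is.null(ann) && !is.null(config$ref_lengths) &&
      nrow(orthologyCalls(ann)) > 0) {
    refLen <- pipelineStage("ref_lengths",
                            readLengthTable(config$ref_lengths))
    ohr <- pipelineStage("ohr",
      computeOhr(ann, productLengths(ac), refLen))
    ohr_sum <- summarizeOhr(ohr, config$ohr_thresholds)
    writeTsv(ohr, out("ohr.tsv"))
    hist_df <- data.frame(bin = names(ohr_sum$histogram),
                          count = unname(ohr_sum$histogram))
    writeTsv(hist_df, out("ohr_hist.tsv"))
    files["ohr"] <- out("ohr.tsv")
    files["ohr_hist"] <- out("ohr_hist.tsv")
  }

  part <- NULL
  if (!is.null(config$reverse_hits)) {
    rev <- readBlastTab(config$reverse_hits, "blastx")
    part <- partitionByNr(productIds(ac), rev, config$e_cutoff)
    writeTsv(data.frame(id = names(part), label = as.character(part)),
             out("labels.tsv"))
    files["labels"] <- out("labels.tsv")
  }

  summary_df <- data.frame(
    key = c("n_products", "n_removed", "n_calls", "e_cutoff",
            "min_identity", "max_overlap_aa", "top_n"),
    value = c(length(ac),
              if (is.null(removals)) 0 else nrow(removals),
              if (is.null(ann)) 0 else nrow(orthologyCalls(ann)),
              config$e_cutoff, config$min_identity,
              config$max_overlap_aa, config$top_n))
  writeTsv(summary_df, out("summary.tsv"))
  files["summary"] <- out("summary.tsv")

  list(collection = ac, removals = removals, annotation = ann,
       ohr = ohr, ohr_summary = ohr_sum, nr_partition = part,
       files = files)
}
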