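## Category partitions of assembly products (nr-hit / no-hit, coding,
## domain-bearing, clade-exclusive) and domain/proteome composition.

#' Partition products by presence of a significant database hit
#'
#' @param product_ids character vector of product ids (superset of the hit
#'   table's query ids).
#' @param nr_hits [HitTable-class] of products vs a reference database.
#' @param e_cutoff significance cutoff (default 1e-5).
#' @return Named factor over `product_ids` with levels `nr_hit`,
#'   `no_nr_hit`.
#' @export
partitionByNr <- function(product_ids, nr_hits, e_cutoff = 1e-5) {
  sig <- unique(hits(filterSignificant(nr_hits, e_cutoff))$query_id)
  extra <- setdiff(sig, product_ids)
  if (length(extra) > 0)
    stop("hit table query not among product ids: ", extra[1L])
  f <- factor(ifelse(product_ids %in% sig, "nr_hit", "no_nr_hit"),
              levels = c("nr_hit", "no_nr_hit"))
  stats::setNames(f, product_ids)
}

#' Partition unidentified products by clade-restricted similarity
#'
#' Among products lacking a reference-database hit, classes them by
#' significant similarity to two clade sequence collections: exclusive to
#' A, exclusive to B, both, or neither. The four classes partition the
#' input exactly; swapping A and B swaps the exclusive labels.
#'
#' @param no_hit_ids ids of products without a reference-database hit.
#' @param cladeA_hits,cladeB_hits [HitTable-class]s of those products vs
#'   each clade collection.
#' @param e_cutoff significance cutoff (default 1e-5).
#' @return Named factor with levels `excl_cladeA`, `excl_cladeB`,
#'   `both_clades`, `no_clade`.
#' @export
cladePartition <- function(no_hit_ids, cladeA_hits, cladeB_hits,
                           e_cutoff = 1e-5) {
  inA <- no_hit_ids %in% hits(filterSignificant(cladeA_hits, e_cutoff))$query_id
  inB <- no_hit_ids %in% hits(filterSignificant(cladeB_hits, e_cutoff))$query_id
  lab <- ifelse(inA & inB, "both_clades",
         ifelse(inA, "excl_cladeA",
         ifelse(inB, "excl_cladeB", "no_clade")))
  stats::setNames(factor(lab, levels = c("excl_cladeA", "excl_cladeB",
                                         "both_clades", "no_clade")),
                  no_hit_ids)
}

#' Overlay coding-region and protein-domain status
#'
#' Marks products with at least one predicted coding region (ESTScan-style
#' calls) as coding, and coding products with at least one domain row
#' (InterProScan-style table) as domain-bearing. Domains are predicted on
#' coding regions, so a domain row for a product without a coding call
#' violates containment and errors unless `relax = TRUE`.
#'
#' @param ids product ids to label.
#' @param coding_calls data.frame with column `id` (one row per predicted
#'   coding region; extra columns such as cds_start/cds_end/strand
#'   ignored).
#' @param domain_table data.frame with column `id` (one row per domain
#'   match; extra columns ignored).
#' @param relax logical; allow domain rows on non-coding products (they are
#'   then ignored rather than an error).
#' @return data.frame with id, coding, domain_bearing (logicals).
#' @export
codingDomainOverlay <- function(ids, coding_calls, domain_table,
                                relax = FALSE) {
  coding <- ids %in% unique(coding_calls$id)
  withDom <- ids %in% unique(domain_table$id)
  viol <- withDom & !coding
  if (any(viol) && !relax)
    stop("domain annotation without a coding call for ", ids[viol][1L],
         " (use relax = TRUE to ignore)")
  data.frame(id = ids, coding = coding,
             domain_bearing = coding & withDom)
}

#' Tally protein-domain families
#'
#' Collapses raw domain accessions into families via `family_map` (e.g. the
#' many zinc-finger Pfam accessions into one "zinc finger (combined)"
#' family; unmapped accessions pass through as their own family),
#' deduplicates per sequence within a family, and reports the `top_k`
#' most frequent families with proportions over the top-k total.
#'
#' @param domain_table data.frame with columns `id`, `accession` (a `name`
#'   column and others are ignored).
#' @param family_map named character vector accession -> family key; may be
#'   empty.
#' @param sequence_subset optional ids restricting the tally.
#' @param top_k families reported in the ranked summary (default 25).
#' @param per_sequence logical; `TRUE` (default) counts each (sequence,
#'   family) incidence once, `FALSE` counts every row.
#' @return List with `counts` (all families, named, ranked descending with
#'   lexicographic tie-break) and `top` (data.frame family, count,
#'   proportion over the top-k total).
#' @export
tallyDomains <- function(domain_table, family_map = character(0),
                         sequence_subset = NULL, top_k = 25,
                         per_sequence = TRUE) {
  d <- domain_table
  if (!is.null(sequence_subset)) d <- d[d$id %in% sequence_subset, ,
                                        drop = FALSE]
  fam <- family_map[d$accession]
  fam[is.na(fam)] <- d$accession[is.na(fam)]
  if (per_sequence) {
    keep <- !duplicated(paste(d$id, fam, sep = "\r"))
    fam <- fam[keep]
  }
  counts <- table(fam)
  counts <- counts[order(-as.integer(counts), names(counts),
                         method = "radix")]
  counts <- stats::setNames(as.integer(counts), names(counts))
  top <- utils::head(counts, top_k)
  top_df <- data.frame(family = names(top), count = unname(top),
                       proportion = unname(top) / sum(top))
  list(counts = counts, top = top_df)
}

#' Representation of a reference proteome in the assembly
#'
#' Fraction of a proteome's proteins with at least one significant hit
#' from/to the assembly.
#'
#' @param proteome_ids all protein ids of the proteome.
#' @param hits_table [HitTable-class]; direction declares whether proteome
#'   proteins are the subjects (`"assembly_to_proteome"`, blastx-style,
#'   default) or the queries (`"proteome_to_assembly"`).
#' @param e_cutoff significance cutoff (default 1e-5).
#' @param direction see above.
#' @param proteome_name label carried into the result.
#' @return List with `proteome_name`, `n_proteins`, `n_with_match`,
#'   `fraction`.
#' @export
proteomeRepresentation <- function(proteome_ids, hits_table,
                                   e_cutoff = 1e-5,
                                   direction = c("assembly_to_proteome",
                                                 "proteome_to_assembly"),
                                   proteome_name = "proteome") {
  direction <- match.arg(direction)
  h <- hits(filterSignificant(hits_table, e_cutoff))
  matched <- unique(if (direction == "assembly_to_proteome") h$subject_id
                    else h$query_id)
  nm <- sum(proteome_ids %in% matched)
  list(proteome_name = proteome_name, n_proteins = length(proteome_ids),
       n_with_match = nm, fraction = nm / length(proteome_ids))
}
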