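## Synthetic ground truth: a gene set with paralog families, splice
## isoforms, isogroup structure, planted full-span duplicates, clade
## membership and domain annotations, plus emulated BLAST hit tables
## consistent with the planted homology. Homology is declared by the truth
## tables, not rediscovered by alignment, so sequences are uniform random
## nucleotides with planted substrings (no codon or 454 error model).

DOMAIN_POOL <- c("DUF_combined", "zinc_finger_combined", "ubiquitin",
                 "RRM_1", "Pkinase", "Ank", "BTB_POZ", "ribosomal_combined",
                 "F-box", "LRR_1")

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateSeq <- function(s, n_mut) {
  if (n_mut == 0) return(s)
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), n_mut)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

#' Generate a synthetic truth set
#'
#' Builds `n_genes` reference proteins and a transcriptome whose planted
#' relations exercise every annotation rule: 1:1 orthologs; alternate
#' isoforms (same isogroup as, or a singleton alongside, an accepted call,
#' overlapping it by more than 14 residues); paralogs (a different isogroup
#' overlapping by more than 14 residues); region-split orthologs (intervals
#' overlapping by at most 14 residues, including exact-boundary pairs at 14
#' and disjoint pairs); full-span contained duplicates at 96-100 percent
#' identity plus near-misses at 90 percent or with partial span (which must
#' survive the redundancy filter); clade membership and domain annotations
#' for the partition analyses. Deterministic for a fixed seed.
#'
#' @param n_genes number of reference genes (>= 1).
#' @param isoform_rate,paralog_rate,split_rate fractions of genes given an
#'   isoform partner, a paralog partner, or a second region-split ortholog;
#'   must sum below 1.
#' @param dup_rate fraction of primary transcripts given a planted
#'   contained duplicate (and half that rate, a near-miss decoy).
#' @param coding_rate fraction of transcripts with a planted coding region.
#' @param domain_rate fraction of coding transcripts with planted domains.
#' @param seed integer RNG seed.
#' @return A `truth_set` list: `proteins` (named aa lengths),
#'   `ref_transcript_len` (named nt cDNA lengths per protein),
#'   `transcripts` (data.frame id, kind, isogroup, length_nt, protein,
#'   category, p_start, p_end, rank), `sequences` (DNAStringSet of all
#'   products incl. duplicates), `duplicates` (data.frame contained_id,
#'   container_id, identity, full_span, removable), `clades` (data.frame
#'   id, clade in A/B/both/none), `coding` (data.frame id, cds_start,
#'   cds_end, strand), `domains` (data.frame id, accession, name),
#'   `params`.
#' @export
generateTruth <- function(n_genes = 500, isoform_rate = 0.08,
                          paralog_rate = 0.06, split_rate = 0.04,
                          dup_rate = 0.05, coding_rate = 0.3,
                          domain_rate = 0.5, seed = 1) {
  stopifnot(n_genes >= 1, isoform_rate >= 0, paralog_rate >= 0,
            split_rate >= 0, dup_rate >= 0, dup_rate < 1)
  if (isoform_rate + paralog_rate + split_rate >= 1)
    stop("isoform, paralog and split rates must sum below 1")
  withPrivateSeed(seed, function() {
    pid <- sprintf("P%05d", seq_len(n_genes))
    plen <- sample(200:800, n_genes, replace = TRUE)
    refUtr <- sample(50:400, n_genes, replace = TRUE)
    roles <- sample(c("simple", "isoform", "paralog", "split"), n_genes,
                    replace = TRUE,
                    prob = c(1 - isoform_rate - paralog_rate - split_rate,
                             isoform_rate, paralog_rate, split_rate))
    tr <- list(); ig_counter <- 0L
    for (i in seq_len(n_genes)) {
      L <- plen[i]
      ig_counter <- ig_counter + 1L
      ig1 <- sprintf("ig%05d", ig_counter)
      t1 <- sprintf("isotig%05d", length(tr) + 1L)
      ## primary call covers a prefix region of the protein
      span1 <- max(60L, floor(L * stats::runif(1, 0.5, 0.95)))
      p1s <- 1L; p1e <- span1
      tr[[length(tr) + 1]] <- data.frame(
        id = t1, kind = "isotig", isogroup = ig1,
        length_nt = span1 * 3L + sample(0:300, 1), protein = pid[i],
        category = "ortholog", p_start = p1s, p_end = p1e, rank = 1L)
      role <- roles[i]
      if (role == "isoform") {
        asSingleton <- stats::runif(1) < 0.5
        t2 <- if (asSingleton) sprintf("GBSNG%05d", length(tr) + 1L)
              else sprintf("isotig%05d", length(tr) + 1L)
        ## overlap strictly above the 14-aa rule; some exactly at 15
        ov <- if (stats::runif(1) < 0.25) 15L
              else sample(16:min(40L, span1 - 1L), 1)
        p2s <- p1e - ov + 1L
        p2e <- min(L, p2s + sample(40:120, 1))
        tr[[length(tr) + 1]] <- data.frame(
          id = t2, kind = if (asSingleton) "singleton" else "isotig",
          isogroup = if (asSingleton) NA_character_ else ig1,
          length_nt = (p2e - p2s + 1L) * 3L + sample(0:150, 1),
          protein = pid[i], category = "isoform",
          p_start = p2s, p_end = p2e, rank = 2L)
      } else if (role == "paralog") {
        ig_counter <- ig_counter + 1L
        t2 <- sprintf("isotig%05d", length(tr) + 1L)
        ov <- if (stats::runif(1) < 0.25) 15L
              else sample(16:min(40L, span1 - 1L), 1)
        p2s <- p1e - ov + 1L
        p2e <- min(L, p2s + sample(40:120, 1))
        tr[[length(tr) + 1]] <- data.frame(
          id = t2, kind = "isotig", isogroup = sprintf("ig%05d", ig_counter),
          length_nt = (p2e - p2s + 1L) * 3L + sample(0:150, 1),
          protein = pid[i], category = "paralog",
          p_start = p2s, p_end = p2e, rank = 2L)
      } else if (role == "split") {
        ig_counter <- ig_counter + 1L
        t2 <- sprintf("isotig%05d", length(tr) + 1L)
        ## distinct-region ortholog: overlap exactly 14 (boundary) or
        ## disjoint; cap the first span so the protein has room
        p1e <- min(p1e, L - 30L); span1 <- p1e
        tr[[length(tr)]]$p_end <- p1e
        tr[[length(tr)]]$length_nt <- span1 * 3L +
          tr[[length(tr)]]$length_nt %% 301L
        ov <- if (stats::runif(1) < 0.5) 14L else -sample(1:10, 1)
        p2s <- p1e - ov + 1L
        p2e <- min(L, p2s + sample(20:80, 1))
        tr[[length(tr) + 1]] <- data.frame(
          id = t2, kind = "isotig", isogroup = sprintf("ig%05d", ig_counter),
          length_nt = (p2e - p2s + 1L) * 3L + sample(0:150, 1),
          protein = pid[i], category = "ortholog",
          p_start = p2s, p_end = p2e, rank = 2L)
      }
    }
    transcripts <- do.call(rbind, tr)
    rownames(transcripts) <- NULL
    seqs <- vapply(transcripts$length_nt, randSeq, character(1))
    names(seqs) <- transcripts$id
    ## planted duplicates: full-span containments above the identity rule,
    ## plus near-misses (90% identity, or partial span) that must survive
    dup <- list()
    primaries <- transcripts$id[transcripts$rank == 1L]
    nd <- floor(dup_rate * length(primaries))
    if (nd > 0) {
      hosts <- sample(primaries, nd)
      idents <- sample(c(96, 98, 100), nd, replace = TRUE)
      for (j in seq_len(nd)) {
        host <- hosts[j]; hs <- seqs[[host]]
        dl <- floor(nchar(hs) * stats::runif(1, 0.4, 0.9))
        st <- sample(seq_len(nchar(hs) - dl + 1L), 1)
        frag <- substr(hs, st, st + dl - 1L)
        frag <- mutateSeq(frag, floor(dl * (100 - idents[j]) / 100))
        did <- sprintf("GBDUP%05d", j)
        seqs[did] <- frag
        dup[[length(dup) + 1]] <- data.frame(
          contained_id = did, container_id = host, identity = idents[j],
          full_span = TRUE, removable = TRUE)
      }
      nmiss <- max(1L, floor(nd / 2))
      hosts2 <- sample(setdiff(primaries, hosts), nmiss)
      for (j in seq_len(nmiss)) {
        host <- hosts2[j]; hs <- seqs[[host]]
        dl <- floor(nchar(hs) * 0.6)
        frag <- substr(hs, 1, dl)
        partial <- j %% 2 == 0
        idn <- if (partial) 99 else 90
        frag <- mutateSeq(frag, floor(dl * (100 - idn) / 100))
        did <- sprintf("GBMISS%05d", j)
        seqs[did] <- frag
        dup[[length(dup) + 1]] <- data.frame(
          contained_id = did, container_id = host, identity = idn,
          full_span = !partial, removable = FALSE)
      }
    }
    duplicates <- if (length(dup)) do.call(rbind, dup) else
      data.frame(contained_id = character(), container_id = character(),
                 identity = numeric(), full_span = logical(),
                 removable = logical())
    ## clade membership and coding/domain overlays over the transcripts
    clade <- sample(c("A", "B", "both", "none"), nrow(transcripts),
                    replace = TRUE, prob = c(0.05, 0.05, 0.03, 0.87))
    coding <- stats::runif(nrow(transcripts)) < coding_rate
    cods <- transcripts[coding, c("id", "length_nt")]
    coding_df <- if (nrow(cods)) data.frame(
      id = cods$id, cds_start = 1L,
      cds_end = pmax(3L, (cods$length_nt %/% 3L) * 3L), strand = "+") else
      data.frame(id = character(), cds_start = integer(),
                 cds_end = integer(), strand = character())
    dom <- list()
    for (id in cods$id) if (stats::runif(1) < domain_rate) {
      fams <- sample(DOMAIN_POOL, sample(1:3, 1))
      dom[[length(dom) + 1]] <- data.frame(id = id, accession = fams,
                                           name = fams)
    }
    domains <- if (length(dom)) do.call(rbind, dom) else
      data.frame(id = character(), accession = character(),
                 name = character())
    structure(list(
      proteins = stats::setNames(plen, pid),
      ref_transcript_len = stats::setNames(plen * 3L + refUtr, pid),
      transcripts = transcripts,
      sequences = Biostrings::DNAStringSet(seqs),
      duplicates = duplicates,
      clades = data.frame(id = transcripts$id, clade = clade),
      coding = coding_df, domains = domains,
      params = list(n_genes = n_genes, isoform_rate = isoform_rate,
                    paralog_rate = paralog_rate, split_rate = split_rate,
                    dup_rate = dup_rate, seed = seed)),
      class = "truth_set")
  })
}

#' Truth set as an AssemblyCollection
#' @param truth a `truth_set` from [generateTruth()].
#' @param include_duplicates logical; include the planted redundant copies.
#' @return An [AssemblyCollection-class].
#' @export
truthAssembly <- function(truth, include_duplicates = TRUE) {
  tt <- truth$transcripts
  ids <- names(truth$sequences)
  kind <- stats::setNames(rep("singleton", length(ids)), ids)
  kind[tt$id] <- tt$kind
  ig <- stats::setNames(rep(NA_character_, length(ids)), ids)
  ig[tt$id] <- tt$isogroup
  ac <- AssemblyCollection(truth$sequences, unname(kind), unname(ig))
  if (!include_duplicates)
    ac <- ac[setdiff(ids, truth$duplicates$contained_id)]
  ac
}

#' Emulate a BLAST tabular hit table from a truth set
#'
#' Noise-free mode emits exactly the HSPs implied by the planted relations:
#' forward (tblastn-style, protein vs transcriptome) rows carry the planted
#' protein-residue intervals with E-values ranked so planted rank-1 calls
#' are best; reverse (blastx-style) rows map each transcript to its planted
#' protein; self (blastn all-vs-all) rows carry the planted containments at
#' their planted identities and spans; clade tables carry rows for members
#' of the requested clade. `drop_rate` removes true rows (the removed
#' transcript ids are recorded in attribute `"dropped"`); `decoy_rate`
#' injects non-reciprocal rows with E-values strictly worse than any true
#' row for the same query, so decoys never displace a true best hit.
#'
#' @param truth a `truth_set` from [generateTruth()].
#' @param direction one of `"forward"`, `"reverse"`, `"self"`, `"cladeA"`,
#'   `"cladeB"`.
#' @param drop_rate fraction of true rows dropped.
#' @param decoy_rate fraction of queries given a decoy row.
#' @param seed RNG seed for the noise draws.
#' @return A [HitTable-class]; attribute `"dropped"` lists the query ids of
#'   dropped true rows.
#' @export
emulateHits <- function(truth, direction = c("forward", "reverse", "self",
                        "cladeA", "cladeB"), drop_rate = 0, decoy_rate = 0,
                        seed = 1) {
  direction <- match.arg(direction)
  tt <- truth$transcripts
  hsp <- function(q, s, pid, alen, qs, qe, ss, se, ev, bits) {
    data.frame(query_id = q, subject_id = s, pct_identity = pid,
               aln_len = as.integer(alen), mismatches = 0L, gap_opens = 0L,
               q_start = as.integer(qs), q_end = as.integer(qe),
               s_start = as.integer(ss), s_end = as.integer(se),
               evalue = ev, bitscore = bits)
  }
  span <- tt$p_end - tt$p_start + 1L
  h <- switch(direction,
    forward = hsp(tt$protein, tt$id, 60, span, tt$p_start, tt$p_end,
                  1L, span * 3L, 10^-(60 - 5 * (tt$rank - 1L)),
                  500 - 50 * (tt$rank - 1L)),
    reverse = hsp(tt$id, tt$protein, 60, span, 1L, span * 3L,
                  tt$p_start, tt$p_end, 1e-40, 400),
    self = {
      d <- truth$duplicates
      if (nrow(d) == 0) emptyHitFrame() else {
        w <- stats::setNames(Biostrings::width(truth$sequences),
                             names(truth$sequences))
        dl <- w[d$contained_id]
        qe <- ifelse(d$full_span, dl, pmax(1L, dl - 60L))
        hsp(d$contained_id, d$container_id, d$identity, qe, 1L, qe,
            1L, qe, 1e-80, 800)
      }
    },
    cladeA = ,
    cladeB = {
      want <- if (direction == "cladeA") c("A", "both") else c("B", "both")
      m <- truth$clades[truth$clades$clade %in% want, , drop = FALSE]
      if (nrow(m) == 0) emptyHitFrame() else
        hsp(m$id, sprintf("%s%05d",
                          if (direction == "cladeA") "LK" else "LM",
                          seq_len(nrow(m))),
            70, 100L, 1L, 100L, 1L, 100L, 1e-8, 120)
    })
  dropped <- character(0)
  if (nrow(h) > 0 && (drop_rate > 0 || decoy_rate > 0)) {
    h <- withPrivateSeed(seed + 7L, function() {
      if (drop_rate > 0) {
        k <- floor(drop_rate * nrow(h))
        if (k > 0) {
          out <- sample(nrow(h), k)
          dropped <<- h$query_id[out]
          h <- h[-out, , drop = FALSE]
        }
      }
      if (decoy_rate > 0) {
        qs <- unique(h$query_id)
        pick <- qs[stats::runif(length(qs)) < decoy_rate]
        if (length(pick) > 0) {
          subj <- sample(unique(h$subject_id), length(pick), replace = TRUE)
          dec <- hsp(pick, subj, 40, 80L, 1L, 80L, 1L, 80L, 1e-10, 60)
          h <- rbind(h, dec)
        }
      }
      h
    })
  }
  ht <- HitTable(h, program = switch(direction, forward = "tblastn",
                                     reverse = "blastx", "blastn"))
  attr(ht, "dropped") <- dropped
  ht
}

#' Planted transcript-to-protein pairs
#' @param truth a `truth_set`.
#' @return data.frame transcript_id, protein_id, category (the planted
#'   categories, in planted order).
#' @export
truthPairs <- function(truth) {
  data.frame(transcript_id = truth$transcripts$id,
             protein_id = truth$transcripts$protein,
             category = truth$transcripts$category)
}

#' Write a complete synthetic bundle to a directory
#'
#' Emits the dialects the pipeline consumes: assembly FASTA, isogroup TSV,
#' forward/reverse/self/clade hit tables, reference transcript lengths,
#' coding calls and domain table.
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @param drop_rate,decoy_rate,seed noise settings passed to
#'   [emulateHits()].
#' @return Named character vector of the written paths, invisibly.
#' @export
writeTruthBundle <- function(truth, dir, drop_rate = 0, decoy_rate = 0,
                             seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  ac <- truthAssembly(truth)
  writeAssemblyFasta(ac, p("assembly.fa"))
  writeIsogroupMap(isogroupMap(ac), p("isogroups.tsv"))
  for (d in c("forward", "reverse", "self", "cladeA", "cladeB"))
    writeBlastTab(emulateHits(truth, d, drop_rate, decoy_rate, seed),
                  p(paste0(d, ".tsv")))
  writeTsv(data.frame(id = names(truth$ref_transcript_len),
                      length = unname(truth$ref_transcript_len)),
           p("ref_lengths.tsv"))
  writeTsv(truth$coding, p("coding.tsv"))
  writeTsv(truth$domains, p("domains.tsv"))
  writeTsv(truthPairs(truth), p("truth_pairs.tsv"))
  out <- c(assembly = p("assembly.fa"), isogroups = p("isogroups.tsv"),
           forward = p("forward.tsv"), reverse = p("reverse.tsv"),
           self = p("self.tsv"), cladeA = p("cladeA.tsv"),
           cladeB = p("cladeB.tsv"), ref_lengths = p("ref_lengths.tsv"),
           coding = p("coding.tsv"), domains = p("domains.tsv"),
           truth_pairs = p("truth_pairs.tsv"))
  invisible(out)
}
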