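# Shared fixture builders: everything is generated in code at test time.

# data.frame of HSPs in the canonical 12 columns
hitFrame <- function(q, s, evalue = 1e-20, bitscore = 100, pident = 98,
                     qs = 1L, qe = 100L, ss = 1L, se = 100L,
                     alen = 100L) {
  data.frame(query_id = q, subject_id = s, pct_identity = pident,
             aln_len = as.integer(alen), mismatches = 0L, gap_opens = 0L,
             q_start = as.integer(qs), q_end = as.integer(qe),
             s_start = as.integer(ss), s_end = as.integer(se),
             evalue = evalue, bitscore = bitscore)
}

randomHitFrame <- function(n, n_query = max(1, n %/% 5),
                           n_subject = max(1, n %/% 3)) {
  hitFrame(q = sprintf("q%03d", sample(n_query, n, replace = TRUE)),
           s = sprintf("s%03d", sample(n_subject, n, replace = TRUE)),
           evalue = 10^-sample(0:80, n, replace = TRUE),
           bitscore = sample(40:900, n, replace = TRUE),
           pident = round(runif(n, 30, 100), 2),
           qs = sample(1:200, n, replace = TRUE),
           qe = sample(201:400, n, replace = TRUE),
           ss = sample(1:200, n, replace = TRUE),
           se = sample(201:400, n, replace = TRUE),
           alen = sample(50:300, n, replace = TRUE))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant a containment instance: base sequences plus contained fragments at
# given identities; returns the collection, the emulated self-hit table and
# the ids expected to be removed under the >95% full-span rule
plantContainments <- function(n_base = 30, identities = c(94, 96, 100),
                              n_per_identity = 3) {
  base_len <- sample(300:600, n_base, replace = TRUE)
  seqs <- vapply(base_len, randomDna, character(1))
  names(seqs) <- sprintf("base%03d", seq_len(n_base))
  rows <- list()
  expect_removed <- character(0)
  k <- 0
  for (idn in identities) for (j in seq_len(n_per_identity)) {
    k <- k + 1
    host <- names(seqs)[k]           # distinct hosts, all base sequences
    hs <- seqs[[host]]
    dl <- floor(nchar(hs) * 0.6)
    frag <- substr(hs, 11, 10 + dl)
    n_mut <- floor(dl * (100 - idn) / 100)
    if (n_mut > 0) {
      v <- strsplit(frag, "")[[1]]
      pos <- sample(dl, n_mut)
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      frag <- paste(v, collapse = "")
    }
    did <- sprintf("frag%03d", k)
    seqs[did] <- frag
    actual_pid <- 100 * (dl - n_mut) / dl
    rows[[k]] <- hitFrame(did, host, evalue = 1e-80, bitscore = 700,
                          pident = actual_pid, qs = 1L, qe = dl,
                          ss = 11L, se = 10L + dl, alen = dl)
    if (actual_pid > 95) expect_removed <- c(expect_removed, did)
  }
  list(collection = AssemblyCollection(seqs, kind = "singleton"),
       self_hits = HitTable(do.call(rbind, rows)),
       expect_removed = sort(expect_removed))
}

# independent containment oracle: dynamic-programming alignment
# (Biostrings global-local: query consumed in full) over every ordered
# pair that survives a pigeonhole seed filter -- a full-span containment
# at > 95% identity must share an exact 16-mer with its container, so
# pairs without one cannot qualify and need no DP
containmentOracle <- function(collection, min_identity = 95, k = 16) {
  seqs <- productSequences(collection)
  len <- productLengths(collection)
  ids <- names(len)
  chr <- as.character(seqs)
  shareKmer <- function(q, s) {
    qs <- chr[[q]]
    starts <- unique(c(seq(1, nchar(qs) - k + 1, by = k),
                       nchar(qs) - k + 1))
    any(vapply(starts, function(i)
      grepl(substr(qs, i, i + k - 1), chr[[s]], fixed = TRUE),
      logical(1)))
  }
  removed <- character(0)
  for (q in ids) for (s in ids) {
    if (q == s) next
    if (!(len[s] > len[q] || (len[s] == len[q] && s < q))) next
    if (!shareKmer(q, s)) next
    aln <- Biostrings::pairwiseAlignment(seqs[[q]], seqs[[s]],
                                         type = "global-local")
    pid <- Biostrings::pid(aln, type = "PID1")
    if (pid > min_identity) { removed <- c(removed, q); break }
  }
  sort(unique(removed))
}
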