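# helper: run the annotator on hand-built forward HSPs with a reverse
# index that confirms every transcript for protein "P"
runHandCase <- function(fwd, reverse_index, isogroup_map = character(0),
                        kinds, cfg = predictorConfig()) {
  orthologyCalls(assignOrthology(HitTable(fwd, "tblastn"), reverse_index,
                                 isogroup_map, kinds, cfg))
}

test_that("reverse index keeps the best significant subject per transcript", {
  rev <- HitTable(rbind(
    hitFrame("t1", "pA", evalue = 1e-30),
    hitFrame("t1", "pB", evalue = 1e-10),
    hitFrame("t2", "pC", evalue = 1e-3)), "blastx")
  idx <- reverseBestIndex(rev, predictorConfig(e_cutoff = 1e-5))
  expect_equal(idx, c(t1 = "pA"))        # t2 fails the cutoff
})

test_that("non-overlapping confirmed transcripts are both orthologs", {
  fwd <- rbind(hitFrame("P", "T1", evalue = 1e-50, qs = 1, qe = 100),
               hitFrame("P", "T2", evalue = 1e-40, qs = 120, qe = 200))
  calls <- runHandCase(fwd, c(T1 = "P", T2 = "P"),
                       kinds = c(T1 = "isotig", T2 = "isotig"),
                       isogroup_map = c(T1 = "g1", T2 = "g2"))
  expect_equal(calls$category, c("ortholog", "ortholog"))
})

test_that("overlapping confirmed transcripts branch to isoform or paralog", {
  fwd <- rbind(hitFrame("P", "T1", evalue = 1e-50, qs = 1, qe = 150),
               hitFrame("P", "T2", evalue = 1e-40, qs = 100, qe = 200))
  rev <- c(T1 = "P", T2 = "P")
  # overlap 51 > 14; same isogroup -> isoform
  same <- runHandCase(fwd, rev, c(T1 = "g1", T2 = "g1"),
                      c(T1 = "isotig", T2 = "isotig"))
  expect_equal(same$category[same$transcript_id == "T2"], "isoform")
  # different isogroup -> paralog
  diff <- runHandCase(fwd, rev, c(T1 = "g1", T2 = "g2"),
                      c(T1 = "isotig", T2 = "isotig"))
  expect_equal(diff$category[diff$transcript_id == "T2"], "paralog")
  # singleton -> isoform regardless of isogroup
  sing <- runHandCase(fwd, rev, c(T1 = "g1"),
                      c(T1 = "isotig", T2 = "singleton"))
  expect_equal(sing$category[sing$transcript_id == "T2"], "isoform")
})

test_that("the 14-residue overlap boundary separates ortholog from the
           isoform/paralog branch", {
  rev <- c(T1 = "P", T2 = "P")
  kinds <- c(T1 = "isotig", T2 = "isotig")
  igm <- c(T1 = "g1", T2 = "g2")
  # overlap exactly 14 -> still a distinct-region ortholog
  f14 <- rbind(hitFrame("P", "T1", evalue = 1e-50, qs = 1, qe = 100),
               hitFrame("P", "T2", evalue = 1e-40, qs = 87, qe = 180))
  expect_equal(runHandCase(f14, rev, igm, kinds)$category,
               c("ortholog", "ortholog"))
  # overlap 15 -> paralog (different isogroup)
  f15 <- rbind(hitFrame("P", "T1", evalue = 1e-50, qs = 1, qe = 100),
               hitFrame("P", "T2", evalue = 1e-40, qs = 86, qe = 180))
  expect_equal(runHandCase(f15, rev, igm, kinds)$category,
               c("ortholog", "paralog"))
})

test_that("unconfirmed candidates are skipped but stay available to other
           proteins; assigned transcripts are not reused", {
  fwd <- rbind(hitFrame("PA", "T1", evalue = 1e-50, qs = 1, qe = 100),
               hitFrame("PA", "T2", evalue = 1e-40, qs = 1, qe = 100),
               hitFrame("PB", "T2", evalue = 1e-30, qs = 1, qe = 100),
               hitFrame("PB", "T1", evalue = 1e-20, qs = 1, qe = 100))
  calls <- runHandCase(fwd, c(T1 = "PA", T2 = "PB"),
                       kinds = c(T1 = "isotig", T2 = "isotig"),
                       isogroup_map = c(T1 = "g1", T2 = "g2"))
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$protein_id[calls$transcript_id == "T1"], "PA")
  expect_equal(calls$protein_id[calls$transcript_id == "T2"], "PB")
  expect_false(anyDuplicated(calls$transcript_id) > 0)
})

test_that("planted truth is recovered in full with planted categories", {
  tr <- generateTruth(500, isoform_rate = 0.08, paralog_rate = 0.06,
                      split_rate = 0.04, seed = 101)
  ac <- truthAssembly(tr)
  ann <- assignOrthology(emulateHits(tr, "forward"),
                         reverseBestIndex(emulateHits(tr, "reverse")),
                         isogroupMap(ac), productKinds(ac))
  got <- orthologyCalls(ann)
  tp <- truthPairs(tr)
  m <- merge(tp, got, by = "transcript_id")
  expect_equal(nrow(m), nrow(tp))                       # every pair found
  expect_true(all(m$protein_id.x == m$protein_id.y))
  expect_true(all(m$category.x == m$category.y))        # planted categories
  # accepted orthologs per protein overlap pairwise by at most 14 residues
  ortho <- got[got$category == "ortholog", ]
  by_p <- split(ortho, ortho$protein_id)
  multi <- by_p[vapply(by_p, nrow, integer(1)) > 1]
  for (g in multi) {
    for (i in seq_len(nrow(g) - 1)) for (j in seq(i + 1, nrow(g))) {
      ov <- min(g$p_end[i], g$p_end[j]) - max(g$p_start[i], g$p_start[j]) + 1
      expect_lte(ov, 14)
    }
  }
})

test_that("output is invariant to row permutations within input tables", {
  tr <- generateTruth(120, seed = 55)
  ac <- truthAssembly(tr)
  fwd <- emulateHits(tr, "forward"); rev <- emulateHits(tr, "reverse")
  ann1 <- assignOrthology(fwd, reverseBestIndex(rev), isogroupMap(ac),
                          productKinds(ac))
  set.seed(1)
  fwd2 <- HitTable(hits(fwd)[sample(nrow(hits(fwd))), ], "tblastn")
  rev2 <- HitTable(hits(rev)[sample(nrow(hits(rev))), ], "blastx")
  ann2 <- assignOrthology(fwd2, reverseBestIndex(rev2), isogroupMap(ac),
                          productKinds(ac))
  o <- function(a) {
    cl <- orthologyCalls(a); cl[order(cl$transcript_id), ]
  }
  expect_equal(o(ann1), o(ann2), ignore_attr = TRUE)
})

test_that("dropping reverse entries reduces recovery by the affected pairs", {
  tr <- generateTruth(300, seed = 77)
  ac <- truthAssembly(tr)
  fwd <- emulateHits(tr, "forward")
  rev <- emulateHits(tr, "reverse", drop_rate = 0.1, seed = 77)
  dropped <- attr(rev, "dropped")
  ann <- assignOrthology(fwd, reverseBestIndex(rev), isogroupMap(ac),
                         productKinds(ac))
  tp <- truthPairs(tr)
  ev <- evaluateAgainstKnown(ann, setNames(tp$protein_id, tp$transcript_id))
  expect_equal(ev$n_recovered, nrow(tp) - length(dropped))
  # the recovered set is exactly the non-dropped transcripts
  expect_setequal(orthologyCalls(ann)$transcript_id,
                  setdiff(tp$transcript_id, dropped))
})

test_that("recovery reporting matches hand fractions", {
  calls <- data.frame(transcript_id = sprintf("t%02d", 1:36),
                      protein_id = sprintf("p%02d", 1:36),
                      category = "ortholog", p_start = 1L, p_end = 10L,
                      evalue = 1e-20)
  known <- setNames(sprintf("p%02d", 1:52), sprintf("t%02d", 1:52))
  ev <- evaluateAgainstKnown(AnnotationTable(calls), known)
  expect_equal(ev$n_known, 52L)
  expect_equal(ev$n_recovered, 36L)
  expect_equal(ev$fraction, 36 / 52)
  expect_equal(round(100 * ev$fraction, 1), 69.2)
  empty <- AnnotationTable(calls[0, ])
  expect_equal(evaluateAgainstKnown(empty, known)$fraction, 0)
  full <- evaluateAgainstKnown(AnnotationTable(calls),
                               setNames(calls$protein_id,
                                        calls$transcript_id))
  expect_equal(full$fraction, 1)
})
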