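test_that("nr-hit partition is exact and monotone in the cutoff", {
  ids <- c("a", "b", "c")
  tab <- HitTable(hitFrame("a", "ref1", evalue = 1e-8))
  p <- partitionByNr(ids, tab, 1e-5)
  expect_equal(as.character(p), c("nr_hit", "no_nr_hit", "no_nr_hit"))
  # shrinking the cutoff can only shrink the hit set
  tab2 <- HitTable(hitFrame(c("a", "b"), "r", evalue = c(1e-8, 1e-6)))
  p5 <- partitionByNr(ids, tab2, 1e-5)
  p7 <- partitionByNr(ids, tab2, 1e-7)
  loose <- names(p5)[p5 == "nr_hit"]
  strict <- names(p7)[p7 == "nr_hit"]
  expect_true(all(strict %in% loose))
  expect_error(partitionByNr(c("a"), tab2, 1e-5), "not among product ids")
  # planted: 400 hit-bearing of 1000
  set.seed(71)
  all_ids <- sprintf("p%04d", 1:1000)
  hit_ids <- sample(all_ids, 400)
  planted <- HitTable(hitFrame(hit_ids, "ref", evalue = 1e-20))
  pp <- partitionByNr(all_ids, planted, 1e-5)
  expect_equal(sum(pp == "nr_hit"), 400L)
  expect_setequal(names(pp)[pp == "nr_hit"], hit_ids)
})

test_that("clade partition forms an exact four-way split and mirrors on
           swap", {
  ids <- c("x", "y", "z")
  hA <- HitTable(hitFrame(c("x", "y"), "LK1", evalue = 1e-8))
  hB <- HitTable(hitFrame("y", "LM1", evalue = 1e-8))
  p <- cladePartition(ids, hA, hB)
  expect_equal(as.character(p), c("excl_cladeA", "both_clades", "no_clade"))
  expect_equal(sum(table(p)), length(ids))
  swapped <- cladePartition(ids, hB, hA)
  expect_equal(as.character(swapped),
               c("excl_cladeB", "both_clades", "no_clade"))
  empty <- cladePartition(ids, HitTable(), HitTable())
  expect_true(all(empty == "no_clade"))
})

test_that("planted clade classes are recovered exactly", {
  tr <- generateTruth(400, seed = 81)
  hA <- emulateHits(tr, "cladeA"); hB <- emulateHits(tr, "cladeB")
  p <- cladePartition(tr$clades$id, hA, hB)
  truth <- tr$clades$clade
  expect_equal(sum(p == "excl_cladeA"), sum(truth == "A"))
  expect_equal(sum(p == "excl_cladeB"), sum(truth == "B"))
  expect_equal(sum(p == "both_clades"), sum(truth == "both"))
  expect_equal(sum(p == "no_clade"), sum(truth == "none"))
})

test_that("coding/domain overlay enforces domain-within-coding", {
  ids <- c("a", "b", "c")
  coding <- data.frame(id = "a", cds_start = 1, cds_end = 300, strand = "+")
  domains <- data.frame(id = "a", accession = "PF00076", name = "RRM_1")
  ov <- codingDomainOverlay(ids, coding, domains)
  expect_equal(ov$coding, c(TRUE, FALSE, FALSE))
  expect_equal(ov$domain_bearing, c(TRUE, FALSE, FALSE))
  # a domain on a non-coding product violates containment
  bad <- data.frame(id = "b", accession = "PF00069", name = "Pkinase")
  expect_error(codingDomainOverlay(ids, coding, bad), "b")
  relaxed <- codingDomainOverlay(ids, coding, bad, relax = TRUE)
  expect_false(any(relaxed$domain_bearing[relaxed$id == "b"]))
  # planted overlay on a generated truth set
  tr <- generateTruth(300, seed = 83)
  ov2 <- codingDomainOverlay(tr$transcripts$id, tr$coding, tr$domains)
  expect_setequal(ov2$id[ov2$coding], tr$coding$id)
  expect_setequal(ov2$id[ov2$domain_bearing], unique(tr$domains$id))
})

test_that("domain tallies collapse families and deduplicate per sequence", {
  fam <- c(PF00096 = "zinc_finger_combined", PF00097 = "zinc_finger_combined",
           DUF1 = "DUF_combined", DUF2 = "DUF_combined")
  one <- data.frame(id = "s1", accession = c("PF00096", "PF00097"),
                    name = "zf")
  t1 <- tallyDomains(one, fam)
  expect_equal(t1$counts[["zinc_finger_combined"]], 1L)

  two <- data.frame(id = c("s1", "s1", "s2"),
                    accession = c("DUF1", "ubiquitin", "DUF2"),
                    name = "x")
  t2 <- tallyDomains(two, fam)
  expect_equal(t2$counts[["DUF_combined"]], 2L)
  expect_equal(t2$counts[["ubiquitin"]], 1L)
  # per-occurrence mode counts rows
  t3 <- tallyDomains(rbind(one, one), fam, per_sequence = FALSE)
  expect_equal(t3$counts[["zinc_finger_combined"]], 4L)
  # proportions over the top-k total normalise to 1
  set.seed(85)
  big <- data.frame(id = sprintf("s%03d", sample(100, 500, replace = TRUE)),
                    accession = sample(names(fam), 500, replace = TRUE),
                    name = "x")
  t4 <- tallyDomains(big, fam, top_k = 2)
  expect_equal(sum(t4$top$proportion), 1, tolerance = 1e-9)
  # invariant to row order and duplicated rows
  t5 <- tallyDomains(big[sample(nrow(big)), ], fam, top_k = 2)
  t6 <- tallyDomains(rbind(big, big), fam, top_k = 2)
  expect_identical(t4$counts, t5$counts)
  expect_identical(t4$counts, t6$counts)
})

test_that("proteome representation counts distinct matched proteins", {
  prot <- sprintf("p%02d", 1:10)
  h <- HitTable(hitFrame(c("t1", "t2", "t3"), c("p01", "p01", "p02"),
                         evalue = 1e-8))
  pr <- proteomeRepresentation(prot, h)
  expect_equal(pr$n_with_match, 2L)
  expect_equal(pr$fraction, 0.2)
  none <- proteomeRepresentation(prot, HitTable())
  expect_equal(none$fraction, 0)
  # planted representation recovered exactly (e.g. a 33.49%-style fraction)
  set.seed(87)
  prot2 <- sprintf("pp%05d", 1:10000)
  matched <- sample(prot2, 3349)
  h2 <- HitTable(hitFrame(sprintf("t%05d", seq_along(matched)), matched,
                          evalue = 1e-9))
  pr2 <- proteomeRepresentation(prot2, h2)
  expect_equal(pr2$fraction, 0.3349)
  # reversed direction counts queries instead
  h3 <- HitTable(hitFrame(matched, "assembly1", evalue = 1e-9))
  pr3 <- proteomeRepresentation(prot2, h3,
                                direction = "proteome_to_assembly")
  expect_equal(pr3$n_with_match, 3349L)
})
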