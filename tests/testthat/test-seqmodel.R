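test_that("FASTA reading infers kinds, uppercases, and validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">isotig00001", "acgtac", "gtacgt",
               ">GXYZ123", paste(rep("ACGTN", 50), collapse = "")), f)
  ac <- readAssemblyFasta(f)
  expect_equal(length(ac), 2L)
  expect_equal(unname(productKinds(ac)), c("isotig", "singleton"))
  expect_equal(unname(productLengths(ac)), c(12L, 250L))
  expect_equal(as.character(productSequences(ac)[[1]]), "ACGTACGTACGT")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s1", "GGCC"), dup)
  expect_error(readAssemblyFasta(dup), "duplicate id s1")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGXT"), bad)
  expect_error(readAssemblyFasta(bad), "position 4")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(readAssemblyFasta(empty), "empty")
})

test_that("FASTA write/read round trip is identity on 100 random records", {
  set.seed(11)
  n <- 100
  seqs <- vapply(sample(5:400, n, replace = TRUE), randomDna, character(1))
  names(seqs) <- sprintf("rec%03d", seq_len(n))
  ac <- AssemblyCollection(seqs, kind = "singleton")
  f <- withr::local_tempfile(fileext = ".fa")
  writeAssemblyFasta(ac, f)
  back <- readAssemblyFasta(f, isotig_pattern = "^$")
  expect_identical(productIds(back), names(seqs))
  expect_identical(as.character(productSequences(back)), seqs)
  # 60-column wrapping on write
  lines <- readLines(f)
  expect_true(all(nchar(lines[!grepl("^>", lines)]) <= 60))
})

test_that("isogroup map loads, inverts and rejects double membership", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isotig1\tg1", "isotig2\tg1", "isotig3\tg2"), f)
  m <- loadIsogroupMap(f)
  groups <- split(names(m), m)
  expect_equal(length(groups), 2L)
  expect_setequal(groups$g1, c("isotig1", "isotig2"))

  clash <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("isotig1\tg1", "isotig1\tg2"), clash)
  expect_error(loadIsogroupMap(clash), "two isogroups")

  # synthetic round trip: written map reloads to the generator's truth
  set.seed(4)
  truth_map <- setNames(sprintf("g%03d", sample(400, 1000, replace = TRUE)),
                        sprintf("isotig%04d", 1:1000))
  out <- withr::local_tempfile(fileext = ".tsv")
  writeIsogroupMap(truth_map, out)
  expect_identical(loadIsogroupMap(out), truth_map)
})

test_that("N50 follows the cumulative >= half-total convention", {
  expect_equal(n50(500), 500)
  expect_equal(n50(c(2, 3, 4, 5, 6)), 5)   # cumulative 6, 11 >= 10
  expect_error(n50(numeric(0)), "empty")

  # brute force over all candidate lengths, on many random instances
  bruteN50 <- function(l) {
    tot <- sum(l)
    max(l[vapply(l, function(L) sum(l[l >= L]) >= tot / 2, logical(1))])
  }
  set.seed(21)
  agree <- vapply(1:1000, function(i) {
    l <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    identical(n50(l), bruteN50(l))
  }, logical(1))
  expect_true(all(agree))
  # order invariance
  l <- sample(1:999, 50)
  expect_identical(n50(l), n50(rev(sort(l))))
})

test_that("length summary matches sort-and-index brute force", {
  expect_equal(lengthSummary(100),
               list(n = 1L, min = 100, max = 100, median = 100, mean = 100))
  expect_equal(lengthSummary(c(100, 200))$median, 150)   # even-n midpoint
  expect_error(lengthSummary(numeric(0)), "empty")

  set.seed(31)
  l <- sample(1:10000, 10001, replace = TRUE)
  s <- sort(l)
  expect_equal(lengthSummary(l),
               list(n = 10001L, min = s[1], max = s[10001],
                    median = s[5001], mean = sum(l) / 10001))
})

test_that("coverage stats are per-contig depths and their weighted mean", {
  one <- coverageStats(c(c1 = 1000), c(c1 = 100))
  expect_equal(one$avg_coverage_per_bp, 10)
  expect_equal(unname(one$contig_depths), 10)

  two <- coverageStats(c(a = 300, b = 100), c(a = 100, b = 100))
  expect_equal(two$avg_coverage_per_bp, 2)
  expect_equal(two$contig_depths, c(a = 3, b = 1))

  expect_error(coverageStats(c(a = 10), c(a = 0)), "zero-length")

  set.seed(41)
  bp <- setNames(runif(200, 0, 1e5), sprintf("c%03d", 1:200))
  len <- setNames(sample(100:5000, 200), names(bp))
  cs <- coverageStats(bp, len)
  # linearity in aligned bp
  expect_equal(coverageStats(3 * bp, len)$avg_coverage_per_bp,
               3 * cs$avg_coverage_per_bp)
  # the average is the length-weighted mean of depths
  expect_equal(cs$avg_coverage_per_bp,
               sum(cs$contig_depths * len) / sum(len), tolerance = 1e-9)
  # extreme-depth tallies partition consistently
  expect_equal(cs$n_low, sum(bp / len <= 10))
  expect_equal(cs$n_high, sum(bp / len >= 10000))
})

test_that("isogroup accessors partition isotigs exactly", {
  tr <- generateTruth(60, seed = 9)
  ac <- truthAssembly(tr)
  gs <- isogroups(ac)
  expect_equal(sum(lengths(gs)), sum(productKinds(ac) == "isotig"))
  expect_false(anyDuplicated(unlist(gs)) > 0)
})
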