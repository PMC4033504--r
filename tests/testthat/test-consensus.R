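fixture <- function(name) system.file("extdata", name, package = "epivote")

test_that("interval tables parse, validate and deduplicate", {
  tracks <- parse_interval_table(fixture("table3_bcell.tsv"))
  expect_setequal(unique(tracks$source), c("DNAStar", "BPAP", "BepiPred"))
  expect_true(any(tracks$source == "BepiPred" & tracks$start == 11 &
                    tracks$end == 18))
  expect_equal(nrow(tracks), 23L)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f)
  expect_equal(nrow(parse_interval_table(f)), 0L)

  # duplicated identical rows collapse under union-merge
  writeLines(c("a\t5\t9", "a\t5\t9", "a\t8\t12"), f)
  merged <- merge_regions(parse_interval_table(f))
  expect_equal(merged, regions(5, 12, source = "a"))

  writeLines(c("a\t5\t9", "a\t9\t7"), f)
  expect_error(parse_interval_table(f), "row 2.*start 9 exceeds end 7")
  writeLines(c("a\t5\t9", "a\tx\t7"), f)
  expect_error(parse_interval_table(f), "row 2.*non-integer")
})

test_that("limit cases: union at k=1, unanimity, unchanged single allele", {
  tr <- random_tracks(80, 3)
  res <- residue_vote_consensus(tr, k = 1, min_len = 1, merge_gap = 0)
  union <- IRanges::reduce(IRanges::IRanges(tr$start, tr$end))
  expect_equal(res$regions$start, IRanges::start(union))
  expect_equal(res$regions$end, IRanges::end(union))

  one <- regions(c(10, 30), c(20, 44), source = "a")
  four <- do.call(rbind, lapply(c("a", "b", "c", "d"), function(s)
    transform(one, source = s)))
  res4 <- allele_support_consensus(four, k = 3)
  expect_equal(res4$regions[, c("start", "end")],
               one[, c("start", "end")])

  solo <- regions(c(5, 10, 40), c(12, 18, 48), source = "x")
  res1 <- allele_support_consensus(solo, k = 1, min_len = 1)
  expect_equal(res1$regions[, c("start", "end")],
               data.frame(start = c(5L, 40L), end = c(18L, 48L)))
})

test_that("support counts distinct tracks, not regions", {
  # two overlapping 9-mers from one allele must count once
  tr <- rbind(regions(c(10, 12), c(18, 20), source = "allele1"),
              regions(30, 35, source = "allele2"))
  res <- residue_vote_consensus(tr, k = 2, min_len = 1, seq_length = 40)
  expect_equal(nrow(res$regions), 0L)
  expect_equal(max(res$support), 1L)
})

test_that("merge_gap bridges below-threshold gaps", {
  tr <- regions(c(1, 8), c(5, 12), source = "a")
  expect_equal(nrow(residue_vote_consensus(tr, 1, min_len = 4,
                                           merge_gap = 0)$regions), 2L)
  res <- residue_vote_consensus(tr, 1, min_len = 4, merge_gap = 2)
  expect_equal(res$regions[, c("start", "end")],
               data.frame(start = 1L, end = 12L))
  expect_equal(res$regions$min_support, 0L)  # bridged residues have no support
})

test_that("voting is monotone in k and intersects at k = n", {
  set.seed(7)
  for (i in 1:25) {
    tr <- random_tracks(100, 4)
    sets <- lapply(1:4, function(k) {
      r <- residue_vote_consensus(tr, k, min_len = 1, seq_length = 100)$regions
      unlist(lapply(seq_len(nrow(r)), function(j) r$start[j]:r$end[j]))
    })
    for (k in 2:4) expect_true(all(sets[[k]] %in% sets[[k - 1]]))
    inter <- Reduce(intersect, lapply(split(tr, tr$source), function(d)
      unique(unlist(mapply(seq, d$start, d$end, SIMPLIFY = FALSE)))))
    expect_setequal(as.integer(unlist(sets[[4]])), as.integer(inter))
  }
})

test_that("consensus never invents residues and ignores track order", {
  set.seed(8)
  for (i in 1:10) {
    tr <- random_tracks(120, 3)
    res <- residue_vote_consensus(tr, 2, seq_length = 120)
    covered <- unique(unlist(mapply(seq, tr$start, tr$end, SIMPLIFY = FALSE)))
    claimed <- unlist(lapply(seq_len(nrow(res$regions)), function(j)
      res$regions$start[j]:res$regions$end[j]))
    expect_true(all(claimed %in% covered))
    perm <- tr[sample(nrow(tr)), ]
    expect_equal(residue_vote_consensus(perm, 2, seq_length = 120)$regions,
                 res$regions)
  }
})

test_that("voting agrees with the position-by-position tally oracle", {
  set.seed(99)
  for (i in 1:200) {
    L <- sample(40:150, 1)
    n <- sample(2:5, 1)
    tr <- random_tracks(L, n)
    k <- sample.int(n, 1)
    min_len <- sample(1:6, 1)
    gap <- sample(0:3, 1)
    got <- residue_vote_consensus(tr, k, min_len = min_len, merge_gap = gap,
                                  seq_length = L)
    want <- oracle_consensus(tr, k, min_len = min_len, merge_gap = gap,
                             seq_length = L)
    expect_equal(got$regions[, c("start", "end")], want, ignore_attr = TRUE)
  }
})

test_that("consensus region invariants hold", {
  tr <- parse_interval_table(fixture("table3_dr.tsv"))
  res <- allele_support_consensus(tr, k = 3, seq_length = 247)
  expect_true(all(res$regions$min_support >= 3))
  expect_true(all(res$regions$length >= 4))
  for (i in seq_len(nrow(res$regions))) {
    s <- res$regions$start[i]; e <- res$regions$end[i]
    if (s > 1) expect_lt(res$support[s - 1], 3)
    if (e < 247) expect_lt(res$support[e + 1], 3)
  }
})

test_that("locus combination unions, merges and maximizes support", {
  a <- residue_vote_consensus(regions(1, 5, source = "x"), 1, min_len = 1,
                              seq_length = 20)
  b <- residue_vote_consensus(regions(10, 12, source = "y"), 1, min_len = 1,
                              seq_length = 20)
  comb <- combine_loci(a, b)
  expect_equal(comb$regions[, c("start", "end")],
               data.frame(start = c(1L, 10L), end = c(5L, 12L)))

  # adjacent regions merge; support is the elementwise maximum
  c2 <- residue_vote_consensus(regions(6, 9, source = "y"), 1, min_len = 1,
                               seq_length = 20)
  comb2 <- combine_loci(a, c2)
  expect_equal(comb2$regions[, c("start", "end")],
               data.frame(start = 1L, end = 9L))
  expect_equal(comb2$support[1:9], rep(1L, 9))

  # an empty partner leaves the other side unchanged
  empty <- residue_vote_consensus(regions(15, 16, source = "z"), 1,
                                  min_len = 4, seq_length = 20)
  expect_equal(nrow(empty$regions), 0L)
  expect_equal(combine_loci(a, empty)$regions[, c("start", "end")],
               a$regions[, c("start", "end")])
})

test_that("parameter validation rejects impossible votes", {
  tr <- random_tracks(50, 2)
  expect_error(residue_vote_consensus(tr, 3), "k=3 exceeds")
  expect_error(residue_vote_consensus(tr[0, ], 1), "no tracks")
  expect_error(consensus_params(0), "k >= 1")
  expect_error(residue_vote_consensus(regions(40, 60, source = "a"), 1,
                                      seq_length = 50), "exceeds the sequence length|exceeds sequence length")
})
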