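test_that("window profiles have NA flanks and the documented shape", {
  kt <- propensity_scales()$kolaskar_tongaonkar
  s <- random_protein(20, seed = 5)
  prof <- window_profile(s, kt, window = 7)
  expect_length(prof$scores, 20L)
  expect_equal(sum(!is.na(prof$scores)), 20L - 7L + 1L)
  expect_true(all(is.na(prof$scores[c(1:3, 18:20)])))

  # homopolymer: constant profile at the residue's scale value
  prof_a <- window_profile(strrep("L", 15), kt, window = 7)
  expect_equal(unique(prof_a$scores[!is.na(prof_a$scores)]),
               unname(kt$values["L"]))

  # window equal to length: exactly one score
  prof_1 <- window_profile(s, kt, window = 19)
  expect_equal(sum(!is.na(prof_1$scores)), 2L)  # length 20, window 19
  expect_equal(sum(!is.na(window_profile(random_protein(19, 1), kt, 19)$scores)), 1L)

  expect_error(window_profile(s, kt, window = 6), "odd")
  expect_error(window_profile(s, kt, window = 21), "exceeds")
  expect_error(window_profile(protein_sequence("MKXVHAA"), kt, 7), "X")
})

test_that("mean-mode profiles match per-window summation", {
  kt <- propensity_scales()$parker
  for (seed in 1:5) {
    s <- random_protein(20, seed)
    chars <- strsplit(s$residues, "")[[1]]
    got <- window_profile(s, kt, window = 7)$scores
    expect_equal(got, oracle_window_mean(chars, kt$values, 7L))
  }
})

test_that("product-mode profiles follow the normalized-product convention", {
  em <- propensity_scales()$emini
  s <- random_protein(15, seed = 9)
  chars <- strsplit(s$residues, "")[[1]]
  got <- window_profile(s, em, window = 5)$scores
  for (c in 3:13) {
    expect_equal(got[c], prod(em$values[chars[(c - 2):(c + 2)]] / 0.37),
                 tolerance = 1e-12)
  }
})

test_that("profiles are translation equivariant", {
  kt <- propensity_scales()$kolaskar_tongaonkar
  s <- random_protein(30, seed = 2)
  base <- window_profile(s, kt, 7)$scores
  prefix <- "GGGGG"
  shifted <- window_profile(paste0(prefix, s$residues), kt, 7)$scores
  defined <- which(!is.na(base))
  expect_equal(shifted[defined + nchar(prefix)], base[defined])
})

test_that("antigenicity thresholding reports extended runs above 1.0", {
  # nothing above threshold: residues all with propensity < 1
  low <- protein_sequence(strrep("NGSK", 8))
  expect_equal(nrow(antigenicity_regions(low)), 0L)

  # one planted high-propensity segment inside a low background
  planted <- protein_sequence(paste0(strrep("N", 20), strrep("V", 10),
                                     strrep("N", 20)))
  reg <- antigenicity_regions(planted)
  expect_equal(nrow(reg), 1L)
  expect_true(reg$start <= 21 && reg$end >= 30)
  expect_gte(reg$end - reg$start + 1, 8)

  # thresholding matches a direct profile computation
  kt <- propensity_scales()$kolaskar_tongaonkar
  for (seed in 1:10) {
    s <- random_protein(60, seed)
    reg <- antigenicity_regions(s)
    prof <- window_profile(s, kt, 7)$scores
    above <- which(!is.na(prof) & prof > 1.0)
    if (nrow(reg) > 0L) {
      # every region is an extended maximal run of above-threshold centers
      for (i in seq_len(nrow(reg))) {
        centers <- (reg$start[i] + 3):(reg$end[i] - 3)
        expect_true(all(centers %in% above))
        expect_false((min(centers) - 1) %in% above)
        expect_false((max(centers) + 1) %in% above)
      }
    }
    runs <- rle(seq_len(60) %in% above)
    long_runs <- sum(runs$values & runs$lengths + 6 >= 8)
    expect_equal(nrow(reg), long_runs)
  }
})

test_that("composite index degenerates correctly and matches its oracle", {
  s <- random_protein(60, seed = 14)
  kt <- propensity_scales()$kolaskar_tongaonkar
  one <- composite_index_regions(s, scales = list(kt), weights = 1,
                                 percentile_cut = 0.8)
  two <- composite_index_regions(s, scales = list(kt, kt),
                                 weights = c(0.5, 0.5), percentile_cut = 0.8)
  expect_equal(one[, c("start", "end")], two[, c("start", "end")])

  # weighted-sum oracle with two different scales
  pk <- propensity_scales()$parker
  got <- composite_index_regions(s, scales = list(kt, pk),
                                 weights = c(0.6, 0.4), percentile_cut = 0.75,
                                 min_len = 4)
  chars <- strsplit(s$residues, "")[[1]]
  z <- function(v) (v - mean(v)) / sd(v)
  comb <- 0.6 * oracle_window_mean(chars, z(kt$values), 7L) +
          0.4 * oracle_window_mean(chars, z(pk$values), 7L)
  cut <- quantile(comb, 0.75, na.rm = TRUE, names = FALSE)
  runs <- rle(ifelse(is.na(comb), FALSE, comb > cut))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= 4
  expect_equal(got[, c("start", "end")],
               data.frame(start = starts[keep], end = ends[keep]),
               ignore_attr = TRUE)
  expect_error(composite_index_regions(s, scales = list()), "empty")
})

test_that("planted high-propensity segments are recovered reliably", {
  # background drawn from low-antigenicity residues, one planted decamer of
  # high-propensity residues; recall over 100 seeded replicates
  low <- c("N", "G", "S", "K", "D", "E", "R", "T", "M")
  high <- c("C", "V", "L", "I", "Y")
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    bg <- sample(low, 60, replace = TRUE)
    at <- sample(5:45, 1)
    bg[at:(at + 9)] <- sample(high, 10, replace = TRUE)
    reg <- antigenicity_regions(protein_sequence(paste(bg, collapse = "")))
    ok <- nrow(reg) > 0 && any(reg$start <= at + 9 & reg$end >= at)
    hits <- hits + ok
  }
  expect_gte(hits / 100, 0.9)
})
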