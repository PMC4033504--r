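# Independent oracles used to cross-check the package implementations.
# They deliberately share no code with the package: the consensus oracle
# tallies a support array position by position, the motif oracle goes
# through regular expressions, and the physicochemical reference values
# were computed with an independent reference implementation of the
# ProtParam formulas and frozen here.

# position-by-position consensus tally
oracle_consensus <- function(tracks, k, min_len = 4L, merge_gap = 0L,
                             seq_length = NULL) {
  L <- if (is.null(seq_length)) max(tracks$end) else seq_length
  support <- integer(L)
  for (src in unique(tracks$source)) {
    covered <- rep(FALSE, L)
    d <- tracks[tracks$source == src, ]
    for (i in seq_len(nrow(d))) covered[d$start[i]:d$end[i]] <- TRUE
    support <- support + covered
  }
  runs <- list()
  i <- 1L
  while (i <= L) {
    if (support[i] >= k) {
      j <- i
      while (j < L && support[j + 1L] >= k) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  merged <- list()
  for (r in runs) {
    if (length(merged) > 0L &&
        r[1] - merged[[length(merged)]][2] - 1L <= merge_gap) {
      merged[[length(merged)]][2] <- r[2]
    } else merged[[length(merged) + 1L]] <- r
  }
  keep <- Filter(function(r) r[2] - r[1] + 1L >= min_len, merged)
  if (length(keep) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = vapply(keep, `[`, integer(1), 1),
             end = vapply(keep, `[`, integer(1), 2))
}

# regex-based PROSITE oracle: expands every repeat-count choice into a
# concrete fixed-length regex, then tests each start position
oracle_prosite_scan <- function(seq_string, pattern_text) {
  raw <- sub("\\.$", "", gsub("\\s", "", pattern_text))
  nterm <- startsWith(raw, "<")
  if (nterm) raw <- substr(raw, 2, nchar(raw))
  cterm <- endsWith(raw, ">")
  if (cterm) raw <- substr(raw, 1, nchar(raw) - 1L)
  toks <- strsplit(raw, "-", fixed = TRUE)[[1]]

  piece <- function(tok) {
    m <- regmatches(tok, regexec(
      "^(x|[A-WYZ]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
      tok))[[1]]
    body <- m[2]
    lo <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    hi <- if (nzchar(m[6])) as.integer(m[6]) else lo
    rx <- if (body == "x") "."
          else if (startsWith(body, "{"))
            paste0("[^X", substr(body, 2, nchar(body) - 1L), "]")
          else if (startsWith(body, "[")) body
          else body
    list(rx = rx, reps = lo:hi)
  }
  pieces <- lapply(toks, piece)
  rep_grid <- expand.grid(lapply(pieces, `[[`, "reps"))
  hits <- NULL
  L <- nchar(seq_string)
  for (g in seq_len(nrow(rep_grid))) {
    reps <- as.integer(rep_grid[g, ])
    rx <- paste0(mapply(function(p, n) strrep(p$rx, n), pieces, reps),
                 collapse = "")
    width <- sum(reps)  # every expanded element consumes one residue
    starts <- if (nterm) 1L else seq_len(L)
    for (s in starts) {
      # fixed-length concrete regex: match it against the exact-length slice
      e <- s + width - 1L
      if (width == 0L || e > L) next
      if (cterm && e != L) next
      if (grepl(paste0("^", rx, "$"), substr(seq_string, s, e))) {
        hits <- rbind(hits, data.frame(start = s, end = e))
      }
    }
  }
  if (is.null(hits)) return(data.frame(start = integer(0), end = integer(0)))
  hits <- unique(hits)
  hits[order(hits$start, hits$end), , drop = FALSE]
}

# random PROSITE pattern for property testing
random_prosite_pattern <- function() {
  n <- sample(2:5, 1)
  toks <- vapply(seq_len(n), function(i) {
    body <- switch(sample(4, 1),
                   "x",
                   sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 1),
                   paste0("[", paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                            sample(2:4, 1)), collapse = ""), "]"),
                   paste0("{", paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                            sample(1:3, 1)), collapse = ""), "}"))
    rep <- switch(sample(3, 1), "",
                  sprintf("(%d)", sample(1:3, 1)),
                  sprintf("(%d,%d)", sample(0:2, 1), sample(2:4, 1)))
    if (grepl("^\\(0", rep)) rep <- sub("^\\(0", "(1", rep)  # keep widths positive
    paste0(body, rep)
  }, character(1))
  paste0(paste(toks, collapse = "-"), ".")
}

# windowed mean by explicit per-window summation
oracle_window_mean <- function(chars, values, w) {
  L <- length(chars)
  half <- (w - 1L) %/% 2L
  out <- rep(NA_real_, L)
  for (c in (half + 1L):(L - half)) {
    out[c] <- sum(values[chars[(c - half):(c + half)]]) / w
  }
  out
}

# Reference physicochemical values computed with an independent
# implementation of the ProtParam formulas (Biopython 1.88) and frozen.
protparam_reference <- list(
  pepA = list(seq = "MKWVTFISLLFLFSSAYSRGVFRRDAHKSE",
              mw = 3580.1219, pi = 10.266413, gravy = 0.073333,
              ii = 48.706667, ai = 78.0,
              charge5 = 4.575969, charge7 = 2.593670, charge9 = 1.735226),
  pepB = list(seq = "GASPQQAQEVHQKLAYEPVWAIGTGKTASPNNVFGESDQLWKMNGNKTDE",
              mw = 5458.8948, pi = 5.134630, gravy = -0.946000,
              ii = 47.264000, ai = 50.8,
              charge5 = 0.343192, charge7 = -2.138999, charge9 = -3.422747),
  # pepC's pI is NA: the reference tool restricts its pI search to the
  # interval [4.05, 12] and reports the clamped bound for this acidic
  # undecapeptide; the true zero of the (exactly agreeing) charge model
  # is at pH 3.9997, checked by grid search in test-physchem.R instead.
  pepC = list(seq = "AYEPVWAIGTG",
              mw = 1163.2785, pi = NA, gravy = 0.318182,
              ii = 8.154545, ai = 80.0,
              charge5 = -0.748438, charge7 = -1.202314, charge9 = -2.053430),
  polyA10 = list(seq = "AAAAAAAAAA",
                 mw = 728.7943, pi = 5.570017, gravy = 1.8,
                 ii = 9.0, ai = 100.0,
                 charge5 = 0.031702, charge7 = -0.204125, charge9 = -0.962549),
  GG = list(seq = "GG",
            mw = 132.1179, pi = 5.525000, gravy = -0.4,
            ii = 66.7, ai = 0.0,
            charge5 = 0.031113, charge7 = -0.239898, charge9 = -0.969343)
)

random_tracks <- function(L, n_tracks, max_regions = 5L) {
  rows <- lapply(seq_len(n_tracks), function(t) {
    n <- sample.int(max_regions, 1L)
    s <- sample.int(L, n, replace = TRUE)
    e <- pmin(L, s + sample.int(15L, n, replace = TRUE) - 1L)
    data.frame(source = sprintf("t%d", t), start = s, end = e)
  })
  do.call(rbind, rows)
}
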