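# Run code under a fixed seed without disturbing the caller's RNG state.
# RNG kind is pinned so that generated fixtures are identical across
# platforms and R sessions.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Planting design for synthetic epitope data
#'
#' Describes a simulation in which "true" epitopes are planted on a
#' random protein and each predictor (or allele) independently reports
#' each epitope with probability `agreement_p`, with jittered boundaries
#' and Poisson-distributed spurious regions — the statistical structure
#' the consensus vote is designed to exploit.
#'
#' Planted epitopes are non-overlapping and separated by at least
#' `2 * boundary_jitter + 2` residues so that jittered reports of
#' distinct epitopes cannot merge.
#'
#' @param seq_length Sequence length in residues.
#' @param n_epitopes Number of planted epitopes.
#' @param epitope_length_range Integer `(min, max)` epitope length.
#' @param n_predictors Number of predictor/allele tracks.
#' @param agreement_p Probability a predictor reports a planted epitope.
#' @param boundary_jitter Maximum residues of uniform random start/end
#'   shift applied to each reported region.
#' @param fp_rate Expected number of spurious regions per predictor
#'   (Poisson).
#' @param seed Integer seed; every generator using the design is fully
#'   deterministic given it.
#' @return A list of class `planting_design`.
#' @export
planting_design <- function(seq_length = 247L, n_epitopes = 4L,
                            epitope_length_range = c(10L, 16L),
                            n_predictors = 3L, agreement_p = 0.9,
                            boundary_jitter = 2L, fp_rate = 1,
                            seed = 1L) {
  stopifnot(seq_length >= 1L, n_epitopes >= 0L,
            length(epitope_length_range) == 2L,
            epitope_length_range[1] >= 1L,
            epitope_length_range[1] <= epitope_length_range[2],
            n_predictors >= 1L, agreement_p >= 0, agreement_p <= 1,
            boundary_jitter >= 0L, fp_rate >= 0)
  structure(list(seq_length = as.integer(seq_length),
                 n_epitopes = as.integer(n_epitopes),
                 epitope_length_range = as.integer(epitope_length_range),
                 n_predictors = as.integer(n_predictors),
                 agreement_p = agreement_p,
                 boundary_jitter = as.integer(boundary_jitter),
                 fp_rate = fp_rate, seed = as.integer(seed)),
            class = "planting_design")
}

#' Random protein sequence
#'
#' Uniform i.i.d. residues over the 20-letter alphabet; reproducible per
#' seed.
#'
#' @param length Number of residues (at least 1).
#' @param seed Integer seed.
#' @param id Identifier of the returned sequence.
#' @return A [protein_sequence()].
#' @export
random_protein <- function(length, seed, id = sprintf("random_%d", seed)) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be >= 1", call. = FALSE)
  with_seed(seed, {
    protein_sequence(paste(sample(AA_ALPHABET, length, replace = TRUE),
                           collapse = ""), id = id)
  })
}

# sample() treats a length-1 x as 1:x; draw lengths safely for lo == hi
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
}

# place n non-overlapping intervals with a minimum separation, uniformly
# distributing the remaining free residues among the n + 1 gaps
plant_epitopes <- function(design) {
  n <- design$n_epitopes
  if (n == 0L) return(regions(integer(), integer(), source = character(0)))
  lens <- sample_range(design$epitope_length_range[1],
                       design$epitope_length_range[2], n)
  sep <- 2L * design$boundary_jitter + 2L
  free <- design$seq_length - sum(lens) - (n - 1L) * sep
  if (free < 0L) {
    stop("infeasible planting design: epitopes cannot fit in the sequence",
         call. = FALSE)
  }
  extra <- tabulate(sample.int(n + 1L, free, replace = TRUE), n + 1L)
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + extra[i]
    starts[i] <- pos
    pos <- pos + lens[i] + sep
  }
  regions(starts, starts + lens - 1L, source = "truth")
}

jitter_region <- function(start, end, jitter, L) {
  if (jitter > 0L) {
    start <- start + sample(-jitter:jitter, 1L)
    end <- end + sample(-jitter:jitter, 1L)
  }
  c(max(1L, min(start, L)), min(L, max(end, 1L)))
}

#' Simulate predictor epitope tracks around planted truth
#'
#' Plants non-overlapping epitopes, then lets each predictor report each
#' epitope independently with probability `agreement_p` (start/end
#' jittered uniformly within `boundary_jitter`) and adds
#' `Poisson(fp_rate)` spurious regions per predictor, placed uniformly
#' (overlaps with planted epitopes allowed; the consensus union-merge
#' resolves them).
#'
#' @param design A [planting_design()].
#' @return A list with `truth` (region table of planted epitopes) and
#'   `tracks` (region table with one source per predictor,
#'   `predictor_1` ... `predictor_n`).
#' @export
simulate_predictor_tracks <- function(design) {
  stopifnot(is(design, "planting_design"))
  with_seed(design$seed, {
    truth <- plant_epitopes(design)
    L <- design$seq_length
    rows <- list()
    for (p in seq_len(design$n_predictors)) {
      src <- sprintf("predictor_%d", p)
      for (i in seq_len(nrow(truth))) {
        if (stats::runif(1) <= design$agreement_p) {
          se <- jitter_region(truth$start[i], truth$end[i],
                              design$boundary_jitter, L)
          rows[[length(rows) + 1L]] <- data.frame(
            source = src, start = se[1], end = se[2])
        }
      }
      n_fp <- stats::rpois(1L, design$fp_rate)
      for (j in seq_len(n_fp)) {
        len <- min(sample_range(design$epitope_length_range[1],
                                design$epitope_length_range[2], 1L), L)
        s <- sample.int(L - len + 1L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, start = s, end = s + len - 1L)
      }
    }
    tracks <- if (length(rows) == 0L) {
      regions(integer(), integer(), source = character(0))
    } else {
      do.call(rbind, rows)
    }
    list(truth = truth, tracks = tracks)
  })
}

#' Simulate per-allele 9-mer binding-core tracks
#'
#' Emulates the per-allele binder lists of MHC class II prediction: for
#' each allele that "agrees" on a planted epitope, overlapping
#' fixed-length cores are tiled across the epitope with random stride
#' 1-3 (the final core is pinned to the epitope end so the whole span is
#' covered). Spurious cores follow `Poisson(fp_rate)` per allele.
#'
#' @param design A [planting_design()]; `epitope_length_range[1]` must
#'   be at least `core_length`.
#' @param core_length Binding-core length (9 for MHC class II).
#' @return A list with `truth` and `tracks` (sources `allele_1` ...
#'   `allele_n`).
#' @export
simulate_allele_peptides <- function(design, core_length = 9L) {
  stopifnot(is(design, "planting_design"))
  core_length <- as.integer(core_length)
  if (design$epitope_length_range[1] < core_length) {
    stop("epitope_length_range minimum is below the core length",
         call. = FALSE)
  }
  with_seed(design$seed, {
    truth <- plant_epitopes(design)
    L <- design$seq_length
    rows <- list()
    for (a in seq_len(design$n_predictors)) {
      src <- sprintf("allele_%d", a)
      for (i in seq_len(nrow(truth))) {
        if (stats::runif(1) <= design$agreement_p) {
          s <- truth$start[i]
          last_start <- truth$end[i] - core_length + 1L
          starts <- integer(0)
          while (s <= last_start) {
            starts <- c(starts, s)
            s <- s + sample(1:3, 1L)
          }
          if (length(starts) == 0L || starts[length(starts)] < last_start) {
            starts <- c(starts, last_start)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            source = src, start = starts, end = starts + core_length - 1L)
        }
      }
      n_fp <- stats::rpois(1L, design$fp_rate)
      for (j in seq_len(n_fp)) {
        s <- sample.int(L - core_length + 1L, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          source = src, start = s, end = s + core_length - 1L)
      }
    }
    tracks <- if (length(rows) == 0L) {
      regions(integer(), integer(), source = character(0))
    } else {
      do.call(rbind, rows)
    }
    rownames(tracks) <- NULL
    list(truth = truth, tracks = tracks)
  })
}

#' Fraction of planted epitopes recovered by a consensus result
#'
#' A planted epitope counts as recovered when at least one consensus
#' region overlaps it.
#'
#' @param truth Region table of planted epitopes.
#' @param result A `consensus_result`.
#' @return Sensitivity in `[0, 1]` (`NaN` when nothing was planted).
#' @export
consensus_sensitivity <- function(truth, result) {
  if (nrow(truth) == 0L) return(NaN)
  hits <- IRanges::countOverlaps(regions_to_iranges(truth),
                                 regions_to_iranges(result$regions))
  mean(hits > 0L)
}

#' Synthetic 247-residue scaffold of the Der f 25 allergen
#'
#' A synthetic stand-in sequence, NOT the real Der f 25 protein: every
#' residue whose identity and position are printed in the source
#' study's tables is placed at that position (the thirteen epitope
#' peptides, the PS00171 active-site undecapeptide at 162-172, the
#' catalytic His94, and the substrate-binding Asn10/Lys12), and all
#' remaining positions are filled with glycine. It exercises every
#' accession-shaped code path (247-residue input, motif scanning,
#' residue lookup, epitope mapping) without pretending to reproduce the
#' real protein's global physicochemical values.
#'
#' @return A [protein_sequence()] with id
#'   `"derf25_synthetic_scaffold"`.
#' @export
derf25_synthetic_scaffold <- function() {
  frags <- list(
    list(10, "NWKMNGNKT"),        # substrate-binding Asn10 + peptide P1
    list(26, "FLKNGPLDSN"),       # P9 and P2 overlap, 26-35
    list(38, "VVVGVPAIYLMLCKNIL"),# P10
    list(66, "YKVDKGAFTGEI"),     # P11/P3 overlap, 66-77
    list(94, "H"),                # catalytic electrophile
    list(99, "NVFGESDQL"),        # P4
    list(132, "EREAGKT"),         # P5
    list(142, "VFRQTQVISK"),      # P12
    list(162, "AYEPVWAIGTG"),     # PS00171 active-site pattern
    list(173, "KTASPQQAQEVHQKL"), # P6
    list(193, "ENVSP"),           # P7
    list(211, "VTANNAKELASQAD"),  # P8
    list(239, "FVQIVNARQ"))       # P13
  chars <- rep("G", 247L)
  for (f in frags) {
    at <- f[[1]]
    sub <- strsplit(f[[2]], "")[[1]]
    chars[at:(at + length(sub) - 1L)] <- sub
  }
  protein_sequence(paste(chars, collapse = ""),
                   id = "derf25_synthetic_scaffold")
}
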