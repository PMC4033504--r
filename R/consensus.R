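#' Consensus voting parameters
#'
#' @param k Minimum number of distinct tracks (predictors or alleles)
#'   that must cover a residue for it to be consensus-positive.
#' @param min_len Minimum length of a reported consensus region.
#' @param merge_gap Maximum gap (residues below the vote threshold)
#'   bridged when merging neighbouring runs.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(k, min_len = 4L, merge_gap = 0L) {
  k <- as.integer(k); min_len <- as.integer(min_len)
  merge_gap <- as.integer(merge_gap)
  stopifnot(k >= 1L, min_len >= 1L, merge_gap >= 0L)
  structure(list(k = k, min_len = min_len, merge_gap = merge_gap),
            class = "consensus_params")
}

#' Read a predictor-track interval table
#'
#' Reads the track TSV dialect (`track_name<TAB>start<TAB>end`, 1-based
#' inclusive, no header) and returns the region table grouped by track.
#' Duplicated or overlapping rows within one track are legitimate (an
#' allele's overlapping 9-mer binding cores, for instance) and are
#' union-merged by the consensus operations before voting.
#'
#' @param path TSV file path.
#' @return A region table, sorted by source then start. Malformed rows
#'   raise an error naming the row number.
#' @export
parse_interval_table <- function(path) {
  df <- read_region_tsv(path)
  df[order(df$source, df$start, df$end), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

track_coverage <- function(tracks, seq_length) {
  if (nrow(tracks) == 0L) {
    return(list(support = integer(seq_length %||% 0L), n_tracks = 0L))
  }
  L <- seq_length %||% max(tracks$end)
  if (any(tracks$end > L)) {
    stop(sprintf("region end %d exceeds sequence length %d",
                 max(tracks$end), L), call. = FALSE)
  }
  per_track <- lapply(split(tracks, tracks$source), function(d) {
    IRanges::reduce(regions_to_iranges(d))
  })
  support <- integer(L)
  for (ir in per_track) {
    cov <- as.integer(IRanges::coverage(ir, width = L))
    support <- support + as.integer(cov > 0L)
  }
  list(support = support, n_tracks = length(per_track))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residue-level k-of-n consensus over predictor tracks
#'
#' The central computation of the package: overlapping regions within
#' each track are first union-merged, per-residue support is the number
#' of distinct tracks covering the residue, and consensus epitopes are
#' the maximal runs of residues with support at least `k`, bridged
#' across gaps of at most `merge_gap` residues and filtered to length at
#' least `min_len`.
#'
#' @param tracks A region table (see [regions()]), one `source` per
#'   predictor or allele.
#' @param k,min_len,merge_gap Voting parameters; see
#'   [consensus_params()]. A [consensus_params()] object can be passed
#'   as `k`.
#' @param seq_length Optional sequence length; defaults to the largest
#'   region end. Supplying it bounds-checks the tracks and sizes the
#'   support vector.
#' @return An object of class `consensus_result`: list with `regions`
#'   (a region table with `length` and `min_support` columns), `support`
#'   (the full per-residue track-count vector) and `params`.
#' @examples
#' tr <- regions(c(1, 3, 2), c(10, 12, 8), source = c("a", "b", "c"))
#' residue_vote_consensus(tr, k = 2)
#' @export
residue_vote_consensus <- function(tracks, k, min_len = 4L, merge_gap = 0L,
                                   seq_length = NULL) {
  if (is(k, "consensus_params")) {
    params <- k
  } else {
    params <- consensus_params(k, min_len = min_len, merge_gap = merge_gap)
  }
  stopifnot(is.data.frame(tracks))
  if (nrow(tracks) == 0L) stop("no tracks supplied", call. = FALSE)
  cov <- track_coverage(tracks, seq_length)
  if (params$k > cov$n_tracks) {
    stop(sprintf("vote threshold k=%d exceeds the %d supplied tracks",
                 params$k, cov$n_tracks), call. = FALSE)
  }
  runs <- true_runs(cov$support >= params$k)
  merged <- if (nrow(runs) == 0L) {
    IRanges::IRanges()
  } else {
    IRanges::reduce(IRanges::IRanges(runs[, "start"], runs[, "end"]),
                    min.gapwidth = params$merge_gap + 1L)
  }
  merged <- merged[IRanges::width(merged) >= params$min_len]
  out <- iranges_to_regions(merged, source = "consensus")
  out$length <- out$end - out$start + 1L
  out$min_support <- vapply(seq_len(nrow(out)), function(i) {
    min(cov$support[out$start[i]:out$end[i]])
  }, integer(1))
  structure(list(regions = out, support = cov$support, params = params),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k=%d, min_len=%d, merge_gap=%d: %d region(s)\n",
              x$params$k, x$params$min_len, x$params$merge_gap,
              nrow(x$regions)))
  if (nrow(x$regions) > 0L) {
    cat(" ", paste(sprintf("%d-%d", x$regions$start, x$regions$end),
                   collapse = ", "), "\n")
  }
  invisible(x)
}

#' Allele-vote consensus over per-allele binder tracks
#'
#' The MHC class II locus rule: each track holds one HLA allele's
#' predicted binding cores (overlapping 9-mers allowed; union-merged
#' within the allele first), and a residue is consensus-positive when at
#' least `k` of the alleles cover it — the classical "k of n alleles
#' show an epitope" vote, with k = 3 of 4 as the default.
#'
#' @inheritParams residue_vote_consensus
#' @return A `consensus_result`; support counts distinct alleles.
#' @export
allele_support_consensus <- function(tracks, k = 3L, min_len = 4L,
                                     merge_gap = 0L, seq_length = NULL) {
  residue_vote_consensus(tracks, k, min_len = min_len,
                         merge_gap = merge_gap, seq_length = seq_length)
}

#' Combine the consensus results of two HLA loci
#'
#' Union of the two region sets with overlapping or immediately adjacent
#' regions merged; the per-residue support vector is the elementwise
#' maximum of the two inputs.
#'
#' @param dr,dq `consensus_result` objects on the same sequence (e.g.
#'   the HLA-DR and HLA-DQ locus votes).
#' @return A `consensus_result` covering both loci.
#' @export
combine_loci <- function(dr, dq) {
  stopifnot(is(dr, "consensus_result"), is(dq, "consensus_result"))
  ir <- c(regions_to_iranges(dr$regions), regions_to_iranges(dq$regions))
  merged <- IRanges::reduce(ir)
  L <- max(length(dr$support), length(dq$support))
  pad <- function(v) c(v, integer(L - length(v)))
  support <- pmax(pad(dr$support), pad(dq$support))
  out <- iranges_to_regions(merged, source = "combined")
  out$length <- out$end - out$start + 1L
  out$min_support <- vapply(seq_len(nrow(out)), function(i) {
    min(support[out$start[i]:out$end[i]])
  }, integer(1))
  params <- consensus_params(min(dr$params$k, dq$params$k),
                             min_len = min(dr$params$min_len, dq$params$min_len),
                             merge_gap = max(dr$params$merge_gap, dq$params$merge_gap))
  structure(list(regions = out, support = support, params = params),
            class = "consensus_result")
}

#' Write a consensus result as TSV
#'
#' Columns `start`, `end`, `length`, `min_support`, 1-based inclusive.
#'
#' @param result A `consensus_result`.
#' @param path Output path.
#' @export
write_consensus_tsv <- function(result, path) {
  utils::write.table(result$regions[, c("start", "end", "length", "min_support")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
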