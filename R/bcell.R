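# package-local cache for the bundled scale tables
the <- new.env(parent = emptyenv())

#' Construct a propensity scale
#'
#' A per-residue numeric table plus its aggregation convention. `mean`
#' scales are averaged over a sliding window; `product` scales (the Emini
#' surface-probability convention) multiply the window's normalized
#' values, i.e. the profile is `prod(value / norm)` over the window.
#'
#' @param name Scale name.
#' @param values Named numeric vector covering exactly the 20 standard
#'   residues.
#' @param combine `"mean"` or `"product"`.
#' @param norm Normalization constant for product mode (1 for mean mode).
#' @return An object of class `propensity_scale`.
#' @export
propensity_scale <- function(name, values, combine = c("mean", "product"),
                             norm = 1) {
  combine <- match.arg(combine)
  if (!setequal(names(values), AA_ALPHABET) || length(values) != 20L) {
    stop("scale must cover exactly the 20 standard residues", call. = FALSE)
  }
  structure(list(name = name, values = values[AA_ALPHABET],
                 combine = combine, norm = norm),
            class = "propensity_scale")
}

#' @export
print.propensity_scale <- function(x, ...) {
  cat(sprintf("<propensity_scale> %s (%s mode)\n", x$name, x$combine))
  print(round(x$values, 3))
  invisible(x)
}

#' Bundled propensity scales
#'
#' Loads the classical scale tables shipped with the package: Parker and
#' Hopp-Woods hydrophilicity, Emini surface fractions (product mode,
#' norm 0.37), Karplus-Schulz flexibility, Kolaskar-Tongaonkar
#' antigenicity, plus the Kyte-Doolittle hydropathy scale.
#'
#' @return Named list of [propensity_scale()] objects.
#' @export
propensity_scales <- function() {
  if (!is.null(the$scales)) return(the$scales)
  tab <- utils::read.table(
    system.file("extdata", "propensity_scales.tsv", package = "epivote"),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  mk <- function(nm, combine = "mean", norm = 1) {
    d <- tab[tab$scale == nm, ]
    propensity_scale(nm, stats::setNames(d$value, d$residue),
                     combine = combine, norm = norm)
  }
  the$scales <- list(
    parker = mk("parker"),
    hopp_woods = mk("hopp_woods"),
    emini = mk("emini", combine = "product", norm = 0.37),
    karplus_schulz = mk("karplus_schulz"),
    kolaskar_tongaonkar = mk("kolaskar_tongaonkar"),
    kyte_doolittle = propensity_scale("kyte_doolittle", KYTE_DOOLITTLE)
  )
  the$scales
}

#' Sliding-window propensity profile
#'
#' Aggregates a residue propensity scale over a centered window of odd
#' width. Scores are assigned to the window's center residue; the
#' `(window - 1) / 2` flanking residues at each end have no complete
#' window and are `NA` (never padded).
#'
#' @param seq A [protein_sequence()] or character scalar (no `X`: unknown
#'   residues have no defined propensity).
#' @param scale A [propensity_scale()].
#' @param window Odd window width, at most the sequence length.
#' @return An object of class `score_profile`: list with `seq_id`,
#'   `window`, and `scores` — a numeric vector of the sequence length
#'   with `NA` flanks; `sum(!is.na(scores)) == length - window + 1`.
#' @export
window_profile <- function(seq, scale, window = 7L) {
  seq <- as_protein_sequence(seq)
  stopifnot(is(scale, "propensity_scale"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  if (window > seq$length) {
    stop(sprintf("window %d exceeds sequence length %d", window, seq$length),
         call. = FALSE)
  }
  check_no_x(seq, "propensity profile")
  vals <- scale$values[strsplit(seq$residues, "")[[1]]]
  L <- seq$length
  half <- (window - 1L) %/% 2L
  scores <- rep(NA_real_, L)
  centers <- (half + 1L):(L - half)
  if (scale$combine == "mean") {
    cs <- cumsum(c(0, vals))
    scores[centers] <- (cs[centers + half + 1L] - cs[centers - half]) / window
  } else {
    lv <- cumsum(c(0, log(vals / scale$norm)))
    scores[centers] <- exp(lv[centers + half + 1L] - lv[centers - half])
  }
  structure(list(seq_id = seq$id, window = window, scale = scale$name,
                 combine = scale$combine, scores = scores),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile> %s: %s, window %d, %d scored residues\n",
              x$seq_id, x$scale, x$window, sum(!is.na(x$scores))))
  invisible(x)
}

#' Write a per-residue profile as a two-column TSV
#'
#' @param profile A `score_profile`.
#' @param path Output path; columns are `position` and `score` (defined
#'   positions only).
#' @export
write_profile_tsv <- function(profile, path) {
  keep <- !is.na(profile$scores)
  utils::write.table(
    data.frame(position = which(keep), score = profile$scores[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# maximal runs of TRUE in a logical vector (NA treated as FALSE)
true_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Antigenicity regions by thresholded window propensity
#'
#' The classical average-propensity antigenicity rule: compute the
#' windowed Kolaskar-Tongaonkar profile, take maximal runs of center
#' residues scoring above a fixed threshold of 1.0, extend each run by
#' half a window on both sides so that regions cover the full windows
#' that triggered them, and keep regions of at least `min_len` residues.
#'
#' @inheritParams window_profile
#' @param scale Propensity scale; defaults to the bundled
#'   Kolaskar-Tongaonkar table.
#' @param threshold Score cutoff (strictly greater-than).
#' @param min_len Minimum region length reported.
#' @return A region table with a `score` column (mean profile score over
#'   the run's centers).
#' @export
antigenicity_regions <- function(seq, scale = NULL, window = 7L,
                                 threshold = 1.0, min_len = 8L) {
  seq <- as_protein_sequence(seq)
  if (is.null(scale)) scale <- propensity_scales()$kolaskar_tongaonkar
  prof <- window_profile(seq, scale, window = window)
  half <- (window - 1L) %/% 2L
  runs <- true_runs(prof$scores > threshold)
  if (nrow(runs) == 0L) {
    out <- regions(integer(), integer())
    out$score <- numeric(0)
    return(out)
  }
  start <- runs[, "start"] - half
  end <- runs[, "end"] + half
  score <- vapply(seq_len(nrow(runs)), function(i) {
    mean(prof$scores[runs[i, "start"]:runs[i, "end"]])
  }, numeric(1))
  keep <- (end - start + 1L) >= min_len
  out <- regions(start[keep], end[keep], source = scale$name)
  out$score <- round(score[keep], 4)
  out
}

#' Composite weighted-propensity regions
#'
#' A DNAStar-style combination of several residue properties: each scale
#' is z-standardized (mean 0, sd 1 across its 20 residue values), the
#' windowed mean profiles are combined as a weighted sum, and maximal
#' runs of center residues above a percentile of the profile's own
#' distribution become candidate epitope regions.
#'
#' @inheritParams window_profile
#' @param scales Named list of [propensity_scale()] objects, or `NULL`
#'   for the default four-property set (Parker hydrophilicity 0.3, Emini
#'   accessibility 0.15, Karplus-Schulz flexibility 0.15,
#'   Kolaskar-Tongaonkar antigenicity 0.4).
#' @param weights Numeric vector parallel to `scales`; normalized to sum
#'   to 1.
#' @param percentile_cut Quantile (in \[0, 1\]) of the defined profile
#'   values above which a center residue is epitope-like.
#' @param min_len Minimum region length reported.
#' @return A region table of candidate regions (runs of above-cutoff
#'   centers).
#' @export
composite_index_regions <- function(seq, scales = NULL, weights = NULL,
                                    window = 7L, percentile_cut = 0.75,
                                    min_len = 4L) {
  seq <- as_protein_sequence(seq)
  if (is.null(scales)) {
    all <- propensity_scales()
    scales <- all[c("parker", "emini", "karplus_schulz", "kolaskar_tongaonkar")]
    if (is.null(weights)) weights <- c(0.3, 0.15, 0.15, 0.4)
  }
  if (length(scales) == 0L) stop("empty scale list", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(scales))
  stopifnot(length(weights) == length(scales), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)

  combined <- 0
  for (i in seq_along(scales)) {
    sc <- scales[[i]]
    zvals <- (sc$values - mean(sc$values)) / stats::sd(sc$values)
    zscale <- propensity_scale(paste0(sc$name, "_z"), zvals)
    prof <- window_profile(seq, zscale, window = window)
    combined <- combined + weights[i] * prof$scores
  }
  cut <- stats::quantile(combined, probs = percentile_cut, na.rm = TRUE,
                         names = FALSE)
  runs <- true_runs(combined > cut)
  keep <- (runs[, "end"] - runs[, "start"] + 1L) >= min_len
  out <- regions(runs[keep, "start"], runs[keep, "end"], source = "composite")
  out$score <- vapply(which(keep), function(i) {
    round(mean(combined[runs[i, "start"]:runs[i, "end"]]), 4)
  }, numeric(1))
  out
}
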