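#' Build a region table
#'
#' Regions are the currency of every epitope prediction in the package: a
#' plain `data.frame` with columns `source`, `start`, `end` (and optionally
#' `score`), all coordinates 1-based and inclusive on both ends — the same
#' convention in which epitope intervals are conventionally printed
#' (e.g. "11-18"). Conversion to 0-based half-open coordinates happens
#' only in the BED writer.
#'
#' @param start,end Integer vectors of 1-based inclusive bounds.
#' @param source Character vector (recycled) naming the predictor or
#'   allele that produced each region.
#' @param score Optional numeric vector.
#' @return A `data.frame` with columns `source`, `start`, `end` and, when
#'   given, `score`.
#' @export
regions <- function(start, end, source = "region", score = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == length(end))
  if (any(is.na(start) | is.na(end))) stop("non-integer region bound", call. = FALSE)
  if (any(start < 1L)) stop("region start must be >= 1", call. = FALSE)
  if (any(start > end)) {
    i <- which(start > end)[1]
    stop(sprintf("region start %d exceeds end %d", start[i], end[i]),
         call. = FALSE)
  }
  df <- data.frame(source = rep_len(as.character(source), length(start)),
                   start = start, end = end)
  if (!is.null(score)) df$score <- as.numeric(rep_len(score, length(start)))
  df
}

regions_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start, end = df$end)
}

iranges_to_regions <- function(ir, source = "region") {
  regions(IRanges::start(ir), IRanges::end(ir), source = source)
}

#' Union-merge regions within each source
#'
#' Overlapping or adjacent regions belonging to the same source (e.g. the
#' overlapping 9-mer binding cores of one HLA allele) are collapsed into
#' their union. Regions from different sources are never merged.
#'
#' @param df A region table (see [regions()]).
#' @return A region table with non-overlapping, sorted regions per source.
#' @export
merge_regions <- function(df) {
  if (nrow(df) == 0L) return(regions(integer(), integer()))
  parts <- lapply(split(df, df$source), function(d) {
    iranges_to_regions(IRanges::reduce(regions_to_iranges(d)),
                       source = d$source[1])
  })
  out <- do.call(rbind, parts[sort(names(parts))])
  rownames(out) <- NULL
  out
}

#' Read and write the predictor-track TSV dialect
#'
#' One row per predicted epitope region: `source<TAB>start<TAB>end`, no
#' header, 1-based inclusive coordinates. This is the dialect in which
#' external predictor output (B-cell tools, per-allele MHC-II binder
#' lists) is supplied to the consensus stage, and in which the bundled
#' worked-example fixtures are encoded.
#'
#' @param path Path to a TSV file.
#' @return For `read_region_tsv`, a region table; rows are validated and
#'   errors report the offending row number.
#' @seealso [parse_interval_table()] for the grouping/merging reader used
#'   by the consensus stage.
#' @export
read_region_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(regions(integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n != 3L)) {
    stop(sprintf("row %d: expected 3 tab-separated fields, got %d",
                 which(n != 3L)[1], n[which(n != 3L)[1]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("row %d: non-integer coordinate", i), call. = FALSE)
  }
  bad <- which(start > end)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: start %d exceeds end %d",
                 bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  }
  regions(start, end, source = m[, 1])
}

#' @rdname read_region_tsv
#' @param df A region table.
#' @export
write_region_tsv <- function(df, path) {
  utils::write.table(df[, c("source", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export regions as BED or GFF3
#'
#' BED uses 0-based half-open coordinates; the conversion from the
#' package-wide 1-based inclusive convention happens here and nowhere
#' else (`start - 1`, `end` unchanged). GFF3 keeps 1-based inclusive
#' coordinates per its specification.
#'
#' @param df A region table.
#' @param seq_id Sequence name for the first column.
#' @param path Output path.
#' @param type GFF3 feature type.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, seq_id, path) {
  bed <- data.frame(chrom = seq_id,
                    chromStart = df$start - 1L,
                    chromEnd = df$end,
                    name = df$source,
                    score = if ("score" %in% names(df)) df$score else 0)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back into a region table
#'
#' Inverse of [write_bed()]; used to round-trip-check coordinate
#' conversion.
#' @param path BED file path.
#' @return A region table.
#' @export
read_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  regions(b[[2]] + 1L, b[[3]], source = b[[4]])
}

#' @rdname write_bed
#' @export
write_gff3 <- function(df, seq_id, path, type = "epitope") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0L) {
    score <- if ("score" %in% names(df)) df$score else NA_real_
    lines <- sprintf("%s\tepivote\t%s\t%d\t%d\t%s\t.\t.\tName=%s",
                     seq_id, type, df$start, df$end,
                     ifelse(is.na(score), ".", format(score)), df$source)
    writeLines(lines, con)
  }
  invisible(path)
}
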