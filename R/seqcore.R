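#' @importFrom methods is
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a validated protein sequence
#'
#' The basic substrate of every analysis in the package: an identifier plus
#' an ordered string over the 20 standard one-letter amino-acid codes.
#' `X` is tolerated as an unknown residue, but operations that need real
#' residue properties (masses, hydropathy, dipeptide weights) refuse
#' sequences containing it rather than silently skipping positions.
#'
#' @param residues Character scalar of one-letter residue codes
#'   (case-insensitive; uppercased on construction).
#' @param id Character scalar identifier.
#' @return An object of class `protein_sequence`: a list with elements
#'   `id`, `residues` and `length`.
#' @examples
#' p <- protein_sequence("MKVLH", id = "toy")
#' length(p)
#' @export
protein_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L,
            is.character(id), length(id) == 1L)
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d in sequence '%s'",
                 chars[bad[1]], bad[1], id), call. = FALSE)
  }
  structure(list(id = id, residues = residues, length = length(chars)),
            class = "protein_sequence")
}

#' @export
length.protein_sequence <- function(x) x$length

#' @export
as.character.protein_sequence <- function(x, ...) x$residues

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s (%d aa)\n", x$id, x$length))
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" ", res, "\n")
  invisible(x)
}

as_protein_sequence <- function(x, id = "seq") {
  if (is(x, "protein_sequence")) return(x)
  protein_sequence(as.character(x), id = id)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return A list of [protein_sequence()] objects, one per record.
#'   Residues are uppercased; gap (`-`) or stop (`*`) characters are
#'   rejected with an error naming the offending character and position.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L ||
      !any(nzchar(trimws(readLines(path, warn = FALSE))))) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  mapply(function(s, id) protein_sequence(s, id = id),
         as.character(set), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A [protein_sequence()] or list of them.
#' @param path Output path.
#' @param width Line-wrap width for the sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    res <- s$residues
    starts <- seq(1L, nchar(res), by = width)
    writeLines(substring(res, starts, pmin(starts + width - 1L, nchar(res))), con)
  }
  invisible(path)
}

#' Translate a coding nucleotide sequence
#'
#' Standard genetic code (translation table 1), reading from `frame` to the
#' first stop codon or the end of the last complete codon. A codon
#' containing `N` is translated when all its expansions agree (e.g. `GCN`
#' is unambiguously Ala) and to `X` otherwise; a codon that is a stop only
#' under some expansions is also `X`, so translation never terminates on an
#' ambiguous codon. A trailing stop is removed.
#'
#' @param nucleotides Character scalar over `ACGT` and `N`
#'   (case-insensitive).
#' @param frame Integer offset in `0:2` at which translation starts.
#' @param id Identifier for the returned protein.
#' @return A [protein_sequence()].
#' @examples
#' translate_cds("ATGAAATAA")$residues  # "MK"
#' @export
translate_cds <- function(nucleotides, frame = 0L, id = "translation") {
  stopifnot(is.character(nucleotides), length(nucleotides) == 1L)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  nt <- toupper(nucleotides)
  chars <- strsplit(nt, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  nt <- substr(nt, frame + 1L, nchar(nt))
  if (nchar(nt) < 3L) stop("fewer than one complete codon after frame offset",
                           call. = FALSE)
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "solve",
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) aa <- substr(aa, 1L, stop_at - 1L)
  if (nchar(aa) == 0L) {
    stop("translation is empty (stop codon at frame start)", call. = FALSE)
  }
  protein_sequence(aa, id = id)
}

#' Residue at a 1-based position
#'
#' All coordinates in this package are 1-based and inclusive; this is the
#' elementary accessor used e.g. to inspect catalytic positions (for a
#' triosephosphate isomerase, the electrophilic His and proton-acceptor
#' Glu of the active site).
#'
#' @param seq A [protein_sequence()] (or character scalar).
#' @param pos 1-based residue index.
#' @return Single one-letter residue code.
#' @export
residue_at <- function(seq, pos) {
  seq <- as_protein_sequence(seq)
  stopifnot(length(pos) == 1L, pos == as.integer(pos))
  if (pos < 1L || pos > seq$length) {
    stop(sprintf("position %d out of range [1, %d]", pos, seq$length),
         call. = FALSE)
  }
  substr(seq$residues, pos, pos)
}
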