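#' Parse a PROSITE-syntax pattern
#'
#' Supports the core PROSITE pattern grammar: fixed residues, `x` (any
#' residue), `[...]` allowed sets, `{...}` forbidden sets, repeat counts
#' `(n)` and ranges `(n,m)`, `-` separators, `<`/`>` terminal anchors and
#' an optional trailing `.`.
#'
#' @param text Pattern text, e.g. `"[AC]-x(2)-{P}."`.
#' @param id Optional pattern identifier (e.g. a PROSITE accession).
#' @return An object of class `motif_pattern`: list with `id`, `pattern`
#'   (normalized string), `elements` (one record per pattern position
#'   group, each with `type`, `residues`, `min_rep`, `max_rep`) and
#'   anchor flags `nterm`, `cterm`.
#' @examples
#' parse_prosite_pattern("A-x-A.")
#' @export
parse_prosite_pattern <- function(text, id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- gsub("\\s", "", text)
  if (!nzchar(raw)) stop("empty pattern", call. = FALSE)
  work <- sub("\\.$", "", raw)
  nterm <- startsWith(work, "<")
  if (nterm) work <- substr(work, 2, nchar(work))
  cterm <- endsWith(work, ">")
  if (cterm) work <- substr(work, 1, nchar(work) - 1L)
  if (!nzchar(work)) stop("pattern has no elements", call. = FALSE)

  tokens <- strsplit(work, "-", fixed = TRUE)[[1]]
  offsets <- cumsum(c(1L + nterm, nchar(tokens)[-length(tokens)] + 1L))
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    off <- offsets[i]
    if (!nzchar(tok)) {
      stop(sprintf("malformed pattern at offset %d: empty element", off),
           call. = FALSE)
    }
    m <- regmatches(tok, regexec(
      "^(x|[A-WYZ]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
      tok))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("malformed pattern element '%s' at offset %d", tok, off),
           call. = FALSE)
    }
    body <- m[2]
    min_rep <- if (nzchar(m[4])) as.integer(m[4]) else 1L
    max_rep <- if (nzchar(m[6])) as.integer(m[6]) else min_rep
    if (max_rep < min_rep) {
      stop(sprintf("repeat range (%d,%d) at offset %d is decreasing",
                   min_rep, max_rep, off), call. = FALSE)
    }
    el <- if (body == "x") {
      list(type = "any", residues = character(0))
    } else if (startsWith(body, "[")) {
      list(type = "allowed",
           residues = strsplit(substr(body, 2, nchar(body) - 1L), "")[[1]])
    } else if (startsWith(body, "{")) {
      list(type = "forbidden",
           residues = strsplit(substr(body, 2, nchar(body) - 1L), "")[[1]])
    } else {
      list(type = "fixed", residues = body)
    }
    el$min_rep <- min_rep
    el$max_rep <- max_rep
    elements[[i]] <- el
  }
  pat <- structure(list(id = id, elements = elements,
                        nterm = nterm, cterm = cterm),
                   class = "motif_pattern")
  pat$pattern <- prosite_pattern_string(pat)
  pat
}

#' Serialize a parsed pattern back to normalized PROSITE syntax
#'
#' @param pattern A `motif_pattern`.
#' @return A normalized pattern string (parsing it again gives an
#'   identical element list).
#' @export
prosite_pattern_string <- function(pattern) {
  stopifnot(is(pattern, "motif_pattern"))
  toks <- vapply(pattern$elements, function(el) {
    body <- switch(el$type,
                   any = "x",
                   fixed = el$residues,
                   allowed = paste0("[", paste(el$residues, collapse = ""), "]"),
                   forbidden = paste0("{", paste(el$residues, collapse = ""), "}"))
    if (el$min_rep == 1L && el$max_rep == 1L) body
    else if (el$min_rep == el$max_rep) sprintf("%s(%d)", body, el$min_rep)
    else sprintf("%s(%d,%d)", body, el$min_rep, el$max_rep)
  }, character(1))
  paste0(if (pattern$nterm) "<" else "", paste(toks, collapse = "-"),
         if (pattern$cterm) ">" else "", ".")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s %s\n",
              if (is.null(x$id)) "(unnamed)" else x$id, x$pattern))
  invisible(x)
}

# Does a single sequence character satisfy one pattern element?
# X (unknown residue) satisfies only 'any' elements.
element_matches <- function(ch, el) {
  switch(el$type,
         any = TRUE,
         fixed = ch == el$residues,
         allowed = ch != "X" && ch %in% el$residues,
         forbidden = ch != "X" && !(ch %in% el$residues))
}

#' Scan a sequence with a PROSITE pattern
#'
#' Reports every match span, including overlapping matches and, for
#' patterns with repeat ranges, every distinct span achievable at a given
#' start. Anchored patterns match only at the respective terminus.
#'
#' @param seq A [protein_sequence()] or character scalar.
#' @param pattern A `motif_pattern` from [parse_prosite_pattern()], or
#'   pattern text to parse on the fly.
#' @return A region table (1-based inclusive `start`/`end`, `source` =
#'   pattern id) with a `text` column holding the matched subsequence,
#'   ordered left to right.
#' @examples
#' pat <- parse_prosite_pattern("A-x-A.")
#' scan_pattern(protein_sequence("CAKAVA"), pat)
#' @export
scan_pattern <- function(seq, pattern) {
  seq <- as_protein_sequence(seq)
  if (is.character(pattern)) pattern <- parse_prosite_pattern(pattern)
  stopifnot(is(pattern, "motif_pattern"))
  chars <- strsplit(seq$residues, "")[[1]]
  L <- length(chars)
  elements <- pattern$elements

  # all end positions (inclusive) of matches of elements[ei..] starting at pos
  ends_from <- function(ei, pos) {
    if (ei > length(elements)) return(pos - 1L)
    el <- elements[[ei]]
    out <- integer(0)
    # elements are identical within a repeat group: extend run length n
    # from min_rep up, abandoning as soon as one copy fails
    if (el$min_rep > 0L) {
      for (n in 1:el$min_rep) {
        p <- pos + n - 1L
        if (p > L || !element_matches(chars[p], el)) return(out)
      }
    }
    out <- c(out, ends_from(ei + 1L, pos + el$min_rep))
    n <- el$min_rep
    while (n < el$max_rep) {
      n <- n + 1L
      p <- pos + n - 1L
      if (p > L || !element_matches(chars[p], el)) break
      out <- c(out, ends_from(ei + 1L, pos + n))
    }
    out
  }

  starts <- if (pattern$nterm) 1L else seq_len(L)
  hits_s <- integer(0); hits_e <- integer(0)
  for (s in starts) {
    ends <- unique(ends_from(1L, s))
    ends <- ends[ends >= s]          # zero-width matches are not reported
    if (pattern$cterm) ends <- ends[ends == L]
    if (length(ends) > 0L) {
      hits_s <- c(hits_s, rep(s, length(ends)))
      hits_e <- c(hits_e, sort(ends))
    }
  }
  src <- if (is.null(pattern$id)) pattern$pattern else pattern$id
  out <- regions(hits_s, hits_e,
                 source = if (length(hits_s)) src else character(0))
  out$text <- if (nrow(out) == 0L) character(0) else
    substring(seq$residues, out$start, out$end)
  out
}

#' Load bundled motif pattern definitions
#'
#' The package ships a small pattern file (`ID<TAB>pattern` per line)
#' containing the triosephosphate-isomerase active-site pattern PS00171
#' and a few classical kinase phosphorylation-site patterns used for
#' illustrative phosphosite motif scanning.
#'
#' @param path Pattern file; defaults to the bundled file.
#' @return Named list of `motif_pattern` objects.
#' @export
load_motif_patterns <- function(path = system.file("extdata", "prosite_patterns.tsv",
                                                   package = "epivote")) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  pats <- lapply(fields, function(f) parse_prosite_pattern(f[2], id = f[1]))
  stats::setNames(pats, vapply(fields, `[`, character(1), 1))
}
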