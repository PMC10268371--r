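#' @title Reading and writing RNA secondary structure files
#' @description Parsers and writers for the three formats in common use for
#'   pseudoknotted secondary structures: BPSEQ, CT and dot-bracket-letter
#'   (db). Each format exists in a headered and a header-free dialect; the
#'   `headered` flag selects between them. All parsers return an
#'   [rna_structure] and all writers produce text that re-parses to an equal
#'   structure.
#' @name structure_io
NULL

split_lines <- function(text) {
  x <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  x[nzchar(trimws(x))]
}

# leading non-record lines: '#'/'>' comments or lines whose tokens do not
# look like a format record; only skipped in the headered dialect
is_comment <- function(line) grepl("^\\s*[#>]", line)

#' Parse a BPSEQ record set
#'
#' BPSEQ holds one line per nucleotide: `position base partner`, with
#' partner 0 for unpaired positions. Positions must be consecutive from 1
#' and partnering must be symmetric (`i -> j` implies `j -> i`).
#'
#' @param text A character vector or single string with the file content.
#' @param headered If `TRUE` (default), leading comment/header lines
#'   (starting with `#` or `>`, or not shaped like records) are skipped;
#'   if `FALSE` every line must be a record (the `-nH` dialect).
#' @return An [rna_structure]. The nucleotide sequence is kept.
#' @examples
#' parse_bpseq("1 A 0\n2 G 5\n3 C 0\n4 U 0\n5 C 2")
#' @export
parse_bpseq <- function(text, headered = TRUE) {
  lines <- split_lines(text)
  rec <- function(line) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    length(tok) == 3L && grepl("^[0-9]+$", tok[1]) && grepl("^[0-9]+$", tok[3])
  }
  if (headered) {
    while (length(lines) && (is_comment(lines[1]) || !rec(lines[1])))
      lines <- lines[-1L]
  }
  if (!length(lines)) stop("no BPSEQ records found")
  tok <- strsplit(trimws(lines), "\\s+")
  bad <- which(!vapply(lines, rec, logical(1)))
  if (length(bad))
    stop("malformed BPSEQ record at line ", bad[1], ": ", lines[bad[1]])
  pos <- vapply(tok, function(t) as.integer(t[1]), integer(1))
  base <- vapply(tok, function(t) t[2], character(1))
  partner <- vapply(tok, function(t) as.integer(t[3]), integer(1))
  parse_partner_records(pos, base, partner, "BPSEQ")
}

#' Parse a CT record set
#'
#' CT holds one 6-column line per nucleotide:
#' `index base previous next partner natural-index`. The headered dialect
#' starts with a title line (typically the length and a name).
#'
#' @inheritParams parse_bpseq
#' @return An [rna_structure].
#' @export
parse_ct <- function(text, headered = TRUE) {
  lines <- split_lines(text)
  toks <- strsplit(trimws(lines), "\\s+")
  rec <- function(t) {
    length(t) >= 6L && all(grepl("^-?[0-9]+$", t[c(1, 3, 4, 5, 6)]))
  }
  if (headered) {
    while (length(toks) && !rec(toks[[1]])) {
      toks <- toks[-1L]
      lines <- lines[-1L]
    }
  }
  if (!length(toks)) stop("no CT records found")
  bad <- which(!vapply(toks, rec, logical(1)))
  if (length(bad))
    stop("malformed CT record (expected 6 columns) at line ", bad[1],
         ": ", lines[bad[1]])
  nc <- lengths(toks)
  if (any(nc != 6L))
    stop("malformed CT record (expected 6 columns) at line ",
         which(nc != 6L)[1], ": ", lines[which(nc != 6L)[1]])
  pos <- vapply(toks, function(t) as.integer(t[1]), integer(1))
  base <- vapply(toks, function(t) t[2], character(1))
  partner <- vapply(toks, function(t) as.integer(t[5]), integer(1))
  parse_partner_records(pos, base, partner, "CT")
}

# shared contract of the partner-column formats
parse_partner_records <- function(pos, base, partner, what) {
  n <- length(pos)
  if (!identical(pos, seq_len(n)))
    stop(what, " positions are not consecutive 1..n")
  if (any(partner < 0L | partner > n))
    stop(what, " partner index out of range")
  if (any(partner == pos))
    stop(what, " position paired with itself")
  idx <- which(partner > 0L)
  if (length(idx)) {
    if (any(abs(partner[idx] - idx) < 2L))
      stop(what, " arc joins adjacent positions")
    back <- partner[partner[idx]]
    if (any(back != idx))
      stop(what, " partnering is not symmetric")
  }
  pr <- idx[idx < partner[idx]]
  pairs <- cbind(pr, partner[pr])
  rna_structure(n, pairs, paste(base, collapse = ""))
}

DB_BRACKETS <- c("()", "[]", "{}", "<>")

#' Parse dot-bracket-letter notation
#'
#' One structure line over `.`, the bracket families `()`, `[]`, `{}`, `<>`
#' and letter families (uppercase opens, the matching lowercase closes).
#' Each family is matched independently with a stack, so crossing families
#' encode pseudoknots. An optional `>`-header line and an optional sequence
#' line may precede the structure line.
#'
#' @param text A character vector or single string with the file content.
#' @return An [rna_structure].
#' @examples
#' parse_dotbracket("([)]")
#' parse_dotbracket("(A.)a")
#' @export
parse_dotbracket <- function(text) {
  lines <- split_lines(text)
  lines <- lines[!vapply(lines, is_comment, logical(1))]
  if (!length(lines)) stop("no dot-bracket content found")
  lines <- trimws(lines)
  sequence <- NULL
  struct_line <- lines[length(lines)]
  if (length(lines) >= 2L) {
    cand <- lines[length(lines) - 1L]
    if (grepl("^[ACGUTNacgutn]+$", cand))
      sequence <- gsub("T", "U", toupper(cand))
  }
  chars <- strsplit(struct_line, "")[[1]]
  n <- length(chars)
  opens <- c("(", "[", "{", "<", LETTERS)
  closes <- c(")", "]", "}", ">", letters)
  stacks <- rep(list(integer(0)), length(opens))
  pairs <- NULL
  for (k in seq_len(n)) {
    ch <- chars[k]
    if (ch == ".") next
    fo <- match(ch, opens)
    if (!is.na(fo)) {
      stacks[[fo]] <- c(stacks[[fo]], k)
      next
    }
    fc <- match(ch, closes)
    if (!is.na(fc)) {
      st <- stacks[[fc]]
      if (!length(st))
        stop("closing symbol '", ch, "' at position ", k, " has no open")
      pairs <- rbind(pairs, c(st[length(st)], k))
      stacks[[fc]] <- st[-length(st)]
      next
    }
    stop("unknown dot-bracket character '", ch, "' at position ", k)
  }
  left <- which(lengths(stacks) > 0L)
  if (length(left))
    stop("unbalanced dot-bracket family '", opens[left[1]], "'")
  if (!is.null(sequence) && nchar(sequence) != n) sequence <- NULL
  rna_structure(n, pairs, sequence)
}

seq_or_N <- function(x) {
  if (!is.null(x$sequence)) strsplit(x$sequence, "")[[1]]
  else rep("N", x$length)
}

#' Write a structure as BPSEQ, CT or dot-bracket-letter text
#'
#' `write_dotbracket()` assigns bracket families greedily (first family, in
#' the order `()`, `[]`, `{}`, `<>`, `A..Z`, whose arcs the new arc does not
#' cross), so a pseudoknot-free structure uses only `()` and a structure
#' with one crossing uses exactly two families.
#'
#' @param x An [rna_structure].
#' @param headered Include a header/comment line (default `TRUE`); the
#'   `FALSE` variant mirrors the header-free (`-nH`) dialect.
#' @param name Identifier placed in the header.
#' @return A single string; it re-parses to a structure equal to `x`.
#' @examples
#' cat(write_dotbracket(parse_dotbracket("([)]")))
#' @name write_structure
NULL

#' @rdname write_structure
#' @export
write_bpseq <- function(x, headered = TRUE, name = "molecule") {
  stopifnot(is_rna_structure(x))
  partner <- integer(x$length)
  partner[x$pairs[, 1L]] <- x$pairs[, 2L]
  partner[x$pairs[, 2L]] <- x$pairs[, 1L]
  body <- paste(seq_len(x$length), seq_or_N(x), partner, collapse = "\n")
  hdr <- if (headered) sprintf("# %s length=%d\n", name, x$length) else ""
  paste0(hdr, body, "\n")
}

#' @rdname write_structure
#' @export
write_ct <- function(x, headered = TRUE, name = "molecule") {
  stopifnot(is_rna_structure(x))
  n <- x$length
  partner <- integer(n)
  partner[x$pairs[, 1L]] <- x$pairs[, 2L]
  partner[x$pairs[, 2L]] <- x$pairs[, 1L]
  i <- seq_len(n)
  nxt <- c(i[-1L], 0L)
  body <- paste(i, seq_or_N(x), i - 1L, nxt, partner, i, collapse = "\n")
  hdr <- if (headered) sprintf("%d %s\n", n, name) else ""
  paste0(hdr, body, "\n")
}

#' @rdname write_structure
#' @export
write_dotbracket <- function(x, headered = TRUE, name = "molecule") {
  stopifnot(is_rna_structure(x))
  p <- x$pairs
  chars <- rep(".", x$length)
  if (nrow(p)) {
    opens <- c("(", "[", "{", "<", LETTERS)
    closes <- c(")", "]", "}", ">", letters)
    fam <- integer(nrow(p))         # pairs are sorted by opening position
    for (a in seq_len(nrow(p))) {
      f <- 1L
      repeat {
        prev <- which(fam[seq_len(a - 1L)] == f)
        cross <- FALSE
        if (length(prev)) {
          i <- p[prev, 1L]; j <- p[prev, 2L]
          cross <- any(i < p[a, 1L] & p[a, 1L] < j & j < p[a, 2L])
        }
        if (!cross) break
        f <- f + 1L
        if (f > length(opens))
          stop("crossing complexity exceeds available bracket families")
      }
      fam[a] <- f
    }
    chars[p[, 1L]] <- opens[fam]
    chars[p[, 2L]] <- closes[fam]
  }
  body <- paste(chars, collapse = "")
  hdr <- if (headered) sprintf(">%s length=%d\n", name, x$length) else ""
  seqline <- if (!is.null(x$sequence)) paste0(x$sequence, "\n") else ""
  paste0(hdr, seqline, body, "\n")
}

#' Read a structure file, auto-detecting the format
#'
#' The format is taken from the file extension: `.bpseq` (BPSEQ), `.ct`
#' (CT) and `.db` / `.dbn` / `.dot` (dot-bracket-letter). Header and
#' header-free dialects are both accepted (`headered = TRUE` skips any
#' leading non-record lines and is safe for either).
#'
#' @param path Path to a structure file.
#' @param format One of `"auto"`, `"bpseq"`, `"ct"`, `"db"`.
#' @param headered Passed to the BPSEQ/CT parsers.
#' @return An [rna_structure].
#' @export
read_structure <- function(path, format = c("auto", "bpseq", "ct", "db"),
                           headered = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      bpseq = "bpseq", ct = "ct",
      db = "db", dbn = "db", dot = "db",
      stop("cannot infer structure format from extension '.", ext, "'")
    )
  }
  text <- readLines(path, warn = FALSE)
  switch(format,
    bpseq = parse_bpseq(text, headered = headered),
    ct = parse_ct(text, headered = headered),
    db = parse_dotbracket(text)
  )
}
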