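#' Read a coded character matrix
#'
#' Two dialects are supported. NEXUS: a standard `DATA` or `CHARACTERS` block
#' with `DIMENSIONS`, a `FORMAT` line declaring `SYMBOLS`, `MISSING` and
#' `GAP`, an optional `CHARSTATELABELS` list and a non-interleaved `MATRIX`.
#' Curly-brace tokens (`{01}`) are polymorphic state sets; the `MISSING`
#' token maps to missing and the `GAP` token to inapplicable (the usual
#' morphology convention for, e.g., attachment characters of an absent
#' muscle). CSV: one row per taxon (first column the taxon label), one column
#' per character (header = character id), `/`-separated polymorphism, `?`
#' missing, `-` inapplicable.
#'
#' Per-character metadata travels in the NEXUS character labels as a trailing
#' `[kind/region/id=N]` tag (written by [write_matrix()]); for CSV it can be
#' supplied via `charmeta`.
#'
#' @param file path to the file, or `NULL` when `text` is given.
#' @param dialect `"nexus"` or `"csv"`.
#' @param text matrix content as a character vector of lines (alternative to
#'   `file`).
#' @param charmeta optional metadata data frame (see [character_matrix()]),
#'   used by the CSV dialect.
#' @return a `"char_matrix"`.
#' @export
read_matrix <- function(file = NULL, dialect = c("nexus", "csv"),
                        text = NULL, charmeta = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    if (is.null(file)) stop("either `file` or `text` must be given")
    text <- readLines(file, warn = FALSE)
  }
  switch(dialect,
         nexus = read_matrix_nexus(text),
         csv = read_matrix_csv(text, charmeta))
}

#' Serialize a coded character matrix
#'
#' Output round-trips through [read_matrix()]: taxa, cells, character ids and
#' (for NEXUS) kind/region metadata are preserved exactly. NEXUS cells use
#' `{...}` polymorphism, `?` missing, `-` inapplicable; metadata is embedded
#' in `CHARSTATELABELS` as a `[kind/region/id=N]` tag.
#'
#' @param m a `"char_matrix"`.
#' @param file optional path; when `NULL` the lines are returned invisibly
#'   only.
#' @param dialect `"nexus"` or `"csv"`.
#' @return character vector of lines, invisibly.
#' @export
write_matrix <- function(m, file = NULL, dialect = c("nexus", "csv")) {
  dialect <- match.arg(dialect)
  maxstate <- if (nrow(m$chars) > 0L) max(m$chars$nstates) - 1L else 0L
  if (maxstate > 9L) stop("states above 9 are not representable in ",
                          dialect, " output")
  lines <- switch(dialect,
                  nexus = write_matrix_nexus(m),
                  csv = write_matrix_csv(m))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# ---- NEXUS ----------------------------------------------------------------

# tokenize one matrix row into cell tokens, honouring {..} and (..) groups
split_cell_tokens <- function(s, lineno) {
  s <- gsub("[[:space:]]", "", s)
  toks <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      while (j <= n && substr(s, j, j) != close) j <- j + 1L
      if (j > n) stop("line ", lineno, ": unterminated '", ch, "' group")
      toks <- c(toks, substr(s, i, j))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

read_matrix_nexus <- function(text) {
  if (!grepl("^#NEXUS", toupper(trimws(text[1])))) {
    stop("line 1: not a NEXUS file (missing #NEXUS header)")
  }
  up <- toupper(text)
  begin <- grep("^\\s*BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (length(begin) == 0L) stop("no DATA or CHARACTERS block found")
  begin <- begin[1]

  ntax <- nchar_ <- NA_integer_
  missing_tok <- "?"; gap_tok <- "-"; symbols <- "0123456789"
  labels <- NULL

  i <- begin + 1L
  taxa <- character(0)
  rows <- list()
  in_matrix <- FALSE
  while (i <= length(text)) {
    line <- trimws(text[i])
    upline <- toupper(line)
    if (!in_matrix) {
      if (grepl("^DIMENSIONS", upline)) {
        mt <- regmatches(upline, regexec("NTAX\\s*=\\s*([0-9]+)", upline))[[1]]
        if (length(mt) == 2L) ntax <- as.integer(mt[2])
        mc <- regmatches(upline, regexec("NCHAR\\s*=\\s*([0-9]+)", upline))[[1]]
        if (length(mc) == 2L) nchar_ <- as.integer(mc[2])
      } else if (grepl("^FORMAT", upline)) {
        ms <- regmatches(line, regexec("SYMBOLS\\s*=\\s*\"([^\"]*)\"", line,
                                       ignore.case = TRUE))[[1]]
        if (length(ms) == 2L) symbols <- gsub("\\s", "", ms[2])
        mm <- regmatches(line, regexec("MISSING\\s*=\\s*(\\S)", line,
                                       ignore.case = TRUE))[[1]]
        if (length(mm) == 2L) missing_tok <- mm[2]
        mg <- regmatches(line, regexec("GAP\\s*=\\s*(\\S)", line,
                                       ignore.case = TRUE))[[1]]
        if (length(mg) == 2L) gap_tok <- mg[2]
      } else if (grepl("^CHARSTATELABELS", upline)) {
        block <- line
        while (!grepl(";\\s*$", block) && i < length(text)) {
          i <- i + 1L
          block <- paste(block, trimws(text[i]))
        }
        labels <- parse_charstatelabels(block)
      } else if (grepl("^MATRIX", upline)) {
        in_matrix <- TRUE
      } else if (grepl("^END\\s*;", upline)) {
        break
      }
    } else {
      if (line == ";" || grepl("^END\\s*;", upline)) {
        if (line == ";") in_matrix <- FALSE else break
      } else if (nzchar(line)) {
        mt <- regmatches(line,
                         regexec("^('[^']+'|\\S+)\\s*(.*)$", line))[[1]]
        if (length(mt) != 3L) {
          stop("line ", i, ": cannot parse matrix row: ", line)
        }
        taxon <- gsub("^'|'$", "", mt[2])
        if (taxon %in% taxa) {
          stop("line ", i, ": duplicate taxon '", taxon,
               "' (interleaved matrices are not supported)")
        }
        toks <- split_cell_tokens(mt[3], i)
        if (!is.na(nchar_) && length(toks) != nchar_) {
          stop("line ", i, ": taxon '", taxon, "' has ", length(toks),
               " cells, expected NCHAR=", nchar_)
        }
        ok_sym <- strsplit(symbols, "")[[1]]
        cells <- vapply(seq_along(toks), function(k) {
          tok <- toks[k]
          if (tok == missing_tok) return(MISSING_TOKEN)
          if (tok == gap_tok) return(INAPPLICABLE_TOKEN)
          body <- gsub("[{}()]", "", tok)
          chs <- strsplit(body, "")[[1]]
          badc <- setdiff(chs, ok_sym)
          if (length(badc) > 0L) {
            stop("line ", i, ": unknown symbol '", badc[1],
                 "' in cell ", k, " of taxon '", taxon, "'")
          }
          parse_cell_token(body)
        }, character(1))
        taxa <- c(taxa, taxon)
        rows[[taxon]] <- cells
      }
    }
    i <- i + 1L
  }
  if (length(rows) == 0L) stop("no matrix rows found")
  if (!is.na(ntax) && length(rows) != ntax) {
    stop("matrix has ", length(rows), " taxa, expected NTAX=", ntax)
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- taxa
  chars <- NULL
  if (!is.null(labels) && nrow(labels) == ncol(cells)) {
    chars <- labels
  }
  nst <- max(1L, nchar(symbols))
  if (is.null(chars)) {
    chars <- data.frame(id = seq_len(ncol(cells)))
  }
  chars$nstates <- rep(nst, nrow(chars))
  character_matrix(cells, chars = chars)
}

# CHARSTATELABELS entries look like:  3 'label text [major/HN/id=112]'
parse_charstatelabels <- function(block) {
  body <- sub("^\\s*CHARSTATELABELS", "", block, ignore.case = TRUE)
  body <- sub(";\\s*$", "", body)
  entries <- strsplit(body, ",")[[1]]
  out <- list()
  for (e in entries) {
    e <- trimws(e)
    if (!nzchar(e)) next
    mt <- regmatches(e, regexec("^([0-9]+)\\s+'(.*)'$", e))[[1]]
    if (length(mt) != 3L) {
      mt <- regmatches(e, regexec("^([0-9]+)\\s+(\\S+)$", e))[[1]]
      if (length(mt) != 3L) next
    }
    lab <- mt[3]
    kind <- "minor"; region <- "FL"; id <- as.integer(mt[2])
    tag <- regmatches(lab,
                      regexec("\\[(major|minor)/(HN|FL|HL|trunk)/id=([0-9]+)\\]\\s*$",
                              lab))[[1]]
    if (length(tag) == 4L) {
      kind <- tag[2]; region <- tag[3]; id <- as.integer(tag[4])
      lab <- trimws(sub("\\[[^]]*\\]\\s*$", "", lab))
    }
    out[[length(out) + 1L]] <- data.frame(
      id = id, label = lab, kind = kind, region = region,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

write_matrix_nexus <- function(m) {
  nst <- if (nrow(m$chars) > 0L) max(m$chars$nstates) else 2L
  symbols <- paste(0:(nst - 1L), collapse = "")
  cells <- apply(m$cells, c(1, 2), function(tok) {
    if (tok %in% c(MISSING_TOKEN, INAPPLICABLE_TOKEN)) return(tok)
    if (nchar(tok) > 1L) paste0("{", tok, "}") else tok
  })
  pad <- max(nchar(m$taxa)) + 2L
  lablines <- vapply(seq_len(nrow(m$chars)), function(j) {
    tag <- sprintf("[%s/%s/id=%d]", m$chars$kind[j], m$chars$region[j],
                   m$chars$id[j])
    sep <- if (j < nrow(m$chars)) "," else ""
    sprintf("    %d '%s %s'%s", j, gsub("'", "", m$chars$label[j]), tag, sep)
  }, character(1))
  rowlines <- vapply(seq_along(m$taxa), function(i) {
    sprintf("    %-*s%s", pad, m$taxa[i], paste(cells[i, ], collapse = ""))
  }, character(1))
  c("#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), nrow(m$chars)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            symbols),
    "  CHARSTATELABELS",
    lablines,
    "  ;",
    "  MATRIX",
    rowlines,
    "  ;",
    "END;")
}

# ---- CSV ------------------------------------------------------------------

read_matrix_csv <- function(text, charmeta = NULL) {
  df <- utils::read.csv(text = text, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 1L) stop("empty CSV matrix")
  taxa <- df[[1]]
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup) > 0L) stop("duplicate taxon '", dup[1], "' in CSV matrix")
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- taxa
  ids <- suppressWarnings(as.integer(colnames(cells)))
  if (is.null(charmeta)) {
    charmeta <- data.frame(id = if (anyNA(ids)) seq_len(ncol(cells)) else ids)
  }
  character_matrix(cells, chars = charmeta)
}

write_matrix_csv <- function(m) {
  cells <- apply(m$cells, c(1, 2), function(tok) {
    st <- cell_states(tok)
    if (is.null(st)) tok else paste(st, collapse = "/")
  })
  header <- paste(c("taxon", m$chars$id), collapse = ",")
  rows <- vapply(seq_along(m$taxa), function(i) {
    paste(c(m$taxa[i], cells[i, ]), collapse = ",")
  }, character(1))
  c(header, rows)
}

#' Compare two character matrices for identical content
#'
#' Equality of taxa, canonical cell tokens, character ids and kind/region
#' metadata; the basis of the write-then-read round-trip guarantee.
#'
#' @param a,b `"char_matrix"` objects.
#' @return `TRUE` or `FALSE`.
#' @export
matrices_identical <- function(a, b) {
  identical(a$taxa, b$taxa) &&
    identical(unname(a$cells), unname(b$cells)) &&
    identical(a$chars$id, b$chars$id) &&
    identical(a$chars$kind, b$chars$kind) &&
    identical(a$chars$region, b$chars$region)
}
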