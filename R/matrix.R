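#' Coded character matrix for discrete anatomical characters
#'
#' The central data container: an ordered set of terminal taxa scored for an
#' ordered set of unordered discrete characters. Each cell holds a non-empty
#' set of integer states (a polymorphic cell holds two or more), or is missing
#' (`"?"`), or inapplicable (`"-"`, e.g. an attachment character for a taxon
#' that lacks the muscle). States are the non-negative integers 0-9; by
#' convention state 0 is the ancestral (plesiomorphic) condition.
#'
#' @param cells character matrix of cell tokens with taxa as rownames.
#'   Tokens may use `"0/1"`, `"{01}"` or `"01"` for polymorphism; `"?"` for
#'   missing; `"-"` for inapplicable.
#' @param chars optional data frame of per-character metadata with columns
#'   `id` (integer character number), `label`, `kind` (`"major"` for muscle
#'   presence/absence, `"minor"` for attachment/belly/fusion detail),
#'   `region` (`"HN"`, `"FL"`, `"HL"` or `"trunk"`) and `nstates`. Missing
#'   columns are filled with placeholder defaults (`kind = "minor"`,
#'   `region = "FL"`, `nstates` from the observed states, at least 2).
#' @param validate if `TRUE`, stop when [validate_matrix()] reports
#'   violations.
#' @return an object of class `"char_matrix"`: a list with elements `taxa`
#'   (character vector), `chars` (metadata data frame) and `cells`
#'   (canonical-token character matrix, taxa x characters).
#' @seealso [validate_matrix()], [read_matrix()], [write_matrix()]
#' @export
#' @examples
#' m <- character_matrix(
#'   rbind(A = c("0", "0"), B = c("1", "0/1")),
#'   chars = data.frame(id = 1:2, label = c("x", "y"),
#'                      kind = "minor", region = "FL", nstates = 2)
#' )
#' m$cells
character_matrix <- function(cells, chars = NULL, validate = TRUE) {
  cells <- as.matrix(cells)
  if (is.null(rownames(cells))) {
    stop("`cells` must have taxon labels as rownames")
  }
  taxa <- rownames(cells)
  canon <- apply(cells, c(1, 2), function(x) parse_cell_token(as.character(x)))
  canon <- matrix(canon, nrow = nrow(cells), dimnames = dimnames(cells))
  nchar_ <- ncol(canon)

  if (is.null(chars)) chars <- data.frame(id = seq_len(nchar_))
  chars <- as.data.frame(chars)
  if (nrow(chars) != nchar_) {
    stop("`chars` has ", nrow(chars), " rows but the matrix has ",
         nchar_, " characters")
  }
  if (is.null(chars$id)) chars$id <- seq_len(nchar_)
  chars$id <- as.integer(chars$id)
  if (is.null(chars$label)) chars$label <- sprintf("character %d", chars$id)
  if (is.null(chars$kind)) chars$kind <- rep("minor", nrow(chars))
  if (is.null(chars$region)) chars$region <- rep("FL", nrow(chars))
  if (is.null(chars$nstates)) {
    obs <- apply(canon, 2, function(col) {
      st <- unlist(lapply(col[!is.na(col)], cell_states))
      if (length(st) == 0L) 1L else max(st) + 1L
    })
    chars$nstates <- pmax(as.integer(obs), 2L)
  }
  chars$nstates <- as.integer(chars$nstates)
  rownames(chars) <- NULL
  colnames(canon) <- as.character(chars$id)

  m <- structure(list(taxa = taxa, chars = chars, cells = canon),
                 class = "char_matrix")
  if (validate) {
    v <- validate_matrix(m)
    if (nrow(v) > 0L) {
      stop("invalid character matrix:\n",
           paste(utils::head(v$message, 5L), collapse = "\n"))
    }
  }
  m
}

#' Check the structural invariants of a character matrix
#'
#' Violations are returned, never thrown, so a partially broken matrix can be
#' inspected. Checked: unique non-empty taxon labels, unique character ids,
#' well-formed cell tokens, cell states within each character's declared
#' state domain, and valid `kind`/`region` codes.
#'
#' @param m a `"char_matrix"` (or a bare list with the same fields, so that
#'   invalid objects can be audited).
#' @return data frame with columns `taxon`, `character` and `message`; zero
#'   rows when every invariant holds.
#' @export
validate_matrix <- function(m) {
  bad <- list()
  note <- function(taxon, character, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      taxon = taxon %||% NA_character_,
      character = character %||% NA_integer_,
      message = message, stringsAsFactors = FALSE)
  }

  taxa <- m$taxa
  if (any(!nzchar(taxa))) note(NA, NA, "empty taxon label")
  dup <- unique(taxa[duplicated(taxa)])
  for (d in dup) note(d, NA, paste0("duplicated taxon label '", d, "'"))

  chars <- m$chars
  dupid <- unique(chars$id[duplicated(chars$id)])
  for (d in dupid) note(NA, d, paste0("duplicated character id ", d))
  for (j in seq_len(nrow(chars))) {
    if (!chars$kind[j] %in% c("major", "minor")) {
      note(NA, chars$id[j], paste0("character ", chars$id[j],
                                   ": unknown kind '", chars$kind[j], "'"))
    }
    if (!chars$region[j] %in% c("HN", "FL", "HL", "trunk")) {
      note(NA, chars$id[j], paste0("character ", chars$id[j],
                                   ": unknown region '", chars$region[j], "'"))
    }
    if (chars$nstates[j] < 1L || chars$nstates[j] > 10L) {
      note(NA, chars$id[j], paste0("character ", chars$id[j],
                                   ": nstates out of range 1-10"))
    }
  }

  cells <- m$cells
  for (i in seq_along(taxa)) {
    for (j in seq_len(ncol(cells))) {
      tok <- cells[i, j]
      if (is.na(tok)) {
        note(taxa[i], chars$id[j],
             paste0("taxon '", taxa[i], "', character ", chars$id[j],
                    ": unparseable cell token"))
        next
      }
      st <- cell_states(tok)
      if (!is.null(st) && any(st >= chars$nstates[j])) {
        note(taxa[i], chars$id[j],
             paste0("taxon '", taxa[i], "', character ", chars$id[j],
                    ": state ", max(st), " outside declared domain 0-",
                    chars$nstates[j] - 1L))
      }
    }
  }

  if (length(bad) == 0L) {
    data.frame(taxon = character(), character = integer(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, bad)
  }
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", length(x$taxa), "taxa x",
      nrow(x$chars), "characters\n")
  cat("  taxa:", paste(utils::head(x$taxa, 8L), collapse = ", "),
      if (length(x$taxa) > 8L) "..." else "", "\n")
  kinds <- table(x$chars$kind)
  cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "), "\n")
  regions <- table(x$chars$region)
  cat("  regions:", paste(names(regions), regions, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# column index of a character id (or positional index already)
char_index <- function(m, char) {
  j <- match(char, m$chars$id)
  if (is.na(j)) stop("character id ", char, " not in matrix")
  j
}

# bitmask matrix: n_char x n_taxa, wildcard for missing/inapplicable
cell_masks <- function(m) {
  n_char <- nrow(m$chars)
  n_taxa <- length(m$taxa)
  M <- matrix(0L, n_char, n_taxa)
  for (j in seq_len(n_char)) {
    ns <- m$chars$nstates[j]
    for (i in seq_len(n_taxa)) {
      M[j, i] <- token_mask(m$cells[i, j], ns)
    }
  }
  colnames(M) <- m$taxa
  rownames(M) <- as.character(m$chars$id)
  M
}

# list of integer state vectors per taxon for one character; NULL entries
# (missing/inapplicable) are expanded to the full domain
char_state_sets <- function(m, char) {
  j <- char_index(m, char)
  ns <- m$chars$nstates[j]
  sets <- lapply(m$cells[, j], function(tok) {
    st <- cell_states(tok)
    if (is.null(st)) 0:(ns - 1L) else st
  })
  names(sets) <- m$taxa
  sets
}

#' Subset a character matrix
#'
#' @param m a `"char_matrix"`.
#' @param taxa,chars taxa labels and character ids to keep (default all).
#' @return a `"char_matrix"`.
#' @export
subset_matrix <- function(m, taxa = NULL, chars = NULL) {
  ti <- if (is.null(taxa)) seq_along(m$taxa) else match(taxa, m$taxa)
  if (anyNA(ti)) stop("unknown taxa: ",
                      paste(taxa[is.na(ti)], collapse = ", "))
  ci <- if (is.null(chars)) seq_len(nrow(m$chars)) else
    vapply(chars, function(ch) char_index(m, ch), integer(1))
  character_matrix(m$cells[ti, ci, drop = FALSE],
                   chars = m$chars[ci, , drop = FALSE])
}
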