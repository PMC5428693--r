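#' Round half away from zero
#'
#' Integer rounding used for printed percentages (consistency and retention
#' indices). Unlike [base::round()], which rounds half to even, values ending
#' in .5 move away from zero, matching the convention of classic parsimony
#' software reports.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# token constants for cells that carry no states
MISSING_TOKEN <- "?"
INAPPLICABLE_TOKEN <- "-"

#' Parse a cell token into a canonical form
#'
#' Accepts "0", "01", "0/1", "{01}" and "(01)" spellings of state sets plus
#' "?" (missing) and "-" (inapplicable). Canonical form is the sorted unique
#' digit string, or the missing/inapplicable token.
#'
#' @param x character vector of raw tokens.
#' @return character vector of canonical tokens; NA where unparseable.
#' @keywords internal
parse_cell_token <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    tok <- trimws(x[[i]])
    if (tok == MISSING_TOKEN) {
      out[i] <- MISSING_TOKEN
    } else if (tok == INAPPLICABLE_TOKEN) {
      out[i] <- INAPPLICABLE_TOKEN
    } else {
      digits <- regmatches(tok, gregexpr("[0-9]", tok))[[1]]
      clean <- gsub("[{}()/, ]", "", tok)
      if (length(digits) == 0L || nchar(clean) != length(digits)) {
        out[i] <- NA_character_
      } else {
        out[i] <- paste(sort(unique(digits)), collapse = "")
      }
    }
  }
  out
}

#' States carried by a canonical cell token
#'
#' @param token a single canonical token.
#' @return integer vector of states; `NULL` for missing/inapplicable cells.
#' @keywords internal
cell_states <- function(token) {
  if (token %in% c(MISSING_TOKEN, INAPPLICABLE_TOKEN)) return(NULL)
  as.integer(strsplit(token, "")[[1]])
}

is_missing_token <- function(token) token == MISSING_TOKEN
is_inapplicable_token <- function(token) token == INAPPLICABLE_TOKEN

# bitmask of a state set over a domain of `nstates` states (states 0-based);
# missing and inapplicable cells are full-domain wildcards so they can never
# force a step
token_mask <- function(token, nstates) {
  full <- bitwShiftL(1L, nstates) - 1L
  st <- cell_states(token)
  if (is.null(st)) return(full)
  mask <- 0L
  for (s in st) mask <- bitwOr(mask, bitwShiftL(1L, s))
  mask
}

mask_popcount <- function(mask) {
  n <- integer(length(mask))
  m <- mask
  while (any(m > 0L)) {
    n <- n + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  n
}

# states (0-based) present in a bitmask
mask_states <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) > 0L) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
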