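#' Specimen-level observation tables
#'
#' Observations are plain data frames with one row per specimen x character
#' (x side when sides were recorded separately): columns `taxon`,
#' `specimen`, `char` (character id), `state` (integer observed condition)
#' and optionally `side` (`"L"`/`"R"`, `NA` when the record is not
#' side-specific). [read_observations()] ingests the CSV form.
#'
#' @param file path to a CSV file with the columns above.
#' @return data frame of observations.
#' @export
read_observations <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("taxon", "specimen", "char", "state")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("observation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$side)) df$side <- NA_character_
  df$char <- as.integer(df$char)
  df$state <- as.integer(df$state)
  df
}

#' Pool own dissections with literature records
#'
#' Specimens are pooled by union. The same specimen reported in both sources
#' with identical records is deduplicated; the same specimen with conflicting
#' records is an error (never silently merged), listing both values.
#'
#' @param own,literature observation data frames (see [read_observations()]).
#' @return pooled observation data frame.
#' @export
merge_specimen_sources <- function(own, literature) {
  if (is.null(literature) || nrow(literature) == 0L) return(own)
  if (is.null(own) || nrow(own) == 0L) return(literature)
  if (is.null(own$side)) own$side <- NA_character_
  if (is.null(literature$side)) literature$side <- NA_character_
  cols <- c("taxon", "specimen", "char", "side", "state")
  pooled <- rbind(own[cols], literature[cols])
  key <- paste(pooled$taxon, pooled$specimen, pooled$char, pooled$side,
               sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    states <- unique(pooled$state[key == k])
    if (length(states) > 1L) {
      parts <- strsplit(k, "\r")[[1]]
      stop("conflicting records for specimen '", parts[2], "' (taxon '",
           parts[1], "', character ", parts[3], "): states ",
           paste(states, collapse = " vs "))
    }
  }
  pooled[!duplicated(key), , drop = FALSE]
}

#' Majority-rule coding of one character for one taxon
#'
#' Implements the coding rule used for muscle characters: a condition is
#' coded for the taxon when it is found in at least 50 percent of the
#' examined units. For binary presence/absence characters the rule is applied
#' to the presence state, so presence in exactly half of the specimens codes
#' as present (the threshold is inclusive). For multistate characters the
#' modal state wins and ties are coded as a polymorphic state set, which the
#' parsimony machinery handles natively.
#'
#' Counting units: with `unit = "specimen"` each specimen contributes total
#' weight 1; a specimen scored differently on its two sides (e.g. a muscle
#' present on one side only) splits its weight 0.5/0.5 between the two
#' conditions. With `unit = "side"` every side-specific record counts as one
#' unit, matching sample sizes quoted as "cases" rather than specimens.
#'
#' @param observations observation data frame for a single taxon (see
#'   [read_observations()]).
#' @param character one row of character metadata (a list or one-row data
#'   frame with at least `id`; `nstates` and `kind` refine the rule).
#' @param unit `"specimen"` (default) or `"side"`.
#' @param presence_state for binary presence/absence characters, the state
#'   meaning "present" (default 1). Set to `NULL` to force plain modal
#'   coding.
#' @return canonical cell token (e.g. `"1"`, `"01"`, or `"?"` with a warning
#'   when the character was never observed).
#' @export
#' @examples
#' obs <- data.frame(taxon = "P_paniscus",
#'                   specimen = paste0("s", 1:11),
#'                   char = 118, state = c(rep(1, 6), rep(0, 5)))
#' code_majority(obs, list(id = 118, nstates = 2))  # "1": 6/11 >= 50%
code_majority <- function(observations, character,
                          unit = c("specimen", "side"),
                          presence_state = 1L) {
  unit <- match.arg(unit)
  id <- as.integer(character$id)
  nstates <- as.integer(character$nstates %||% 2L)
  obs <- observations[observations$char == id & !is.na(observations$state), ,
                      drop = FALSE]
  if (nrow(obs) == 0L) {
    warning("no observations for character ", id, "; coded as missing")
    return(MISSING_TOKEN)
  }
  if (length(unique(obs$taxon)) > 1L) {
    stop("code_majority expects observations for a single taxon, got: ",
         paste(unique(obs$taxon), collapse = ", "))
  }

  if (unit == "side") {
    w <- stats::aggregate(list(weight = rep(1, nrow(obs))),
                          by = list(state = obs$state), FUN = sum)
  } else {
    # each specimen contributes weight 1, split equally across the distinct
    # states it shows (0.5/0.5 for a bilaterally asymmetric specimen)
    parts <- split(obs$state, obs$specimen)
    w <- list()
    for (st in parts) {
      tab <- table(st)
      share <- rep(1 / length(tab), length(tab))
      w[[length(w) + 1L]] <- data.frame(state = as.integer(names(tab)),
                                        weight = share)
    }
    w <- do.call(rbind, w)
    w <- stats::aggregate(weight ~ state, data = w, FUN = sum)
  }
  total <- sum(w$weight)

  binary <- nstates == 2L && !is.null(presence_state)
  if (binary) {
    present <- sum(w$weight[w$state == presence_state])
    if (present / total >= 0.5) {
      return(as.character(presence_state))
    }
    return(as.character(1L - as.integer(presence_state)))
  }

  top <- w$state[w$weight == max(w$weight)]
  paste(sort(unique(top)), collapse = "")
}

#' Code a full observation table into a character matrix
#'
#' Applies [code_majority()] per taxon and character.
#'
#' @param observations observation data frame covering one or more taxa.
#' @param chars character metadata data frame (see [character_matrix()]).
#' @param unit,presence_state passed to [code_majority()].
#' @return a `"char_matrix"` over the taxa present in `observations`.
#' @export
code_observations <- function(observations, chars,
                              unit = c("specimen", "side"),
                              presence_state = 1L) {
  unit <- match.arg(unit)
  taxa <- unique(observations$taxon)
  cells <- matrix(MISSING_TOKEN, length(taxa), nrow(chars),
                  dimnames = list(taxa, as.character(chars$id)))
  for (i in seq_along(taxa)) {
    sub <- observations[observations$taxon == taxa[i], , drop = FALSE]
    for (j in seq_len(nrow(chars))) {
      if (any(sub$char == chars$id[j] & !is.na(sub$state))) {
        cells[i, j] <- code_majority(sub, chars[j, ], unit = unit,
                                     presence_state = presence_state)
      } else {
        cells[i, j] <- MISSING_TOKEN
      }
    }
  }
  character_matrix(cells, chars = chars)
}
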