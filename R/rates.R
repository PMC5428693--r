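#' Pairwise character-state differences between two taxa
#'
#' A character counts as a difference only when the two taxa's coded state
#' sets are disjoint: a polymorphic taxon that overlaps the other taxon's
#' state is not a consistent difference, and missing or inapplicable cells
#' (full-domain wildcards) never count. This matches the notion of a
#' consistent between-species difference rather than within-species
#' variation.
#'
#' @param m a `"char_matrix"`.
#' @param taxon_a,taxon_b terminal labels.
#' @param major_only restrict to `kind == "major"` characters (muscle
#'   presence/absence).
#' @param regions optional character vector of body regions (`"HN"`, `"FL"`,
#'   `"HL"`, `"trunk"`) to restrict to.
#' @return list with `count` and `characters` (data frame: id, label, kind,
#'   region, and the two taxa's cell tokens).
#' @export
#' @examples
#' fx <- build_paper_fixtures()
#' pairwise_differences(fx$matrix, "P_troglodytes", "P_paniscus")$count  # 7
pairwise_differences <- function(m, taxon_a, taxon_b, major_only = FALSE,
                                 regions = NULL) {
  ia <- match(taxon_a, m$taxa)
  ib <- match(taxon_b, m$taxa)
  if (is.na(ia)) stop("unknown taxon '", taxon_a, "'")
  if (is.na(ib)) stop("unknown taxon '", taxon_b, "'")
  keep <- rep(TRUE, nrow(m$chars))
  if (major_only) keep <- keep & m$chars$kind == "major"
  if (!is.null(regions)) keep <- keep & m$chars$region %in% regions

  differs <- logical(nrow(m$chars))
  for (j in which(keep)) {
    sa <- cell_states(m$cells[ia, j])
    sb <- cell_states(m$cells[ib, j])
    if (is.null(sa) || is.null(sb)) next  # wildcard overlaps everything
    differs[j] <- length(intersect(sa, sb)) == 0L
  }
  idx <- which(differs)
  chars <- m$chars[idx, c("id", "label", "kind", "region"), drop = FALSE]
  chars$state_a <- m$cells[ia, idx]
  chars$state_b <- m$cells[ib, idx]
  rownames(chars) <- NULL
  list(count = length(idx), characters = chars)
}

#' Divergence rate in changes per million years
#'
#' @param n_changes number of character changes.
#' @param span_ma time span in Ma; must be positive.
#' @return the full-precision rate `n_changes / span_ma`.
#' @seealso [format_rate()] for the display convention.
#' @export
#' @examples
#' divergence_rate(28, 8)   # 3.5
#' divergence_rate(2, 7.1)  # 0.2816901...
divergence_rate <- function(n_changes, span_ma) {
  if (any(span_ma <= 0)) stop("span_ma must be positive")
  n_changes / span_ma
}

#' Display rounding for divergence rates
#'
#' Rates of one change per Ma or more print with one decimal, slower rates
#' with two (so 28/8 prints as "3.5" and 2/7.1 as "0.28").
#'
#' @param rate numeric rates.
#' @return character vector.
#' @export
format_rate <- function(rate) {
  vapply(rate, function(r) {
    if (is.na(r)) return(NA_character_)
    if (abs(r) >= 1) sprintf("%.1f", r) else sprintf("%.2f", r)
  }, character(1))
}

#' Calibrated per-branch rate table
#'
#' One row per branch of a dated tree, with the change count, the branch's
#' time span (parent age minus child age) and the implied rate. Optionally,
#' whole-lineage rows (`scope = "lineage"`) sum changes and spans along the
#' path from the root to a named tip, e.g. the full human lineage since the
#' chimpanzee-human split. Zero-span branches are permitted only when they
#' carry no changes; rate rows always satisfy `rate * span == n_changes` at
#' full precision.
#'
#' @param tree a dated `"phylo"` (see [set_node_ages()]); every branch must
#'   have both endpoint ages.
#' @param changes a change table from [map_branch_changes()], or a data frame
#'   with `branch` and `n_changes` columns.
#' @param lineages optional tip labels for root-to-tip lineage rows.
#' @return data frame of class `"rate_table"`: `scope`, `branch`,
#'   `n_changes`, `span_ma`, `rate`, `rate_display`.
#' @export
branch_rate_table <- function(tree, changes, lineages = character(0)) {
  spans <- branch_spans(tree)
  counts <- if (!is.null(changes$n_changes)) {
    changes[, c("branch", "n_changes")]
  } else {
    agg <- table(changes$branch)
    data.frame(branch = names(agg), n_changes = as.integer(agg),
               stringsAsFactors = FALSE)
  }
  n <- counts$n_changes[match(spans$branch_label, counts$branch)]
  n[is.na(n)] <- counts$n_changes[match(spans$branch[is.na(n)],
                                        counts$branch)]
  n[is.na(n)] <- 0L

  rows <- data.frame(scope = "branch",
                     branch = spans$branch_label,
                     n_changes = n,
                     span_ma = spans$span_ma,
                     stringsAsFactors = FALSE)

  if (length(lineages) > 0L) {
    ages <- node_ages(tree)
    kids <- tree_children(tree)
    root <- tree_root(tree)
    parent_of <- integer(max(tree$edge))
    for (k in seq_len(nrow(tree$edge))) {
      parent_of[tree$edge[k, 2]] <- tree$edge[k, 1]
    }
    clade <- node_clades(tree)
    n_tip <- length(tree$tip.label)
    for (tip in lineages) {
      v <- match(tip, tree$tip.label)
      if (is.na(v)) stop("unknown lineage tip '", tip, "'")
      total <- 0L
      span <- ages[root] - ages[v]
      while (v != root) {
        lab <- if (v <= n_tip) tree$tip.label[v] else
          paste(clade[[v]], collapse = "+")
        hit <- match(lab, rows$branch[rows$scope == "branch"])
        total <- total + rows$n_changes[rows$scope == "branch"][hit]
        v <- parent_of[v]
      }
      rows <- rbind(rows, data.frame(scope = "lineage", branch = tip,
                                     n_changes = total, span_ma = span,
                                     stringsAsFactors = FALSE))
    }
  }

  zero_span <- rows$span_ma == 0
  if (any(zero_span & rows$n_changes > 0)) {
    stop("branch '", rows$branch[zero_span & rows$n_changes > 0][1],
         "' has changes but zero time span")
  }
  rows$rate <- ifelse(zero_span, 0, rows$n_changes / rows$span_ma)
  rows$rate_display <- format_rate(rows$rate)
  class(rows) <- c("rate_table", "data.frame")
  rows
}

#' Node-age calibration presets for the hominoid working topology
#'
#' Two published dating schemes for the splits that matter to the rate
#' arithmetic: the default sets the chimpanzee-human split at 8 Ma and the
#' common chimpanzee-bonobo split at 2 Ma (recent genomic estimates); the
#' alternative scheme sets them at 7.5 and 3 Ma. Deeper nodes carry
#' conventional hominoid ages and only affect display, not the quoted rates.
#'
#' @param preset `"splits_8_2"` (default) or `"splits_7.5_3"`.
#' @return calibration data frame for [set_node_ages()].
#' @export
calibration_preset <- function(preset = c("splits_8_2", "splits_7.5_3")) {
  preset <- match.arg(preset)
  panhomo <- if (preset == "splits_8_2") 8 else 7.5
  pan <- if (preset == "splits_8_2") 2 else 3
  data.frame(
    clade = c("root",
              "Hylobatids+Homo",
              "Pongo+Homo",
              "Gorilla+Homo",
              "P_troglodytes+Homo",
              "P_troglodytes+P_paniscus"),
    age_ma = c(25, 20, 16, 9, panhomo, pan),
    stringsAsFactors = FALSE)
}
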