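# Evidence-weighted activation scoring: literature-evidence records ->
# weighted activator-target edges -> cumulative activator scores.
#
# Weights follow a fixed rubric: genetically demonstrated activation in the
# early embryo scores 10; biochemical/promoter studies in early embryos and
# genetic studies at other stages score 5; unconfirmed genetic screens 5;
# in vitro biochemical assays 2; bioinformatic evidence 1.

EVIDENCE_WEIGHTS <- c(
  genetic_early_embryo = 10L,
  biochemical_promoter_early = 5L,
  genetic_other_stage = 5L,
  genetic_screen_unconfirmed = 5L,
  in_vitro_biochemical = 2L,
  bioinformatic = 1L
)

#' Activation-score weight of an evidence category
#'
#' @param category one of `genetic_early_embryo` (10),
#'   `biochemical_promoter_early` (5), `genetic_other_stage` (5),
#'   `genetic_screen_unconfirmed` (5), `in_vitro_biochemical` (2),
#'   `bioinformatic` (1). Vectorised.
#' @return integer weight(s).
#' @export
score_category <- function(category) {
  w <- EVIDENCE_WEIGHTS[category]
  if (anyNA(w))
    stop("unknown evidence category: ",
         paste(unique(category[is.na(w)]), collapse = ", "),
         "; valid categories are ",
         paste(names(EVIDENCE_WEIGHTS), collapse = ", "), call. = FALSE)
  unname(w)
}

#' Read an evidence table
#'
#' TSV with header columns `activator`, `target`, `category`, `source`;
#' extra columns are ignored with a warning. Lines starting with `#` are
#' comments.
#'
#' @param path path to the TSV file.
#' @return data frame of evidence records.
#' @export
read_evidence <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("activator", "target", "category")
  if (!all(need %in% names(d)))
    stop("evidence table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(d), c(need, "source"))
  if (length(extra))
    warning("ignoring extra evidence column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  if (!"source" %in% names(d)) d$source <- NA_character_
  validate_evidence(d[, c("activator", "target", "category", "source")])
}

validate_evidence <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("no evidence records", call. = FALSE)
  if (any(!nzchar(records$activator)) || any(!nzchar(records$target)))
    stop("activator and target must be non-empty", call. = FALSE)
  score_category(records$category)  # errors on unknown categories
  records
}

#' Build an activation map from evidence records
#'
#' Each (activator, target) pair receives one edge weight: by default the
#' maximum category weight over that pair's records, so that several
#' corroborating citations of the same interaction are not double-counted
#' (`combine = "sum"` adds them instead). Cumulative activator scores are
#' the sum of edge weights over targets, and the ranking is by descending
#' cumulative score with lexicographic tie-break.
#'
#' @param records data frame with columns `activator`, `target`,
#'   `category` (and optionally `source`), e.g. from [read_evidence()].
#' @param combine `"max"` (default) or `"sum"` across records of one pair.
#' @return object of class `activation_map`: list with `edges` (data frame
#'   activator/target/weight), `cumulative` (named integer vector, ranking
#'   order), and `ranking` (activator names in rank order).
#' @export
build_activation_map <- function(records, combine = c("max", "sum")) {
  combine <- match.arg(combine)
  records <- validate_evidence(records)
  records$weight <- score_category(records$category)
  key <- paste(records$activator, records$target, sep = "\r")
  agg <- tapply(records$weight, key, if (combine == "max") max else sum)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(
    activator = vapply(parts, `[`, character(1), 1),
    target = vapply(parts, `[`, character(1), 2),
    weight = as.integer(agg), stringsAsFactors = FALSE)
  edges <- edges[order(edges$activator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  cumulative <- tapply(edges$weight, edges$activator, sum)
  cumulative <- as.integer(cumulative)
  names(cumulative) <- sort(unique(edges$activator))
  ord <- order(-cumulative, names(cumulative))
  cumulative <- cumulative[ord]
  structure(list(edges = edges, cumulative = cumulative,
                 ranking = names(cumulative), combine = combine),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat("Activation map:", length(x$ranking), "activators,",
      nrow(x$edges), "edges (", x$combine, "rule )\n")
  top <- utils::head(x$cumulative, 8)
  cat("  top scores:",
      paste(sprintf("%s=%d", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.activation_map <- function(object, ...) {
  data.frame(activator = names(object$cumulative),
             score = unname(object$cumulative),
             n_targets = as.integer(table(object$edges$activator)[
               names(object$cumulative)]),
             rank = seq_along(object$cumulative),
             stringsAsFactors = FALSE)
}

#' Serialize an activation map
#'
#' `tsv` emits the edge list with weights; `json` emits edges plus
#' cumulative scores; `dot` emits a Graphviz digraph in which the penwidth
#' of each edge grows with its weight (as in an activation-map figure where
#' line thickness encodes activation strength). Output is deterministic.
#'
#' @param map an `activation_map`.
#' @param format `"tsv"`, `"json"` or `"dot"`.
#' @return a single string of serialized text.
#' @export
export_map <- function(map, format = c("tsv", "json", "dot")) {
  stopifnot(inherits(map, "activation_map"))
  format <- match.arg(format)
  e <- map$edges
  if (format == "tsv") {
    body <- paste(e$activator, e$target, e$weight, sep = "\t")
    return(paste(c("activator\ttarget\tweight", body, ""), collapse = "\n"))
  }
  if (format == "json") {
    return(jsonlite::toJSON(
      list(edges = e, cumulative = as.list(map$cumulative),
           ranking = map$ranking),
      auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  width <- 0.5 + 0.35 * e$weight  # monotone in weight
  lines <- sprintf("  \"%s\" -> \"%s\" [penwidth=%.2f, label=%d];",
                   e$activator, e$target, width, e$weight)
  paste(c("digraph activation_map {", "  rankdir=TB;", lines, "}", ""),
        collapse = "\n")
}
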