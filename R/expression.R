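# Expression stage: fold changes mutant vs wild type, threshold regulation
# calls, gene-category composition of regulated sets, and set overlap.
#
# Expression tables are data frames with a gene_id column plus replicate
# columns named wt_rep* and mut_rep* (non-negative intensities).

expression_columns <- function(table) {
  wt <- grep("^wt_rep", names(table), value = TRUE)
  mut <- grep("^mut_rep", names(table), value = TRUE)
  if (!"gene_id" %in% names(table))
    stop("expression table needs a gene_id column", call. = FALSE)
  if (length(wt) < 1 || length(mut) < 1)
    stop("expression table needs >= 1 wt_rep* and >= 1 mut_rep* column",
         call. = FALSE)
  if (anyDuplicated(table$gene_id))
    stop("duplicate gene_id rows in expression table", call. = FALSE)
  vals <- as.matrix(table[, c(wt, mut)])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  list(wt = wt, mut = mut)
}

#' Read an expression table
#'
#' TSV with first column `gene_id` and replicate columns named `wt_rep*`
#' and `mut_rep*`.
#'
#' @param path path to the TSV file.
#' @return validated expression data frame.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  expression_columns(d)
  d
}

#' Read a gene-category table
#'
#' Two-column TSV (`gene_id`, `category`) mapping genes to `zygotic`,
#' `maternal`, `maternal_zygotic`, `housekeeping`, or `other`.
#'
#' @param path path to the TSV file.
#' @return named character vector gene_id -> category.
#' @export
read_categories <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 2) stop("category table needs two columns", call. = FALSE)
  stats::setNames(as.character(d[[2]]), d[[1]])
}

GENE_CATEGORIES <- c("zygotic", "maternal", "maternal_zygotic",
                     "housekeeping", "other")

#' Fold changes, mutant over wild type
#'
#' `fold_change = (mean(mut) + pseudocount) / (mean(wt) + pseudocount)`
#' per gene, so values below 1 indicate down-regulation in the mutant.
#'
#' @param table expression data frame (see [read_expression()]).
#' @param pseudocount added to both means before the ratio (default 1 on
#'   the raw intensity scale); must be positive if any mean is zero.
#' @return named numeric vector of fold changes.
#' @export
fold_changes <- function(table, pseudocount = 1) {
  cols <- expression_columns(table)
  wt_mean <- rowMeans(table[, cols$wt, drop = FALSE])
  mut_mean <- rowMeans(table[, cols$mut, drop = FALSE])
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(wt_mean == 0))
    stop("zero wild-type mean with pseudocount 0 (gene ",
         table$gene_id[which(wt_mean == 0)[1]], ")", call. = FALSE)
  stats::setNames((mut_mean + pseudocount) / (wt_mean + pseudocount),
                  table$gene_id)
}

#' Call regulation at a symmetric fold-change threshold
#'
#' A gene is `down` if its mutant/wild-type ratio is at most `1 / theta`
#' and `up` if at least `theta`; otherwise `unchanged`. The default
#' threshold 1.5 calls genes changed by at least 1.5-fold in either
#' direction.
#'
#' @param fc named fold-change vector from [fold_changes()].
#' @param theta fold-change threshold, > 1 (default 1.5).
#' @return object of class `regulation_calls`: data frame with `gene_id`,
#'   `fold_change`, `direction`; counts in attribute `"counts"`.
#' @export
call_regulation <- function(fc, theta = 1.5) {
  if (theta <= 1) stop("theta must be > 1", call. = FALSE)
  direction <- ifelse(fc <= 1 / theta, "down",
                      ifelse(fc >= theta, "up", "unchanged"))
  out <- data.frame(gene_id = names(fc), fold_change = unname(fc),
                    direction = unname(direction),
                    stringsAsFactors = FALSE)
  counts <- c(down = sum(direction == "down"),
              up = sum(direction == "up"),
              unchanged = sum(direction == "unchanged"))
  structure(out, counts = counts, theta = theta,
            class = c("regulation_calls", "data.frame"))
}

#' @export
print.regulation_calls <- function(x, ...) {
  n <- attr(x, "counts")
  cat(sprintf(
    "Regulation calls at %.2g-fold: %d down, %d up, %d unchanged (of %d)\n",
    attr(x, "theta"), n[["down"]], n[["up"]], n[["unchanged"]], nrow(x)))
  invisible(x)
}

#' Regulated genes in one direction
#'
#' @param calls a `regulation_calls` object.
#' @param direction `"down"`, `"up"` or `"unchanged"`.
#' @return character vector of gene ids.
#' @export
regulated_genes <- function(calls, direction = c("down", "up", "unchanged")) {
  direction <- match.arg(direction)
  calls$gene_id[calls$direction == direction]
}

#' Gene-category composition of a regulated set
#'
#' Fraction of the genes called in `direction` falling into each gene
#' category (zygotic, maternal, maternal_zygotic, housekeeping, other);
#' genes without a category are counted as `other`. Fractions sum to 1.
#'
#' @param calls a `regulation_calls` object.
#' @param categories named vector gene_id -> category (see
#'   [read_categories()]); may be `NULL`, in which case everything is
#'   `other`.
#' @param direction which call class to profile (default `"down"`).
#' @return named numeric vector of fractions over the category vocabulary.
#' @export
category_composition <- function(calls, categories,
                                 direction = c("down", "up", "unchanged")) {
  direction <- match.arg(direction)
  genes <- regulated_genes(calls, direction)
  if (length(genes) == 0)
    stop("no genes called '", direction, "'", call. = FALSE)
  cat <- if (is.null(categories)) rep("other", length(genes))
         else unname(categories[genes])
  cat[is.na(cat) | !cat %in% GENE_CATEGORIES] <- "other"
  tab <- table(factor(cat, levels = GENE_CATEGORIES))
  stats::setNames(as.numeric(tab) / length(genes), GENE_CATEGORIES)
}

#' Overlap between two gene sets
#'
#' @param setA,setB character vectors of gene ids.
#' @return list with `intersection` (size), `size_a`, `size_b`,
#'   `jaccard`, and the shared ids in `genes`.
#' @export
set_overlap <- function(setA, setB) {
  a <- unique(setA); b <- unique(setB)
  shared <- intersect(a, b)
  uni <- union(a, b)
  list(intersection = length(shared), size_a = length(a),
       size_b = length(b),
       jaccard = if (length(uni) == 0) 0 else length(shared) / length(uni),
       genes = shared)
}
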