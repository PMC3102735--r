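# Sequence and annotation IO: FASTA in/out, GFF3/BED annotation readers,
# promoter-window extraction and base composition.
#
# Sequence sets are plain named character vectors (upper-case, IUPAC
# alphabet); annotations are data frames with columns gene_id, contig,
# strand, tss (0-based). All internal coordinates are 0-based half-open;
# the 1-based GFF3 convention is converted in the reader only.

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and line breaks removed. Characters outside the
#' IUPAC nucleotide alphabet raise an error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    withCallingHandlers(
      Biostrings::readDNAStringSet(path),
      warning = function(w) {
        if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
          stop("illegal characters outside the IUPAC alphabet in '",
               path, "'", call. = FALSE)
        invokeRestart("muffleWarning")
      }),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(set))
  # first whitespace-delimited token of the header is the id
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl(paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"), seqs)
  if (any(bad))
    stop("illegal non-IUPAC characters in FASTA record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  validate_sequences(seqs, where = path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  validate_sequences(seqs)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene annotations with transcription start sites
#'
#' Reads GFF3 or BED (detected from the extension, or forced via `format`)
#' and reduces each gene to a transcription start site. GFF3 coordinates
#' (1-based inclusive) and BED coordinates (0-based half-open) are both
#' converted to a 0-based TSS position: for a `+` strand feature the TSS is
#' the first base of the feature, for `-` strand the last. For GFF3 input
#' with several transcripts per gene the 5'-most transcript start is taken.
#'
#' @param path annotation file path.
#' @param format `"gff3"`, `"bed"`, or `"auto"`.
#' @return data frame with columns `gene_id`, `contig`, `strand`, `tss`
#'   (0-based integer).
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) stop("cannot read ", format, " '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) stop("no features in ", path, call. = FALSE)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("features without strand in ", path, call. = FALSE)
  if (format == "gff3") {
    type <- as.character(gr$type)
    keep <- if (any(type == "gene")) type == "gene"
            else type %in% c("mRNA", "transcript")
    gr <- gr[keep]; strand <- strand[keep]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids) || anyNA(ids))
      stop("GFF3 features lack ID attributes in ", path, call. = FALSE)
    # rtracklayer ranges are 1-based inclusive
    tss <- ifelse(strand == "+",
                  BiocGenerics::start(gr) - 1L,
                  BiocGenerics::end(gr) - 1L)
    ann <- data.frame(gene_id = as.character(ids),
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE)
    # several transcripts per gene: keep the 5'-most start per id
    if (anyDuplicated(ann$gene_id)) {
      ann <- do.call(rbind, lapply(split(ann, ann$gene_id), function(d) {
        d[if (d$strand[1] == "+") which.min(d$tss) else which.max(d$tss), ]
      }))
      rownames(ann) <- NULL
    }
  } else {
    ids <- gr$name
    if (is.null(ids)) stop("BED file lacks a name column: ", path,
                           call. = FALSE)
    tss <- ifelse(strand == "+",
                  BiocGenerics::start(gr) - 1L,
                  BiocGenerics::end(gr) - 1L)
    ann <- data.frame(gene_id = as.character(ids),
                      contig = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE)
  }
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann) {
  need <- c("gene_id", "contig", "strand", "tss")
  if (!all(need %in% names(ann)))
    stop("annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(ann$strand %in% c("+", "-")))
    stop("annotation strand must be '+' or '-'", call. = FALSE)
  if (any(ann$tss < 0)) stop("negative TSS position", call. = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotations", call. = FALSE)
  invisible(ann)
}

#' Extract promoter windows upstream of transcription start sites
#'
#' For a `+` strand gene the window is the half-open interval
#' `[tss - window_bp, tss)` on the forward strand; for a `-` strand gene it
#' is `[tss + 1, tss + 1 + window_bp)` reverse-complemented, so that in both
#' cases the returned sequence reads 5' to 3' towards the TSS. Windows that
#' run off a contig end are truncated, kept, and recorded in
#' `truncated_ids`.
#'
#' @param genome named character vector of contig sequences.
#' @param annotations data frame as returned by [read_annotations()].
#' @param window_bp window size in bp upstream of the TSS (default 4000).
#' @return object of class `promoter_set`: a list with `records` (named
#'   character vector of windows), `window_bp`, and `truncated_ids`.
#' @export
extract_promoters <- function(genome, annotations, window_bp = 4000) {
  validate_sequences(genome, where = "genome")
  validate_annotations(annotations)
  if (window_bp < 1) stop("window_bp must be >= 1", call. = FALSE)
  missing <- setdiff(annotations$contig, names(genome))
  if (length(missing))
    stop("contig(s) not in genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  clen <- nchar(genome)
  records <- character(nrow(annotations))
  truncated <- character(0)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    L <- clen[[a$contig]]
    if (a$tss >= L)
      stop("TSS of ", a$gene_id, " (", a$tss, ") outside contig ",
           a$contig, " (length ", L, ")", call. = FALSE)
    if (a$strand == "+") {
      from0 <- max(0L, a$tss - window_bp)   # 0-based half-open [from0, tss)
      to0 <- a$tss
      win <- substr(genome[[a$contig]], from0 + 1L, to0)
    } else {
      from0 <- a$tss + 1L                   # [tss+1, tss+1+window_bp)
      to0 <- min(L, a$tss + 1L + window_bp)
      win <- reverse_complement(substr(genome[[a$contig]], from0 + 1L, to0))
    }
    if (nchar(win) == 0)
      stop("empty promoter window for ", a$gene_id, call. = FALSE)
    if (nchar(win) < window_bp) truncated <- c(truncated, a$gene_id)
    records[i] <- win
  }
  names(records) <- annotations$gene_id
  structure(list(records = records, window_bp = as.integer(window_bp),
                 truncated_ids = truncated),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set:", length(x$records), "windows of",
      x$window_bp, "bp\n")
  if (length(x$truncated_ids))
    cat("  truncated at contig ends:",
        paste(x$truncated_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Base composition of a sequence set
#'
#' AT and GC fractions over all A/C/G/T bases; ambiguous bases (N etc.) are
#' excluded from the tally.
#'
#' @param seqs named character vector of sequences (or a `promoter_set`).
#' @return object of class `genome_composition`: list with `at_fraction`
#'   and `gc_fraction`.
#' @examples
#' base_composition(c(x = "ATGC"))  # at 0.5, gc 0.5
#' @export
base_composition <- function(seqs) {
  if (inherits(seqs, "promoter_set")) seqs <- seqs$records
  validate_sequences(seqs)
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, c("A", "C", "G", "T"), drop = FALSE])
  total <- sum(counts)
  if (total == 0)
    stop("degenerate input: no unambiguous A/C/G/T bases", call. = FALSE)
  at <- (counts[["A"]] + counts[["T"]]) / total
  structure(list(at_fraction = at, gc_fraction = 1 - at),
            class = "genome_composition")
}

#' @export
print.genome_composition <- function(x, ...) {
  cat(sprintf("Base composition: %.1f%% AT / %.1f%% GC\n",
              100 * x$at_fraction, 100 * x$gc_fraction))
  invisible(x)
}

#' Drosophila melanogaster genome composition
#'
#' The default composition constant used throughout: 57.4% AT and 42.6% GC,
#' the slightly AT-rich composition of the D. melanogaster genome.
#'
#' @return a `genome_composition` with `at_fraction = 0.574`.
#' @export
dmel_composition <- function() {
  structure(list(at_fraction = 0.574, gc_fraction = 0.426),
            class = "genome_composition")
}
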