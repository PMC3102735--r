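# Degenerate IUPAC consensus motifs, sequence scanning and binding-site
# cluster detection.

#' Parse a degenerate IUPAC consensus motif
#'
#' @param name motif name (e.g. `"STAT"`).
#' @param pattern IUPAC consensus string, e.g. `"TTCnnnGAA"` (STAT92E) or
#'   `"CAGGTAG"` (Zelda / TAGteam). Case-insensitive.
#' @return object of class `consensus_motif`: list with `name`, `pattern`
#'   (upper-cased), `length`, and `allowed`, a per-position list of allowed
#'   base sets.
#' @examples
#' parse_motif("STAT", "TTCnnnGAA")
#' @export
parse_motif <- function(name, pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || nchar(pattern) == 0)
    stop("pattern must be a non-empty string", call. = FALSE)
  pattern <- toupper(pattern)
  ch <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code '", ch[bad[1]], "' at position ", bad[1],
         " of motif '", name, "'", call. = FALSE)
  allowed <- IUPAC_TABLE[ch]
  names(allowed) <- NULL
  structure(list(name = name, pattern = pattern,
                 length = nchar(pattern), allowed = allowed),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  n_fixed <- sum(lengths(x$allowed) == 1)
  cat("Consensus motif ", x$name, ": ", x$pattern, " (", x$length,
      " bp, ", n_fixed, " fixed positions)\n", sep = "")
  invisible(x)
}

#' Reverse-complement a consensus motif
#'
#' @param motif a `consensus_motif`.
#' @return a `consensus_motif` matching the reverse complement.
#' @export
reverse_complement_motif <- function(motif) {
  stopifnot(inherits(motif, "consensus_motif"))
  parse_motif(motif$name, reverse_complement(motif$pattern))
}

# per-position membership lookup over codes A=1,C=2,G=3,T=4,ambiguous=5.
# A sequence N (or any ambiguity code) matches only a fully degenerate
# motif position.
motif_lookup <- function(motif) {
  lapply(motif$allowed, function(set) {
    acgt <- c("A", "C", "G", "T") %in% set
    c(acgt, length(set) == 4L)
  })
}

scan_codes <- function(codes, lookup, L) {
  n <- length(codes)
  if (n < L) return(integer(0))
  ok <- lookup[[1]][codes[seq_len(n - L + 1L)]]
  if (L > 1) for (j in 2:L) {
    ok <- ok & lookup[[j]][codes[j:(n - L + j)]]
  }
  which(ok) - 1L  # 0-based starts
}

#' Scan one sequence for motif hits
#'
#' Reports every start position where each sequence base is a member of the
#' motif's allowed set at that position. Overlapping hits are all reported.
#' An ambiguous sequence base (N) matches only a fully degenerate motif
#' position. In `"both"` mode the reverse complement of the motif is also
#' scanned against the forward sequence and reported with strand `"-"` (the
#' start is still the forward-strand offset of the matched window).
#'
#' @param seq single named sequence (length-1 named character vector), or an
#'   unnamed string plus `seq_id`.
#' @param motif a `consensus_motif`.
#' @param strands `"forward"` (default) or `"both"`.
#' @param seq_id id used in the output when `seq` is unnamed.
#' @return data frame of hits: `seq_id`, `start` (0-based), `strand`,
#'   `site` (matched substring, forward-strand orientation).
#' @export
scan_sequence <- function(seq, motif, strands = c("forward", "both"),
                          seq_id = NULL) {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "consensus_motif"))
  if (is.null(seq_id))
    seq_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  s <- toupper(unname(seq[1]))
  codes <- seq_to_codes(s)
  L <- motif$length
  starts <- scan_codes(codes, motif_lookup(motif), L)
  strand <- rep("+", length(starts))
  if (strands == "both") {
    rc <- reverse_complement_motif(motif)
    rstarts <- scan_codes(codes, motif_lookup(rc), L)
    starts <- c(starts, rstarts)
    strand <- c(strand, rep("-", length(rstarts)))
  }
  ord <- order(starts, strand)
  starts <- starts[ord]; strand <- strand[ord]
  site <- if (length(starts)) substring(s, starts + 1L, starts + L)
          else character(0)
  data.frame(seq_id = rep(seq_id, length(starts)),
             start = starts, strand = strand, site = site,
             stringsAsFactors = FALSE)
}

#' Scan a sequence set for motif hits
#'
#' @param seqs named character vector of sequences or a `promoter_set`.
#' @param motif a `consensus_motif`.
#' @param strands `"forward"` or `"both"`.
#' @return data frame of hits across all sequences (see [scan_sequence()]).
#' @export
scan_set <- function(seqs, motif, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (inherits(seqs, "promoter_set")) seqs <- seqs$records
  validate_sequences(seqs)
  out <- lapply(names(seqs), function(id)
    scan_sequence(seqs[[id]], motif, strands, seq_id = id))
  do.call(rbind, out)
}

#' Find clusters of binding sites
#'
#' A cluster is a maximal chain of hits on one sequence in which each pair
#' of consecutive start offsets differs by at most `max_gap` bp (single
#' linkage; reduces to the pairwise "two sites within 500 bp" rule for two
#' sites). Singletons are not clusters.
#'
#' @param hits data frame of hits for a single `seq_id` (as returned by
#'   [scan_sequence()]), or for several sequences if `group = TRUE`.
#' @param max_gap maximum gap between consecutive start offsets (default
#'   500).
#' @param group if `TRUE`, split `hits` by `seq_id` and cluster each group.
#' @return data frame with one row per cluster: `seq_id`, `count`, `span`
#'   (bp between first and last start), `first_start`, `last_start`, and
#'   `starts` (comma-separated offsets).
#' @export
find_clusters <- function(hits, max_gap = 500, group = FALSE) {
  stopifnot(is.data.frame(hits), all(c("seq_id", "start") %in% names(hits)))
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  empty <- data.frame(seq_id = character(0), count = integer(0),
                      span = integer(0), first_start = integer(0),
                      last_start = integer(0), starts = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  if (group) {
    parts <- lapply(split(hits, hits$seq_id), find_clusters,
                    max_gap = max_gap, group = FALSE)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  if (length(unique(hits$seq_id)) > 1)
    stop("hits span several seq_ids; use group = TRUE", call. = FALSE)
  starts <- sort(unique(hits$start))
  brk <- which(diff(starts) > max_gap)
  chain <- rep(seq_len(length(brk) + 1L),
               diff(c(0L, brk, length(starts))))
  rows <- lapply(split(starts, chain), function(st) {
    if (length(st) < 2) return(NULL)
    data.frame(seq_id = hits$seq_id[1], count = length(st),
               span = max(st) - min(st), first_start = min(st),
               last_start = max(st),
               starts = paste(st, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write motif hits as 6-column BED
#'
#' @param hits hit data frame from [scan_set()].
#' @param motif the motif scanned (its name and length fill the BED name
#'   and end columns).
#' @param path output path.
#' @param header_lines optional comment lines (each prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, motif, path, header_lines = character(0)) {
  n <- nrow(hits)
  bed <- data.frame(chrom = hits$seq_id, start = hits$start,
                    end = hits$start + motif$length,
                    name = rep(motif$name, n),
                    score = rep(0L, n), strand = hits$strand)
  write_bed_file(bed, path, header_lines)
}

#' Write site clusters as BED (count in the score column)
#'
#' @param clusters cluster data frame from [find_clusters()].
#' @param motif the motif scanned.
#' @param path output path.
#' @param header_lines optional comment lines.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, motif, path,
                               header_lines = character(0)) {
  n <- nrow(clusters)
  bed <- data.frame(chrom = clusters$seq_id, start = clusters$first_start,
                    end = clusters$last_start + motif$length,
                    name = rep(paste0(motif$name, "_cluster"), n),
                    score = clusters$count, strand = rep(".", n))
  write_bed_file(bed, path, header_lines)
}

write_bed_file <- function(bed, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  if (nrow(bed))
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
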