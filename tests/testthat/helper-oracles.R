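# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's vectorised code paths: the scanner
# oracle walks characters one by one, and the cluster oracle builds an
# all-pairs adjacency graph.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# position-by-position brute-force matcher; returns 0-based starts.
# An ambiguous sequence base matches only a fully degenerate motif position.
oracle_scan <- function(seq, pattern) {
  seq <- toupper(seq); pattern <- toupper(pattern)
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  L <- length(p); n <- length(s)
  hits <- integer(0)
  if (n < L) return(hits)
  for (i in 1:(n - L + 1)) {
    ok <- TRUE
    for (j in 1:L) {
      base <- s[i + j - 1]
      allowed <- iupac_sets[[p[j]]]
      match_j <- if (base %in% c("A", "C", "G", "T")) base %in% allowed
                 else length(allowed) == 4
      if (!match_j) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# cluster oracle: exhaustive pairwise adjacency (|si - sj| <= gap) and
# connected components by breadth-first search; components of size >= 2.
oracle_clusters <- function(starts, gap = 500) {
  starts <- sort(unique(starts))
  n <- length(starts)
  if (n == 0) return(list())
  adj <- abs(outer(starts, starts, "-")) <= gap
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    queue <- i; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    if (length(comp) >= 2) comps <- c(comps, list(sort(starts[comp])))
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# NOTE: for sorted 1-d points, pairwise single linkage equals
# consecutive-gap chaining, which is what makes this an independent route.

random_iupac_motif <- function(len, p_degenerate = 0.3) {
  codes <- names(iupac_sets)
  plain <- c("A", "C", "G", "T")
  ch <- vapply(seq_len(len), function(i) {
    if (runif(1) < p_degenerate) sample(codes, 1) else sample(plain, 1)
  }, character(1))
  paste(ch, collapse = "")
}

random_sequence <- function(len, alphabet = c("A", "C", "G", "T"),
                            p = NULL) {
  paste(sample(alphabet, len, replace = TRUE, prob = p), collapse = "")
}

# tiny two-contig genome fixture used by promoter-extraction tests
make_test_genome <- function(seed = 42, len = c(chr1 = 20000, chr2 = 10000)) {
  set.seed(seed)
  vapply(len, function(L) random_sequence(L), character(1))
}
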