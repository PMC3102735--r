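stat <- parse_motif("STAT", "TTCnnnGAA")
zld <- parse_motif("Zld", "CAGGTAG")

test_that("consensus parsing builds the right allowed sets", {
  expect_equal(stat$length, 9L)
  expect_equal(sum(lengths(stat$allowed) == 1), 6L)  # 6 fixed nucleotides
  expect_equal(sum(lengths(stat$allowed) == 4), 3L)  # nnn fully degenerate
  expect_equal(zld$length, 7L)
  expect_true(all(lengths(zld$allowed) == 1))
  expect_equal(parse_motif("deg", "RYN")$allowed,
               list(c("A", "G"), c("C", "T"), c("A", "C", "G", "T")))
  expect_error(parse_motif("bad", "TTX"), "'X' at position 3")
  expect_error(parse_motif("bad", ""), "non-empty")
})

test_that("scanning reports all (overlapping) matches at the right offsets", {
  expect_equal(scan_sequence(c(s = "TTCAAAGAA"), stat)$start, 0L)
  # overlapping windows both match
  hits <- scan_sequence(c(s = "TTCTTCGAAGAA"), stat)
  expect_equal(hits$start, c(0L, 3L))
  expect_equal(hits$site, c("TTCTTCGAA", "TTCGAAGAA"))
  expect_equal(nrow(scan_sequence(c(s = "ACGT"), stat)), 0L)
})

test_that("sequence N matches only fully degenerate motif positions", {
  expect_equal(scan_sequence(c(s = "TTCNNNGAA"), stat)$start, 0L)
  expect_equal(nrow(scan_sequence(c(s = "TTCAAANAA"), stat)), 0L)
  expect_equal(nrow(scan_sequence(c(s = "NAGGTAG"), zld)), 0L)
})

test_that("the STAT consensus is its own reverse complement, so both-strand scanning mirrors forward hits", {
  expect_equal(reverse_complement_motif(stat)$pattern, "TTCNNNGAA")
  set.seed(11)
  for (i in 1:10) {
    s <- c(x = random_sequence(500))
    fwd <- scan_sequence(s, stat, strands = "forward")
    both <- scan_sequence(s, stat, strands = "both")
    expect_equal(sort(both$start[both$strand == "-"]), sort(fwd$start))
  }
})

test_that("scanner agrees with a position-by-position brute-force oracle", {
  set.seed(101)
  for (i in 1:80) {
    len <- sample(20:400, 1)
    s <- random_sequence(len, alphabet = c("A", "C", "G", "T", "N"),
                         p = c(0.23, 0.23, 0.23, 0.23, 0.08))
    pat <- random_iupac_motif(sample(2:10, 1))
    got <- scan_sequence(c(x = s), parse_motif("m", pat))$start
    expect_identical(got, oracle_scan(s, pat),
                     info = paste(pat, "on", substr(s, 1, 40)))
  }
})

test_that("scanner agrees with Biostrings IUPAC matching on N-free sequences", {
  set.seed(202)
  for (i in 1:25) {
    s <- random_sequence(300)
    pat <- random_iupac_motif(sample(3:9, 1))
    got <- scan_sequence(c(x = s), parse_motif("m", pat))$start
    ref <- BiocGenerics::start(Biostrings::matchPattern(
      pat, Biostrings::DNAString(s), fixed = FALSE)) - 1L
    expect_identical(got, as.integer(ref))
  }
})

test_that("hit count is invariant under reverse-complementing sequence and motif", {
  set.seed(303)
  for (i in 1:20) {
    s <- random_sequence(300)
    pat <- random_iupac_motif(sample(3:9, 1))
    m <- parse_motif("m", pat)
    n_fwd <- nrow(scan_sequence(c(x = s), m))
    n_rc <- nrow(scan_sequence(c(x = reverse_complement(s)),
                               reverse_complement_motif(m)))
    expect_equal(n_rc, n_fwd)
  }
})

test_that("relaxing a motif position never decreases the hit count", {
  set.seed(404)
  relax <- c(A = "R", C = "Y", G = "R", T = "Y", R = "D", Y = "B",
             S = "V", W = "D", K = "B", M = "V", B = "N", D = "N",
             H = "N", V = "N", N = "N")
  for (i in 1:20) {
    s <- random_sequence(400)
    pat <- random_iupac_motif(6)
    ch <- strsplit(pat, "")[[1]]
    j <- sample(6, 1)
    ch2 <- ch; ch2[j] <- relax[[ch[j]]]
    n1 <- nrow(scan_sequence(c(x = s), parse_motif("m", pat)))
    n2 <- nrow(scan_sequence(c(x = s),
                             parse_motif("m", paste(ch2, collapse = ""))))
    expect_gte(n2, n1)
  }
})

test_that("cluster calling implements maximal chains with <= max_gap consecutive spacing", {
  mk <- function(starts) data.frame(seq_id = rep("s", length(starts)),
                                    start = starts,
                                    strand = rep("+", length(starts)),
                                    site = rep("X", length(starts)))
  one <- find_clusters(mk(c(100, 400)))
  expect_equal(one$count, 2L)
  expect_equal(one$span, 300L)
  expect_equal(nrow(find_clusters(mk(c(100, 700)))), 0L)  # gap 600 > 500
  chain <- find_clusters(mk(c(100, 550, 1000)))
  expect_equal(chain$count, 3L)  # chaining through the middle site
  expect_equal(chain$starts, "100,550,1000")
  expect_equal(nrow(find_clusters(mk(numeric(0)))), 0L)
  expect_error(find_clusters(data.frame(seq_id = c("a", "b"),
                                        start = c(1, 2))),
               "group")
})

test_that("cluster calling matches the exhaustive pairwise-linkage oracle", {
  set.seed(505)
  for (i in 1:60) {
    starts <- sort(sample(0:4000, sample(0:15, 1)))
    got <- find_clusters(data.frame(seq_id = rep("s", length(starts)),
                                    start = starts),
                         max_gap = 500)
    want <- oracle_clusters(starts, 500)
    expect_equal(nrow(got), length(want))
    if (nrow(got)) {
      expect_equal(strsplit(got$starts, ","),
                   lapply(want, as.character))
    }
  }
})

test_that("hits and clusters serialise to 6-column BED", {
  seqs <- c(a = "TTCAAAGAATTTTCGGGGAA")
  hits <- scan_set(seqs, stat)
  f <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, stat, f, header_lines = "seed=1")
  lines <- readLines(f)
  expect_match(lines[1], "^# seed=1")
  fields <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(fields) == 6))
  expect_equal(fields[[1]][1:3], c("a", "0", "9"))
})
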