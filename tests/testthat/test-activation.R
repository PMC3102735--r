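rec <- function(act, tgt, cat) data.frame(activator = act, target = tgt,
                                          category = cat,
                                          source = "src",
                                          stringsAsFactors = FALSE)

test_that("evidence categories carry the fixed weight rubric", {
  expect_equal(score_category("genetic_early_embryo"), 10L)
  expect_equal(score_category("biochemical_promoter_early"), 5L)
  expect_equal(score_category("genetic_other_stage"), 5L)
  expect_equal(score_category("genetic_screen_unconfirmed"), 5L)
  expect_equal(score_category("in_vitro_biochemical"), 2L)
  expect_equal(score_category("bioinformatic"), 1L)
  expect_error(score_category("hearsay"), "valid categories")
})

test_that("cumulative scores sum edge weights across targets", {
  records <- rbind(rec("zld", "g1", "genetic_early_embryo"),
                   rec("zld", "g2", "in_vitro_biochemical"))
  map <- build_activation_map(records)
  expect_equal(sort(map$edges$weight), c(2L, 10L))
  expect_equal(map$cumulative[["zld"]], 12L)
  expect_equal(map$ranking[1], "zld")
})

test_that("duplicate evidence for one pair takes the maximum weight by default, the sum on request", {
  records <- rbind(rec("a", "g1", "genetic_early_embryo"),
                   rec("a", "g1", "bioinformatic"))
  for (ord in list(1:2, 2:1)) {
    map <- build_activation_map(records[ord, ])
    expect_equal(nrow(map$edges), 1L)
    expect_equal(map$edges$weight, 10L)
    expect_equal(map$cumulative[["a"]], 10L)
  }
  expect_equal(build_activation_map(records,
                                    combine = "sum")$cumulative[["a"]], 11L)
})

test_that("ranking is by descending score with lexicographic tie-break", {
  records <- rbind(rec("beta", "g1", "genetic_other_stage"),
                   rec("alpha", "g2", "genetic_screen_unconfirmed"),
                   rec("gamma", "g3", "genetic_early_embryo"))
  map <- build_activation_map(records)
  expect_equal(map$ranking, c("gamma", "alpha", "beta"))  # 10, 5, 5
})

test_that("cumulative scores are order-invariant and monotone under added evidence", {
  g <- gen_evidence_table(n_records = 40, seed = 21)
  base <- build_activation_map(g$records)
  set.seed(3)
  perm <- build_activation_map(g$records[sample(nrow(g$records)), ])
  expect_identical(base$cumulative, perm$cumulative)
  # adding a record never decreases any score
  extra <- rbind(g$records, rec("act_1", "gene_99", "bioinformatic"))
  more <- build_activation_map(extra)
  common <- names(base$cumulative)
  expect_true(all(more$cumulative[common] >= base$cumulative[common]))
})

test_that("with single-record pairs the cumulative score is the plain weight sum", {
  records <- rbind(rec("a", "g1", "genetic_early_embryo"),
                   rec("a", "g2", "genetic_other_stage"),
                   rec("a", "g3", "bioinformatic"))
  map <- build_activation_map(records)
  expect_equal(map$cumulative[["a"]], 10L + 5L + 1L)
})

test_that("generated evidence tables come with correct analytic truth", {
  for (seed in c(1, 7, 99)) {
    g <- gen_evidence_table(seed = seed)
    map <- build_activation_map(g$records)
    truth <- g$truth[sort(names(g$truth))]
    got <- map$cumulative[sort(names(g$truth))]
    expect_identical(unname(got), unname(truth))
  }
  expect_identical(gen_evidence_table(seed = 5)$records,
                   gen_evidence_table(seed = 5)$records)
})

test_that("map serialization is deterministic and monotone in edge styling", {
  records <- rbind(rec("a", "g1", "genetic_early_embryo"),
                   rec("b", "g2", "bioinformatic"))
  map <- build_activation_map(records)
  tsv <- export_map(map, "tsv")
  expect_identical(tsv, export_map(map, "tsv"))
  expect_equal(length(strsplit(tsv, "\n")[[1]]), 3L)  # header + 2 edges
  dot <- export_map(map, "dot")
  w10 <- as.numeric(sub(".*penwidth=([0-9.]+).*", "\\1",
                        grep("g1", strsplit(dot, "\n")[[1]], value = TRUE)))
  w1 <- as.numeric(sub(".*penwidth=([0-9.]+).*", "\\1",
                       grep("g2", strsplit(dot, "\n")[[1]], value = TRUE)))
  expect_gt(w10, w1)
  expect_error(export_map(map, "xml"))
  json <- jsonlite::fromJSON(export_map(map, "json"))
  expect_equal(json$cumulative$a, 10L)
})

test_that("evidence TSV reading enforces the header and warns on extras", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("activator\ttarget\tcategory\tsource\tnote",
               "zld\tg1\tgenetic_early_embryo\tref1\tx"), f)
  expect_warning(records <- read_evidence(f), "note")
  expect_equal(build_activation_map(records)$cumulative[["zld"]], 10L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(read_evidence(bad), "needs columns")
})
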