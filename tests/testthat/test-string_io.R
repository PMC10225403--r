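test_that("well-formed links files parse with alias mapping applied", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score",
               "OS1 OS2 700", "OS2 OS3 450", "OS1 OS3 399"), f)
  el <- parse_string_links(f)
  expect_s3_class(el, "edge_list")
  expect_equal(nrow(el), 3L)
  expect_false(is_deduplicated(el))
  expect_equal(edge_provenance(el)$raw_records, 3L)

  mapped <- parse_string_links(f, alias_table = c(OS1 = "RHD3"))
  expect_equal(mapped$protein_a[1], "RHD3")
  expect_equal(mapped$protein_b[1], "OS2")
  expect_equal(mapped$combined_score[1], 700L)
  expect_equal(edge_provenance(mapped)$alias_unmapped_endpoints, 4L)
})

test_that("parser rejects malformed input with line numbers", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score", "A B 1500"), f)
  expect_error(parse_string_links(f), "outside \\[0, 1000\\].*line.*2")

  writeLines(c("protein1 protein2 combined_score", "A B 500", "A C x2"), f)
  expect_error(parse_string_links(f), "non-integer.*line.*3")

  writeLines(c("protein1 protein2 combined_score", "A B 500", "A 300"), f)
  expect_error(parse_string_links(f), "fewer than 3 fields.*3")

  writeLines("protein1 protein2 combined_score", f)
  expect_error(parse_string_links(f), "no records")

  expect_error(parse_string_links(tempfile()), "not found")
})

test_that("score filtering honors the strict/inclusive comparator and boundary", {
  el <- make_edge_list(c("A", "B", "C"), c("X", "Y", "Z"), c(399L, 400L, 401L))
  expect_equal(nrow(filter_by_score(el, 400)), 1L)
  expect_equal(nrow(filter_by_score(el, 400, strict = FALSE)), 2L)
  expect_error(filter_by_score(el, 1500), "\\[0, 1000\\]")
  prov <- edge_provenance(filter_by_score(el, 400))
  expect_equal(prov$score_filter$records_before, 3L)
  expect_equal(prov$score_filter$records_after, 1L)

  empty <- filter_by_score(el, 1000)
  expect_equal(nrow(filter_by_score(empty, 400)), 0L)
})

test_that("deduplication collapses unordered pairs, drops self-loops, keeps max score", {
  el <- make_edge_list(c("A", "B", "A"), c("B", "A", "C"),
                       c(500L, 500L, 450L))
  ded <- deduplicate(el)
  expect_true(is_deduplicated(ded))
  expect_equal(nrow(ded), 2L)
  expect_equal(ded$protein_a, c("A", "A"))
  expect_equal(ded$protein_b, c("B", "C"))
  expect_equal(ded$combined_score, c(500L, 450L))

  loops <- make_edge_list("A", "A", 900L)
  dloops <- deduplicate(loops)
  expect_equal(nrow(dloops), 0L)
  expect_equal(edge_provenance(dloops)$deduplication$self_loops_removed, 1L)

  # unequal duplicate scores keep the maximum
  uneq <- make_edge_list(c("A", "B"), c("B", "A"), c(420L, 800L))
  expect_equal(deduplicate(uneq)$combined_score, 800L)
})

test_that("deduplication is idempotent and halves symmetric duplicate lists", {
  set.seed(11)
  a <- sprintf("P%02d", sample(1:30, 40, replace = TRUE))
  b <- sprintf("Q%02d", sample(1:30, 40, replace = TRUE))
  keep <- !duplicated(paste(a, b))
  a <- a[keep]; b <- b[keep]
  m <- sum(keep)
  s <- sample(0:1000, m, replace = TRUE)
  el <- make_edge_list(c(a, b), c(b, a), c(s, s))
  d1 <- deduplicate(el)
  expect_equal(nrow(d1), m)
  d2 <- deduplicate(d1)
  expect_equal(as.data.frame(d1), as.data.frame(d2))
})

test_that("filtering and deduplication commute when duplicates share scores", {
  set.seed(3)
  a <- sprintf("P%02d", sample(1:15, 30, replace = TRUE))
  b <- sprintf("Q%02d", sample(1:15, 30, replace = TRUE))
  keep <- !duplicated(paste(a, b))
  a <- a[keep]; b <- b[keep]
  s <- sample(0:1000, sum(keep), replace = TRUE)
  el <- make_edge_list(c(a, b), c(b, a), c(s, s))
  fd <- deduplicate(filter_by_score(el, 400))
  df <- filter_by_score(deduplicate(el), 400)
  expect_equal(as.data.frame(fd), as.data.frame(df))
})

test_that("edge lists round-trip through the writer and parser", {
  el <- deduplicate(make_edge_list(c("A", "B", "C"), c("B", "C", "D"),
                                   c(500L, 650L, 720L)))
  f <- tempfile(fileext = ".tsv")
  write_edge_list(el, f)
  back <- deduplicate(parse_string_links(f))
  expect_equal(as.data.frame(back), as.data.frame(el))
})

test_that("seed lists load with dropout bookkeeping and set semantics", {
  f <- tempfile()
  writeLines(c("# known root proteins", "S1", "S2", "", "S3", "S2"), f)
  expect_warning(ss <- load_seed_list(f, c("S1", "S3", "X")), "duplicated")
  expect_s3_class(ss, "seed_set")
  expect_equal(sort(ss$ids), c("S1", "S2", "S3"))
  expect_equal(ss$missing_from_network, "S2")

  all_in <- suppressWarnings(load_seed_list(f, c("S1", "S2", "S3")))
  expect_length(all_in$missing_from_network, 0L)

  writeLines(c("", "# only comments"), f)
  expect_error(load_seed_list(f, "A"), "no IDs")
})

test_that("SIF and provenance writers emit the documented formats", {
  el <- deduplicate(make_edge_list(c("A", "B"), c("B", "C"), c(500L, 600L)))
  sif <- tempfile(fileext = ".sif")
  write_sif(el, sif)
  expect_equal(readLines(sif), c("A pp B", "B pp C"))

  pj <- tempfile(fileext = ".json")
  write_provenance(el, pj)
  prov <- jsonlite::read_json(pj)
  expect_equal(prov$raw_records, 2L)
  expect_equal(prov$deduplication$edges_after, 2L)
})
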