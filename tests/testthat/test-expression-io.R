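test_that("expression TSV round-trips at full precision and keeps sample order", {
  m <- make_expr(12, 5, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  m2 <- read_expression(path, collapse = "none")
  expect_identical(colnames(m2), colnames(m))
  expect_identical(rownames(m2), rownames(m))
  expect_equal(m2, m, tolerance = 1e-12)
})

test_that("max_mean collapsing keeps the highest-mean probe and is idempotent", {
  path <- write_expr_tsv(c(
    "gene_id\tS1\tS2",
    "A\t4\t6",    # mean 5
    "A\t6\t8",    # mean 7 -> kept
    "B\t1\t2"))
  m <- read_expression(path, collapse = "max_mean")
  expect_identical(rownames(m), c("A", "B"))
  expect_equal(unname(m["A", ]), c(6, 8))
  expect_identical(collapse_probes(m), m)
})

test_that("malformed input is rejected with the offending location named", {
  na_path <- write_expr_tsv(c("gene_id\tS1\tS2", "A\t1\tNA", "B\t2\t3"))
  expect_error(read_expression(na_path), "gene 'A'.*sample 'S2'")
  one_col <- write_expr_tsv(c("gene_id", "A", "B"))
  expect_error(read_expression(one_col), "header")
  text_cell <- write_expr_tsv(c("gene_id\tS1\tS2", "A\t1\t2", "B\tx\t3"))
  expect_error(read_expression(text_cell), "gene 'B'.*sample 'S1'")
})

test_that("transposed files load to genes-in-rows", {
  m <- make_expr(6, 3, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(t(m), path)
  expect_equal(read_expression(path, transpose = TRUE, collapse = "none"), m,
               tolerance = 1e-12)
})

test_that("log-scale heuristic flags linear-scale matrices without mutating them", {
  m <- make_expr(5, 3, seed = 1)
  m[1, 1] <- 14.2
  chk <- check_log_scale(m)
  expect_true(chk$plausible)
  expect_match(chk$message, "plausible")

  lin <- m
  lin[2, 2] <- 20000
  expect_warning(chk2 <- check_log_scale(lin), "linear-scale")
  expect_false(chk2$plausible)

  zeros <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_true(check_log_scale(zeros)$plausible)
})

test_that("GMT parsing follows the format, deduplicates, and round-trips", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("UP_SIG\tdesc\tA\tB\tC", "S\td\tA\tA\tB"), path)
  expect_warning(sets <- read_gmt(path), "duplicate genes in set 'S'")
  expect_identical(sets$UP_SIG, c("A", "B", "C"))
  expect_identical(sets$S, c("A", "B"))

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_identical(unclass(read_gmt(out))[1:2], unclass(sets)[1:2])

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_length(read_gmt(empty), 0)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("OK\tdesc\tA", "SHORT\tdesc"), bad)
  expect_error(read_gmt(bad), "line 2")
})

test_that("sample annotation validation enforces id uniqueness and time/event pairing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = c("a", "b"), egfr_status = c("hotspot_mutant", "wild_type"),
    kras_status = "wild_type", rfs_time = c(10, 20),
    rfs_event = c(TRUE, FALSE), pdl1 = c(1.2, 3.4)), path)
  ann <- read_sample_annotation(path)
  expect_identical(ann$sample_id, c("a", "b"))
  expect_true("pdl1" %in% colnames(ann))  # aux columns preserved

  readr::write_tsv(tibble::tibble(sample_id = c("a", "a")), path)
  expect_error(read_sample_annotation(path), "duplicate sample_id")

  readr::write_tsv(tibble::tibble(sample_id = "a", rfs_time = 5), path)
  expect_error(read_sample_annotation(path), "rfs_event")
})
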