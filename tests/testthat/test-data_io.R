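# Readers, writers and the composite gene set.

test_that("expression TSV round-trips and respects on-disk orientation", {
  x <- matrix(c(1.5, -2.25, 3.125, 0.5, 1e-7, 42), 3, 2,
              dimnames = list(c("CASP8", "CFLAR", "NINJ1"), c("sA", "sB")))
  f <- withr::local_tempfile(fileext = ".tsv")
  save_expression(x, f)
  expect_equal(load_expression(f), x, tolerance = 1e-9)

  # samples-by-genes file loads to the transpose of the same data
  ft <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(x), t(x), check.names = FALSE)
  write.table(df, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_expression(ft, orientation = "samples_by_genes"), x,
               tolerance = 1e-9)
})

test_that("expression loader rejects duplicates, non-numeric cells and NaN", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "CASP8\t1\t2", "CASP8\t3\t4"), f)
  expect_error(load_expression(f), "CASP8")

  writeLines(c("gene\ts1\ts2", "BAX\t1\toops", "BAK1\t3\t4"), f)
  expect_error(load_expression(f), "BAX.*s2|s2.*BAX")

  writeLines(c("gene\ts1\ts2", "BAX\t1\tNaN", "BAK1\t3\t4"), f)
  expect_error(load_expression(f))
})

test_that("MatrixMarket triplets load with sidecar names", {
  x <- matrix(c(0, 2, 1.5, 0, 0, 3), 3, 2,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  d <- withr::local_tempdir()
  mtx <- file.path(d, "m.mtx")
  Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), mtx)
  writeLines(rownames(x), file.path(d, "m_rows.txt"))
  writeLines(colnames(x), file.path(d, "m_cols.txt"))
  expect_equal(load_expression(mtx), x, tolerance = 1e-9)
})

test_that("GMT files round-trip and malformed lines are rejected", {
  sets <- list(apoptosis = c("CASP8", "CFLAR", "E2F1"),
               pyroptosis = c("CASP8", "CARD8"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_identical(read_gmt(f), sets)
  writeLines("half\tline", f)
  expect_error(read_gmt(f), "malformed")
})

test_that("composite gene set annotates multi-pathway members", {
  # the three cell-death lists share CASP8 (and more); keep_annotated must
  # record every pathway naming each gene
  lists <- list(
    apoptosis = c("BAD", "BIRC3", "CASP8", "CFLAR", "E2F1", "TNFRSF10A"),
    pyroptosis = c("CASP8", "CARD8", "GSDMA", "NINJ1"),
    necroptosis = c("BIRC3", "CASP8", "CFLAR", "TNFRSF10A", "USP25"))
  gs <- build_composite_geneset(lists, overlap_mode = "keep_annotated")
  expect_setequal(gs$provenance[["CASP8"]],
                  c("apoptosis", "pyroptosis", "necroptosis"))
  expect_setequal(gs$provenance[["CFLAR"]], c("apoptosis", "necroptosis"))
  expect_identical(gs$genes, sort(unique(unlist(lists))))

  dropped <- build_composite_geneset(lists, overlap_mode = "drop_shared")
  expect_false(any(c("CASP8", "CFLAR", "BIRC3", "TNFRSF10A") %in%
                     dropped$genes))
  expect_true(all(c("BAD", "E2F1", "CARD8", "USP25") %in% dropped$genes))
})

test_that("composite gene set edge cases follow the definition", {
  # disjoint lists: drop_shared output is the plain union
  disj <- list(A = c("g1", "g2"), B = c("g3"))
  expect_setequal(build_composite_geneset(disj, "drop_shared")$genes,
                  c("g1", "g2", "g3"))
  # forced by definition: shared g2 leaves only g1
  expect_identical(
    build_composite_geneset(list(A = c("g1", "g2"), B = "g2"),
                            "drop_shared")$genes, "g1")
  expect_error(build_composite_geneset(list(A = character(0))), "empty")
})

test_that("provenance multiplicities match brute-force membership counts", {
  set.seed(41)
  for (rep in 1:5) {
    pool <- sprintf("G%02d", 1:30)
    lists <- lapply(setNames(1:4, paste0("p", 1:4)), function(i)
      sample(pool, sample(3:12, 1)))
    gs <- build_composite_geneset(lists, "keep_annotated")
    brute <- sapply(gs$genes, function(g)
      sum(vapply(lists, function(s) g %in% s, logical(1))))
    expect_identical(unname(lengths(gs$provenance)), unname(brute))
  }
})

test_that("survival tables are validated row by row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ok <- data.frame(sample_id = paste0("s", 1:5), time = c(1, 2, 3, 4, 5),
                   event = c(1L, 0L, 1L, 1L, 0L))
  write.table(ok, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- load_survival(f)
  expect_equal(nrow(got), 5L)
  expect_identical(got$event, ok$event)

  bad <- ok; bad$time[3] <- -3
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_survival(f), "s3")

  bad <- ok; bad$event[2] <- 2L
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_survival(f), "event")

  write.table(ok[, c("sample_id", "time")], f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_survival(f), "event")
})
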