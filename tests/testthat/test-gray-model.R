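test_that("gray_space validates inputs and builds a symmetric kNN adjacency", {
  sp <- make_space(120, seed = 3)
  expect_s3_class(sp, "gray_space")
  # adjacency canonical (i < j), irreflexive, in range
  expect_true(all(sp$adjacency[, 1] < sp$adjacency[, 2]))
  expect_true(all(sp$adjacency >= 1 & sp$adjacency <= sp$n_gray))
  expect_error(gray_space(cbind(1:3, 0, NA), rep("SUBCORTEX", 3)), "finite")
  expect_error(gray_space(cbind(1:3, 0, 0), rep("BRAINSTEM", 3)), "tags")
})

test_that("plaintext dense roundtrip is an exact inverse", {
  sp <- line_space(50)
  set.seed(1)
  ts <- dense_timeseries(matrix(rnorm(500), 10, 50), sp, tr_seconds = 0.8)
  path <- tempfile(fileext = ".tsv")
  write_dense(ts, path, dialect = "plaintext")
  back <- read_dense(path, dialect = "plaintext")
  expect_identical(back$values, ts$values)
  expect_identical(back$tr_seconds, 0.8)
  expect_identical(back$space$structure, sp$structure)
})

test_that("plaintext reader reports malformed rows and missing TR", {
  sp <- line_space(5)
  ts <- dense_timeseries(matrix(1:20 / 7, 4, 5), sp, 2)
  path <- tempfile()
  write_dense(ts, path)
  lines <- readLines(path)
  lines[3] <- paste(strsplit(lines[3], "\t")[[1]][1:3], collapse = "\t")
  writeLines(lines, path)
  expect_error(read_dense(path), "Row 3")
  # missing TR in sidecar
  write_dense(ts, path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  meta$tr_seconds <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_dense(path), "tr_seconds")
})

test_that("dense_timeseries enforces its invariants", {
  sp <- line_space(5)
  expect_error(dense_timeseries(matrix(1, 1, 5), sp, 1), "2 frames")
  expect_error(dense_timeseries(matrix(1, 4, 4), sp, 1), "n_gray")
  expect_error(dense_timeseries(matrix(1, 4, 5), sp, 0), "positive")
})

test_that("label map roundtrips preserve labels and palette byte-identically", {
  sp <- line_space(60)
  set.seed(2)
  lm <- label_map(sample(0:14, 60, replace = TRUE), sp)
  path <- tempfile()
  write_labels(lm, path)
  back <- read_labels(path)
  expect_identical(back$labels, lm$labels)
  expect_identical(back$palette, lm$palette)
  # out-of-range label rejected
  m <- readLines(path)
  m[5] <- "99"
  writeLines(m, path)
  expect_error(read_labels(path), "palette range")
})

test_that("overlap map roundtrip preserves per-network membership counts", {
  sp <- line_space(40)
  set.seed(3)
  om <- overlap_map(matrix(rbinom(40 * 14, 1, 0.2), 14, 40), sp)
  path <- tempfile()
  write_labels(om, path)
  back <- read_labels(path)
  expect_s3_class(back, "overlap_map")
  expect_identical(rowSums(back$membership), rowSums(om$membership))
  expect_identical(back$membership, om$membership)
})

test_that("reader/writer pairs invert on random instances (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:80, 1)
    sp <- make_space(max(100, n), seed = seed)
    ts <- dense_timeseries(matrix(rnorm(6 * sp$n_gray), 6), sp,
                           tr_seconds = runif(1, 0.5, 3))
    p1 <- tempfile()
    write_dense(ts, p1)
    expect_identical(read_dense(p1)$values, ts$values)
    lm <- label_map(sample(0:5, sp$n_gray, replace = TRUE), sp,
                    palette = canonical_networks()[1:5])
    p2 <- tempfile()
    write_labels(lm, p2)
    expect_identical(read_labels(p2)$labels, lm$labels)
  }
})

test_that("scalar map roundtrips through plaintext and cifti", {
  sp <- line_space(30)
  sm <- scalar_map(rnorm(30), sp, name = "overlap_count")
  p <- tempfile()
  write_scalar(sm, p)
  expect_equal(read_scalar(p)$values, sm$values)
  p2 <- tempfile(fileext = ".dscalar.nii")
  write_cifti_scalar(sm, p2)
  back <- read_cifti_scalar(p2)
  expect_equal(back$values, sm$values, tolerance = 1e-7)
  expect_identical(back$name, "overlap_count")
})

test_that("cifti2 dense roundtrip preserves values, TR, structure and coords", {
  sp <- make_space(120, seed = 9)
  set.seed(4)
  ts <- dense_timeseries(matrix(rnorm(120 * 8), 8), sp, tr_seconds = 0.72)
  path <- tempfile(fileext = ".dtseries.nii")
  write_dense(ts, path, dialect = "cifti2")
  back <- read_dense(path, dialect = "cifti2")
  expect_equal(back$values, ts$values, tolerance = 1e-7)  # float32 on disk
  expect_equal(back$tr_seconds, 0.72, tolerance = 1e-12)
  expect_identical(back$space$structure, sp$structure)
  expect_equal(back$space$coords, sp$coords, tolerance = 1e-12)
})

test_that("cifti2 label roundtrip preserves labels and palette", {
  sp <- make_space(100, seed = 2)
  lm <- label_map(sample(0:14, 100, replace = TRUE), sp)
  path <- tempfile(fileext = ".dlabel.nii")
  write_labels(lm, path, dialect = "cifti2")
  back <- read_labels(path, dialect = "cifti2")
  expect_identical(back$labels, lm$labels)
  expect_identical(back$palette, lm$palette)
  om <- overlap_map(matrix(rbinom(100 * 14, 1, 0.1), 14, 100), sp)
  p2 <- tempfile(fileext = ".dlabel.nii")
  write_labels(om, p2, dialect = "cifti2")
  expect_identical(read_labels(p2, dialect = "cifti2")$membership, om$membership)
})

test_that("cifti2 writer output is readable by an independent CIFTI reader", {
  sp <- make_space(100, seed = 5)
  set.seed(6)
  ts <- dense_timeseries(matrix(rnorm(100 * 6), 6), sp, tr_seconds = 0.8)
  path <- tempfile(fileext = ".dtseries.nii")
  write_dense(ts, path, dialect = "cifti2")
  out <- tempfile(fileext = ".txt")
  script <- paste0(
    "import nibabel, numpy; img = nibabel.load('", path, "'); ",
    "d = numpy.asarray(img.get_fdata()); ",
    "numpy.savetxt('", out, "', d); ",
    "print(img.header.matrix.get_index_map(0).series_step)")
  res <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  expect_true(is.null(status) || status == 0)
  ext <- as.matrix(read.table(out))
  dimnames(ext) <- NULL
  expect_equal(ext, ts$values, tolerance = 1e-6)
  expect_equal(as.numeric(res[length(res)]), 0.8, tolerance = 1e-9)
})
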