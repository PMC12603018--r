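test_that("IGHV calls collapse to their subgroup", {
  expect_equal(normalize_ighv("IGHV11-2*01"), "IGHV11")
  expect_equal(normalize_ighv("IGHV1-55"), "IGHV1")
  expect_equal(normalize_ighv("IGHV1S22*01"), "IGHV1")
  expect_equal(normalize_ighv(c("IGHV12-3*01", "IGHV9-4")),
               c("IGHV12", "IGHV9"))
  expect_error(normalize_ighv("IGKV1-1"), "IGHV")
  expect_error(normalize_ighv(NA_character_), "IGHV")
})

test_that("AIRR rows map onto clone records", {
  path <- write_airr_fixture(tibble::tibble(
    junction_aa = "CARWDGYW", v_call = "IGHV1-55*01", d_call = "IGHD2-1",
    j_call = "IGHJ3", duplicate_count = 10, productive = "T",
    n1_length = 3, n2_length = 1
  ))
  rec <- read_clone_table(path, "airr")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$v_gene, "IGHV1")
  expect_equal(rec$v_call, "IGHV1-55*01")
  expect_equal(rec$cdr3_aa, "CARWDGYW")
  expect_equal(rec$read_count, 10)
  expect_equal(rec$n1_len, 3)
  expect_true(rec$productive)
})

test_that("MiXCR rows map onto clone records, first hit wins", {
  path <- write_airr_fixture(tibble::tibble(
    cloneCount = 7,
    aaSeqCDR3 = "CMRYGNYWYFDVW",
    nSeqCDR3 = paste(rep("TGT", 13), collapse = ""),
    allVHitsWithScore = "IGHV11-2*01(1200),IGHV11-1*01(900)",
    allDHitsWithScore = "IGHD1-1*01(300)",
    allJHitsWithScore = "IGHJ1*01(500)"
  ))
  rec <- read_clone_table(path, "mixcr")
  expect_equal(rec$v_call, "IGHV11-2*01")
  expect_equal(rec$v_gene, "IGHV11")
  expect_equal(rec$d_gene, "IGHD1-1*01")
  expect_equal(rec$read_count, 7)
  expect_true(rec$productive)
})

test_that("header-only file yields an empty record set", {
  path <- write_airr_fixture(tibble::tibble(
    junction_aa = character(0), v_call = character(0),
    d_call = character(0), j_call = character(0),
    duplicate_count = numeric(0), productive = character(0)
  ))
  rec <- read_clone_table(path, "airr")
  expect_equal(nrow(rec), 0L)
})

test_that("format errors name the offending column or row", {
  path <- write_airr_fixture(tibble::tibble(
    junction_aa = "CARW", v_call = "IGHV1-1"
  ))
  expect_error(read_clone_table(path, "airr"), "duplicate_count")
  path2 <- write_airr_fixture(tibble::tibble(
    junction_aa = "CARWDGYW", v_call = "IGHV1-55*01", d_call = "IGHD2-1",
    j_call = "IGHJ3", duplicate_count = "abc", productive = "T"
  ))
  expect_error(read_clone_table(path2, "airr"), "row 1")
  expect_error(read_clone_table(tempfile(), "airr"), "not found")
})

test_that("QC filter drops low-quality and non-functional records", {
  rec <- make_records(c("CARWDGYW", "CAR*WGYW", "CARAAGYW", "CARCCGYW"),
                      read_count = 10,
                      mean_quality = c(29.9, 35, NA, 30))
  fl <- filter_records(rec)
  expect_equal(fl$kept$cdr3_aa, c("CARAAGYW", "CARCCGYW"))
  expect_equal(fl$rejected$reason, c("quality<Q30", "non-functional"))
  # productivity flag, and the require_productive switch
  rec2 <- make_records("CARWDGYW", 5, productive = FALSE)
  expect_equal(nrow(filter_records(rec2)$kept), 0L)
  expect_equal(nrow(filter_records(rec2, require_productive = FALSE)$kept),
               1L)
  # empty input passes through
  empty <- filter_records(rec[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$rejected), 0L)
})

test_that("aggregation merges CDR3-identical rows and normalizes fractions", {
  rec <- make_records(c("CARWDGYW", "CARWDGYW", "CMRYGNYWYFDVW"),
                      read_count = c(6, 4, 10))
  rep <- aggregate_repertoire(rec, "S1", "SPL")
  expect_equal(nrow(rep$clones), 2L)
  expect_equal(sort(rep$clones$fraction), c(0.5, 0.5))
  expect_equal(sum(rep$clones$fraction), 1, tolerance = 1e-12)
  # single row
  one <- aggregate_repertoire(make_records("CARW", 5), "S1")
  expect_equal(one$clones$fraction, 1)
  # zero reads is an error
  expect_error(aggregate_repertoire(make_records("CARW", 0), "S1"),
               "empty repertoire")
})

test_that("gene labels merge by read-count majority, ties lexicographic", {
  rec <- make_records(c("CARWDGYW", "CARWDGYW"), read_count = c(7, 3),
                      v_call = c("IGHV11-2*01", "IGHV1-55*01"))
  rep <- aggregate_repertoire(rec, "S1")
  expect_equal(rep$clones$v_gene, "IGHV11")
  # reversed weights flip the vote
  rec$read_count <- c(3, 7)
  expect_equal(aggregate_repertoire(rec, "S1")$clones$v_gene, "IGHV1")
  # exact tie: lexicographically smaller label wins
  rec$read_count <- c(5, 5)
  expect_equal(aggregate_repertoire(rec, "S1")$clones$v_gene, "IGHV1")
})

test_that("aggregation is order-independent", {
  set.seed(42)
  rec <- make_records(sample(c("CARW", "CARWW", "CMRW"), 20, replace = TRUE),
                      read_count = sample(1:50, 20, replace = TRUE),
                      v_call = sample(c("IGHV1-1", "IGHV11-2"), 20,
                                      replace = TRUE))
  base <- aggregate_repertoire(rec, "S1")
  for (i in 1:5) {
    shuf <- aggregate_repertoire(rec[sample(nrow(rec)), ], "S1")
    expect_equal(shuf$clones, base$clones)
  }
})

test_that("filtering commutes with aggregation when QC is clone-constant", {
  rec <- make_records(c("CARW", "CARW", "CMRW", "CMRW"),
                      read_count = c(4, 6, 3, 7),
                      mean_quality = c(35, 35, 20, 20))
  a <- aggregate_repertoire(filter_records(rec)$kept, "S1")
  full <- aggregate_repertoire(rec, "S1")
  kept_aa <- setdiff(full$clones$cdr3_aa,
                     unique(filter_records(rec)$rejected$cdr3_aa))
  expect_setequal(a$clones$cdr3_aa, kept_aa)
})

test_that("clone tables round-trip through both dialects", {
  set.seed(7)
  for (dialect in c("airr", "mixcr")) {
    aa <- replicate(6, random_aa(12))
    rec <- make_records(aa, read_count = sample(5:500, 6),
                        v_call = sample(c("IGHV1-55*01", "IGHV11-2*01",
                                          "IGHV12-3*01"), 6, replace = TRUE),
                        cdr3_nt = vapply(aa, function(s) {
                          paste(sample(c("A","C","G","T"), 3 * nchar(s),
                                       replace = TRUE), collapse = "")
                        }, character(1)))
    rep <- aggregate_repertoire(rec, "S1", "SPL")
    path <- tempfile(fileext = ".tsv")
    write_clone_table(rep, path, dialect)
    back <- aggregate_repertoire(read_clone_table(path, dialect), "S1", "SPL")
    expect_equal(back$clones$cdr3_aa, rep$clones$cdr3_aa)
    expect_equal(back$clones$read_count, rep$clones$read_count)
    expect_equal(back$clones$v_gene, rep$clones$v_gene)
    expect_equal(back$clones$fraction, rep$clones$fraction)
  }
  # empty repertoire writes a header-only file
  rep1 <- make_repertoire(1)
  rep1$clones <- rep1$clones[0, ]
  path <- tempfile(fileext = ".tsv")
  write_clone_table(rep1, path, "airr")
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 0L)
  # AIRR contract columns present
  write_clone_table(make_repertoire(c(0.6, 0.4)), path, "airr")
  cols <- names(readr::read_tsv(path, show_col_types = FALSE))
  expect_true(all(c("junction_aa", "v_call", "j_call",
                    "duplicate_count") %in% cols))
})
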