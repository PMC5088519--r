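test_that("TSV expression round trip is lossless and byte-identical", {
    set.seed(42)
    m <- matrix(round(rnorm(6, 8, 2), 4), 3, 2,
                dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
    des <- data.frame(sample_id = c("s1", "s2"), group = "CC6", zt_time = 6,
                      replicate_group = "CC6.t", study = "t", platform = "p")
    f <- tempfile(fileext = ".tsv")
    writeExpression(SleepExpressionSet(m, des), f)
    ds <- loadExpression(f, des)
    expect_equal(dim(exprsMatrix(ds)), c(3L, 2L))
    expect_identical(featureIds(ds), rownames(m))
    expect_equal(exprsMatrix(ds), m, tolerance = 1e-6)
    # canonical formatting: rewriting the loaded matrix reproduces the file
    f2 <- tempfile(fileext = ".tsv")
    writeExpression(ds, f2)
    expect_identical(readLines(f), readLines(f2))
})

test_that("expression loader rejects malformed input with actionable errors", {
    des <- data.frame(sample_id = c("s1", "s2"), group = "CC6", zt_time = 6,
                      replicate_group = "r", study = "t", platform = "p")
    f <- tempfile()
    writeLines(c("feature_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), f)
    expect_error(loadExpression(f, des), "gA")
    writeLines(c("feature_id\ts1\ts2", "gA\t1\tx"), f)
    expect_error(loadExpression(f, des), "non-numeric.*gA.*s2")
    writeLines(c("feature_id\ts1\ts2", "gA\t1\tNA"), f)
    expect_error(loadExpression(f, des), "missing")
    # design lacking a sample present in the matrix
    writeLines(c("feature_id\ts1\ts3", "gA\t1\t2"), f)
    expect_error(loadExpression(f, des), "s3")
})

test_that("loader warns on apparently linear-scale values and converts bases", {
    des <- data.frame(sample_id = "s1", group = "CC6", zt_time = 6,
                      replicate_group = "r", study = "t", platform = "p")
    f <- tempfile()
    writeLines(c("feature_id\ts1", "gA\t1500", "gB\t2"), f)
    expect_warning(loadExpression(f, des), "linear")
    # natural-log input rescaled to log2
    writeLines(c("feature_id\ts1", "gA\t1", "gB\t2"), f)
    ds <- loadExpression(f, des, base = exp(1))
    expect_equal(exprsMatrix(ds)[, 1], c(gA = log2(exp(1)), gB = 2 * log2(exp(1))))
})

test_that("GEO series-matrix table blocks parse", {
    f <- tempfile()
    writeLines(c("!Series_title\t\"demo\"",
                 "!series_matrix_table_begin",
                 "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
                 "\"gA\"\t5.5\t6.5",
                 "\"gB\"\t7.0\t8.0",
                 "!series_matrix_table_end"), f)
    des <- data.frame(sample_id = c("GSM1", "GSM2"), group = c("CC6", "SD"),
                      zt_time = 6, replicate_group = c("c", "s"),
                      study = "t", platform = "p")
    ds <- loadExpression(f, des, format = "geo_series_matrix")
    expect_equal(exprsMatrix(ds)["gA", "GSM2"], 6.5)
    expect_equal(dim(ds), c(2L, 2L))
    writeLines(c("no", "table", "here"), f)
    expect_error(loadExpression(f, des, format = "geo_series_matrix"),
                 "series-matrix")
})

test_that("design tables validate required columns and round trip", {
    f <- tempfile()
    d <- data.frame(sample_id = c("s1", "s2"), group = c("CC6", "SD"),
                    zt_time = c(6, 6), replicate_group = c("a", "b"),
                    study = "t", platform = "p")
    writeDesign(d, f)
    expect_equal(loadDesign(f), d)
    writeDesign(d[, -2], f)
    expect_error(loadDesign(f), "group")
})

test_that("GMT parsing follows the term/description/genes layout", {
    f <- tempfile()
    writeLines(c("TERM1\tdesc\tG1\tG2", "TERM2\tother\tG2\tG3\tG4"), f)
    gsc <- loadGMT(f)
    expect_setequal(geneSets(gsc)$TERM1, c("G1", "G2"))
    expect_length(geneSets(gsc)$TERM2, 3)
    f2 <- tempfile()
    writeGMT(gsc, f2)
    expect_identical(readLines(f), readLines(f2))
    writeLines("TERM1\tonly-two-fields", f)
    expect_error(loadGMT(f), "fewer than 3")
})

test_that("control lists load with contrast labels, warnings and flags", {
    neg <- tempfile(); pos <- tempfile()
    writeLines(c("g1", "g2"), neg)
    writeLines(c("SD_vs_CC6\tg5", "SD_vs_CC6\tg6", "RS1_vs_CC7\tg7"), pos)
    cs <- loadControls(neg, pos)
    expect_setequal(negativeControls(cs), c("g1", "g2"))
    expect_setequal(positiveControls(cs, "SD_vs_CC6"), c("g5", "g6"))
    # one-column positives apply to every contrast
    writeLines(c("g5", "g6"), pos)
    cs <- loadControls(neg, pos)
    expect_setequal(positiveControls(cs, "anything"), c("g5", "g6"))
    # empty positives: warning, empty map
    writeLines(character(), pos)
    expect_warning(cs <- loadControls(neg, pos), "empty")
    expect_length(positiveControls(cs), 0)
    # ids absent from the dataset are flagged
    d <- toyDataset(matrix(1:4, 2), c("CC6", "SD"))
    writeLines("not_there", neg)
    expect_warning(loadControls(neg, NULL, dataset = d), "absent")
    # overlap between negative and positive sets violates validity
    expect_error(ControlGeneSets("g5", list(all = "g5")), "negative and positive")
})

test_that("SleepExpressionSet validity enforces the data contract", {
    m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
    des <- data.frame(sample_id = c("s1", "s2"), group = "CC6", zt_time = 6,
                      replicate_group = "r", study = "t", platform = "p")
    expect_s4_class(SleepExpressionSet(m, des), "SleepExpressionSet")
    m_bad <- m; m_bad[1, 1] <- NA
    expect_error(SleepExpressionSet(m_bad, des), "non-finite")
    des_bad <- des; des_bad$zt_time <- c(6, 25)
    expect_error(SleepExpressionSet(m, des_bad), "zt_time")
    # replicate_group must not straddle groups within a study
    des_bad2 <- des; des_bad2$group <- c("CC6", "SD")
    expect_error(SleepExpressionSet(m, des_bad2), "replicate_group")
})
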