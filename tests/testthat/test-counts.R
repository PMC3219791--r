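lane_summary_path <- system.file("extdata", "example_lane_summary.tsv",
                                 package = "droughtseq")

test_that("read_counts validates shape, values and lane agreement", {
  d <- withr::local_tempdir()
  counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           L1 = c(0L, 5L, 2L), L2 = c(1L, 3L, 0L))
  sheet <- tibble::tibble(lane = c("L1", "L2"), tissue = "shoot",
                          condition = c("trt", "ctl"), contrast = "trt",
                          replicate = 1L)
  readr::write_tsv(counts, file.path(d, "c.tsv"))
  readr::write_tsv(sheet, file.path(d, "s.tsv"))
  cm <- read_counts(file.path(d, "c.tsv"), file.path(d, "s.tsv"))
  expect_equal(dim(as.matrix(cm$counts[-1])), c(3L, 2L))

  counts$L1[2] <- -1L
  readr::write_tsv(counts, file.path(d, "bad.tsv"))
  expect_error(read_counts(file.path(d, "bad.tsv"), file.path(d, "s.tsv")),
               class = "droughtseq_format_error")

  sheet2 <- sheet[1, ]
  readr::write_tsv(sheet2, file.path(d, "s2.tsv"))
  expect_error(read_counts(file.path(d, "c.tsv"), file.path(d, "s2.tsv")),
               class = "droughtseq_design_error")

  counts_dup <- tibble::tibble(gene_id = c("g1", "g1"), L1 = c(1L, 2L),
                               L2 = c(0L, 0L))
  readr::write_tsv(counts_dup, file.path(d, "dup.tsv"))
  expect_error(read_counts(file.path(d, "dup.tsv"), file.path(d, "s.tsv")),
               class = "droughtseq_format_error")
})

test_that("qc_summary reproduces the printed lane-summary arithmetic", {
  lane_summary <- readr::read_tsv(lane_summary_path, show_col_types = FALSE)
  qc <- qc_summary(lane_summary)
  g <- function(cat) unname(qc$grand$total[qc$grand$category == cat])
  expect_equal(g("total_reads"), 689.5)
  expect_equal(g("purity_filtered"), 535.9)
  expect_equal(g("uniquely_mapped"), 462.9)
  f <- function(nm) unname(qc$fractions$value[qc$fractions$name == nm])
  expect_equal(f("pct_unique_of_total"), 67.1)
  # uniquely mapped / purity filtered ~ 86-87%
  expect_true(f("pct_unique_of_purity_filtered") >= 86 &
                f("pct_unique_of_purity_filtered") <= 87)
})

test_that("qc_summary reports undefined fractions on all-zero totals", {
  zeroes <- tibble::tibble(sample = "s1", total_reads = 0,
                           purity_filtered = 0, uniquely_mapped = 0)
  qc <- qc_summary(zeroes)
  expect_true(all(is.na(qc$fractions$value)))
  expect_error(qc_summary(tibble::tibble(sample = "s1", total_reads = 1)),
               class = "droughtseq_format_error")
})

test_that("call_expressed uses summed raw counts and is monotone in min_raw", {
  counts <- rbind(g1 = c(0L, 1L, 0L, 1L), g2 = c(0L, 1L, 0L, 0L),
                  g3 = c(5L, 5L, 5L, 5L), g4 = c(0L, 0L, 0L, 0L))
  cm <- toy_count_matrix(counts)
  ann <- tibble::tibble(gene_id = paste0("g", 1:4),
                        confidence = c("high", "high", "low", "high"))
  res <- call_expressed(cm, ann, min_raw = 2)
  expect_setequal(res$expressed, c("g1", "g3"))
  # gene with a single 1 in any lane is not expressed at min_raw = 2
  expect_false("g2" %in% res$expressed)
  # min_raw = 0 makes every gene expressed
  expect_equal(length(call_expressed(cm, ann, min_raw = 0)$expressed), 4L)
  # monotone: raising the threshold never adds genes
  prev <- call_expressed(cm, ann, min_raw = 0)$expressed
  for (mr in c(1, 2, 5, 20)) {
    cur <- call_expressed(cm, ann, min_raw = mr)$expressed
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # breakdown arithmetic
  hb <- res$breakdown[res$breakdown$confidence == "high", ]
  expect_equal(hb$n_expressed, 1L)
  expect_equal(hb$pct, round(100 / 3, 1))
})

test_that("expressed-percentage helper matches printed-precision arithmetic", {
  expect_equal(pct_of(25568, 27640), 92.5)
  expect_equal(pct_of(5809, 34144), 17.0)
  expect_equal(pct_of(3915, 5809), 67.4)
  expect_equal(pct_of(2971, 26466), 11.2)
  expect_true(is.na(pct_of(3, 0)))
})

test_that("unannotated genes are warned about and counted as unclassified", {
  counts <- rbind(g1 = c(3L, 3L), g2 = c(4L, 4L))
  cm <- toy_count_matrix(counts)
  ann <- tibble::tibble(gene_id = "g1", confidence = "high")
  expect_warning(res <- call_expressed(cm, ann), "unclassified")
  expect_true("unclassified" %in% res$breakdown$confidence)
})

test_that("quantile normalization equalizes lane distributions", {
  m <- cbind(L1 = c(1, 2, 3), L2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  cm <- quantile_normalize(toy_count_matrix(m))
  norm <- as.matrix(cm$normalized[-1])
  expect_equal(sort(norm[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(sort(norm[, 2]), c(2.5, 3.5, 4.5))
  # identical lanes unchanged
  m2 <- cbind(L1 = c(5, 1, 9), L2 = c(5, 1, 9))
  cm2 <- quantile_normalize(toy_count_matrix(m2))
  expect_equal(unname(as.matrix(cm2$normalized[-1])), unname(m2))
  # tie-free lanes: sorted value vectors become identical across lanes and
  # equal the mean of order statistics; rank order within a lane preserved
  set.seed(4)
  m3 <- matrix(sample(1:10000, 600), ncol = 6,
               dimnames = list(paste0("g", 1:100), paste0("L", 1:6)))
  cm3 <- quantile_normalize(toy_count_matrix(m3))
  n3 <- as.matrix(cm3$normalized[-1])
  ref <- rowMeans(apply(m3, 2, sort))
  for (j in 1:6) {
    expect_equal(sort(n3[, j]), ref, ignore_attr = TRUE)
    expect_equal(rank(n3[, j], ties.method = "average"),
                 unname(rank(m3[, j], ties.method = "average")))
  }
  # per-lane medians equalized
  expect_equal(stats::var(apply(n3, 2, median)), 0)
})

test_that("quantile normalization with ties matches the rank-average oracle", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rpois(50 * 4, 3), ncol = 4,
                dimnames = list(paste0("g", 1:50), paste0("L", 1:4)))
    cm <- quantile_normalize(toy_count_matrix(m))
    norm <- unname(as.matrix(cm$normalized[-1]))
    expect_equal(norm, unname(qn_oracle(m)), tolerance = 1e-10)
    # tied entries within a lane share one normalized value
    for (j in seq_len(ncol(m))) {
      tied <- split(norm[, j], m[, j])
      expect_true(all(vapply(tied, function(v) diff(range(v)) < 1e-12,
                             logical(1))))
    }
  }
})

test_that("single-lane normalization is a warning no-op", {
  m <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(paste0("g", 1:3), "L1"))
  expect_warning(cm <- quantile_normalize(toy_count_matrix(m)), "no-op")
  expect_equal(unname(as.matrix(cm$normalized[-1])[, 1]), c(1, 2, 3))
})

test_that("depth arithmetic and bin assignment follow the coverage definition", {
  # 100 reads of 50 bp on a 1000 bp gene = 5X; all replicates equal
  counts <- rbind(g1 = rep(100L, 3), g2 = rep(0L, 3))
  cm <- toy_count_matrix(counts, tissue = rep("shoot", 3),
                         condition = rep("trt", 3), contrast = rep("c", 3))
  ann <- tibble::tibble(gene_id = c("g1", "g2"), length = c(1000, 1000))
  prof <- depth_profile(cm, ann, read_length = 50)
  expect_equal(prof$median_depth[prof$gene_id == "g1"], 5)
  bins <- depth_bins(prof)
  expect_equal(as.character(bins$bin[bins$n > 0 & grepl("5", bins$bin)][1]),
               "(2x,5x]")
  expect_equal(bins$n[bins$bin == "0x"], 1L)
  # partition property: bins sum to gene count
  expect_equal(sum(bins$n), 2L)
  expect_error(depth_bins(prof, edges = c(5, 2)),
               class = "droughtseq_config_error")
})

test_that("median depth uses the middle order statistic across replicates", {
  counts <- rbind(g1 = c(10L, 20L, 90L))
  cm <- toy_count_matrix(counts, tissue = rep("root", 3),
                         condition = rep("trt", 3), contrast = rep("c", 3))
  ann <- tibble::tibble(gene_id = "g1", length = 100)
  prof <- depth_profile(cm, ann, read_length = 50)
  expect_equal(prof$median_depth, 20 * 50 / 100)
  # raw-count mode bypasses the length scaling
  prof_raw <- depth_profile(cm, ann, mode = "raw_count")
  expect_equal(prof_raw$median_depth, 20)
})

test_that("replicate correlations report both Spearman and Pearson", {
  set.seed(2)
  base <- rpois(200, 50)
  m <- cbind(L1 = base + rpois(200, 5), L2 = base + rpois(200, 5),
             L3 = base + rpois(200, 5))
  rownames(m) <- paste0("g", 1:200)
  cm <- toy_count_matrix(m, tissue = rep("shoot", 3),
                         condition = rep("trt", 3), contrast = rep("c", 3))
  rc <- replicate_correlation(cm)
  expect_equal(nrow(rc), 3L)
  expect_true(all(c("spearman", "pearson") %in% names(rc)))
  expect_true(all(rc$spearman > 0.9))
})
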