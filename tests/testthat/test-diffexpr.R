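# Balanced NB two-group fixture with known dispersion.
nb_fixture <- function(n_genes, mean, phi, n = 3, lfc = NULL, seed = 1) {
  set.seed(seed)
  mu <- rep(mean, n_genes)
  trt_mu <- if (is.null(lfc)) mu else mu * 2^lfc
  draw <- function(m) {
    if (phi > 0) matrix(rnbinom(n_genes * n, mu = m, size = 1 / phi), ncol = n)
    else matrix(rpois(n_genes * n, m), ncol = n)
  }
  two_group_cm(draw(trt_mu), draw(mu))
}

test_that("contrast definition enforces replication and disjointness", {
  cm <- nb_fixture(10, 20, 0.1)
  con <- define_contrast(cm, "shoot", "trt", "ctl")
  expect_length(con$treat_lanes, 3L)
  expect_error(define_contrast(cm, "shoot", "trt", "missing"),
               class = "droughtseq_design_error")
})

test_that("common dispersion is recovered from simulated counts", {
  # Poisson data: estimated phi collapses toward zero
  cm0 <- nb_fixture(5000, 30, 0, seed = 7)
  con <- define_contrast(cm0, "shoot", "trt", "ctl")
  d0 <- estimate_common_dispersion(cm0, con)
  expect_lt(d0$phi, 0.01)
  # NB data at phi = 0.2
  cm2 <- nb_fixture(5000, 30, 0.2, seed = 8)
  d2 <- estimate_common_dispersion(cm2, define_contrast(cm2, "shoot", "trt", "ctl"))
  expect_true(d2$phi > 0.15 && d2$phi < 0.25)
})

test_that("dispersion estimate agrees with the conditional-ML reference", {
  cm <- nb_fixture(2000, 40, 0.15, seed = 3)
  con <- define_contrast(cm, "shoot", "trt", "ctl")
  fit <- estimate_common_dispersion(cm, con)
  y <- as.matrix(cm$counts[-1])
  grp <- factor(rep(c("T", "C"), each = 3))
  d <- edgeR::DGEList(counts = y, group = grp)
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(fit$phi, d$common.dispersion, tolerance = 0.05)
})

test_that("degenerate flat-likelihood input still returns a finite dispersion", {
  m <- matrix(5L, nrow = 4, ncol = 6,
              dimnames = list(paste0("g", 1:4), NULL))
  cm <- two_group_cm(m[, 1:3], m[, 4:6])
  con <- define_contrast(cm, "shoot", "trt", "ctl")
  fit <- estimate_common_dispersion(cm, con)
  expect_true(is.finite(fit$phi) && fit$phi >= 0)
  zero <- two_group_cm(matrix(0L, 2, 3), matrix(0L, 2, 3))
  expect_error(
    estimate_common_dispersion(zero, define_contrast(zero, "shoot", "trt", "ctl")),
    class = "droughtseq_design_error"
  )
})

test_that("exact test handles null and boundary genes by convention", {
  m_trt <- rbind(g_null = c(10L, 10L, 10L), g_zero = c(0L, 0L, 0L),
                 g_hot = c(10L, 10L, 10L))
  m_ctl <- rbind(g_null = c(10L, 10L, 10L), g_zero = c(0L, 0L, 0L),
                 g_hot = c(0L, 0L, 0L))
  cm <- two_group_cm(m_trt, m_ctl)
  con <- define_contrast(cm, "shoot", "trt", "ctl")
  fit <- exact_test(cm, con, 0)
  tbl <- tidy(fit)
  # perfectly balanced gene: p = 1, logFC = 0
  expect_equal(tbl$pvalue[tbl$gene_id == "g_null"], 1)
  expect_equal(tbl$logFC[tbl$gene_id == "g_null"], 0)
  # zero-total gene: p = 1, logFC = 0 by convention
  expect_equal(tbl$pvalue[tbl$gene_id == "g_zero"], 1)
  expect_equal(tbl$logFC[tbl$gene_id == "g_zero"], 0)
  # all-mass-on-one-side gene at phi = 0: conditional binomial, outcomes at
  # most as probable as (30, 0) are y = 0 and y = 30, each at (1/2)^30
  expect_equal(tbl$pvalue[tbl$gene_id == "g_hot"], 2 * 0.5^30)
})

test_that("phi -> 0 exact test converges to the conditional binomial test", {
  # one gene, unequal split 20 vs 10 over 3+3 lanes
  m_trt <- rbind(g = c(8L, 6L, 6L))
  m_ctl <- rbind(g = c(4L, 3L, 3L))
  cm <- two_group_cm(m_trt, m_ctl)
  con <- define_contrast(cm, "shoot", "trt", "ctl")
  p0 <- tidy(exact_test(cm, con, 0))$pvalue
  # binomial oracle: sum of outcomes at most as probable as 20 of 30 at 1/2
  probs <- dbinom(0:30, 30, 0.5)
  p_oracle <- sum(probs[probs <= probs[21] * (1 + 1e-10)])
  expect_equal(p0, p_oracle, tolerance = 1e-12)
  p_small <- tidy(exact_test(cm, con, 1e-8))$pvalue
  expect_equal(p_small, p_oracle, tolerance = 1e-4)
})

test_that("exact test p matches a conditional Monte-Carlo simulation", {
  # unconditional NB draws binned by total: the empirical conditional
  # frequency of partitions at most as frequent as the observed one is an
  # implementation-independent estimate of the exact p
  phi <- 0.2; mean <- 5; n <- 3
  cases <- list(c(20L, 10L), c(22L, 6L), c(14L, 14L))
  set.seed(99)
  draws <- matrix(rnbinom(5e5 * 2 * n, mu = mean, size = 1 / phi), ncol = 2 * n)
  s1 <- rowSums(draws[, 1:n]); s2 <- rowSums(draws[, (n + 1):(2 * n)])
  tot <- s1 + s2
  for (cs in cases) {
    y1 <- cs[1]; t <- y1 + cs[2]
    cond <- s1[tot == t]
    expect_gt(length(cond), 2000)
    freq <- table(cond) / length(cond)
    f_obs <- freq[[as.character(y1)]]
    # bracket the oracle: outcomes clearly less probable than the observed
    # one bound p from below, possibly-less-probable ones from above
    tol <- 6 / sqrt(f_obs * length(cond))
    p_lo <- sum(freq[freq <= f_obs * (1 - tol)])
    p_hi <- sum(freq[freq <= f_obs * (1 + tol)])
    se <- sqrt(p_hi * (1 - p_hi) / length(cond))
    p_exact <- droughtseq:::nb_exact_pval(y1, t, n, n, phi)
    expect_gte(p_exact, p_lo - 3 * se)
    expect_lte(p_exact, p_hi + 3 * se)
  }
})

test_that("exact test is antisymmetric under group-label swap", {
  cm <- nb_fixture(200, 30, 0.1, lfc = rep(c(0, 1), each = 100), seed = 5)
  con <- define_contrast(cm, "shoot", "trt", "ctl")
  con_swap <- define_contrast(cm, "shoot", "ctl", "trt")
  disp <- estimate_common_dispersion(cm, con)
  f1 <- tidy(exact_test(cm, con, disp))
  f2 <- tidy(exact_test(cm, con_swap, disp))
  expect_equal(f1$pvalue, f2$pvalue, tolerance = 1e-12)
  expect_equal(f1$logFC, -f2$logFC, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "droughtseq_format_error")
  # adjusted >= raw always
  set.seed(1)
  p <- runif(100)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("the three-part DE filter gates on depth, fold change and p", {
  fit <- structure(list(
    table = tibble::tibble(
      gene_id = c("lowdepth", "lowlfc", "highp", "de_up", "de_down"),
      mean_treat = c(10, 100, 100, 200, 25),
      mean_control = c(1, 60, 100, 50, 100),
      logFC = c(3, 0.9, 0, 2, -2),
      pvalue = c(1e-8, 1e-8, 0.9, 1e-8, 1e-8),
      padj = c(1e-6, 1e-6, 0.95, 1e-6, 1e-6)
    ),
    phi = 0.1,
    contrast = list(name = "shoot.trt.vs.ctl", tissue = "shoot",
                    treatment = "trt", control = "ctl")
  ), class = "de_fit")
  prof <- tidyr::expand_grid(
    gene_id = fit$table$gene_id,
    group = c("shoot.trt", "shoot.ctl")
  )
  prof$median_depth <- ifelse(prof$gene_id == "lowdepth", 0.5, 5)
  res <- apply_de_filters(fit, prof)
  expect_setequal(res$gene_id[res$is_de], c("de_up", "de_down"))
  expect_equal(res$direction[res$gene_id == "de_up"], "up")
  expect_equal(res$direction[res$gene_id == "de_down"], "down")
  # depth gate excludes regardless of p; lfc gate excludes strong p too
  expect_false(res$is_de[res$gene_id == "lowdepth"])
  expect_false(res$is_de[res$gene_id == "lowlfc"])
  expect_equal(res$direction[!res$is_de], rep("ns", 3))
})

test_that("exact test p-values match edgeR on a shared fixture", {
  # lanes are permutations of one value pool, so library sizes are exactly
  # equal and edgeR's pseudo-counts reduce to the raw counts
  set.seed(12)
  pool <- rnbinom(500, mu = 25, size = 10)
  y <- vapply(1:6, function(j) sample(pool), numeric(500))
  rownames(y) <- paste0("g", 1:500)
  cm <- two_group_cm(y[, 1:3], y[, 4:6])
  con <- define_contrast(cm, "shoot", "trt", "ctl")
  fit <- exact_test(cm, con, 0.1)
  d <- edgeR::DGEList(counts = y, group = rep(c("T", "C"), each = 3))
  d$common.dispersion <- 0.1
  et <- edgeR::exactTest(d, pair = c("C", "T"))
  expect_gt(cor(fit$table$pvalue, et$table$PValue, method = "spearman"), 0.999)
  expect_lt(max(abs(fit$table$pvalue - et$table$PValue)), 0.01)
})

test_that("overlap regions and percentages match hand counts", {
  ov <- overlap_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  shared <- ov$regions[ov$regions$region == "A&B", ]
  expect_equal(shared$n, 2L)
  expect_setequal(ov$regions$region, c("A", "B", "A&B"))
  pw <- ov$pairwise
  expect_equal(pw$n_shared, 2L)
  expect_equal(pw$pct_of_union, round(100 * 2 / 4, 1))
  expect_equal(pw$pct_of_a, round(100 * 2 / 3, 1))
  # identical lists = 100% overlap
  ov2 <- overlap_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ov2$pairwise$pct_of_union, 100)
  expect_error(overlap_sets(list(A = "a")), class = "droughtseq_design_error")
})

test_that("top-k table ranks regions by absolute fold change", {
  a <- tibble::tibble(gene_id = c("a", "b", "c"), logFC = c(3, -2, 1))
  b <- tibble::tibble(gene_id = c("b", "d"), logFC = c(-2, 5))
  ov <- overlap_sets(list(A = a, B = b), top_k = 1)
  expect_equal(ov$top$gene_id[ov$top$region == "A"], "a")
  expect_equal(ov$top$gene_id[ov$top$region == "B"], "d")
  expect_equal(ov$top$gene_id[ov$top$region == "A&B"], "b")
})
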