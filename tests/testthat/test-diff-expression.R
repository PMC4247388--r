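make_counts <- function(mat) {
  tibble::as_tibble(cbind(
    tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(mat)))),
    tibble::as_tibble(mat, .name_repair = "minimal")))
}

fixture_counts <- function(n_genes = 50, n_samples = 4, seed = 51) {
  set.seed(seed)
  mat <- matrix(rnbinom(n_genes * n_samples, mu = exp(runif(n_genes * n_samples, 2, 8)),
                        size = 5), n_genes, n_samples)
  colnames(mat) <- paste0("s", seq_len(n_samples))
  mat
}

test_that("identical samples get unit TMM factors", {
  mat <- fixture_counts(n_samples = 1)
  mat <- cbind(mat, mat, mat)[, 1:3]
  colnames(mat) <- paste0("s", 1:3)
  f <- tmm_factors(mat)
  expect_equal(f$norm_factor, rep(1, 3))
})

test_that("a pure library-size difference contributes nothing to TMM", {
  a <- fixture_counts(n_samples = 1, seed = 52)
  mat <- cbind(a, 2 * a)
  colnames(mat) <- c("sA", "sB")
  f <- tmm_factors(mat)
  expect_equal(f$norm_factor[1], f$norm_factor[2], tolerance = 1e-12)
})

test_that("TMM factors match the direct-formula oracle to 1e-9", {
  mat <- fixture_counts(n_genes = 50, n_samples = 4, seed = 53)
  got <- tmm_factors(mat)$norm_factor
  want <- unname(oracle_tmm(mat))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("log-CPM follows its closed form and is monotone in counts", {
  mat <- matrix(c(0L, 10L, 100L, 1000L), 4, 1,
                dimnames = list(NULL, "s1"))
  factors <- tibble::tibble(sample_id = "s1", lib_size = 1e6, norm_factor = 1)
  lc <- log_cpm(mat, factors)$s1
  expect_equal(lc, log2((c(0, 10, 100, 1000) + 0.5) / (1e6 + 1) * 1e6))
  expect_true(all(diff(lc) > 0))
  # doubling counts and library sizes is invariant up to the pseudocount
  mat2 <- mat * 2L
  factors2 <- tibble::tibble(sample_id = "s1", lib_size = 2e6, norm_factor = 1)
  lc2 <- log_cpm(mat2, factors2)$s1
  expect_equal(lc2[3:4], lc[3:4], tolerance = 1e-3)
})

test_that("the unmoderated contrast equals the textbook two-sample t", {
  set.seed(54)
  mat <- matrix(rnorm(12, mean = 5), 2, 6)
  colnames(mat) <- paste0("s", 1:6)
  rownames(mat) <- c("gA", "gB")
  labels <- tibble::tibble(sample_id = colnames(mat),
                           group = rep(c("focal", "other"), each = 3))
  got <- group_contrast(mat, labels, moderation = "none")
  for (i in 1:2) {
    want <- oracle_two_sample_t(mat[i, 1:3], mat[i, 4:6])
    expect_equal(got$t[i], want$t)
    expect_equal(got$df[i], want$df)
    expect_equal(got$p_raw[i], want$p)
    expect_equal(got$logFC[i], mean(mat[i, 1:3]) - mean(mat[i, 4:6]))
  }
})

test_that("identical groups give logFC 0 and p 1; zero variance errors without moderation", {
  mat <- matrix(rep(c(3, 7), each = 6), 2, 6, byrow = TRUE)
  colnames(mat) <- paste0("s", 1:6)
  labels <- tibble::tibble(sample_id = colnames(mat),
                           group = rep(c("focal", "other"), each = 3))
  expect_error(group_contrast(mat, labels, moderation = "none"),
               "zero within-group variance")
  got <- group_contrast(mat, labels, moderation = "shrink", prior_var = 1)
  expect_equal(got$logFC, c(0, 0))
  expect_equal(got$p_raw, c(1, 1))
})

test_that("moderation converges to the plain t as the prior df vanishes", {
  set.seed(55)
  mat <- matrix(rnorm(24, 5), 4, 6)
  colnames(mat) <- paste0("s", 1:6)
  labels <- tibble::tibble(sample_id = colnames(mat),
                           group = rep(c("focal", "other"), each = 3))
  plain <- group_contrast(mat, labels, moderation = "none")
  shrunk <- group_contrast(mat, labels, moderation = "shrink",
                           prior_df = 1e-9, prior_var = 1)
  expect_equal(shrunk$t, plain$t, tolerance = 1e-6)
  expect_equal(shrunk$p_raw, plain$p_raw, tolerance = 1e-6)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(56)
  for (i in 1:200) {
    p <- runif(sample(2:30, 1))
    got <- bh_adjust(p)
    expect_equal(got, oracle_bh(p), label = sprintf("vector %d", i))
    # monotone non-decreasing in rank; rejection sets nest across levels
    expect_true(all(diff(got[order(p)]) >= -1e-15))
  }
})

test_that("the B threshold is the log-odds transform rounded up at 1e-3", {
  expect_equal(b_threshold_from_probability(0.5), 0)
  expect_equal(b_threshold_from_probability(0.95), 2.945)
  expect_error(b_threshold_from_probability(1), "in \\(0, 1\\)")
  for (p in seq(0.05, 0.95, by = 0.05)) {
    b <- b_threshold_from_probability(p)
    expect_gte(1 / (1 + exp(-b)), p)
    expect_lt(b - log(p / (1 - p)), 1e-3)
  }
})

test_that("the triple threshold flags and annotates the first failing condition", {
  rec <- tibble::tibble(
    gene_id = c("grb14-like", "near_lfc", "near_b", "low_padj"),
    logFC = c(5.21, 1.99, 3, 3),
    p_adj = c(5.20e-6, 1e-9, 0.01, 0.2),
    B = c(10.73, 20, 2.944, 10))
  got <- call_differential(rec)
  expect_equal(got$flagged, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(got$reason, c(NA, "lfc", "B", "padj"))
  expect_error(call_differential(rec[, c("gene_id", "logFC", "p_adj")]),
               "check_b")
  no_b <- call_differential(rec[, c("gene_id", "logFC", "p_adj")],
                            check_b = FALSE)
  expect_equal(no_b$flagged, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("fold enrichment and Fisher p behave on worked examples", {
  background <- sprintf("b%03d", 1:100)
  gene_list <- background[1:10]
  term_map <- tibble::tibble(
    term = "T1",
    gene_id = c(background[1:3], background[50:51]))  # 5 in bg, 3 in list
  res <- term_enrichment(gene_list, term_map, background)
  expect_equal(res$fold_enrichment, 6.0)
  expect_equal(res$list_count, 3L)
  # zero overlap: fold 0, one-sided p 1
  term0 <- tibble::tibble(term = "T0", gene_id = background[90:99])
  res0 <- term_enrichment(gene_list, term0, background)
  expect_equal(res0$fold_enrichment, 0)
  expect_equal(res0$fisher_p, 1)
  expect_error(term_enrichment(gene_list, term_map, character(0)), "non-empty")
  expect_error(term_enrichment("zzz", term_map, background), "subset")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration on small tables", {
  set.seed(57)
  for (i in 1:30) {
    N <- sample(10:50, 1)
    n <- sample(2:(N - 1), 1)
    K <- sample(1:N, 1)
    background <- sprintf("b%02d", 1:N)
    gene_list <- sample(background, n)
    term_map <- tibble::tibble(term = "T", gene_id = sample(background, K))
    res <- term_enrichment(gene_list, term_map, background)
    k <- res$list_count
    expect_equal(res$fisher_p, oracle_hyper_tail(k, K, n, N),
                 label = sprintf("table %d", i))
  }
})

test_that("the full pipeline recovers a strong planted effect and tidies", {
  samp <- tibble::tibble(sample_id = paste0("s", 1:8),
                         species_id = rep(c("bw", "ot"), each = 4),
                         group = rep(c("focal", "other"), each = 4))
  sim <- simulate_counts(120, samp, 2e5, dispersion = 0.01,
                         planted_effects = c(g0007 = 5, g0019 = -5), seed = 58)
  fit <- de_analysis(sim$counts, samp)
  rec <- tidy(fit)
  expect_s3_class(rec, "tbl_df")
  expect_true(all(c("g0007", "g0019") %in% rec$gene_id[rec$flagged]))
  g <- glance(fit)
  expect_equal(g$n_genes, 120L)
  expect_equal(g$n_flagged, sum(rec$flagged))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "120 genes")
})
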