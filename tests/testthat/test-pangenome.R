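det_matrix <- function(n_det, n_elig = 14, gene_id = "g1") {
  m <- matrix(FALSE, 1, n_elig,
              dimnames = list(gene_id, sprintf("s%02d", 1:n_elig)))
  if (n_det > 0) m[1, seq_len(n_det)] <- TRUE
  m
}

expr_matrix <- function(n_expr, n_samples = 14, gene_id = "g1") {
  m <- matrix(FALSE, 1, n_samples,
              dimnames = list(gene_id, sprintf("s%02d", 1:n_samples)))
  if (n_expr > 0) m[1, seq_len(n_expr)] <- TRUE
  m
}

test_that("the dispensable filter chain applies all three thresholds", {
  elig <- sprintf("s%02d", 1:9)
  # detected 4, absent 5, expressed 6: dispensable
  c1 <- call_dispensable(det_matrix(4, 9), expr_matrix(6, 9), elig)
  expect_true(c1$dispensable)
  # detected everywhere: core
  c2 <- call_dispensable(det_matrix(9, 9), expr_matrix(9, 9), elig)
  expect_false(c2$dispensable)
  # expression filter: 5 expressed samples is one too few
  c3 <- call_dispensable(det_matrix(4, 9), expr_matrix(5, 9), elig)
  expect_false(c3$dispensable)
  # detected 3 or absent 4 fail the detection filters
  c4 <- call_dispensable(det_matrix(3, 9), expr_matrix(9, 9), elig)
  expect_false(c4$dispensable)
  c5 <- call_dispensable(det_matrix(5, 9), expr_matrix(9, 9), elig)
  expect_false(c5$dispensable)  # absent only 4
  expect_error(call_dispensable(det_matrix(4, 8), expr_matrix(6, 8),
                                sprintf("s%02d", 1:8)),
               "need at least 9 eligible samples")
})

test_that("raising the detection thresholds never enlarges the set", {
  set.seed(61)
  n_g <- 40; n_s <- 14
  det <- matrix(runif(n_g * n_s) < 0.5, n_g, n_s,
                dimnames = list(sprintf("g%02d", 1:n_g),
                                sprintf("s%02d", 1:n_s)))
  expr <- matrix(TRUE, n_g, n_s, dimnames = dimnames(det))
  elig <- colnames(det)
  base <- call_dispensable(det, expr, elig, threshold_config())
  harder <- call_dispensable(det, expr, elig,
                             threshold_config(min_detect_samples = 6))
  expect_true(all(base$dispensable | !harder$dispensable))
  harder2 <- call_dispensable(det, expr, elig,
                              threshold_config(min_absent_samples = 7))
  expect_true(all(base$dispensable | !harder2$dispensable))
})

test_that("cassette clustering groups rank-adjacent dispensable genes", {
  g <- toy_genome(chrom_len = 12000,
                  gene_bounds = lapply(seq(500, 10500, by = 1000),
                                       function(s) c(s, s + 600L)))
  ids <- g$genes$gene_id  # 11 genes, ranks 1..11
  mk_calls <- function(disp_ids) {
    data.frame(gene_id = ids, n_samples_detected = 5L,
               n_samples_absent = 6L, n_samples_expressed = 8L,
               dispensable = ids %in% disp_ids, stringsAsFactors = FALSE)
  }
  cc <- cluster_cassettes(mk_calls(ids[5:7]), g)
  expect_equal(nrow(cc$cassettes), 1)
  expect_equal(cc$cassettes$genes, paste(ids[5:7], collapse = ","))
  expect_equal(cc$cassettes$start, g$genes$start[5])
  expect_equal(cc$cassettes$end, g$genes$end[7])
  cc2 <- cluster_cassettes(mk_calls(ids[c(5, 9)]), g)
  expect_equal(nrow(cc2$cassettes), 0)
  expect_setequal(cc2$singletons, ids[c(5, 9)])
  # partition property: every dispensable gene in exactly one cassette or
  # the singleton list
  set.seed(62)
  for (i in 1:5) {
    disp <- sample(ids, 5)
    cc3 <- cluster_cassettes(mk_calls(disp), g)
    in_cas <- unlist(strsplit(cc3$cassettes$genes, ","))
    expect_setequal(c(in_cas, cc3$singletons), disp)
    expect_false(anyDuplicated(c(in_cas, cc3$singletons)) > 0)
  }
})

test_that("depletion ratio separates absent, partial and present genes", {
  g <- toy_genome(chrom_len = 30000,
                  gene_bounds = lapply(seq(1000, 26000, by = 2500),
                                       function(s) c(s, s + 900L)))
  ids <- g$genes$gene_id
  depth <- matrix(10, length(ids), 1, dimnames = list(ids, "s1"))
  depth[1, 1] <- 0; depth[2, 1] <- 5
  gsm <- toy_gsm(depth * 9L, depth = depth)
  d0 <- depletion_profile(gsm, g, ids[1], "s1")
  expect_equal(d0$depletion_ratio, 0)
  expect_equal(d0$state, "absent")
  d5 <- depletion_profile(gsm, g, ids[2], "s1")
  expect_equal(d5$depletion_ratio, 0.5)
  expect_equal(d5$state, "partial")
  d10 <- depletion_profile(gsm, g, ids[3], "s1")
  expect_equal(d10$depletion_ratio, 1)
  expect_equal(d10$state, "present")
  # zero baseline: undefined and flagged
  gsm0 <- toy_gsm(depth * 0L, depth = depth * 0)
  du <- depletion_profile(gsm0, g, ids[1], "s1")
  expect_equal(du$state, "undefined")
})

test_that("border estimates need two absent samples and match on identical input", {
  tr <- data.frame(chrom_id = "chr1", start = seq(0, 9800, by = 200),
                   end = seq(200, 10000, by = 200),
                   depth = c(rep(20, 25), rep(0, 10), rep(20, 15)))
  cassette <- list(chrom_id = "chr1", start = 5010, end = 6990)
  expect_error(border_consistency(list(s1 = tr), cassette), "at least 2")
  bc <- border_consistency(list(s1 = tr, s2 = tr), cassette)
  expect_equal(bc$max_deviation, 0)
  expect_true(all(abs(bc$estimates$position[bc$estimates$edge == "start"] -
                        5010) <= 200))
  expect_true(all(abs(bc$estimates$position[bc$estimates$edge == "end"] -
                        6990) <= 200))
})

test_that("the activity contrast matches exact rank-test enumeration", {
  act <- c(a1 = 0.9, a2 = 0.85, a3 = 0.8, a4 = 0.75,
           b1 = 0.5, b2 = 0.45, b3 = 0.4, b4 = 0.35)
  calls <- data.frame(gene_id = names(act),
                      n_samples_detected = 5L, n_samples_absent = 6L,
                      n_samples_expressed = 8L,
                      dispensable = grepl("^a", names(act)),
                      stringsAsFactors = FALSE)
  res <- dispensable_expression_contrast(act, calls)
  # all dispensable above all core, 4 vs 4: exact two-sided p = 2/70
  orc <- oracle_mww(act[1:4], act[5:8])
  expect_equal(res$p_value, 2 / 70)
  expect_equal(res$p_value, orc$p_value)
  expect_equal(res$U, 16)
  expect_gt(res$mean_dispensable, res$mean_core)
  calls$dispensable <- TRUE
  expect_error(dispensable_expression_contrast(act, calls), "non-empty")
})

test_that("the planted activity shift is detected with high power", {
  set.seed(63)
  hits <- replicate(100, {
    disp <- pmin(1, pmax(0, rnorm(50, 0.73, 0.15)))
    core <- pmin(1, pmax(0, rnorm(500, 0.56, 0.15)))
    mww_test(disp, core)$p_value < 0.01
  })
  expect_gte(mean(hits), 0.9)
})
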