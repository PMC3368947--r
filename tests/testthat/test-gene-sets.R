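# small synthetic per-gene count table; counts crafted so statistics are
# finite for any nonempty subset
mk_table <- function(n, ns_mult = 1, seed = 1) {
  set.seed(seed)
  m <- sample(50:150, n, replace = TRUE)           # basepairs per gene
  s_ts <- round(m * 0.5)
  n_ts <- m - s_ts
  s_tv <- round(m * 0.55)
  n_tv <- 2 * m - s_tv
  sSite <- (s_ts + s_tv) / 3
  nsSite <- (n_ts + n_tv) / 3
  df <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                   nsSNV = rpois(n, 2 * ns_mult) + 1,
                   sSNV = rpois(n, 2) + 1,
                   sSite = sSite, nsSite = nsSite,
                   sSite_ts = s_ts / 3, nsSite_ts = n_ts / 3)
  class(df) <- c("gene_table", "data.frame")
  df
}

test_that("permutation p-value is 1 when the statistic cannot differ", {
  tbl <- mk_table(10)
  # identical rows: every partition gives the same pooled statistic
  tbl[, -1] <- lapply(tbl[, -1], function(x) rep(x[1], nrow(tbl)))
  res <- permutation_test(tbl, tbl$gene_id[1:5], tbl$gene_id[6:10],
                          statistic = "rdnsv", n_perm = 200, seed = 4)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed_difference, 0)
})

test_that("exhaustive 3-vs-3 agrees with an independent brute-force oracle", {
  tbl <- mk_table(6, seed = 8)
  set_a <- tbl$gene_id[1:3]
  set_b <- tbl$gene_id[4:6]
  res <- permutation_test(tbl, set_a, set_b, statistic = "Rn_Rs",
                          exhaustive = TRUE)
  # oracle: enumerate all choose(6,3) = 20 partitions by hand
  stat <- function(rows) {
    (sum(rows$nsSNV) / sum(rows$nsSite)) / (sum(rows$sSNV) / sum(rows$sSite))
  }
  d_obs <- stat(tbl[1:3, ]) - stat(tbl[4:6, ])
  picks <- combn(6, 3)
  d_all <- apply(picks, 2, function(ix) {
    stat(tbl[ix, ]) - stat(tbl[-ix, ])
  })
  p_oracle <- mean(abs(d_all) >= abs(d_obs) - 1e-12)
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$observed_difference, d_obs)
  expect_equal(res$n_perm, 20)
  # Monte-Carlo mode approaches the exhaustive value
  mc <- permutation_test(tbl, set_a, set_b, statistic = "Rn_Rs",
                         n_perm = 2000, seed = 99)
  se <- sqrt(p_oracle * (1 - p_oracle) / 2000)
  expect_lt(abs(mc$p_value - p_oracle), 3 * se + 2 / 2001)
})

test_that("permutation test validates inputs and bounds its p-value", {
  tbl <- mk_table(8)
  expect_error(permutation_test(tbl, tbl$gene_id[1:4], tbl$gene_id[3:6]),
               "disjoint")
  expect_error(permutation_test(tbl, c(tbl$gene_id[1:3], "nope"),
                                tbl$gene_id[4:6]), "absent")
  res <- permutation_test(tbl, tbl$gene_id[1:4], tbl$gene_id[5:8],
                          n_perm = 99, seed = 2)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
})

test_that("background quantiles: constant statistic, determinism, power", {
  tbl <- mk_table(60)
  # constant statistic across genes -> degenerate envelope
  tblc <- tbl
  tblc[, -1] <- lapply(tblc[, -1], function(x) rep(x[1], nrow(tblc)))
  env <- background_quantiles(tblc, set_size = 10, n_draws = 50, seed = 5)
  expect_equal(env$q_lower, env$q_upper)
  # seeded reproducibility
  e1 <- background_quantiles(tbl, set_size = 15, n_draws = 10, seed = 11)
  e2 <- background_quantiles(tbl, set_size = 15, n_draws = 10, seed = 11)
  expect_identical(e1$draws, e2$draws)
  expect_error(background_quantiles(tbl, set_size = 100), "universe")
  # a candidate set with depressed nsSNV counts falls below q2.5
  tbl2 <- mk_table(200, seed = 3)
  cand <- tbl2$gene_id[1:40]
  tbl2$nsSNV[1:40] <- pmax(0, round(tbl2$nsSNV[1:40] * 0.2))
  env2 <- background_quantiles(tbl2, set_size = 40, n_draws = 400, seed = 6)
  expect_lt(gene_set_statistic(tbl2, cand), env2$q_lower)
})

test_that("tissue-specific selection ranks by Z-score specificity", {
  tissues <- paste0("t", 1:10)
  expr <- matrix(2^5, nrow = 5, ncol = 10,
                 dimnames = list(sprintf("g%02d", 1:5), tissues))
  # g01: 8-fold higher in target tissue t1 -> specific there
  expr["g01", "t1"] <- 2^8
  # g03: specific in both target tissues -> outranks g01
  expr["g03", c("t1", "t2")] <- 2^8
  # g04: specific in a non-target tissue only
  expr["g04", "t9"] <- 2^8
  # g02, g05: constant -> specific nowhere (logged, not an error)
  expect_message(
    gs <- select_tissue_specific(expr, target_tissues = c("t1", "t2"), K = 3),
    "zero-variance")
  rk <- gs$ranking
  expect_equal(rk$gene_id[1:2], c("g03", "g01"))
  expect_equal(rk$n_target[rk$gene_id == "g03"], 2)
  expect_equal(rk$n_target[rk$gene_id == "g01"], 1)
  expect_equal(rk$n_total[rk$gene_id == "g02"], 0)
  expect_equal(rk$n_target[rk$gene_id == "g04"], 0)
  expect_true(all(c("g03", "g01", "g04") %in% gs$genes))
  expect_error(select_tissue_specific(expr, "t99"), "not in matrix")
  expect_error(select_tissue_specific(expr - 40, "t1"), "positive")
})

test_that("disjoint_gene_sets removes shared members from both sets", {
  expect_message(d <- disjoint_gene_sets(c("a", "b", "c"), c("c", "d")),
                 "removing 1")
  expect_equal(d$set_a, c("a", "b"))
  expect_equal(d$set_b, "d")
  expect_equal(d$shared, "c")
})
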