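test_that("hypergeometric tail matches forced cases and the enumeration oracle", {
  expect_equal(hypergeom_tail(30, 10, 5, 0), 1)        # "at least 0"
  expect_equal(hypergeom_tail(10, 10, 4, 4), 1)        # every draw marked
  expect_equal(hypergeom_tail(20, 6, 7, 4),
               enum_hypergeom_tail(20, 6, 7, 4), tolerance = 1e-12)
  # independent library route as a second cross-check
  expect_equal(hypergeom_tail(20, 6, 7, 4),
               stats::phyper(3, 6, 14, 7, lower.tail = FALSE),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:25) {
    N <- sample(5:200, 1); M <- sample(0:N, 1); n <- sample(0:N, 1)
    m <- sample(0:min(M, n), 1)
    expect_equal(hypergeom_tail(N, M, n, m),
                 stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric tail is monotone in m and symmetric in (M, n)", {
  N <- 40; M <- 12; n <- 9
  p <- vapply(0:min(M, n), function(m) hypergeom_tail(N, M, n, m),
              numeric(1))
  expect_true(all(diff(p) < 0))
  set.seed(9)
  for (i in 1:20) {
    N <- sample(10:80, 1); M <- sample(1:N, 1); n <- sample(1:N, 1)
    m <- sample(0:min(M, n), 1)
    expect_equal(hypergeom_tail(N, M, n, m), hypergeom_tail(N, n, M, m),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric tail validates its counts", {
  expect_error(hypergeom_tail(10, 12, 3, 1), "M exceeds N")
  expect_error(hypergeom_tail(10, 5, 12, 1), "n exceeds N")
  expect_error(hypergeom_tail(10, 5, 5, 6), "m exceeds")
  expect_error(hypergeom_tail(10.5, 5, 5, 2), "integers")
})

test_that("BH adjustment reproduces the hand-derived step-up vectors", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.04, 0.8)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("BH agrees with an independent step-up evaluation and dominates Bonferroni", {
  set.seed(13)
  for (i in 1:30) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, stepup_bh(p), tolerance = 1e-12)
    expect_true(all(q <= 1) && all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))     # monotone in p order
    # BH rejections at level Q contain the Bonferroni rejections
    expect_true(all(q[p * length(p) < 0.05] < 0.05))
  }
})

test_that("functional enrichment counts follow the population definitions", {
  # 40 peptides, 10 in category s, activity F on 8 overall, 6 of them in s
  d <- toy_dataset(40, in_s = 10, f_ids = c(1:6, 11:12))
  res <- functional_enrichment(d, d, "TM", 1)
  row <- res[res$key == "1" & res$activity == "F", ]
  expect_equal(unlist(row[c("N", "M", "n", "m")]),
               c(N = 40, M = 8, n = 10, m = 6))
  expect_equal(row$p, stats::phyper(5, 8, 32, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # M = 0 activities give p = 1
  expect_true(all(res$p[res$M == 0] == 1))
  # q is a BH adjustment over the full (s, f) batch
  expect_equal(res$q, bh_adjust(res$p))
})

test_that("categories below min_category in the original set are not tested", {
  d <- toy_dataset(40, in_s = 4, f_ids = 1:4)
  res <- functional_enrichment(d, d, "TM", 1, enrich_config())
  expect_false("1" %in% res$key)            # 4 members < 5
  expect_true("2" %in% res$key)
  # the filter uses the original dataset, not the representative set
  d2 <- toy_dataset(40, in_s = 8, f_ids = 1:4)
  reps2 <- subset_dataset(d2, d2$peptides$id[-(1:7)])
  res2 <- functional_enrichment(reps2, d2, "TM", 1)
  expect_true("1" %in% res2$key)
})

test_that("structural enrichment restricts the population to annotated peptides", {
  # 35 peptides, 30 TM-annotated; 5 in s; F on 12 annotated + 2 unannotated;
  # 4 of the 5 in s have F
  d <- toy_dataset(35, in_s = 5, f_ids = c(1:4, 6:13, 31:32),
                   annotated = 30)
  res <- structural_enrichment(d, d, "TM", 1)
  row <- res[res$key == "1" & res$activity == "F", ]
  expect_equal(unlist(row[c("N", "M", "n", "m")]),
               c(N = 30, M = 5, n = 12, m = 4))
  expect_equal(row$p, stats::phyper(3, 5, 25, 12, lower.tail = FALSE),
               tolerance = 1e-12)
  # m = n single-branch case agrees with the oracle
  d2 <- toy_dataset(20, in_s = 6, f_ids = 1:3)
  row2 <- structural_enrichment(d2, d2, "TM", 1)
  row2 <- row2[row2$key == "1" & row2$activity == "F", ]
  expect_equal(unlist(row2[c("n", "m")]), c(n = 3, m = 3))
  expect_equal(row2$p, enum_hypergeom_tail(20, 6, 3, 3), tolerance = 1e-12)
})

test_that("with equal populations the two directions give identical raw p", {
  d <- toy_dataset(30, in_s = 8, f_ids = c(1:5, 9:12))  # fully annotated
  rf <- functional_enrichment(d, d, "TM", 1)
  rs <- structural_enrichment(d, d, "TM", 1)
  key <- function(r) paste(r$key, r$activity)
  rs <- rs[match(key(rf), key(rs)), ]
  expect_equal(rf$N, rs$N)                   # populations coincide
  expect_equal(rf$p, rs$p, tolerance = 1e-12)
})

test_that("mutual arrows are a pure function of the two q-values", {
  g <- generate_amp_dataset(null_config(4001, lift = 5))
  arr <- arrows_on_dataset(g$dataset)
  Q <- enrich_config()$Q
  expect_identical(arr$arrow,
                   ifelse(arr$q_fun < Q & arr$q_struct < Q, "<->",
                          ifelse(arr$q_fun < Q, "->",
                                 ifelse(arr$q_struct < Q, "<-", "."))))
  expect_identical(arr$qualifies_table, arr$n_original >= 10)
})

test_that("the sweep recovers a planted association at the 100% column", {
  g <- generate_amp_dataset(null_config(2024, lift = 8))
  sw <- representative_sweep(g$dataset, cluster_config(c(1.0)))
  en <- enrichment_sweep(g$dataset, sw$datasets, "TM")
  planted <- en$mutual[en$mutual$key == "1" & en$mutual$activity == "F", ]
  expect_identical(planted$arrow, "<->")
  # single-threshold input: one column in the arrow matrix
  am <- render_arrow_matrix(en$mutual, drop_empty = FALSE)
  expect_identical(setdiff(names(am),
                           c("scheme", "level1", "level2", "activity")),
                   "100")
})

test_that("scheme without labels raises an informative error", {
  d <- toy_dataset(20, in_s = 6, f_ids = 1:3)
  expect_error(functional_enrichment(d, d, "CATH", 1), "no CATH labels")
})
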