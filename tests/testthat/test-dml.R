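test_that("site qualification requires the coverage floor in every sample", {
  # 4 samples, 5 sites; site 101 exactly at 20x everywhere, 201 has one 19x
  mk <- function(id, covs) set_of(id, "WT", c(101, 201, 301, 401, 501),
                                  n_meth = covs %/% 2,
                                  n_unmeth = covs - covs %/% 2)
  s1 <- mk("a", c(20, 19, 30, 5, 100)); s2 <- mk("b", c(20, 25, 30, 50, 100))
  s3 <- mk("c", c(20, 25, 30, 50, 100)); s4 <- mk("d", c(20, 25, 30, 50, 100))
  cmp <- comparison(list(s1, s2), list(s3, s4), "t_vs_c")
  q <- qualify_sites(cmp, 20L)
  expect_setequal(q$pos, c(101L, 301L, 501L))

  # exhaustive scan oracle over all sites
  covs <- rbind(c(20, 19, 30, 5, 100), c(20, 25, 30, 50, 100),
                c(20, 25, 30, 50, 100), c(20, 25, 30, 50, 100))
  expect_setequal(q$pos, c(101, 201, 301, 401, 501)[
    vapply(1:5, function(j) all(covs[, j] >= 20), logical(1))])
  expect_error(comparison(list(), list(s1)), "non-empty")
})

test_that("group percentages pool counts coverage-weighted", {
  expect_equal(group_percent(0, 10), 0)
  expect_equal(group_percent(c(3, 7), c(7, 3)), 50)
  expect_equal(group_percent(c(5, 5), c(0, 0)), 100)
  expect_error(group_percent(0, 0), "zero total")
})

test_that("Fisher exact p matches exhaustive enumeration and fisher.test", {
  tables <- list(c(18, 2, 2, 18), c(5, 5, 5, 5), c(10, 0, 3, 7),
                 c(1, 9, 9, 1), c(12, 8, 7, 13), c(30, 1, 25, 6))
  for (tb in tables) {
    p <- test_unit_fisher(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p, fisher_brute(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  expect_equal(test_unit_fisher(5, 5, 5, 5), 1)
  expect_warning(p0 <- test_unit_fisher(0, 0, 5, 5), "degenerate")
  expect_equal(p0, 1)
})

test_that("Fisher p is symmetric under group and label swaps", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample(0:20, 4, TRUE)
    p1 <- suppressWarnings(test_unit_fisher(a[1], a[2], a[3], a[4]))
    p2 <- suppressWarnings(test_unit_fisher(a[3], a[4], a[1], a[2]))
    p3 <- suppressWarnings(test_unit_fisher(a[2], a[1], a[4], a[3]))
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("logistic LRT equals the IRLS glm fit and the closed-form deviance", {
  set.seed(4)
  for (i in 1:15) {
    tc <- matrix(sample(1:40, 6, TRUE), ncol = 2)
    cc <- matrix(sample(1:40, 6, TRUE), ncol = 2)
    res <- test_unit_logistic(tc, cc)
    # independent IRLS route
    m <- rbind(tc, cc)
    grp <- factor(rep(c("t", "c"), each = 3))
    fit <- stats::glm(m ~ grp, family = stats::binomial())
    fit0 <- stats::glm(m ~ 1, family = stats::binomial())
    expect_equal(res$statistic, fit0$deviance - fit$deviance,
                 tolerance = 1e-8)
    # deviance identity against the closed-form binomial log-likelihood
    ll <- function(M, U, p) sum(M * log(p)) + sum(U * log(1 - p))
    p_t <- sum(tc[, 1]) / sum(tc); p_c <- sum(cc[, 1]) / sum(cc)
    p_0 <- sum(m[, 1]) / sum(m)
    expect_equal(res$statistic,
                 2 * (ll(sum(tc[, 1]), sum(tc[, 2]), p_t) +
                        ll(sum(cc[, 1]), sum(cc[, 2]), p_c) -
                        ll(sum(m[, 1]), sum(m[, 2]), p_0)),
                 tolerance = 1e-8)
    expect_equal(res$p, stats::pchisq(res$statistic, 1, lower.tail = FALSE))
  }
})

test_that("logistic LRT behaves at the null and agrees with chi-square asymptotics", {
  res <- test_unit_logistic(c(12, 12), c(24, 24))
  expect_lt(abs(res$statistic), 1e-9)
  expect_equal(res$p, 1, tolerance = 1e-6)
  # 1v1 moderate counts: within 10% relative of the pooled chi-square test
  res2 <- test_unit_logistic(c(30, 20), c(18, 32))
  chi <- suppressWarnings(stats::chisq.test(matrix(c(30, 20, 18, 32), 2,
                                                   byrow = TRUE),
                                            correct = FALSE))
  expect_equal(res2$p, chi$p.value, tolerance = 0.1)
  expect_warning(r0 <- test_unit_logistic(c(0, 0), c(5, 5)), "zero coverage")
  expect_equal(r0$p, 1)
})

test_that("BH adjustment matches the hand example and the brute-force oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(numeric(0)), numeric(0))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (n in c(1, 7, 50, 200)) {
    p <- runif(n)^2
    q <- adjust_bh(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    # monotone non-decreasing when sorted by p
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("DM calling uses inclusive boundaries and exclusive statuses", {
  cfg <- analysis_config()
  expect_equal(call_dm(-25.0, 0.01, cfg), "hypo")
  expect_equal(call_dm(-24.9, 0.001, cfg), "ns")
  expect_equal(call_dm(30, 0.001, cfg), "hyper")
  expect_equal(call_dm(-30, 0.011, cfg), "ns")
  set.seed(6)
  d <- runif(200, -100, 100); q <- runif(200)
  st <- call_dm(d, q, cfg)
  expect_true(all(st[d < 0] != "hyper") && all(st[d > 0] != "hypo"))
  expect_true(all(st %in% c("hypo", "hyper", "ns")))
})

test_that("state classification partitions [0, 100] with 20 partial and 80 high", {
  expect_equal(classify_state(50), "partial")
  expect_equal(classify_state(80), "high")
  expect_equal(classify_state(19.999), "unmethylated")
  expect_equal(classify_state(20), "partial")
  expect_error(classify_state(101), "\\[0, 100\\]")
  x <- seq(0, 100, by = 0.25)
  st <- classify_state(x)
  expect_true(all(st %in% c("unmethylated", "partial", "high")))
  expect_equal(st, ifelse(x >= 80, "high",
                          ifelse(x >= 20, "partial", "unmethylated")))
})

test_that("identical groups give zero differences and no calls", {
  set.seed(7)
  s <- set_of("x", "WT", 1:50 * 100, rbinom(50, 30, 0.5), 30)
  s2 <- meth_call_set("y", "WT", s$calls)
  dm <- run_site_dml(comparison(s, s2, "same_vs_same"))
  qual <- dm[status != "unqualified"]
  expect_true(nrow(qual) > 0)
  expect_equal(qual$diff, rep(0, nrow(qual)))
  expect_true(all(qual$status == "ns"))
})

test_that("planted site losses are recovered and null data yields almost no calls", {
  set.seed(8)
  n <- 2000
  pos <- sort(sample(1e6, n))
  level <- runif(n, 0.55, 0.95)
  planted <- sort(sample(n, 150))
  mk_group <- function(ids, lev) lapply(ids, function(id) {
    cov <- 1L + rnbinom(n, size = 5, mu = 29)
    meth <- rbinom(n, cov, lev)
    set_of(id, "g", pos, meth, cov - meth)
  })
  lev_ko <- level; lev_ko[planted] <- level[planted] - 0.40
  wt <- mk_group(c("w1", "w2", "w3"), level)
  ko <- mk_group(c("k1", "k2", "k3"), lev_ko)
  dm <- run_site_dml(comparison(ko, wt, "ko_vs_wt"))
  expect_identical(attr(dm, "test_method"), "logistic")
  qual <- dm[status != "unqualified"]
  planted_units <- sprintf("chr1:%d", pos[planted])
  hit <- qual[unit %in% planted_units]
  expect_gte(mean(hit$status == "hypo"), 0.90)   # power on -40% sites
  null_part <- qual[!unit %in% planted_units]
  expect_lte(mean(null_part$status != "ns"), 0.01)  # false-call rate
  expect_lte(mean(null_part$q <= 0.01),
             0.01 + 3 * sqrt(0.01 * 0.99 / nrow(null_part)))
})
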