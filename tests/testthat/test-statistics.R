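test_that("Kruskal-Wallis H matches the hand-worked example", {
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/42 (12 + 75) - 21 = 27/7
  kt <- kw_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kt$H, 27 / 7)
  expect_equal(kt$p, stats::pchisq(27 / 7, 1, lower.tail = FALSE))
})

test_that("Kruskal-Wallis applies the tie correction", {
  v <- c(1, 1, 2, 2, 3, 3, 4, 5)
  g <- rep(c("a", "b"), 4)
  kt <- kw_test(v, g)
  # independent tie-corrected computation
  r <- rank(v); n <- length(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  ties <- table(v)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kt$H, h)
})

test_that("degenerate and invalid inputs are handled", {
  kt <- kw_test(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(kt$H, 0)
  expect_equal(kt$p, 1)
  expect_error(kw_test(1:4, rep("a", 4)), "two groups")
  expect_error(kw_test(c(1, NA, 3, 4), rep(c("a", "b"), 2)), "NA")
})

test_that("H is invariant to group label swapping and monotone transforms", {
  set.seed(8)
  v <- rnorm(20); g <- rep(c("a", "b"), 10)
  expect_equal(kw_test(v, g)$H,
               kw_test(v, ifelse(g == "a", "b", "a"))$H)
  expect_equal(kw_test(v, g)$H, kw_test(exp(v), g)$H)
})

test_that("package exact permutation p agrees with an independent oracle", {
  set.seed(12)
  for (rep in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    v <- rnorm(n1 + n2)
    g <- rep(c("a", "b"), c(n1, n2))
    kt <- kw_test(v, g, exact = TRUE)
    expect_lte(abs(kt$p_exact - exact_kw_oracle(v, g)), 0.02)
  }
})

test_that("chi-square p tracks the exact p at n = 8 per group", {
  set.seed(13)
  gaps <- replicate(20, {
    v <- rnorm(16); g <- rep(c("a", "b"), each = 8)
    kt <- kw_test(v, g, exact = TRUE)
    abs(kt$p - kt$p_exact)
  })
  # the chi-square approximation sits between the >=- and >-convention
  # exact p-values; its honest accuracy bound at this size is ~0.06
  expect_lt(max(gaps), 0.06)
})

test_that("eta-squared from H reproduces worked examples and floors at zero", {
  expect_equal(eta_squared_from_h(8.65, 56), (8.65 - 1) / 54)
  expect_equal(round(eta_squared_from_h(8.65, 56), 2), 0.14)
  expect_equal(round(eta_squared_from_h(15.27, 89), 2), 0.16)
  expect_equal(eta_squared_from_h(0.5, 20), 0)       # floored
  expect_error(eta_squared_from_h(3, 2), "more observations")
})

test_that("AUROC matches hand examples and is orientation-free", {
  expect_equal(auroc_stat(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_equal(auroc_stat(c(4, 5, 6), c(1, 2, 3)), 1)   # reported as max(A, 1-A)
  expect_equal(auroc_stat(c(1, 2), c(1, 2)), 0.5)
  expect_equal(auroc_stat(c(1, 3), c(2, 4)), 0.75)
  # ties counted half
  expect_equal(auroc_stat(c(1, 1), c(1, 1)), 0.5)
  expect_gte(auroc_stat(rnorm(10), rnorm(10)), 0.5)
})

test_that("BH adjustment matches an independent step-up oracle", {
  out <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(out$significant))           # p_(4) = 0.04 <= 0.05 rejects all
  expect_equal(out$p_adj, rep(0.04, 4))

  set.seed(14)
  for (rep in 1:20) {
    p <- runif(sample(3:15, 1))^sample(1:3, 1)
    res <- bh_adjust(p, alpha = 0.05)
    expect_equal(res$significant, bh_reject_oracle(p, 0.05))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("observed behavior is the sign of the PD-minus-CN median shift", {
  expect_equal(observed_behavior(c(1, 2, 3), c(4, 5, 6)), "up")
  expect_equal(observed_behavior(c(1, 2, 9), c(0, 1, 2)), "down")
  expect_equal(observed_behavior(c(1, 2, 3), c(0, 2, 7)), "tie")
})

test_that("Spearman correlation matches hand examples and is standardization-invariant", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)

  set.seed(15)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(100 + 5 * x, y)$rho, base$rho)
  expect_equal(spearman_cor(100 + 5 * x, y)$p, base$p)
  # NA pairs dropped
  expect_equal(spearman_cor(c(x, NA), c(y, 1))$n, 30)
})

test_that("biomarker families partition the catalog and reject unknowns", {
  expect_equal(biomarker_family("F0STD"), "acoustic")
  expect_equal(biomarker_family("NPCNT"), "linguistic")
  expect_equal(biomarker_family(c("RHYSTD", "IU")), c("cognitive", "cognitive"))
  expect_error(biomarker_family("BOGUS"), "unknown biomarker")
})

test_that("group_tests corrects within dataset x task x family", {
  set.seed(16)
  n <- 30
  meta <- tibble::tibble(subject_id = sprintf("S%02d", 1:n),
                         group = rep(c("CN", "PD"), each = n / 2))
  mk <- function(bm, shift) tibble::tibble(
    subject_id = meta$subject_id, dataset = "D1", task = "SS", biomarker = bm,
    value = rnorm(n) + ifelse(meta$group == "PD", shift, 0))
  table <- dplyr::bind_rows(mk("F0STD", 3), mk("SILTIME", 0), mk("WORDCNT", 3))
  res <- group_tests(table, meta)
  expect_equal(nrow(res), 3)
  expect_equal(res$n_cn, rep(15, 3))

  # BH within the acoustic family only: the adjusted acoustic p-values are
  # a function of the two acoustic raw p-values alone
  ac <- res[res$family == "acoustic", ]
  oracle <- stats::p.adjust(ac$p, method = "BH")
  expect_equal(ac$p_adj, oracle)
  lg <- res[res$family == "linguistic", ]
  expect_equal(lg$p_adj, lg$p)                 # family of size one
  expect_true(res$significant[res$biomarker == "F0STD"])
})

test_that("group_tests skips single-group cells with a warning", {
  meta <- tibble::tibble(subject_id = c("A", "B"), group = c("CN", "CN"))
  table <- tibble::tibble(subject_id = c("A", "B"), dataset = "D", task = "SS",
                          biomarker = "F0STD", value = c(1, 2))
  expect_warning(res <- group_tests(table, meta), "one group")
  expect_equal(nrow(res), 0)
})

test_that("correlate_severity uses PD subjects only", {
  set.seed(17)
  n <- 40
  meta <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:n),
    group = rep(c("CN", "PD"), each = n / 2),
    updrs3 = c(rep(NA, n / 2), 20 + 1:20))
  table <- tibble::tibble(
    subject_id = meta$subject_id, dataset = "D", task = "SS",
    biomarker = "SILDUR",
    value = ifelse(meta$group == "PD", dplyr::coalesce(meta$updrs3, 0) + rnorm(n, 0, 2),
                   rnorm(n, 100)))   # CN values wild: must not matter
  res <- correlate_severity(table, meta)
  expect_equal(nrow(res), 1)
  expect_equal(res$n, 20)
  expect_gt(res$rho, 0.8)
  expect_equal(res$scale, "updrs3")
})
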