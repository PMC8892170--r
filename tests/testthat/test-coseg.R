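test_that("xor_distance counts differing rows and validates input", {
  expect_equal(xor_distance(c(0, 1, 1, 0, 1), c(1, 1, 0, 0, 1)), 2)
  a <- c(0, 1, 0, 1)
  expect_equal(xor_distance(a, a), 0)
  expect_equal(xor_distance(c(0, 0, 0, 0), c(1, 1, 1, 1)), 4)
  expect_error(xor_distance(c(0, 1), c(0, 1, 1)), "length mismatch")
  expect_error(xor_distance(c(0, 2), c(0, 1)), "0/1")
})

test_that("xor_distance is a metric on random binary triples", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    a <- rbinom(n, 1, 0.3); b <- rbinom(n, 1, 0.5); c <- rbinom(n, 1, 0.7)
    dab <- xor_distance(a, b); dba <- xor_distance(b, a)
    expect_identical(dab, dba)
    expect_true(xor_distance(a, c) <= dab + xor_distance(b, c))
    if (all(a == b)) expect_equal(dab, 0) else expect_gt(dab, 0)
  }
})

test_that("normalized distance follows the selected denominator", {
  expect_equal(normalized_distance(2, 3, 3, 2, "union"), 0.5)
  expect_equal(normalized_distance(2, 3, 3, 2, "min_mac"), 2 / 3)
  expect_equal(normalized_distance(2, 3, 3, 2, "max_mac"), 2 / 3)
  expect_equal(normalized_distance(2, 3, 3, 2, "sum_mac"), 2 / 6)
  # identical non-empty carrier sets -> 0 in every mode
  for (m in c("union", "min_mac", "max_mac", "sum_mac"))
    expect_equal(normalized_distance(0, 4, 4, 4, m), 0)
  # disjoint carrier sets -> maximal Jaccard distance
  expect_equal(normalized_distance(4, 2, 2, 0, "union"), 1)
  # degenerate (both monomorphic) -> NA
  expect_true(is.na(normalized_distance(0, 0, 0, 0, "union")))
  expect_error(normalized_distance(1, 3, 3, 2), "inconsistent")
})

test_that("union-normalized distance is bounded in [0, 1] on random pairs", {
  set.seed(5)
  for (i in 1:100) {
    a <- rbinom(80, 1, runif(1, 0.05, 0.6))
    b <- rbinom(80, 1, runif(1, 0.05, 0.6))
    if (sum(a) + sum(b) == 0) next
    ov <- sum(a & b)
    nd <- normalized_distance(xor_distance(a, b), sum(a), sum(b), ov, "union")
    expect_true(nd >= 0 && nd <= 1)
    if (nd == 0) expect_true(all(a == b) && sum(a) > 0)
  }
})

test_that("exact p-value matches closed-form and enumeration oracles", {
  # closed form: P(overlap = 2) with n = 4, mac 2/2 is 1/6
  expect_equal(exact_pvalue(4, 2, 2, 0), 1 / 6, tolerance = 1e-12)
  # maximal distance is never extreme toward co-segregation
  expect_equal(exact_pvalue(4, 2, 2, 4), 1)
  # perfect co-segregation of two common variants in a large panel
  expect_lt(exact_pvalue(1000, 50, 50, 0), 1e-20)

  # enumeration oracle: place mac_a carriers in all C(n, mac_a) ways
  enum_pvalue <- function(n, mac_a, mac_b, obs) {
    b <- c(rep(1, mac_b), rep(0, n - mac_b))
    sets <- utils::combn(n, mac_a)
    hits <- 0
    for (j in seq_len(ncol(sets))) {
      a <- integer(n); a[sets[, j]] <- 1L
      if (sum(a != b) <= obs) hits <- hits + 1
    }
    hits / ncol(sets)
  }
  for (case in list(c(6, 3, 2, 1), c(6, 3, 2, 3), c(7, 4, 4, 2), c(8, 2, 5, 3))) {
    expect_equal(exact_pvalue(case[1], case[2], case[3], case[4]),
                 enum_pvalue(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
})

test_that("exact p-value is monotone in the observed distance and checks feasibility", {
  n <- 60; ma <- 12; mb <- 20
  xors <- seq(abs(ma - mb), min(ma + mb, 2 * n - ma - mb), by = 2)
  ps <- exact_pvalue(n, ma, mb, xors)
  expect_true(all(diff(ps) >= 0))
  expect_true(all(ps > 0 & ps <= 1))
  expect_equal(ps[length(ps)], 1)
  # wrong parity and out-of-range distances are consistency errors
  expect_error(exact_pvalue(60, 12, 20, 7), "infeasible")
  expect_error(exact_pvalue(60, 12, 20, 40), "infeasible")
  expect_error(exact_pvalue(10, 0, 5, 5), "infeasible")
})

test_that("permutation p-value is seeded, bounded away from zero, and tracks the exact null", {
  a <- rbinom(100, 1, 0.3); b <- a
  p1 <- permutation_pvalue(a, b, 500, seed = 42)
  p2 <- permutation_pvalue(a, b, 500, seed = 42)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 501)
  expect_error(permutation_pvalue(a, b, 50), ">= 100")

  set.seed(9)
  for (i in 1:5) {
    x <- rbinom(120, 1, 0.3); y <- rbinom(120, 1, 0.4)
    pe <- exact_pvalue(120, sum(x), sum(y), sum(x != y))
    pp <- permutation_pvalue(x, y, 2000, seed = i)
    se <- sqrt(pe * (1 - pe) / 2000)
    expect_lt(abs(pp - pe), 4 * se + 1 / 2001)
  }
})

test_that("scan_pairs emits one record per pair with deterministic ordering and calls", {
  set.seed(21)
  n <- 200
  codes <- matrix(rbinom(n * 11, 1, 0.2), n)
  colnames(codes) <- c("r1", paste0("m", 1:10))
  codes[, "m1"] <- codes[, "r1"] # planted perfect-LD pair
  bm <- as_coseg_matrix(codes)
  rec <- scan_pairs(bm, "r1", paste0("m", 1:10))
  expect_equal(nrow(rec), 10L)
  expect_equal(rec$marker_id[1], "m1") # smallest p sorts first
  expect_equal(rec$normalized_distance[1], 0)
  expect_equal(rec$p_value[1], min(rec$p_value))
  expect_identical(rec$cosegregating, rec$p_value < 0.01)
  # invariance of the record set under marker order permutation
  rec2 <- scan_pairs(bm, "r1", sample(paste0("m", 1:10)))
  expect_identical(rec, rec2)
  # chunked processing returns identical records
  rec3 <- scan_pairs(bm, "r1", paste0("m", 1:10), chunk_size = 3L)
  expect_identical(rec, rec3)
})

test_that("scan_pairs excludes monomorphic columns and self pairs", {
  codes <- cbind(r1 = c(1L, 1L, 0L, 0L), m1 = c(1L, 0L, 1L, 0L), m2 = 0L)
  bm <- as_coseg_matrix(codes)
  rec <- scan_pairs(bm, "r1", c("r1", "m1", "m2"))
  expect_equal(rec$marker_id, "m1")
  excl <- attr(rec, "excluded")
  expect_true("m2" %in% excl$id)
  expect_error(scan_pairs(bm, character(), "m1"), "empty")
  expect_error(scan_pairs(bm, "nope", "m1"), "not in matrix")
})

test_that("Benjamini-Hochberg mode never calls more pairs than raw mode", {
  set.seed(31)
  codes <- matrix(rbinom(300 * 41, 1, 0.15), 300)
  colnames(codes) <- c("r1", paste0("m", 1:40))
  bm <- as_coseg_matrix(codes)
  raw <- scan_pairs(bm, "r1", paste0("m", 1:40), coseg_config(alpha = 0.05))
  bh <- scan_pairs(bm, "r1", paste0("m", 1:40),
                   coseg_config(alpha = 0.05, multiple_testing = "benjamini_hochberg"))
  expect_lte(sum(bh$cosegregating), sum(raw$cosegregating))
  expect_identical(raw$p_value, bh$p_value)
})

test_that("permutation null model inside the scan agrees with the exact null", {
  set.seed(41)
  codes <- matrix(rbinom(150 * 4, 1, 0.3), 150)
  colnames(codes) <- c("r1", "m1", "m2", "m3")
  bm <- as_coseg_matrix(codes)
  ex <- scan_pairs(bm, "r1", c("m1", "m2", "m3"))
  pm <- scan_pairs(bm, "r1", c("m1", "m2", "m3"),
                   coseg_config(null_model = "permutation", n_permutations = 2000))
  m <- match(pm$marker_id, ex$marker_id)
  se <- sqrt(ex$p_value[m] * (1 - ex$p_value[m]) / 2000)
  expect_true(all(abs(pm$p_value - ex$p_value[m]) < 4 * se + 1 / 2001))
})

test_that("type-I error of the exact test is conservative under independence", {
  np <- generate_null_pairs(4000, 300, c(0.05, 0.5), seed = 17)
  mac_a <- colSums(np$a); mac_b <- colSums(np$b)
  xor <- mac_a + mac_b - 2 * colSums(np$a * np$b)
  p <- exact_pvalue(300, mac_a, mac_b, xor)
  for (alpha in c(0.01, 0.05)) {
    rate <- mean(p < alpha)
    # valid (conservative) discrete test: rejection rate at most nominal
    # plus Monte-Carlo noise
    expect_lte(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / 4000))
  }
})
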