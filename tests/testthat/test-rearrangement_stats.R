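# RR / ARR / RW formulas, outliers, regressions, group tests, contact maps

make_counts <- function(per_site, per_pair) counts_table(per_site, per_pair)

test_that("RR follows Nre / (2 Nnorm + Nre) with boundary handling", {
  ct <- make_counts(
    data.frame(site_id = c("a", "b", "c", "d"),
               n_norm = c(4, 0, 7, 0), n_re = c(2, 5, 0, 0)),
    data.frame(site_a = character(0), site_b = character(0),
               n_re = numeric(0)))
  rr <- compute_rr(ct)
  expect_equal(rr$rr, c(2 / 10, 1.0, 0.0, NA_real_), tolerance = 1e-12)
})

test_that("ARR divides the class-restricted rate by partner count", {
  # locus a on chr1 with 70 inter partners emulated via partner counts:
  # build 3 loci on chr1 and 70 elsewhere is heavy; verify the formula on
  # a small layout instead and check the documented example numerically
  sites <- lox_site_table(c("a", "b", "c", "d"),
                          c("chr1", "chr1", "chr2", "chr2"),
                          c(100, 50000, 100, 50000))
  ct <- make_counts(
    data.frame(site_id = c("a", "b", "c", "d"),
               n_norm = c(12, 10, 8, 6), n_re = c(6, 2, 4, 4)),
    data.frame(site_a = c("a", "a", "c"), site_b = c("c", "d", "d"),
               n_re = c(2, 4, 4)))
  arr_inter <- compute_arr(ct, sites, "inter")
  # locus a: inter Nre = 6, Nall = 30, 2 inter partners -> (6/30)/2 = 0.1
  expect_equal(arr_inter$arr[1], (6 / 30) / 2, tolerance = 1e-12)
  arr_intra <- compute_arr(ct, sites, "intra")
  expect_equal(arr_intra$arr[1], 0)       # no intra events for a
  # direct check of the documented worked example
  expect_equal((6 / 30) / 70, 0.002857, tolerance = 1e-3)
  # single-locus chromosome: intra partners 0 -> NA
  sites2 <- lox_site_table(c("a", "b"), c("chr1", "chr2"), c(100, 100))
  ct2 <- make_counts(
    data.frame(site_id = c("a", "b"), n_norm = c(5, 5), n_re = c(1, 1)),
    data.frame(site_a = "a", site_b = "b", n_re = 1))
  expect_true(all(is.na(compute_arr(ct2, sites2, "intra")$arr)))
  # global-constant normalisation divides by the rearranged-locus total
  arr_tot <- compute_arr(ct, sites, "inter",
                         normalization = "total_rearranged")
  expect_equal(arr_tot$arr[1], (6 / 30) / 4, tolerance = 1e-12)
})

test_that("RW matches Eq. form, is symmetric and depth-invariant", {
  ct <- make_counts(
    data.frame(site_id = c("a", "b"), n_norm = c(1.5, 4), n_re = c(1, 1)),
    data.frame(site_a = "a", site_b = "b", n_re = 1))
  rw <- compute_rw(ct)
  expect_equal(rw["a", "b"], 1 / sqrt(4 * 9), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    ct <- rand_counts_table(n = 5)
    rw <- compute_rw(ct)
    expect_equal(unclass(rw), t(unclass(rw)))
    expect_true(all(diag(rw) == 0))
    expect_true(all(rw >= 0))
    # RW_ij = 0 iff Nre_ij = 0
    nre <- pair_count_matrix(ct)
    expect_identical(unname(unclass(rw) == 0), unname(nre == 0))
    # uniform count scaling leaves RW unchanged
    ct2 <- counts_table(
      transform(ct$per_site, n_norm = 3 * n_norm, n_re = 3 * n_re),
      transform(ct$per_pair, n_re = 3 * n_re))
    expect_equal(unclass(compute_rw(ct2)), unclass(rw), tolerance = 1e-12)
  }
})

test_that("Tukey upper-fence outliers follow the quartile arithmetic", {
  expect_equal(unname(find_outliers(c(1, 1, 1, 1, 10))), 10)
  expect_length(find_outliers(rep(2, 6)), 0L)
  expect_length(find_outliers(c(1, 2, 3, 4, 5)), 0L)
  expect_error(find_outliers(c(1, 2, 3, 4)), ">= 5")
  # hand-computed fence: q(type 7) on 1..8 plus a spike
  v <- c(1:8, 50)
  q <- quantile(v, c(.25, .75), type = 7)
  expect_equal(unname(find_outliers(v)),
               v[v > q[2] + 1.5 * (q[2] - q[1])])
})

test_that("RW ~ 1/d regression is exact on proportional input", {
  sites <- lox_site_table(paste0("s", 1:5), rep("chr1", 5),
                          c(10000, 30000, 60000, 100000, 150000))
  cen <- centromere_table("chr1", 190000, 190100) # all loci on one arm
  loci <- sites$site_id
  rw <- matrix(0, 5, 5, dimnames = list(loci, loci))
  for (i in 1:4) for (j in (i + 1):5) {
    d <- abs(sites$position[i] - sites$position[j])
    rw[i, j] <- rw[j, i] <- 5 / d
  }
  class(rw) <- c("rw_matrix", class(rw))
  fit <- rw_distance_regression(rw, sites, cen)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(fit$slope, 5, tolerance = 1e-9)
  expect_equal(fit$n_pairs, 10L)
  # centromere between s4 and s5 removes cross-arm pairs
  cen2 <- centromere_table("chr1", 120000, 120100)
  fit2 <- rw_distance_regression(rw, sites, cen2)
  expect_equal(fit2$n_pairs, choose(4, 2) + 0) # s5 alone on the right arm
  # permuted RW against distance carries no signal
  set.seed(11)
  sites3 <- lox_site_table(paste0("t", 1:20), rep("chr1", 20),
                           sort(sample.int(500000, 20)))
  cen3 <- centromere_table("chr1", 590000, 590100)
  loci3 <- sites3$site_id
  rw3 <- matrix(0, 20, 20, dimnames = list(loci3, loci3))
  vals <- runif(choose(20, 2), 0, 0.05)
  k <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    k <- k + 1
    rw3[i, j] <- rw3[j, i] <- vals[k]
  }
  class(rw3) <- c("rw_matrix", class(rw3))
  fit3 <- rw_distance_regression(rw3, sites3, cen3)
  expect_lt(fit3$r_squared, 0.15)
  expect_gt(fit3$p_value, 0.05)
})

test_that("group tests match independent implementations to 1e-6", {
  sites <- lox_site_table(paste0("s", 1:10),
                          rep(c("chr1", "chr2"), each = 5),
                          rep(c(1, 2, 3, 4, 5) * 10000, 2))
  # identical ARR distributions -> Mann-Whitney p = 1
  sr <- data.frame(site_id = sites$site_id, arr_intra = rep(1:5, 2),
                   arr_inter = rep(1:5, 2),
                   open_chromatin = NA)
  gt <- group_tests(sr)
  expect_equal(gt$intra_vs_inter$p_value, 1, tolerance = 1e-9)
  # separated groups: p below 0.001 for both tests
  sr2 <- data.frame(site_id = sites$site_id,
                    arr_intra = rep(0, 10), arr_inter = rep(1, 10),
                    open_chromatin = rep(c(TRUE, FALSE), 5))
  sr2$arr_inter <- sr2$arr_inter + ifelse(sr2$open_chromatin, 1, 0) +
    rep(c(0.01, -0.01, 0.02, -0.02, 0), 2)
  gt2 <- group_tests(sr2)
  expect_lt(gt2$intra_vs_inter$p_value, 0.001)
  expect_lt(gt2$open_vs_closed$p_value, 0.001)
  # Mann-Whitney against exact enumeration (small n, no ties)
  set.seed(3)
  x <- round(runif(5), 3); y <- round(runif(4) + 0.4, 3)
  sr3 <- data.frame(site_id = paste0("x", 1:9),
                    arr_intra = c(x, rep(NA, 4)),
                    arr_inter = c(rep(NA, 5), y), open_chromatin = NA)
  gt3 <- group_tests(sr3)
  # independent reimplementation of the tie-corrected normal-approx
  # Mann-Whitney p-value
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  pman <- 2 * pnorm(-abs((U - n1 * n2 / 2) / sqrt(sig2)))
  expect_equal(gt3$intra_vs_inter$p_value, pman, tolerance = 1e-6)
  # and the approximation tracks full enumeration
  expect_lt(abs(gt3$intra_vs_inter$p_value - exact_mw_p(x, y)), 0.05)
  # t test against the closed form
  op <- c(1.2, 1.4, 1.1, 1.8); cl <- c(0.9, 0.8, 1.0)
  sr4 <- data.frame(site_id = paste0("z", 1:7),
                    arr_intra = rep(1, 7),
                    arr_inter = c(op, cl),
                    open_chromatin = c(rep(TRUE, 4), rep(FALSE, 3)))
  gt4 <- group_tests(sr4)
  n1 <- 4; n2 <- 3
  sp <- sqrt(((n1 - 1) * var(op) + (n2 - 1) * var(cl)) / (n1 + n2 - 2))
  tstat <- (mean(op) - mean(cl)) / (sp * sqrt(1 / n1 + 1 / n2))
  pref <- 2 * pt(-abs(tstat), n1 + n2 - 2)
  expect_equal(gt4$open_vs_closed$p_value, pref, tolerance = 1e-6)
  expect_equal(gt4$open_vs_closed$statistic, tstat, tolerance = 1e-6)
  # empty group errors name the group
  sr5 <- sr4; sr5$open_chromatin <- TRUE
  expect_error(group_tests(sr5), "closed")
})

test_that("contact correlation behaves at the fixed points", {
  sites <- lox_site_table(paste0("s", 1:6),
                          rep(c("chr1", "chr2", "chr3"), each = 2),
                          rep(c(10000, 40000), 3))
  loci <- sites$site_id
  set.seed(21)
  rw <- matrix(0, 6, 6, dimnames = list(loci, loci))
  for (i in 1:5) for (j in (i + 1):6)
    rw[i, j] <- rw[j, i] <- runif(1)
  class(rw) <- c("rw_matrix", class(rw))
  self <- contact_correlation(rw, unclass(rw), sites)
  expect_equal(self$statistic, 1, tolerance = 1e-9)
  const <- contact_correlation(rw, matrix(3, 6, 6), sites)
  expect_true(is.na(const$statistic))
  expect_error(contact_correlation(rw, matrix(1, 4, 4), sites),
               "dimensions")
  # independent contact values: weak correlation
  set.seed(22)
  perm <- matrix(0, 6, 6)
  v <- runif(15)
  k <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    k <- k + 1
    perm[i, j] <- perm[j, i] <- v[k]
  }
  ind <- contact_correlation(rw, perm, sites)
  expect_gt(ind$p_value, 0.05)
})

test_that("contact ratio maps are median-centred log2 ratios", {
  A <- matrix(runif(16, 1, 5), 4)
  expect_true(all(contact_ratio_map(A, A) == 0))
  expect_true(all(abs(contact_ratio_map(2 * A, A)) < 1e-12))
  B <- A
  B[2, 3] <- A[2, 3] * 2
  r <- contact_ratio_map(B, A)
  expect_gt(r[2, 3], 0)
  expect_equal(sum(r > 1e-9), 1L)
  expect_error(contact_ratio_map(A, matrix(1, 3, 3)), "shape")
})

test_that("network export filters by threshold and round-trips weights", {
  sites <- lox_site_table(c("a", "b", "c"), c("chr1", "chr1", "chr2"),
                          c(1000, 2000, 1000))
  rw <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"),
                                        c("a", "b", "c")))
  rw["a", "b"] <- rw["b", "a"] <- 0.28
  rw["a", "c"] <- rw["c", "a"] <- 0.01
  rw["b", "c"] <- rw["c", "b"] <- 0.05
  class(rw) <- c("rw_matrix", class(rw))
  paths <- export_network(rw, sites, 0.02, tempfile())
  intra <- read_report(paths[["intra"]])
  inter <- read_report(paths[["inter"]])
  expect_equal(nrow(intra) + nrow(inter), 2L) # 0.28 and 0.05 pass
  expect_equal(intra$weight, 0.28)
  expect_equal(inter$weight, 0.05)
  # a threshold above the maximum leaves empty edge lists
  paths2 <- export_network(rw, sites, 0.5, tempfile())
  expect_equal(nrow(read_report(paths2[["intra"]])), 0L)
})
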