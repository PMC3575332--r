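test_that("recombination counting skips missing values", {
  expect_equal(count_recombinations(c(1, 1, -1, -1, 1)), 2L)
  expect_equal(count_recombinations(rep(1L, 10)), 0L)
  expect_equal(count_recombinations(c(1, 0, -1)), 1L)
  expect_equal(count_recombinations(c(0, 0)), 0L)
  expect_equal(count_recombinations(integer(0)), 0L)
})

test_that("mean recombinations sums per individual across groups", {
  # individual 1: 1 + 1 changes, individual 2: 2 + 0 -> mean 2
  m <- matrix(c("h", "h", "a", "h", "a",     # i1 over M1..M5
                "h", "a", "h", "a", "a"),    # i2 over M1..M5
              5, 2, dimnames = list(paste0("M", 1:5), c("i1", "i2")))
  gm <- geno_matrix(m, lg = c(1, 1, 1, 2, 2))
  ph <- setNames(rep("1-", 5), paste0("M", 1:5))
  mr <- mean_recombinations(gm, ph)
  expect_equal(unname(mr$per_individual), c(2, 2))
  expect_equal(mr$mean, 2)
  # simulated clean matrix: mean equals the simulated crossover mean
  truth <- simulate_clean(sim_params(n_individuals = 15,
                                     lg_lengths_cM = c(70, 50),
                                     markers_per_lg = 60, seed = 13))
  mr <- mean_recombinations(truth$clean, truth$phases)
  true_tot <- tapply(truth$crossovers$n_marker_resolved,
                     truth$crossovers$individual, sum)
  expect_equal(unname(mr$per_individual[names(true_tot)]),
               unname(as.vector(true_tot)))
  # all-constant matrix
  gm0 <- make_gm(rep("h", 12), 4, 3)
  expect_equal(mean_recombinations(gm0)$mean, 0)
})

test_that("percent reduction reproduces the headline map arithmetic", {
  # (22.45 - 6.5) / 22.45 = 71.05%, i.e. 71.0 at one decimal; reports
  # quoting 71.1 for these rates rounded from unrounded means
  expect_equal(percent_reduction(22.45, 6.5), 71.0)
  expect_equal(percent_reduction(11.22, 3.7), 67.0)
  expect_equal(percent_reduction(3.3, 3.3), 0)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("genotype bins partition markers by identical vectors", {
  gm <- make_gm(c("h", "h", "a", "a", "a", "h",
                  "h", "h", "a", "h", "h", "a"), 6, 2)
  # rows: M1=(h,h) M2=(h,h) M3=(a,a) M4=(a,h) M5=(a,h) M6=(h,a)
  b <- bin_markers(gm, "LG1")
  expect_equal(b$n_bins, 4)
  expect_equal(b$bin_id, c(1, 1, 2, 3, 3, 4))
  expect_equal(unname(b$representative), c("M01", "M03", "M04", "M06"))
  expect_setequal(unlist(b$members), rownames(gm$calls))  # partition
  # all rows distinct
  gm2 <- make_gm(c("h", "a", "h", "h", "a", "a"), 3, 2)
  expect_equal(bin_markers(gm2, "LG1")$n_bins, 3)
  gm3 <- make_gm(c("h", NA, "h", "h"), 2, 2)
  expect_error(bin_markers(gm3, "LG1"), "impute first")
})

test_that("recombination fractions count discordant informative meioses", {
  v <- rep(c(1L, -1L), length.out = 71)
  same <- recombination_fraction(v, v)
  expect_equal(same$r_hat, 0)
  expect_equal(same$n_informative, 71L)
  # 5 discordant of 50 informative
  a <- rep(1L, 50); b <- a; b[1:5] <- -1L
  expect_equal(recombination_fraction(a, b)$r_hat, 0.10)
  # fully opposite vectors: complementary phase adopted, flip recorded
  opp <- recombination_fraction(v, -v)
  expect_equal(opp$r_hat, 0)
  expect_true(opp$flipped)
  # missing in either vector is skipped
  skip <- recombination_fraction(c(1L, 0L, 1L), c(1L, 1L, 0L))
  expect_equal(skip$n_informative, 1L)
  und <- recombination_fraction(c(0L, 0L), c(1L, -1L))
  expect_true(und$undefined)
})

test_that("two-point LOD matches the closed form and a likelihood grid", {
  v <- rep(c(1L, -1L), length.out = 71)
  expect_equal(two_point_lod(v, v)$lod, 71 * log10(2))
  # r = 0.5: null model, LOD 0
  a <- rep(c(1L, 1L, -1L, -1L), 10)
  b <- rep(c(1L, -1L), 20)
  res <- two_point_lod(a, b)
  expect_equal(res$r_hat, 0.5)
  expect_equal(res$lod, 0)
  # R = 5, n = 50 against an exhaustive binomial likelihood grid
  a <- rep(1L, 50); b <- a; b[seq(3, 43, by = 10)] <- -1L
  res <- two_point_lod(a, b)
  grid <- seq(1e-6, 0.5, length.out = 200001)
  loglik <- function(r, R, n) R * log10(r) + (n - R) * log10(1 - r)
  lod_grid <- max(loglik(grid, 5, 50)) - loglik(0.5, 5, 50)
  expect_equal(res$lod, lod_grid, tolerance = 1e-6)
  expect_true(two_point_lod(c(0L, 0L), c(1L, 1L))$undefined)
})

test_that("linkage grouping joins markers above the LOD threshold", {
  v <- rep(c(1L, -1L), length.out = 71)
  X <- rbind(A = v, B = v)                     # r = 0, LOD 21.4 >= 7
  expect_equal(length(unique(group_markers(X))), 1)
  set.seed(55)
  Y <- rbind(A = v, B = sample(v))             # shuffled: unlinked
  expect_equal(length(unique(group_markers(Y))), 2)
  # raising min_lod never merges components
  p <- sim_params(n_individuals = 40, lg_lengths_cM = c(60, 60),
                  markers_per_lg = 25, missing_mean = 0.2, error_rate = 0,
                  seed = 77)
  truth <- simulate_progeny(p)
  X <- rbind(encode_group(truth$observed, truth$phases, "LG1"),
             encode_group(truth$observed, truth$phases, "LG2"))
  sizes <- vapply(c(3, 7, 12, 20), function(l)
    length(unique(group_markers(X, min_lod = l))), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("Kosambi distances follow the mapping function", {
  expect_equal(kosambi_cM(0), 0)
  expect_equal(kosambi_cM(0.25), 25 * log(3))
  expect_equal(round(kosambi_cM(0.25), 2), 27.47)
  # small-r limit: d ~ 100 r within 1% for r <= 0.05
  r <- c(0.01, 0.03, 0.05)
  expect_true(all(abs(kosambi_cM(r) - 100 * r) / (100 * r) < 0.01))
  # strictly increasing and above 100 r on (0, 0.5)
  r <- seq(0.01, 0.49, by = 0.01)
  d <- kosambi_cM(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(d > 100 * r))
  expect_error(kosambi_cM(0.5), "r < 0.5")
})

test_that("map length sums adjacent-bin Kosambi distances", {
  # two bins separated by r = 0.25: 10 discordant of 40
  calls <- rbind(rep(c("h", "a"), each = 20),
                 rep(c("h", "a", "h", "a"), times = c(15, 5, 5, 15)))
  dimnames(calls) <- list(c("M1", "M2"), sprintf("i%02d", 1:40))
  gm <- geno_matrix(calls, lg = c(1, 1))
  ph <- setNames(rep("1-", 2), c("M1", "M2"))
  row <- map_length_along_order(gm, "1", ph)
  expect_equal(row$length_cM, 25 * log(3), tolerance = 1e-10)
  expect_equal(row$n_bins, 2)
  expect_equal(row$cM_per_bin * row$n_bins, row$length_cM)
  # single bin: zero length
  gm1 <- make_gm(rep("h", 8), 2, 4)
  expect_equal(map_length_along_order(gm1, "LG1")$length_cM, 0)
  # binning collapses identical neighbors, so adjacent bins always differ
  b <- bin_markers(gm1, "LG1")
  expect_equal(b$n_bins, 1)
})

test_that("map length approaches the simulated group length", {
  p <- sim_params(n_individuals = 71, lg_lengths_cM = 80,
                  markers_per_lg = 400, missing_mean = 0, error_rate = 0,
                  seed = 101)
  truth <- simulate_clean(p)
  row <- map_length_along_order(truth$clean, "LG1", truth$phases)
  # sampling error band at n = 71 (adjacent-bin estimate, no interference)
  expect_gt(row$length_cM, 80 * 0.6)
  expect_lt(row$length_cM, 80 * 1.4)
})

test_that("chi-squared scan tests the 1:1 testcross ratio", {
  calls <- rbind(c(rep("h", 35), rep("a", 36)),
                 c(rep("h", 50), rep("a", 21)),
                 c(rep("h", 30), rep("a", 30), rep(NA, 11)))
  dimnames(calls) <- list(c("M1", "M2", "M3"), sprintf("i%02d", 1:71))
  gm <- geno_matrix(calls, lg = rep(1, 3))
  scan <- chi_square_scan(gm)
  expect_equal(scan$chi2[1], (35 - 36)^2 / 71)
  expect_equal(round(scan$chi2[1], 4), 0.0141)
  expect_equal(scan$sig_level[1], "")
  expect_equal(round(scan$chi2[2], 2), 11.85)
  expect_gt(scan$chi2[2], 10.828)
  expect_equal(scan$sig_level[2], "0.001")
  expect_equal(scan$chi2[3], 0)            # equal counts
  expect_equal(scan$n[3], 60)              # missing excluded from counts
  # agreement with the stats::chisq.test goodness-of-fit route
  for (i in 1:3) {
    ct <- suppressWarnings(stats::chisq.test(
      c(scan$count_class1[i], scan$count_class2[i]), p = c(0.5, 0.5)))
    expect_equal(scan$chi2[i], unname(ct$statistic))
    expect_equal(scan$p[i], ct$p.value)
  }
  # label-swap invariance and monotonicity in |count difference|
  swapped <- chi_square_scan(geno_matrix(
    ifelse(calls == "h", "a", ifelse(calls == "a", "h", NA)),
    lg = rep(1, 3)))
  expect_equal(swapped$chi2, scan$chi2)
  d30 <- (45 - 15)^2 / 60; d10 <- (35 - 25)^2 / 60
  expect_gt(d30, d10)
})

test_that("greedy nearest-neighbor chaining recovers a monotone order", {
  # staircase bins: bin j carries a crossover after individual j, so
  # r(i, j) = |i - j| / n is strictly monotone along the true order and
  # nearest-neighbor chaining provably recovers it (or its reversal)
  k <- 12; n <- 40
  reps <- t(vapply(seq_len(k), function(j)
    c(rep(-1L, 2 * j), rep(1L, n - 2 * j)), integer(n)))
  rownames(reps) <- sprintf("B%02d", seq_len(k))
  ord <- order_markers_greedy(reps)
  expect_setequal(ord, seq_len(k))
  expect_true(identical(ord, seq_len(k)) || identical(ord, rev(seq_len(k))))
  # shuffled input recovers the same chain up to direction
  set.seed(9)
  perm <- sample(k)
  ord2 <- perm[order_markers_greedy(reps[perm, ])]
  expect_true(identical(ord2, seq_len(k)) || identical(ord2, rev(seq_len(k))))
  expect_equal(order_markers_greedy(reps[1:2, ]), 1:2)
  # deterministic under repetition
  expect_identical(ord, order_markers_greedy(reps))
})

test_that("chaining a simulated clean group is a permutation and stable", {
  p <- sim_params(n_individuals = 71, lg_lengths_cM = 90,
                  markers_per_lg = 40, missing_mean = 0, error_rate = 0,
                  seed = 121)
  truth <- simulate_clean(p)
  b <- bin_markers(truth$clean, "LG1")
  X <- encode_group(truth$clean, truth$phases, "LG1")
  reps <- X[b$representative, , drop = FALSE]
  ord <- order_markers_greedy(reps)
  expect_setequal(ord, seq_len(nrow(reps)))
  expect_identical(ord, order_markers_greedy(reps))
  # chained order stays close to the true order: adjacent chain neighbors
  # are within a few bins of each other on the true map
  pos <- order(ord)
  expect_true(stats::cor(pos, seq_along(pos), method = "spearman") > 0.95 ||
                stats::cor(pos, rev(seq_along(pos)), method = "spearman") > 0.95)
})
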