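# Chromosome-pair matrix, elbow clustering, DR score and bootstrap null.

toy_trans_net <- function(v, chrom_a = "chr1", chrom_b = "chr2") {
  da <- make_domains(chrom_a, (seq_len(nrow(v)) - 1L) * 100000L,
                     seq_len(nrow(v)) * 100000L)
  db <- make_domains(chrom_b, (seq_len(ncol(v)) - 1L) * 100000L,
                     seq_len(ncol(v)) * 100000L)
  domain_interaction_matrix(v, da, db, kind = "trans")
}

test_that("chrom_pair_matrix normalizes totals by length products", {
  v <- matrix(1:6 / 10, 2, 3)
  net <- toy_trans_net(v)
  lens <- c(chr1 = 2e5, chr2 = 3e5)
  m <- chrom_pair_matrix(list("chr1|chr2" = net), lens)
  expect_equal(m["chr1", "chr2"], sum(v) / (2e5 * 3e5))
  expect_equal(m["chr2", "chr1"], m["chr1", "chr2"])
  expect_true(is.na(m["chr1", "chr1"]))
  # linearity
  net2 <- net; net2$values <- net2$values * 2
  m2 <- chrom_pair_matrix(list("chr1|chr2" = net2), lens)
  expect_equal(m2["chr1", "chr2"], 2 * m["chr1", "chr2"])
  expect_error(chrom_pair_matrix(list(), lens), "missing")
})

test_that("rss elbow finds planted two-cluster structure", {
  set.seed(91)
  n <- 10
  m <- matrix(abs(rnorm(n * n, 1, 0.05)), n, n); m <- (m + t(m)) / 2
  m[1:5, 1:5] <- m[1:5, 1:5] + 10
  m[6:10, 6:10] <- m[6:10, 6:10] + 10
  diag(m) <- NA
  e <- rss_elbow(m, k_max = 6, seed = 1)
  expect_equal(e$elbow_k, 2L)
  expect_equal(e$verdict, "clusters")
  # k = number of rows: every point its own center
  full <- rss_elbow(m, k_max = n, seed = 1)
  expect_lt(full$rss[[as.character(n)]], 1e-8)
  expect_error(rss_elbow(m, k_max = 2), "k_max")
})

test_that("featureless pair matrices yield no evident clusters", {
  set.seed(92)
  n <- 12
  m <- matrix(abs(rnorm(n * n, 1, 0.01)), n, n); m <- (m + t(m)) / 2
  diag(m) <- NA
  e <- rss_elbow(m, seed = 2)
  expect_equal(e$verdict, "no evident clusters")
})

test_that("dr_score matches direct arithmetic and centers at zero", {
  v <- rbind(c(1, 1), c(0.5, 0.5), c(0, 0))
  net <- toy_trans_net(v)
  p <- dr_score(net)
  expect_equal(unname(p$S), c(2, 1, 0))
  expect_equal(p$mean_S, 1)
  expect_equal(unname(p$DR), c(1, 0, -1))
  expect_equal(p$sigma, sqrt(2 / 3))

  const <- toy_trans_net(matrix(1, 4, 5))
  pc <- dr_score(const)
  expect_equal(unname(pc$DR), rep(0, 4))
  expect_equal(pc$sigma, 0)

  expect_error(dr_score(toy_trans_net(matrix(0, 3, 3))), "degenerate")
})

test_that("mean(DR) is zero to 1e-9 on random networks", {
  set.seed(93)
  for (rep in 1:5) {
    net <- toy_trans_net(matrix(rexp(30 * 40), 30, 40))
    expect_lt(abs(mean(dr_score(net)$DR)), 1e-9)
  }
})

test_that("bootstrap_shuffle permutes values, preserving the multiset", {
  set.seed(94)
  net <- toy_trans_net(matrix(rexp(200), 10, 20))
  sh <- bootstrap_shuffle(net, seed = 1)
  expect_equal(sort(as.numeric(sh$values)), sort(as.numeric(net$values)))
  expect_false(identical(sh$values, net$values))
  expect_identical(bootstrap_shuffle(net, seed = 1)$values, sh$values)
  expect_false(identical(bootstrap_shuffle(net, seed = 2)$values, sh$values))

  # cis shuffle keeps symmetry and the upper-triangle multiset
  d <- make_domains("chr1", (0:9) * 100000L, (1:10) * 100000L)
  v <- matrix(runif(100), 10, 10); v <- (v + t(v)) / 2
  cis <- domain_interaction_matrix(v, d, kind = "cis")
  shc <- bootstrap_shuffle(cis, seed = 3)
  expect_equal(shc$values[upper.tri(shc$values)][order(shc$values[upper.tri(shc$values)])],
               sort(cis$values[upper.tri(cis$values)]))
  expect_equal(shc$values, t(shc$values))
})

test_that("shuffling leaves the intensity distribution fit unchanged", {
  set.seed(95)
  net <- toy_trans_net(matrix(rexp(100 * 120, rate = 10), 100, 120))
  f0 <- fit_exponential(pool_interactions(net))
  f1 <- fit_exponential(pool_interactions(bootstrap_shuffle(net, seed = 6)))
  expect_equal(f1$I0, f0$I0, tolerance = 1e-9)
})

test_that("sign runs follow the zero-crossing definition", {
  r <- sign_run_lengths(c(1, 2, -1, -3, -2))
  expect_equal(r$run_lengths, c(2L, 3L))
  expect_equal(r$mean_run, 2.5)

  alt <- sign_run_lengths(c(1, -1, 1, -1, 1))
  expect_equal(alt$run_lengths, rep(1L, 5))
  expect_equal(alt$mean_run, 1)

  withz <- sign_run_lengths(c(1, 1, 0, -1, 0, 0, 2))
  expect_equal(withz$run_lengths, c(2L, 1L, 1L))
  expect_equal(sum(withz$run_lengths) + withz$n_zero, 7L)

  expect_error(sign_run_lengths(rep(0, 5)), "all-zero")
})

test_that("iid sign sequences reproduce the 1/(2p(1-p)) mean run length", {
  for (p in c(0.3, 0.5)) {
    means <- vapply(1:20, function(s) {
      set.seed(s)
      x <- ifelse(runif(5000) < p, 1, -1)
      sign_run_lengths(x)$mean_run
    }, numeric(1))
    expected <- 1 / (2 * p * (1 - p))
    se <- stats::sd(means) / sqrt(length(means))
    expect_lt(abs(mean(means) - expected), 4 * se + 0.02)
  }
})

test_that("banded trans matrices beat their bootstrap null", {
  for (s in 1:5) {
    g <- generate_genome(synthetic_genome_spec(
      n_chromosomes = 2, domains_per_chromosome = 100,
      band_fraction = 0.2, band_amplitude = 2), seed = s)
    d <- dr_bootstrap(g$nets$trans[[1]], replicates = 25, seed = s)
    expect_gt(d$sigma, d$sigma_rand)
    expect_gt(d$mean_run, d$mean_run_rand)
  }
})
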