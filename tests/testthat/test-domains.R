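# Internal-domain filtering, labeling, and the interaction statistic.

test_that("filter_internal_domains implements strict containment", {
  d <- make_domains("chr1", c(0L, 200000L), c(100000L, 300000L))
  expect_equal(filter_internal_domains(d)$id, d$id)  # disjoint: both kept

  nested <- make_domains("chr1", c(0L, 20000L), c(100000L, 80000L))
  kept <- filter_internal_domains(nested)
  expect_equal(kept$id, "chr1:0-100000")

  # same interval on another chromosome is not contained
  cross <- make_domains(c("chr1", "chr2"), c(0L, 20000L), c(100000L, 80000L))
  expect_equal(nrow(filter_internal_domains(cross)), 2L)
})

test_that("nested chains match a brute-force containment oracle", {
  # A > B > C plus disjoint D
  d <- make_domains("chr1", c(0L, 10000L, 20000L, 500000L),
                    c(100000L, 90000L, 80000L, 600000L))
  kept <- filter_internal_domains(d)
  expect_setequal(kept$id, c("chr1:0-100000", "chr1:500000-600000"))

  # randomized fixtures against an all-pairs double loop
  set.seed(5)
  for (rep in 1:5) {
    n <- 30
    start <- sample.int(1000, n) * 1000L
    end <- start + sample.int(500, n) * 1000L
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    d <- make_domains(chrom, start, end)
    d <- d[!duplicated(d$id), ]
    internal <- vapply(seq_len(nrow(d)), function(i) {
      any(vapply(seq_len(nrow(d)), function(j) {
        i != j && d$chrom[i] == d$chrom[j] &&
          d$start[j] <= d$start[i] && d$end[i] <= d$end[j] &&
          !(d$start[i] == d$start[j] && d$end[i] == d$end[j])
      }, logical(1)))
    }, logical(1))
    expect_setequal(filter_internal_domains(d)$id, d$id[!internal])
  }
})

test_that("filtering is idempotent, order-independent, and collapses duplicates", {
  set.seed(9)
  n <- 40
  start <- sample.int(300, n, replace = TRUE) * 1000L
  d <- make_domains("chr1", start, start + sample.int(100, n, TRUE) * 1000L)
  once <- filter_internal_domains(d)
  twice <- filter_internal_domains(once)
  expect_equal(once$id, twice$id)
  shuffled <- filter_internal_domains(d[sample(nrow(d)), ])
  expect_equal(shuffled$id, once$id)
  expect_lte(nrow(once), nrow(d))

  dup <- rbind(d[1, ], d[1, ])
  expect_equal(nrow(filter_internal_domains(dup)), 1L)
})

test_that("subcompartment assignment honors single-only and majority rules", {
  ann <- data.frame(chrom = "chr1", start = c(0L, 150000L),
                    end = c(150000L, 200000L), label = c("A1", "B1"),
                    stringsAsFactors = FALSE)
  inside <- make_domains("chr1", 10000L, 90000L)
  for (mode in c("single", "majority")) {
    r <- assign_subcompartments(inside, ann, mode)
    expect_equal(r$domains$subcompartment, "A1")
    expect_equal(r$report$fraction_assigned, 1)
  }
  # 150 kb of A1 and 50 kb of B1
  split <- make_domains("chr1", 0L, 200000L)
  expect_true(is.na(assign_subcompartments(split, ann, "single")$domains$subcompartment))
  expect_equal(assign_subcompartments(split, ann, "majority")$domains$subcompartment, "A1")

  outside <- make_domains("chr1", 500000L, 600000L)
  r <- assign_subcompartments(outside, ann, "single")
  expect_true(is.na(r$domains$subcompartment))
  expect_equal(r$report$n_assigned, 0L)
})

test_that("majority ties and conflicting annotations are handled", {
  ann <- data.frame(chrom = "chr1", start = c(0L, 100000L),
                    end = c(100000L, 200000L), label = c("A1", "B1"),
                    stringsAsFactors = FALSE)
  tied <- make_domains("chr1", 0L, 200000L)
  r <- assign_subcompartments(tied, ann, "majority")
  expect_true(is.na(r$domains$subcompartment))
  expect_equal(r$report$n_ties, 1L)

  overlapping <- data.frame(chrom = "chr1", start = c(0L, 50000L),
                            end = c(100000L, 150000L),
                            label = c("A1", "B1"), stringsAsFactors = FALSE)
  expect_error(assign_subcompartments(tied, overlapping), "overlapping")
})

test_that("domain_interaction matches the stated hand-computed example", {
  # 10 kb bins; a = bins {0,1}, b = bins {2,3}
  m <- matrix(0, 4, 4)
  m[1, 3] <- 1; m[1, 4] <- 2; m[2, 3] <- 3; m[2, 4] <- 4
  m <- m + t(m)
  cm <- contact_matrix(m, "chr1", bin_size = 10000)
  a <- list(chrom = "chr1", start = 0, end = 20000)
  b <- list(chrom = "chr1", start = 20000, end = 40000)
  expect_equal(domain_interaction(cm, a, b), 10 / (20000 * 20000))
  expect_equal(domain_interaction(cm, b, a), domain_interaction(cm, a, b))

  zero <- contact_matrix(matrix(0, 4, 4), "chr1", bin_size = 10000)
  expect_equal(domain_interaction(zero, a, b), 0)
  out <- list(chrom = "chr1", start = 0, end = 900000)
  expect_error(domain_interaction(cm, a, out), "extent")
})

test_that("domain_interaction equals a brute-force double loop (50x50)", {
  cm <- random_cis_cm(50, seed = 21)
  set.seed(22)
  for (rep in 1:10) {
    s <- sort(sample(0:48, 4)) * 10000
    a <- list(chrom = "chr1", start = s[1], end = s[2] + 10000)
    b <- list(chrom = "chr1", start = s[3], end = s[4] + 10000)
    expect_equal(domain_interaction(cm, a, b), brute_interaction(cm, a, b),
                 tolerance = 1e-12)
  }
})

test_that("build_interaction_matrices composes per-pair calls", {
  d <- make_domains(rep(c("chr1", "chr2"), each = 2),
                    c(0L, 100000L, 0L, 200000L),
                    c(100000L, 300000L, 200000L, 400000L))
  set.seed(31)
  mats <- list(
    chr1 = random_cis_cm(30, seed = 31),
    chr2 = random_cis_cm(40, seed = 32, chrom = "chr2"),
    "chr1|chr2" = contact_matrix(matrix(runif(30 * 40), 30, 40),
                                 "chr1", "chr2", 10000))
  nets <- build_interaction_matrices(mats, d)
  expect_named(nets$cis, c("chr1", "chr2"))
  expect_named(nets$trans, "chr1|chr2")
  expect_equal(dim(nets$trans[["chr1|chr2"]]$values), c(2L, 2L))
  # oracle equivalence, including NA diagonal for cis
  d1 <- d[d$chrom == "chr1", ]
  expect_equal(nets$cis$chr1$values[1, 2],
               domain_interaction(mats$chr1, d1[1, ], d1[2, ]))
  expect_true(all(is.na(diag(nets$cis$chr1$values))))
  d2 <- d[d$chrom == "chr2", ]
  expect_equal(nets$trans[["chr1|chr2"]]$values[2, 1],
               domain_interaction(mats[["chr1|chr2"]], d1[2, ], d2[1, ]))
  expect_error(build_interaction_matrices(mats[c("chr1", "chr2")], d),
               "chr1\\|chr2")
})

test_that("domain-pair sums conserve the matrix total when domains tile", {
  cm <- random_cis_cm(12, seed = 41)
  d <- make_domains("chr1", c(0L, 40000L, 90000L),
                    c(40000L, 90000L, 120000L))
  total <- sum(vapply(seq_len(3), function(i) {
    sum(vapply(seq_len(3), function(j) {
      domain_interaction(cm, d[i, ], d[j, ]) *
        (d$end[i] - d$start[i]) * (d$end[j] - d$start[j])
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(total, sum(as.matrix(cm$mat)), tolerance = 1e-9)
})

test_that("cis_trans_ratio is the ratio of pool means", {
  expect_equal(cis_trans_ratio(rep(8.5e-6, 3), rep(1e-8, 5)), 850)
  expect_equal(cis_trans_ratio(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_error(cis_trans_ratio(numeric(0), 1), "non-empty")
  expect_error(cis_trans_ratio(1, c(0, 0)), "zero")
})
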