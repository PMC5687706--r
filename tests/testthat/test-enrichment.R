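# Subcompartment enrichment, top interactors and composition.

# Four labeled domains on one chromosome with planted pair means:
# AA = 3, AB = 1, BB = 2 -> H0 = 2, H = {+0.5, -0.5, 0}.
planted_net <- function() {
  d <- make_domains("chr1", (0:3) * 100000L, (1:4) * 100000L,
                    label = c("A1", "A1", "B1", "B1"))
  v <- matrix(NA_real_, 4, 4)
  v[1, 2] <- 3
  v[1, 3] <- v[1, 4] <- v[2, 3] <- v[2, 4] <- 1
  v[3, 4] <- 2
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  domain_interaction_matrix(v, d, kind = "cis")
}

test_that("enrichment follows the (mean - H0)/H0 formula", {
  hm <- subcompartment_enrichment(planted_net(), "cis")
  expect_equal(hm$H0, 2)
  expect_equal(hm$N_c, 3L)
  expect_equal(hm$H["A1", "A1"], 0.5)
  expect_equal(hm$H["A1", "B1"], -0.5)
  expect_equal(hm$H["B1", "B1"], 0)
  expect_equal(hm$H, t(hm$H))
})

test_that("H is zero-mean over label pairs and scale invariant", {
  net <- planted_net()
  hm <- subcompartment_enrichment(net, "cis")
  ut <- upper.tri(hm$H, diag = TRUE)
  expect_lt(abs(mean(hm$H[ut])), 1e-9)

  scaled <- net
  scaled$values <- scaled$values * 1e6
  hm2 <- subcompartment_enrichment(scaled, "cis")
  expect_equal(hm2$H, hm$H, tolerance = 1e-12)

  uniform <- net
  uniform$values[!is.na(uniform$values)] <- 7
  hm3 <- subcompartment_enrichment(uniform, "cis")
  expect_equal(unname(hm3$H[ut]), rep(0, 3))
})

test_that("unlabeled domains are excluded and sparse label pairs reported", {
  d1 <- make_domains("chr1", (0:2) * 100000L, (1:3) * 100000L,
                     label = c("A1", "B1", NA))
  v1 <- matrix(runif(9) + 0.5, 3, 3); v1 <- (v1 + t(v1)) / 2
  net1 <- domain_interaction_matrix(v1, d1, kind = "cis")
  d2 <- make_domains("chr2", (0:1) * 100000L, (1:2) * 100000L,
                     label = c("B2", "B2"))
  v2 <- matrix(1, 2, 2)
  net2 <- domain_interaction_matrix(v2, d2, kind = "cis")
  hm <- subcompartment_enrichment(list(net1, net2), "cis")
  expect_setequal(hm$labels, c("A1", "B1", "B2"))
  # labels occurring once per chromosome have no homotypic cis pairs,
  # and cross-chromosome label pairs have no cis pairs at all
  expect_setequal(hm$missing_pairs,
                  c("A1|A1", "B1|B1", "A1|B2", "B1|B2"))
  expect_true(is.na(hm$H["A1", "B2"]))
  expect_error(subcompartment_enrichment(net2, "cis"), "two")
  expect_error(subcompartment_enrichment(net1, "trans"), "scope")
})

test_that("top_interactors matches a brute-force sort oracle", {
  set.seed(71)
  d <- make_domains("chr1", (0:19) * 100000L, (1:20) * 100000L)
  v <- matrix(runif(400), 20, 20); v <- (v + t(v)) / 2
  net <- domain_interaction_matrix(v, d, kind = "cis")
  top <- top_interactors(net, 0.05)
  means <- rowMeans(net$values, na.rm = TRUE)
  expect_equal(top$id, d$id[which.max(means)])
  expect_false(attr(top, "ties"))

  frac <- 0.3
  oracle <- d$id[order(-means)][seq_len(ceiling(frac * 20))]
  expect_setequal(top_interactors(net, frac)$id, oracle)
  expect_setequal(top_interactors(net, 1)$id, d$id)
  expect_error(top_interactors(net, 0), "fraction")
})

test_that("ties at the cutoff are broken by coordinate and flagged", {
  d <- make_domains("chr1", (0:3) * 100000L, (1:4) * 100000L)
  v <- matrix(1, 4, 4)
  net <- domain_interaction_matrix(v, d, kind = "cis")
  top <- top_interactors(net, 0.5)
  expect_equal(top$id, d$id[1:2])
  expect_true(attr(top, "ties"))
})

test_that("compartment composition counts labels and N.A.", {
  d <- make_domains("chr1", (0:3) * 100000L, (1:4) * 100000L,
                    label = c("A1", "A1", "B1", NA))
  comp <- compartment_composition(d)
  expect_equal(comp[["A1"]], 0.5)
  expect_equal(comp[["B1"]], 0.25)
  expect_equal(comp[["N.A."]], 0.25)
  expect_equal(sum(comp), 1)
  single <- compartment_composition(d[1:2, ])
  expect_equal(unname(single), 1)
  expect_error(compartment_composition(d[0, ]), "empty")
})

test_that("homotypic cis boost surfaces as diagonal enrichment", {
  g <- generate_genome(synthetic_genome_spec(
    n_chromosomes = 3, domains_per_chromosome = 60,
    homotypic_boost = 3), seed = 81)
  dom <- filter_internal_domains(g$domains)
  hm <- subcompartment_enrichment(g$nets$cis, "cis")
  diag_mean <- mean(diag(hm$H), na.rm = TRUE)
  off <- hm$H[upper.tri(hm$H)]
  expect_gt(diag_mean, mean(off, na.rm = TRUE))
})

test_that("A1 trans boost enriches A1 among trans top interactors", {
  g <- generate_genome(synthetic_genome_spec(
    n_chromosomes = 3, domains_per_chromosome = 100,
    a1_trans_boost = 4, band_fraction = 0), seed = 82)
  top <- top_interactors(g$nets$trans, 0.05)
  all_frac <- compartment_composition(
    g$nets$trans[[1]]$domains_row)[["A1"]]
  top_frac <- compartment_composition(top)[["A1"]]
  expect_gt(top_frac, all_frac)
})
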