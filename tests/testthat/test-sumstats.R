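test_that("worked fixture reproduces the hand-enumerated statistics", {
  f1 <- fixture_F1()
  expect_equal(nucleotide_diversity(f1), 11 / 6 / 100)
  expect_equal(watterson_theta(f1), 3 / (11 / 6 * 100))
  d <- tajimas_d(f1)
  expect_equal(as.numeric(d), 1.0898, tolerance = 1e-4)
  expect_identical(attr(d, "status"), "ok")
  afs <- folded_afs(f1)
  expect_identical(afs$counts, c(`1` = 1L, `2` = 2L))
})

test_that("pi and Watterson agree on simple cases and for n = 2", {
  s1 <- strrep("A", 100); s2 <- s1
  for (p in c(3, 20, 50, 80)) substr(s2, p, p) <- "T"
  a <- haplotype_alignment(c(s1, s2))
  expect_equal(nucleotide_diversity(a), 0.04)
  expect_equal(watterson_theta(a), 0.04)  # a_1 = 1
  expect_equal(nucleotide_diversity(haplotype_alignment(c(s1, s1))), 0)

  set.seed(31)
  r <- simulate_coalescent_gc(sim_params(theta = 2e-3, genome_length = 5000,
                                         sample_size = 2), emit = "sites")
  expect_equal(nucleotide_diversity(r$alignment),
               watterson_theta(r$alignment))
})

test_that("Tajima's D is undefined at S = 0 and its sign follows
           pi_total - thetaW_total", {
  a <- haplotype_alignment(rep(strrep("A", 50), 4))
  d0 <- tajimas_d(a)
  expect_true(is.na(d0))
  expect_identical(attr(d0, "status"), "no_segregating_sites")
  expect_equal(watterson_theta(a), 0)

  set.seed(32)
  for (i in 1:20) {
    r <- simulate_coalescent_gc(sim_params(theta = 2e-3,
                                           genome_length = 10000,
                                           sample_size = 8), emit = "sites")
    aln <- r$alignment
    S <- length(aln$variant_positions)
    if (S == 0) next
    d <- tajimas_d(aln)
    lhs <- nucleotide_diversity(aln) * aln$usable_length -
      S / sum(1 / seq_len(7))
    expect_equal(sign(as.numeric(d)), sign(lhs))
  }
})

test_that("neutral folded spectrum matches the closed-form class weights", {
  # sites within a replicate share one genealogy, so pooled counts are
  # overdispersed relative to multinomial; compare replicate-level class
  # means against the closed form theta*L*(1/i + 1/(n-i)) with
  # replicate-level standard errors
  set.seed(33)
  n <- 10; R <- 250
  mat <- t(replicate(R, {
    r <- simulate_coalescent_gc(sim_params(theta = 2e-3,
                                           genome_length = 10000,
                                           sample_size = n), emit = "sites")
    folded_afs(r$alignment)$counts
  }))
  i <- seq_len(n %/% 2)
  E <- 2e-3 * 10000 * (1 / i + 1 / (n - i)) / (1 + (i == n / 2))
  z <- (colMeans(mat) - E) / (apply(mat, 2, sd) / sqrt(R))
  expect_true(all(abs(z) < 4))
})

test_that("folded spectrum total equals the biallelic site count", {
  set.seed(34)
  r <- simulate_coalescent_gc(sim_params(theta = 3e-3, genome_length = 10000,
                                         sample_size = 10), emit = "sites")
  afs <- folded_afs(r$alignment)
  expect_identical(sum(afs$counts) + afs$n_excluded_sites,
                   length(r$alignment$variant_positions))
})

test_that("four-gamete profile: construction, singleton rule, invariances", {
  # sites at 5 and 12 with all four combinations across n = 4
  s <- rep(strrep("A", 100), 4)
  put <- function(x, p, b) { substr(x, p, p) <- b; x }
  s[1] <- put(put(s[1], 5, "T"), 12, "G")
  s[2] <- put(s[2], 5, "T")
  s[3] <- put(s[3], 12, "G")
  a <- haplotype_alignment(s)
  f <- four_gamete_profile(a)
  expect_equal(f$proportions[1], 1)
  expect_identical(f$n_pairs, c(1L, 0L, 0L, 0L, 0L, 0L))

  # a singleton site joins no pair
  s[4] <- put(s[4], 60, "C")
  f2 <- four_gamete_profile(haplotype_alignment(s))
  expect_identical(sum(f2$n_pairs), 1L)

  # invariant to sample reordering and allele-label complementation
  set.seed(35)
  r <- simulate_coalescent_gc(sim_params(theta = 3e-3, rho = 3e-4,
                                         tract_length = 500,
                                         genome_length = 10000,
                                         sample_size = 10), emit = "sites")
  aln <- r$alignment
  f3 <- four_gamete_profile(aln)
  perm <- aln
  ord <- sample(10)
  perm$variant_alleles <- perm$variant_alleles[ord, , drop = FALSE]
  perm$sample_ids <- perm$sample_ids[ord]
  perm$host_ids <- perm$host_ids[ord]
  expect_equal(four_gamete_profile(perm)$proportions, f3$proportions)
  comp <- aln
  comp$variant_alleles <- chartr("ACGT", "TGCA", comp$variant_alleles)
  expect_equal(four_gamete_profile(comp)$proportions, f3$proportions)
})

test_that("Hudson Fst matches hand values and bootstrap behaves", {
  expect_equal(fst_between_hosts(0.2, 0.8, seed = 1)$fst, 0.36 / 0.68)
  expect_equal(fst_between_hosts(c(1, 1, 0), c(0, 0, 1), seed = 1)$fst, 1)
  expect_equal(fst_between_hosts(c(0.3, 0.5), c(0.3, 0.5), seed = 1)$fst, 0)
  expect_error(fst_between_hosts(NA, NA), "no usable sites")

  set.seed(36)
  p1 <- runif(80, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + rnorm(80, 0, 0.25), 0), 1)
  inside <- replicate(40, {
    f <- fst_between_hosts(p1, p2, n_bootstrap = 300)
    f$ci_low <= f$fst && f$fst <= f$ci_high && f$ci_low <= f$ci_high
  })
  expect_gte(mean(inside), 0.99)
})

test_that("summary TSV follows the feature-contract column order", {
  sv <- summary_vector(fixture_F1())
  tf <- tempfile(fileext = ".tsv")
  write_summary_tsv(sv, tf)
  got <- read.table(tf, header = TRUE, sep = "\t")
  expect_identical(names(got),
                   c("pi", "watterson", paste0("f4_bin", 1:6),
                     "n_samples", "n_sites_used"))
  expect_equal(got$pi, 11 / 6 / 100)
})
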