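test_that("binomial error filter matches hand-computed tail probabilities", {
  mk <- function(alt_count, depth = 100) {
    calls <- paste0(strrep("C", alt_count), strrep("A", depth - alt_count))
    data.frame(chrom = "ref", position = 1L, ref_base = "A", depth = depth,
               base_calls = calls, base_qualities = strrep("I", depth),
               n_indel_events = 0L, stringsAsFactors = FALSE)
  }
  # alt 1 of 100 at e = 0.01: P(X >= 1) ~ 0.634, not called
  out1 <- call_within_host_variants(mk(1), error_rate = 0.01, alpha = 0.05)
  expect_identical(nrow(out1$variants), 0L)
  # alt 10 of 100: P(X >= 10) ~ 1.1e-7, called
  out10 <- call_within_host_variants(mk(10), error_rate = 0.01, alpha = 0.05)
  expect_identical(nrow(out10$variants), 1L)
  expect_equal(out10$variants$alt_freq, 0.1)
  expect_equal(out10$variants$p_value,
               pbinom(9, 100, 0.01, lower.tail = FALSE))
})

test_that("coverage and indel-proximity filters drop the right columns", {
  set.seed(51)
  pu <- symbiocoal:::error_only_pileup(200, 100, 0)
  # one high-coverage column with a strong variant: excluded by the 1-SD rule
  pu$depth[7] <- 300L
  pu$base_calls[7] <- paste0(strrep("T", 150), strrep(pu$ref_base[7], 150))
  pu$base_qualities[7] <- strrep("I", 300)
  # an indel-bearing column with variant columns within 5 bp
  pu$n_indel_events[100] <- 1L
  pu$base_calls[103] <- paste0(strrep("G", 50), strrep(pu$ref_base[103], 50))
  out <- call_within_host_variants(pu, error_rate = 0.01)
  expect_identical(nrow(out$variants), 0L)
  expect_gte(out$n_depth_filtered, 1L)
  expect_gte(out$n_indel_filtered, 1L)
  # the same variant outside the window is called
  pu$base_calls[150] <- paste0(strrep("G", 50), strrep(pu$ref_base[150], 50))
  out2 <- call_within_host_variants(pu, error_rate = 0.01)
  expect_identical(out2$variants$position, 150L)
  # all-filtered input returns a status, not an error
  near <- pu[100:101, ]  # both within the indel-proximity window
  expect_identical(call_within_host_variants(near, error_rate = 0.01)$status,
                   "all columns filtered")
})

test_that("false positives stay below alpha and high-frequency variants are
           recovered", {
  set.seed(52)
  pu <- symbiocoal:::error_only_pileup(4000, 100, 0.01)
  out <- call_within_host_variants(pu, error_rate = 0.01, alpha = 0.05)
  expect_lte(nrow(out$variants) / out$n_usable_sites, 0.05)

  tv <- make_variant_pileup(1500, 100, 0.15, 0.01)
  outv <- call_within_host_variants(tv, error_rate = 0.01, alpha = 0.05)
  expect_gte(nrow(outv$variants) / nrow(tv), 0.99)
})

test_that("within-host folded spectrum folds and bins correctly", {
  v <- data.frame(alt_freq = c(0.9, 0.5, 0.04))
  afs <- within_host_folded_afs(v, n_bins = 10)
  expect_identical(sum(afs$counts), 3L)
  expect_identical(afs$counts[2], 1L)   # 0.1 falls in (0.05, 0.10]
  expect_identical(afs$counts[10], 1L)  # 0.5 in the last bin
  expect_identical(afs$counts[1], 1L)   # 0.04 in (0, 0.05]
  none <- within_host_folded_afs(data.frame(), n_bins = 5)
  expect_identical(none$counts, integer(5))
  expect_identical(none$status, "no variants")

  # 50:50 error-free mixture piles all mass in the 0.5 bin
  set.seed(53)
  mix <- make_variant_pileup(400, 200, 0.5, 0)
  calls <- call_within_host_variants(mix, error_rate = 1e-4)
  afs2 <- within_host_folded_afs(calls$variants, n_bins = 10)
  expect_gt(sum(afs2$counts[9:10]) / sum(afs2$counts), 0.98)
})

test_that("read-pair four-gamete cutoffs behave exactly as stated", {
  obs <- function(counts) {
    cfg <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
    do.call(rbind, lapply(1:4, function(k) {
      if (counts[k] == 0) return(NULL)
      data.frame(read_id = sprintf("r%d_%d", k, seq_len(counts[k])),
                 pos_a = 10L, base_a = cfg[k, 1],
                 pos_b = 40L, base_b = cfg[k, 2])
    }))
  }
  # balanced counts, total 120: flagged
  expect_true(read_pair_four_gamete(obs(c(30, 30, 30, 30)))$all_four_flag)
  # two-gamete mixture: never flagged
  expect_false(read_pair_four_gamete(obs(c(100, 0, 0, 100)))$all_four_flag)
  # boundary: proportions exactly 0.05 are NOT above the cutoff
  r <- read_pair_four_gamete(obs(c(94, 2, 2, 2)))
  expect_false(r$all_four_flag)
  r2 <- read_pair_four_gamete(obs(c(85, 5, 5, 5)))  # 5/100 == 0.05 exactly
  expect_false(r2$all_four_flag)
  r3 <- read_pair_four_gamete(obs(c(82, 6, 6, 6)))  # 0.06 > 0.05
  expect_true(r3$all_four_flag)
  # total 99 is below the observation floor
  r4 <- read_pair_four_gamete(obs(c(69, 10, 10, 10)))
  expect_false(r4$all_four_flag)
  expect_identical(r4$status, "insufficient_observations")
  # off-allele observations are discarded and counted
  o <- obs(c(50, 30, 30, 30))
  o$base_a[1] <- "N"
  r5 <- read_pair_four_gamete(o)
  expect_identical(r5$n_discarded, 1L)
  expect_identical(r5$total, 139L)
})

test_that("phasing flags arise from >= 4 haplotypes but never from <= 3,
           and read-backed signal is at least the consensus signal", {
  put <- function(x, p, b) { substr(x, p, p) <- b; x }
  base <- strrep("A", 400)
  h_ab <- put(put(base, 100, "C"), 160, "G")
  h_aB <- put(base, 100, "C")
  h_Ab <- put(base, 160, "G")
  h_AB <- base

  set.seed(54)
  three <- read_sim_spec(c(h_AB, h_aB, h_Ab), weights = c(0.4, 0.3, 0.3),
                         depth = 400, error_rate = 0, read_length = 100,
                         insert_mean = 150, insert_sd = 10)
  ph3 <- read_pair_four_gamete(make_reads(three)$phasing)
  expect_false(any(ph3$all_four_flag))

  four <- read_sim_spec(c(h_AB, h_aB, h_Ab, h_ab),
                        weights = c(0.25, 0.25, 0.25, 0.25),
                        depth = 400, error_rate = 0, read_length = 100,
                        insert_mean = 150, insert_sd = 10)
  ph4 <- read_pair_four_gamete(make_reads(four)$phasing)
  qualifying <- ph4[ph4$status == "ok", ]
  expect_gt(nrow(qualifying), 0)
  expect_true(all(qualifying$all_four_flag))

  # consensus chromosomes of the 4-haplotype mixture: the read-backed
  # failure proportion is >= the consensus-based proportion on these loci
  cons <- four_gamete_profile(haplotype_alignment(c(h_AB, h_aB, h_Ab, h_ab)))
  cons_prop <- sum(cons$n_failing) / sum(cons$n_pairs)
  rb_prop <- mean(qualifying$all_four_flag)
  expect_gte(rb_prop, cons_prop)
})
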