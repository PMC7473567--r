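test_that("metapopulation alignments are seed-deterministic and mutation-free
           input gives identical sequences", {
  tp0 <- transmission_params(20, 5, 0.2, mutation_rate = 0)
  a0 <- make_metapopulation_alignment(tp0, hosts_sampled = 4,
                                      symbionts_per_host = 2,
                                      genome_length = 5000, seed = 61)
  expect_identical(length(unique(a0$sequences)), 1L)
  expect_identical(length(a0$sequences), 8L)

  tp <- transmission_params(20, 5, 0.2, mutation_rate = 5e-3)
  a1 <- make_metapopulation_alignment(tp, 4, 2, 5000, seed = 62)
  a2 <- make_metapopulation_alignment(tp, 4, 2, 5000, seed = 62)
  expect_identical(a1$sequences, a2$sequences)
  expect_identical(a1$host_ids, a2$host_ids)
  tf1 <- tempfile(); tf2 <- tempfile()
  write_fasta_alignment(a1, tf1); write_fasta_alignment(a2, tf2)
  expect_identical(readLines(tf1), readLines(tf2))
})

test_that("Fst contrasts the transmission regimes as expected", {
  # between-host differentiation of two hosts, over 10 quasi-unlinked
  # genome windows so the site bootstrap is meaningful
  tp_v <- transmission_params(40, 8, 0, mutation_rate = 0.02,
                              bottleneck = 1)
  av <- make_metapopulation_alignment(tp_v, hosts_sampled = 2,
                                      symbionts_per_host = 4,
                                      genome_length = 50000, n_loci = 10,
                                      seed = 63)
  fv <- host_group_freqs(av, "host1", "host2")
  fst_v <- fst_between_hosts(fv$p1, fv$p2, fv$n1, fv$n2, seed = 64)
  expect_gt(fst_v$ci_low, 0)

  tp_h <- transmission_params(40, 8, 1, mutation_rate = 0.02)
  ah <- make_metapopulation_alignment(tp_h, 2, 4, 50000, n_loci = 10,
                                      seed = 65)
  fh <- host_group_freqs(ah, "host1", "host2")
  fst_h <- fst_between_hosts(fh$p1, fh$p2, fh$n1, fh$n2, seed = 66)
  expect_lte(fst_h$ci_low, 0.02)
  expect_gt(fst_v$fst, fst_h$fst)
})

test_that("read simulation is internally consistent", {
  put <- function(x, p, b) { substr(x, p, p) <- b; x }
  h1 <- strrep("A", 500)
  h2 <- put(put(h1, 120, "C"), 300, "G")
  spec <- read_sim_spec(c(h1, h2), weights = c(0.5, 0.5), depth = 60,
                        error_rate = 0, read_length = 80, insert_mean = 220,
                        insert_sd = 20, seed = 67)
  rd <- make_reads(spec)

  # error-free single-haplotype reads give zero alternate calls
  one <- make_reads(read_sim_spec(h1, depth = 30, error_rate = 0,
                                  read_length = 80, seed = 68))
  alt <- mapply(function(b, r) sum(strsplit(b, "")[[1]] != r),
                one$pileup$base_calls, one$pileup$ref_base)
  expect_identical(sum(alt), 0L)

  # pileup regenerated from the emitted read set matches byte-for-byte
  pu2 <- symbiocoal:::pileup_from_reads(rd$reads, rd$reference, rd$qual_char)
  expect_identical(pu2, rd$pileup)

  # coverage accounting: total depth equals total sequenced bases
  expect_identical(sum(rd$pileup$depth),
                   as.integer(2 * rd$n_pairs * spec$read_length))

  # 50:50 mixture: alt frequency at a variant site within binomial bounds
  v <- rd$pileup[rd$pileup$position == 120, ]
  bc <- table(strsplit(v$base_calls, "")[[1]])
  p_alt <- bc[["C"]] / v$depth
  ci <- qbinom(c(0.005, 0.995), v$depth, 0.5) / v$depth
  expect_true(p_alt >= ci[1] && p_alt <= ci[2])

  # phasing rows only reference variant positions
  expect_true(all(rd$phasing$pos_a %in% rd$variant_positions))
  expect_true(all(rd$phasing$pos_b %in% rd$variant_positions))
  expect_error(read_sim_spec(h1, read_length = 600), "read_length")
})

test_that("VCF fixtures encode their truth table", {
  fx <- make_vcf_fixture(n_pass = 6, n_fail = 4, seed = 69)
  kept <- filter_consensus_sites(fx$records, "genotyping")
  expect_identical(nrow(kept), 6L)
  expect_setequal(kept$position, fx$truth$position[fx$truth$should_pass])
  # a record violating only the MQ0 rule is removed
  mq0_fail <- fx$truth$position[!is.na(fx$truth$violated_rule) &
                                  fx$truth$violated_rule == "mq0_reads"]
  expect_false(any(mq0_fail %in% kept$position))
  # truth round-trips through the filter report
  tf <- tempfile(fileext = ".tsv")
  write_site_report(kept, tf)
  back <- read.table(tf, header = TRUE, sep = "\t")
  expect_setequal(back$position, kept$position)
})

test_that("the worked fixture has its documented structure", {
  f1 <- fixture_F1()
  expect_identical(length(f1$sample_ids), 4L)
  expect_identical(f1$genome_length, 100L)
  expect_identical(f1$variant_positions, c(10L, 50L, 90L))
  b <- symbiocoal:::biallelic_sites(f1)
  expect_identical(b$minor_count, c(1L, 2L, 2L))
})
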