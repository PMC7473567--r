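# Generators for every input the pipeline consumes: host-labelled
# metapopulation alignments, read pairs with pileups and phasing tables,
# VCF-style filter fixtures with known truth, and the shared worked
# fixture used in examples.

#' Simulate a host-labelled metapopulation alignment
#'
#' Sequences come either from the panmictic gene-conversion coalescent
#' (host labels attached round-robin) or from genealogies of the
#' host-structured transmission model mapped to sequences (each mutation
#' of the forward genealogy is assigned a distinct genomic position and a
#' derived base).
#'
#' @param params a [sim_params()] (panmictic) or [transmission_params()]
#'   (structured) object.
#' @param hosts_sampled,symbionts_per_host sampling design.
#' @param genome_length bp (structured mode; panmictic mode takes it from
#'   `params`).
#' @param n_loci structured mode: number of independent forward
#'   realizations whose mutations are mapped into successive genome
#'   windows.  The forward model emits one genealogy per run; a
#'   recombining genome behaves as many quasi-unlinked segments, which
#'   `n_loci > 1` emulates (and which makes site-resampling bootstraps
#'   meaningful).
#' @param seed optional randomization seed.
#' @return a [haplotype_alignment()] with host labels.
#' @export
make_metapopulation_alignment <- function(params, hosts_sampled = 5L,
                                          symbionts_per_host = 2L,
                                          genome_length = 100000L,
                                          n_loci = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- hosts_sampled * symbionts_per_host
  hosts <- rep(paste0("host", seq_len(hosts_sampled)),
               each = symbionts_per_host)
  if (inherits(params, "sim_params")) {
    p <- params
    p$sample_size <- as.integer(n)
    p$seed <- NULL
    rep1 <- simulate_coalescent_gc(p, emit = "alignment")
    aln <- rep1$alignment
    aln$host_ids <- hosts
    aln$sample_ids <- paste0(hosts, "_s", rep(seq_len(symbionts_per_host),
                                              hosts_sampled))
    return(aln)
  }
  stopifnot(inherits(params, "transmission_params"))
  win <- genome_length %/% n_loci
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, genome_length, replace = TRUE)
  seqm <- matrix(rep(ref, each = n), nrow = n)
  for (k in seq_len(n_loci)) {
    x <- cpp_transmission(params$n_hosts, params$n_symbionts,
                          params$horizontal_rate, params$mutation_rate,
                          params$bottleneck, params$n_generations,
                          0L, 0L, TRUE, hosts_sampled, symbionts_per_host)
    parent <- x$tree_parent
    nmut <- x$tree_nmut
    nodes <- x$sample_nodes + 1L  # 1-based
    path_nodes <- lapply(nodes, function(v) {
      out <- integer(0)
      while (v > 1L) { out <- c(out, v); v <- parent[v] + 1L }
      out
    })
    mut_nodes <- sort(unique(unlist(path_nodes)))
    n_mut <- sum(nmut[mut_nodes])
    if (n_mut > win / 10)
      stop("genome_length too small for the realized mutation count (",
           n_mut, " in one of ", n_loci, " windows)")
    if (n_mut == 0L) next
    pos <- (k - 1L) * win + sort(sample.int(win, n_mut))
    mut_of_node <- split(seq_len(n_mut),
                         rep(seq_along(mut_nodes), nmut[mut_nodes]))
    der <- vapply(ref[pos], function(b) sample(setdiff(bases, b), 1L), "")
    for (i in seq_len(n)) {
      idx <- unlist(mut_of_node[match(path_nodes[[i]], mut_nodes)],
                    use.names = FALSE)
      seqm[i, pos[idx]] <- der[idx]
    }
  }
  seqs <- apply(seqm, 1, paste, collapse = "")
  ids <- paste0(hosts, "_s", rep(seq_len(symbionts_per_host), hosts_sampled))
  haplotype_alignment(seqs, sample_ids = ids, host_ids = hosts)
}

#' Specification for synthetic paired-end reads
#'
#' @param haplotypes equal-length nucleotide strings.
#' @param weights mixture weights (sum to 1).
#' @param depth mean per-position coverage.
#' @param error_rate independent per-base substitution probability in
#'   `[0, 0.5)`; errors substitute uniformly to one of the other bases.
#' @param read_length,insert_mean,insert_sd library geometry in bp.
#' @param seed optional randomization seed.
#' @return a `read_sim_spec` list.
#' @export
read_sim_spec <- function(haplotypes, weights = NULL, depth = 100,
                          error_rate = 0.01, read_length = 100L,
                          insert_mean = 300L, insert_sd = 30L, seed = NULL) {
  if (length(unique(nchar(haplotypes))) != 1L)
    stop("haplotypes must have equal length")
  if (is.null(weights)) weights <- rep(1 / length(haplotypes),
                                       length(haplotypes))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (depth <= 0) stop("depth must be > 0")
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  if (read_length > nchar(haplotypes[1]))
    stop("spec error: read_length exceeds haplotype length")
  structure(list(haplotypes = toupper(haplotypes), weights = weights,
                 depth = depth, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = insert_sd, seed = seed),
            class = "read_sim_spec")
}

# pileup data frame from a read table (used both by make_reads and by the
# internal-consistency check that regenerates the pileup from the reads)
pileup_from_reads <- function(reads, ref, qual_char, chrom = "ref") {
  L <- nchar(ref)
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  calls <- vector("list", L)
  for (i in seq_len(nrow(reads))) {
    s <- reads$start[i]
    b <- strsplit(reads$seq[i], "", fixed = TRUE)[[1]]
    for (k in seq_along(b)) {
      p <- s + k - 1L
      calls[[p]] <- c(calls[[p]], b[k])
    }
  }
  depth <- lengths(calls)
  data.frame(chrom = chrom, position = seq_len(L), ref_base = refv,
             depth = depth,
             base_calls = vapply(calls, paste, "", collapse = ""),
             base_qualities = strrep(qual_char, depth),
             n_indel_events = 0L, stringsAsFactors = FALSE)
}

#' Simulate paired reads from a haplotype mixture
#'
#' Draws read pairs from weighted haplotypes with independent per-base
#' errors, and emits three mutually consistent artifacts: the read table,
#' a pileup over the first haplotype as reference, and the read-pair
#' phasing table (one row per read pair per co-observed pair of variant
#' sites).  Quality strings are a constant phred matching
#' `-10*log10(error_rate)` (capped at Q40 for error-free input), so
#' quality-derived and fixed error modes agree on generated data.
#'
#' @param spec a [read_sim_spec()].
#' @return list with `reads` (read_id, hap, mate, start, seq), `pileup`
#'   (data frame in [parse_pileup()] layout), `phasing` (read_id, pos_a,
#'   base_a, pos_b, base_b), `variant_positions`, `reference`,
#'   `qual_char`, `n_pairs`.
#' @export
make_reads <- function(spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- nchar(spec$haplotypes[1])
  rl <- spec$read_length
  n_pairs <- max(1L, as.integer(round(spec$depth * L / (2 * rl))))
  hapm <- do.call(rbind, strsplit(spec$haplotypes, "", fixed = TRUE))
  vpos <- which(apply(hapm, 2, function(x) length(unique(x)) > 1L))
  bases <- c("A", "C", "G", "T")
  q <- if (spec$error_rate > 0)
    min(40L, as.integer(round(-10 * log10(spec$error_rate)))) else 40L
  qual_char <- intToUtf8(q + 33L)

  hap <- sample.int(length(spec$haplotypes), n_pairs, replace = TRUE,
                    prob = spec$weights)
  ins <- pmin(L, pmax(2L * rl, as.integer(round(
    rnorm(n_pairs, spec$insert_mean, spec$insert_sd)))))
  start1 <- vapply(ins, function(i) sample.int(L - i + 1L, 1L), 1L)
  start2 <- start1 + ins - rl

  one_read <- function(h, s) {
    b <- hapm[h, s:(s + rl - 1L)]
    if (spec$error_rate > 0) {
      err <- which(runif(rl) < spec$error_rate)
      for (k in err) b[k] <- sample(setdiff(bases, b[k]), 1L)
    }
    paste(b, collapse = "")
  }
  reads <- data.frame(
    read_id = rep(paste0("rp", seq_len(n_pairs)), each = 2L),
    hap = rep(hap, each = 2L),
    mate = rep(1:2, n_pairs),
    start = as.integer(rbind(start1, start2)),
    seq = NA_character_, stringsAsFactors = FALSE)
  reads$seq <- vapply(seq_len(nrow(reads)),
                      function(i) one_read(reads$hap[i], reads$start[i]), "")

  pu <- pileup_from_reads(reads, spec$haplotypes[1], qual_char)

  # phasing: variant sites co-observed on the two mates of one pair
  phl <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    rows <- reads[c(2L * i - 1L, 2L * i), ]
    cover <- lapply(1:2, function(m)
      vpos[vpos >= rows$start[m] & vpos <= rows$start[m] + rl - 1L])
    obs_base <- function(m, p)
      substr(rows$seq[m], p - rows$start[m] + 1L, p - rows$start[m] + 1L)
    sites <- sort(unique(c(cover[[1]], cover[[2]])))
    if (length(sites) < 2L) next
    # base observed at each site (mate 1 wins if both cover it)
    bs <- vapply(sites, function(p)
      if (p %in% cover[[1]]) obs_base(1, p) else obs_base(2, p), "")
    pr <- t(combn(seq_along(sites), 2L))
    phl[[i]] <- data.frame(read_id = paste0("rp", i),
                           pos_a = sites[pr[, 1]], base_a = bs[pr[, 1]],
                           pos_b = sites[pr[, 2]], base_b = bs[pr[, 2]],
                           stringsAsFactors = FALSE)
  }
  phasing <- do.call(rbind, phl[!vapply(phl, is.null, NA)])
  if (is.null(phasing))
    phasing <- data.frame(read_id = character(0), pos_a = integer(0),
                          base_a = character(0), pos_b = integer(0),
                          base_b = character(0))
  list(reads = reads, pileup = pu, phasing = phasing,
       variant_positions = vpos, reference = spec$haplotypes[1],
       qual_char = qual_char, n_pairs = n_pairs)
}

#' VCF-style filter fixture with known truth
#'
#' Constructs `n_pass` records passing every genotyping-mode threshold and
#' `n_fail` records each violating exactly one named threshold, cycling
#' through the four rules (quality/depth, Fisher's strand, genotype
#' quality, MQ0 count).
#'
#' @param n_pass,n_fail record counts.
#' @param seed optional randomization seed.
#' @return list with `records` ([site_records()]) and `truth` (data frame
#'   with `position`, `should_pass`, `violated_rule`).
#' @export
make_vcf_fixture <- function(n_pass, n_fail, seed = NULL) {
  if (n_pass + n_fail < 1) stop("need at least one record")
  if (!is.null(seed)) set.seed(seed)
  n <- n_pass + n_fail
  pos <- sort(sample.int(100000L, n))
  qd <- runif(n, 5, 30)
  fs <- runif(n, 0, 30)
  gq <- runif(n, 40, 99)
  mq0 <- sample(0:3, n, replace = TRUE)
  rules <- rep(c("quality_by_depth", "fisher_strand", "genotype_quality",
                 "mq0_reads"), length.out = max(n_fail, 1L))
  violated <- rep(NA_character_, n)
  if (n_fail > 0) {
    fail_idx <- sample.int(n, n_fail)
    for (k in seq_len(n_fail)) {
      i <- fail_idx[k]
      violated[i] <- rules[k]
      switch(rules[k],
             quality_by_depth = { qd[i] <- runif(1, 0, 1.9) },
             fisher_strand = { fs[i] <- runif(1, 60.1, 200) },
             genotype_quality = { gq[i] <- runif(1, 0, 19.9) },
             mq0_reads = { mq0[i] <- sample(6:20, 1) })
    }
  }
  refs <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alts <- vapply(refs, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  rec <- site_records(position = pos, ref_allele = refs, alt_alleles = alts,
                      quality_by_depth = qd, fisher_strand = fs,
                      genotype_quality = gq, mq0_reads = mq0)
  list(records = rec,
       truth = data.frame(position = pos, should_pass = is.na(violated),
                          violated_rule = violated,
                          stringsAsFactors = FALSE))
}

#' The shared worked fixture: 4 haplotypes, 100 bp, 3 biallelic sites
#'
#' Sites at positions 10 (minor allele count 1), 50 (count 2) and
#' 90 (count 2); total pairwise differences 11, giving per-site
#' pi = 11/6/100, Watterson's theta = 3/(11/6 * 100) and
#' Tajima's D of about 1.09.
#'
#' @return a [haplotype_alignment()].
#' @export
fixture_F1 <- function() {
  base <- strrep("A", 100)
  put <- function(s, pos, b) {
    substr(s, pos, pos) <- b
    s
  }
  s1 <- put(base, 50, "C")
  s2 <- put(put(base, 50, "C"), 90, "T")
  s3 <- put(base, 90, "T")
  s4 <- put(base, 10, "G")
  haplotype_alignment(c(s1, s2, s3, s4),
                      sample_ids = paste0("s", 1:4))
}
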