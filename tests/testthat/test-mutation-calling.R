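test_that("events are called per column with 1-based reference coordinates", {
  # multi-base deletion decomposes into per-base events; insertion is one
  # event anchored after the preceding reference position
  aln <- pairwise_from_gapped("ACGTACGT--", "AC--ACGTTT")
  ev <- call_mutations(aln)
  expect_identical(ev$kind, c("deletion", "deletion", "insertion"))
  expect_identical(ev$site, c(3L, 4L, 8L))
  expect_identical(ev$label, c("G3del", "U4del", "8insUU"))
  # substitution call
  ev2 <- call_mutations(pairwise_from_gapped("ACGT", "ACCT"))
  expect_identical(ev2$label, "G3C")
  # identity alignment: empty set
  expect_identical(nrow(call_mutations(pairwise_from_gapped("ACGT", "ACGT"))), 0L)
})

test_that("insertions before the first reference base anchor at position 0", {
  ev <- call_mutations(pairwise_from_gapped("--ACGT", "GGACGT"))
  expect_identical(ev$site, 0L)
  expect_identical(ev$kind, "insertion")
  expect_identical(ev$alt, "GG")
})

test_that("parasite events lift to host coordinates outside the window", {
  refs <- tiny_refs(seed = 51L)
  win <- refs$windows[["parasite-alpha"]]
  ret <- retained_sites(refs, "parasite-alpha")
  par_ref <- refs$sequences[["parasite-alpha"]]
  # mutate the 5th and the 35th base of the parasite reference
  mut_sites_par <- c(5L, 35L)
  read <- par_ref
  alts <- character(2)
  for (k in seq_along(mut_sites_par)) {
    cur <- substr(read, mut_sites_par[k], mut_sites_par[k])
    alts[k] <- setdiff(c("A", "C", "G", "T"), cur)[1]
    read <- apply_sub(read, mut_sites_par[k], alts[k])
  }
  aln <- align_to_reference(read, par_ref)
  lifted <- lift_events_to_host(call_mutations(aln), refs, "parasite-alpha")
  expect_identical(lifted$site, ret[mut_sites_par])
  expect_true(all(lifted$site < win[1] | lifted$site > win[2]))
  expect_identical(lifted$alt, alts)
})

test_that("simulated parasite reads never produce events inside the window", {
  cfg <- simulation_config(
    n_rounds = 6L, host_length = 150L,
    deletion_windows = list("parasite-alpha" = c(20L, 130L)),
    substitution_rate = 2e-3, indel_rate = 0, deletion_event_rate = 0.02,
    init_molecules = 40L, droplet_capacity = 60L,
    replication_factor_host = 4, max_population = 5e4,
    reads_per_round = 150L, seq_error_rate = 0, seed = 52L)
  sim <- simulate_serial_transfer(cfg)
  reads <- sim$reads[sim$reads$class_label == "parasite-alpha", ]
  expect_gt(nrow(reads), 0L)
  ft <- build_frequency_table(reads, sim$refs)
  expect_true(all(ft$site < 20L | ft$site > 130L))
})

test_that("frequency table equals direct counting", {
  refs <- tiny_refs(seed = 53L)
  host <- refs$host
  alt3 <- setdiff(c("A", "C", "G", "T"), substr(host, 3, 3))[1]
  seqs <- c(rep(seq_with_subs(host, 3L, alt3), 3), rep(host, 17))
  reads <- make_read_df(seqs, round = 1L, class_label = "host")
  ft <- build_frequency_table(reads, refs)
  expect_identical(nrow(ft), 1L)
  expect_identical(ft$count, 3L)
  expect_identical(ft$depth, 20L)
  expect_equal(ft$frequency, 0.15)
  expect_identical(ft$label, mutation_label(3L, "substitution",
                                            substr(host, 3, 3), alt3))
})

test_that("a zero-error clonal population yields an empty table", {
  refs <- tiny_refs(seed = 54L)
  reads <- make_read_df(rep(refs$host, 10))
  ft <- build_frequency_table(reads, refs)
  expect_identical(nrow(ft), 0L)
})

test_that("a planted 0.5-frequency mutation is recovered within 3 SE", {
  refs <- tiny_refs(seed = 55L)
  ev <- event_row(7L, "substitution", substr(refs$host, 7, 7),
                  setdiff(c("A", "C", "G", "T"), substr(refs$host, 7, 7))[1])
  pop <- make_population(refs, list(ev, NULL), c(1L, 1L))
  reads <- sample_reads(pop, 2000L, seq_error_rate = 0, seed = 56L)
  ft <- build_frequency_table(reads, refs)
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(ft$frequency[ft$label == ev$label] - 0.5), 3 * se)
})

test_that("dominance uses strict inequality and reports distinct sites", {
  tab <- data.frame(
    round = c(1L, 1L, 2L, 2L), class_label = "host",
    site = c(3L, 5L, 3L, 5L), kind = "substitution",
    ref = c("A", "C", "A", "C"), alt = c("G", "T", "G", "T"),
    label = c("A3G", "C5U", "A3G", "C5U"),
    count = c(2L, 3L, 1L, 2L), depth = 20L,
    frequency = c(0.10, 0.15, 0.05, 0.10), stringsAsFactors = FALSE)
  dom <- identify_dominant(tab, 0.10)
  # A3G peaks at exactly 0.10 -> excluded ("more than 10%")
  expect_identical(dom$mutations$label, "C5U")
  expect_identical(dom$sites, 5L)
  expect_error(identify_dominant(tab, 0), "strictly between")
  expect_error(identify_dominant(tab, 1.5), "strictly between")
  # empty table -> empty set
  expect_identical(nrow(identify_dominant(tab[0, ], 0.1)$mutations), 0L)
})

test_that("two mutations at one site collapse to a single site", {
  refs <- tiny_refs(seed = 57L)
  host <- refs$host
  others <- setdiff(c("A", "C", "G", "T"), substr(host, 9, 9))
  seqs <- c(rep(seq_with_subs(host, 9L, others[1]), 4),
            rep(seq_with_subs(host, 9L, others[2]), 4),
            rep(host, 12))
  reads <- make_read_df(seqs)
  dom <- identify_dominant(build_frequency_table(reads, refs), 0.10)
  expect_identical(nrow(dom$mutations), 2L)
  expect_identical(length(dom$sites), 1L)
})

test_that("dominant calling equals a brute-force scan on simulated data", {
  cfg <- simulation_config(
    n_rounds = 4L, host_length = 100L, deletion_windows = list(),
    substitution_rate = 4e-3, indel_rate = 0, deletion_event_rate = 0,
    init_molecules = 40L, droplet_capacity = 60L,
    replication_factor_host = 4, max_population = 5e4,
    reads_per_round = 120L, seq_error_rate = 0, seed = 58L)
  sim <- simulate_serial_transfer(cfg)
  ft <- build_frequency_table(sim$reads, sim$refs)
  dom <- identify_dominant(ft, 0.10)
  # brute force: per-read labels recounted directly
  evs <- coevotrace:::call_read_events(sim$reads, sim$refs)
  labels <- lapply(evs, function(e) if (is.null(e)) character() else e$label)
  groups <- paste(sim$reads$round, sim$reads$class_label)
  expect_identical(sort(dom$mutations$label),
                   brute_force_dominant(labels, groups, 0.10))
})

test_that("genotype projection pools identical vectors with exact frequencies", {
  refs <- tiny_refs(seed = 59L)
  host <- refs$host
  s <- c(3L, 7L)
  alts <- vapply(s, function(p) setdiff(c("A", "C", "G", "T"),
                                        substr(host, p, p))[1], "")
  seqs <- c(rep(host, 5),                                   # 00
            rep(seq_with_subs(host, s[2], alts[2]), 3),     # 01
            rep(seq_with_subs(host, s, alts), 2))           # 11
  reads <- make_read_df(seqs)
  ft <- build_frequency_table(reads, refs)
  dom <- identify_dominant(ft, 0.10)
  g <- project_genotypes(reads, refs, dom)
  expect_identical(g$vector, c("00", "01", "11"))
  expect_equal(g$frequency, c(0.5, 0.3, 0.2))
  expect_identical(g$rank, 1:3)
  expect_equal(sum(g$frequency), 1)
})

test_that("with no dominant sites every group collapses to one genotype", {
  refs <- tiny_refs(seed = 60L)
  reads <- make_read_df(rep(refs$host, 8), round = 2L)
  dom <- identify_dominant(build_frequency_table(reads, refs), 0.10)
  g <- project_genotypes(reads, refs, dom)
  expect_identical(nrow(g), 1L)
  expect_equal(g$frequency, 1)
})

test_that("parasite genotypes mask dominant sites inside their window", {
  refs <- tiny_refs(seed = 61L)
  host <- refs$host
  win <- refs$windows[["parasite-alpha"]]
  inside <- win[1] + 5L
  outside <- 5L
  alt_in <- setdiff(c("A", "C", "G", "T"), substr(host, inside, inside))[1]
  alt_out <- setdiff(c("A", "C", "G", "T"), substr(host, outside, outside))[1]
  host_reads <- make_read_df(
    rep(seq_with_subs(host, c(inside, outside), c(alt_in, alt_out)), 10),
    class_label = "host")
  par_reads <- make_read_df(
    rep(seq_with_subs(host, outside, alt_out, window = win), 10),
    class_label = "parasite-alpha", ids = sprintf("par_%02d", 1:10))
  reads <- rbind(host_reads, par_reads)
  dom <- identify_dominant(build_frequency_table(reads, refs), 0.10)
  expect_identical(nrow(dom$mutations), 2L)
  g <- project_genotypes(reads, refs, dom)
  par_vec <- g$vector[g$class_label == "parasite-alpha"]
  host_vec <- g$vector[g$class_label == "host"]
  expect_identical(host_vec, "11")
  # site order: outside (5) before inside; the window site is masked
  expect_identical(par_vec, "1-")
})

test_that("reads with N at an unmasked dominant site are dropped", {
  refs <- tiny_refs(seed = 62L)
  host <- refs$host
  alt <- setdiff(c("A", "C", "G", "T"), substr(host, 4, 4))[1]
  mut <- seq_with_subs(host, 4L, alt)
  ambiguous <- apply_sub(host, 4L, "N")
  reads <- make_read_df(c(rep(mut, 4), rep(host, 5), ambiguous))
  dom <- identify_dominant(build_frequency_table(reads, refs), 0.10)
  g <- project_genotypes(reads, refs, dom)
  expect_identical(sum(g$n_reads), 9L)
  expect_equal(g$frequency[g$vector == "1"], 4 / 9)
})

test_that("genotype frequencies sum to one per group before truncation", {
  cfg <- simulation_config(
    n_rounds = 3L, host_length = 100L, deletion_windows = list(),
    substitution_rate = 3e-3, indel_rate = 0, deletion_event_rate = 0,
    init_molecules = 40L, droplet_capacity = 60L,
    replication_factor_host = 4, max_population = 5e4,
    reads_per_round = 100L, seq_error_rate = 0, seed = 63L)
  sim <- simulate_serial_transfer(cfg)
  ft <- build_frequency_table(sim$reads, sim$refs)
  dom <- identify_dominant(ft, 0.05)
  g <- project_genotypes(sim$reads, sim$refs, dom, top_n = 1000L)
  sums <- tapply(g$frequency, paste(g$round, g$class_label), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # truncation keeps the most frequent genotypes
  g2 <- project_genotypes(sim$reads, sim$refs, dom, top_n = 2L)
  expect_true(all(tapply(g2$rank, paste(g2$round, g2$class_label),
                         function(r) all(r <= 2L))))
})
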