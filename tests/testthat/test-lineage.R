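# Build a two-class experiment with controlled per-round frequencies:
# each entry of `design` gives, per round, the fraction of reads carrying
# each planted mutation, separately for host and parasite.
lineage_fixture <- function(seed = 81L) {
  refs <- tiny_refs(seed = seed)
  host <- refs$host
  win <- refs$windows[["parasite-alpha"]]
  sites <- c(5L, 12L, 175L)   # all in the parasite's retained region
  alts <- vapply(sites, function(p)
    setdiff(c("A", "C", "G", "T"), substr(host, p, p))[1], "")
  labels <- mutation_label(sites, "substitution",
                           vapply(sites, function(p) substr(host, p, p), ""),
                           alts)
  build_reads <- function(round, class_label, fractions, n = 20L) {
    counts <- round(fractions * n)
    seqs <- rep(if (class_label == "host") host else
      excise_window(host, win), n)
    for (k in seq_along(sites)) {
      if (counts[k] == 0) next
      for (i in seq_len(counts[k])) {
        s <- seqs[i]
        # re-apply on the class sequence: map host site to class coordinates
        pos <- if (class_label == "host") sites[k] else
          match(sites[k], setdiff(seq_len(nchar(host)), win[1]:win[2]))
        seqs[i] <- apply_sub(s, pos, alts[k])
      }
    }
    make_read_df(seqs, round = round, class_label = class_label,
                 ids = sprintf("%s_r%d_%03d", class_label, round, seq_len(n)))
  }
  list(refs = refs, sites = sites, alts = alts, labels = labels,
       build_reads = build_reads)
}

test_that("parasite-unique mutations are those never dominant in the host", {
  fx <- lineage_fixture()
  # mutation 1: parasite 0.4, host 0 everywhere -> unique
  # mutation 2: parasite 0.5, host 0.3 in round 2 -> not unique
  # mutation 3: parasite 0.2, host at most 0.05 -> unique (threshold mode)
  reads <- rbind(
    fx$build_reads(1L, "host", c(0, 0, 0.05)),
    fx$build_reads(2L, "host", c(0, 0.3, 0)),
    fx$build_reads(1L, "parasite-alpha", c(0.4, 0.5, 0.2)),
    fx$build_reads(2L, "parasite-alpha", c(0.4, 0.5, 0.2)))
  ft <- build_frequency_table(reads, fx$refs)
  dom <- identify_dominant(ft, 0.10)
  rep_thr <- find_unique_mutations(ft, dom, fx$refs, "parasite-alpha")
  expect_setequal(rep_thr$label, fx$labels[c(1, 3)])
  expect_identical(rep_thr$first_round[rep_thr$label == fx$labels[1]], 1L)
  expect_identical(rep_thr$last_round[rep_thr$label == fx$labels[1]], 2L)
  # absent mode additionally drops the mutation the host carries at 0.05
  rep_abs <- find_unique_mutations(ft, dom, fx$refs, "parasite-alpha",
                                   mode = "absent")
  expect_identical(rep_abs$label, fx$labels[1])
  expect_error(find_unique_mutations(ft, dom, fx$refs, "no-such-class"),
               "unknown class")
})

test_that("a parasite class with no dominant mutations yields an empty report", {
  fx <- lineage_fixture(seed = 82L)
  reads <- rbind(fx$build_reads(1L, "host", c(0.5, 0, 0)),
                 fx$build_reads(1L, "parasite-alpha", c(0, 0, 0)))
  ft <- build_frequency_table(reads, fx$refs)
  dom <- identify_dominant(ft, 0.10)
  rep <- find_unique_mutations(ft, dom, fx$refs, "parasite-alpha")
  expect_identical(nrow(rep), 0L)
})

test_that("persistence tracking reports spans and gaps", {
  fx <- lineage_fixture(seed = 83L)
  # rounds 13, 24, 33: above threshold throughout -> no gaps
  reads <- rbind(
    fx$build_reads(13L, "parasite-alpha", c(0.4, 0, 0)),
    fx$build_reads(24L, "parasite-alpha", c(0.3, 0, 0)),
    fx$build_reads(33L, "parasite-alpha", c(0.2, 0, 0)))
  ft <- build_frequency_table(reads, fx$refs)
  tr <- track_persistence(ft, fx$labels[1], "parasite-alpha", 0.10)
  expect_identical(tr$rounds_above, c(13L, 24L, 33L))
  expect_identical(tr$first_round, 13L)
  expect_identical(tr$last_round, 33L)
  expect_identical(tr$gaps, integer(0))
  expect_error(track_persistence(ft, "Z999Z", "parasite-alpha"),
               "does not occur")
})

test_that("a mutation that surges and disappears leaves a bounded track", {
  fx <- lineage_fixture(seed = 84L)
  # present at 53 and 60, dips below threshold at 57, gone by 65
  reads <- rbind(
    fx$build_reads(53L, "parasite-alpha", c(0.6, 0, 0)),
    fx$build_reads(57L, "parasite-alpha", c(0.05, 0, 0)),
    fx$build_reads(60L, "parasite-alpha", c(0.4, 0, 0)),
    fx$build_reads(65L, "parasite-alpha", c(0, 0, 0)))
  ft <- build_frequency_table(reads, fx$refs)
  tr <- track_persistence(ft, fx$labels[1], "parasite-alpha", 0.10)
  expect_identical(tr$rounds_above, c(53L, 60L))
  expect_identical(tr$last_round, 60L)
  expect_identical(tr$gaps, 57L)
  # never above threshold -> empty track
  tr2 <- track_persistence(ft, fx$labels[1], "parasite-alpha", 0.9)
  expect_identical(length(tr2$rounds_above), 0L)
  expect_true(is.na(tr2$first_round))
})

test_that("origin matching finds same- or earlier-round masked-0 hosts", {
  g <- data.frame(
    vector = c("110", "010", "01-", "11-"),
    class_label = c("host", "host", "parasite-alpha", "parasite-alpha"),
    round = c(1L, 2L, 2L, 1L),
    genotype_id = c("h1", "h2", "p1", "p2"),
    stringsAsFactors = FALSE)
  hits <- match_parasite_origin(g)
  # p1 ("01-") matches h2 ("010") in the same round
  expect_identical(hits$host_id[hits$parasite_id == "p1"], "h2")
  expect_identical(hits$round_lag[hits$parasite_id == "p1"], 0L)
  # p2 ("11-") matches h1 in round 1
  expect_identical(hits$host_id[hits$parasite_id == "p2"], "h1")
  # a parasite differing at a retained site matches nothing
  g2 <- rbind(g, data.frame(vector = "00-", class_label = "parasite-alpha",
                            round = 2L, genotype_id = "p3",
                            stringsAsFactors = FALSE))
  hits2 <- match_parasite_origin(g2)
  expect_false("p3" %in% hits2$parasite_id)
  # empty parasite set -> empty result
  expect_identical(nrow(match_parasite_origin(g[g$class_label == "host", ])), 0L)
})

test_that("origin matching never uses later-round hosts", {
  g <- data.frame(
    vector = c("11-", "110"),
    class_label = c("parasite-alpha", "host"),
    round = c(1L, 2L),
    genotype_id = c("p", "h"),
    stringsAsFactors = FALSE)
  expect_identical(nrow(match_parasite_origin(g)), 0L)
})

test_that("results are invariant under permutation of input order", {
  fx <- lineage_fixture(seed = 85L)
  reads <- rbind(
    fx$build_reads(1L, "host", c(0, 0.3, 0)),
    fx$build_reads(1L, "parasite-alpha", c(0.4, 0.5, 0.2)))
  set.seed(86)
  shuffled <- reads[sample(nrow(reads)), ]
  ft1 <- build_frequency_table(reads, fx$refs)
  ft2 <- build_frequency_table(shuffled, fx$refs)
  dom1 <- identify_dominant(ft1, 0.10); dom2 <- identify_dominant(ft2, 0.10)
  expect_identical(dom1$mutations, dom2$mutations)
  r1 <- find_unique_mutations(ft1, dom1, fx$refs, "parasite-alpha")
  r2 <- find_unique_mutations(ft2, dom2, fx$refs, "parasite-alpha")
  expect_identical(r1, r2)
})

test_that("every origin candidate pair is also a cross-class edge", {
  fx <- lineage_fixture(seed = 87L)
  reads <- rbind(
    fx$build_reads(1L, "host", c(0.5, 0.3, 0)),
    fx$build_reads(1L, "parasite-alpha", c(0.5, 0.3, 0)))
  ft <- build_frequency_table(reads, fx$refs)
  dom <- identify_dominant(ft, 0.10)
  g <- project_genotypes(reads, fx$refs, dom)
  origins <- match_parasite_origin(g)
  edges <- build_edges(build_distance_matrix(g))
  cross <- edges[edges$type == "cross", ]
  cross_pairs <- c(paste(cross$id1, cross$id2), paste(cross$id2, cross$id1))
  expect_gt(nrow(origins), 0L)
  for (k in seq_len(nrow(origins)))
    expect_true(paste(origins$host_id[k], origins$parasite_id[k]) %in% cross_pairs)
})
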