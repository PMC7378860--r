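# Fixture builders. Sequence surgery here is done with plain string
# operations so fixtures do not depend on the package's own materialization.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

apply_sub <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

excise_window <- function(seq, w) {
  paste0(substr(seq, 1, w[1] - 1), substr(seq, w[2] + 1, nchar(seq)))
}

# substitute a set of host sites (with fixed alt bases) into a host-derived
# sequence, then optionally excise a deletion window (host coordinates)
seq_with_subs <- function(host, sites, alts, window = NULL) {
  s <- host
  for (k in seq_along(sites)) s <- apply_sub(s, sites[k], alts[k])
  if (!is.null(window)) s <- excise_window(s, window)
  s
}

make_read_df <- function(sequences, round = 1L, class_label = "host",
                         passes = NA_integer_, ids = NULL) {
  n <- length(sequences)
  data.frame(
    id = ids %||% sprintf("fix_%04d", seq_len(n)),
    sequence = sequences,
    round = rep_len(round, n),
    class_label = rep_len(class_label, n),
    mol = NA_integer_,
    passes = rep_len(passes, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small two-class reference set used across tests
tiny_refs <- function(L = 200L, window = c(30L, 170L), seed = 42L) {
  set.seed(seed)
  generate_reference_set(L, list("parasite-alpha" = window))
}

# length bins matched to tiny_refs geometry
tiny_bins <- function(L = 200L, window = c(30L, 170L)) {
  Lp <- L - (window[2] - window[1] + 1L)
  data.frame(class_label = c("host", "parasite-alpha"),
             min_length = c(L - 20L, Lp - 15L),
             max_length = c(L + 20L, Lp + 15L),
             stringsAsFactors = FALSE)
}

# an event data.frame row in the package's layout
event_row <- function(site, kind, ref, alt) {
  data.frame(site = site, kind = kind, ref = ref, alt = alt,
             label = mutation_label(site, kind, ref, alt),
             stringsAsFactors = FALSE)
}

# population of given genotypes (list of event data.frames or NULL) with
# copy counts, all one class and round
make_population <- function(refs, events_list, copy_counts,
                            class_label = "host", round = 1L) {
  n <- length(events_list)
  members <- data.frame(
    molecule_id = seq_len(n), parent_id = rep(NA_integer_, n),
    class_label = rep_len(class_label, n),
    copy_count = as.integer(copy_counts),
    stringsAsFactors = FALSE)
  replicator_population(round, members, events_list, refs)
}
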