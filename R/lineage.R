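#' Parasite-unique mutations
#'
#' Reports the parasite class's dominant mutations that were never found in
#' the corresponding (retained) region of the host: a mutation qualifies if
#' its site lies in the class's retained region and its host frequency
#' never exceeds the threshold in any sequenced round (mode `"threshold"`,
#' the default, symmetric with dominance calling) or if the host carries no
#' read at all with the mutation (mode `"absent"`).
#'
#' @param table A [build_frequency_table()] result covering both classes.
#' @param dominant A [identify_dominant()] result.
#' @param refs A [reference_set()].
#' @param parasite_class Parasite class label.
#' @param host_class Host class label (default `"host"`).
#' @param threshold Host-frequency threshold for mode `"threshold"`;
#'   defaults to the dominance threshold.
#' @param mode `"threshold"` or `"absent"`.
#' @return A `data.frame` with one row per unique mutation: `label`, `site`,
#'   `kind`, `ref`, `alt`, `first_round`, `last_round` (rounds where the
#'   parasite frequency exceeded the dominance threshold).
#' @export
find_unique_mutations <- function(table, dominant, refs, parasite_class,
                                  host_class = "host",
                                  threshold = NULL,
                                  mode = c("threshold", "absent")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dominant, "dominant_set"), inherits(refs, "reference_set"))
  known <- c("host", names(refs$windows))
  if (!parasite_class %in% known) stop("unknown class label: ", parasite_class)
  if (!host_class %in% known) stop("unknown class label: ", host_class)
  threshold <- threshold %||% dominant$threshold
  w <- dominant$witnesses
  para_w <- w[w$class_label == parasite_class, , drop = FALSE]
  if (nrow(para_w) == 0L)
    return(data.frame(label = character(), site = integer(),
                      kind = character(), ref = character(),
                      alt = character(), first_round = integer(),
                      last_round = integer(), stringsAsFactors = FALSE))
  ret <- retained_sites(refs, parasite_class)
  host_rows <- table[table$class_label == host_class, , drop = FALSE]
  labs <- unique(para_w$label)
  out <- list()
  for (lab in labs) {
    site <- para_w$site[para_w$label == lab][1]
    if (!(site %in% ret)) next
    h <- host_rows[host_rows$label == lab, , drop = FALSE]
    unique_in_parasite <- if (mode == "threshold")
      !any(h$frequency > threshold) else !any(h$count > 0)
    if (!unique_in_parasite) next
    rounds <- sort(para_w$round[para_w$label == lab])
    out[[length(out) + 1L]] <- data.frame(
      label = lab, site = site,
      kind = para_w$kind[para_w$label == lab][1],
      ref = para_w$ref[para_w$label == lab][1],
      alt = para_w$alt[para_w$label == lab][1],
      first_round = rounds[1], last_round = rounds[length(rounds)],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(label = character(), site = integer(), kind = character(),
               ref = character(), alt = character(), first_round = integer(),
               last_round = integer(), stringsAsFactors = FALSE)
  res <- res[order(res$site, res$label), ]
  rownames(res) <- NULL
  res
}

#' Track the persistence of one mutation across rounds
#'
#' Lists the sequenced rounds in which the mutation's frequency exceeds the
#' threshold in the given class, with first/last round and the gaps
#' (sequenced rounds between first and last where it dropped back below).
#' Mutations routinely appear, persist and disappear again in both host and
#' parasite populations.
#'
#' @param table A [build_frequency_table()] result.
#' @param label Mutation label (e.g. `"C1986U"`); must occur in the table.
#' @param class_label Class to track the mutation in.
#' @param threshold Frequency threshold (default 0.10).
#' @return A list of class `persistence_track`: `label`, `class_label`,
#'   `rounds_above` (sorted), `first_round`, `last_round`, `gaps`
#'   (sequenced rounds inside the span where the mutation was below
#'   threshold).
#' @export
track_persistence <- function(table, label, class_label, threshold = 0.10) {
  stopifnot(is.data.frame(table))
  if (!label %in% table$label)
    stop("mutation '", label, "' does not occur in the frequency table")
  sequenced <- sort(unique(table$round[table$class_label == class_label]))
  rows <- table[table$label == label & table$class_label == class_label, ,
                drop = FALSE]
  above <- sort(rows$round[rows$frequency > threshold])
  gaps <- integer()
  if (length(above) >= 1L) {
    span <- sequenced[sequenced >= above[1] & sequenced <= above[length(above)]]
    gaps <- setdiff(span, above)
  }
  structure(list(
    label = label, class_label = class_label, threshold = threshold,
    rounds_above = above,
    first_round = if (length(above)) above[1] else NA_integer_,
    last_round = if (length(above)) above[length(above)] else NA_integer_,
    gaps = gaps
  ), class = "persistence_track")
}

#' @export
print.persistence_track <- function(x, ...) {
  if (length(x$rounds_above) == 0L) {
    cat("<persistence_track>", x$label, "in", x$class_label,
        ": never above", x$threshold, "\n")
  } else {
    cat("<persistence_track>", x$label, "in", x$class_label, ": rounds",
        paste(x$rounds_above, collapse = ", "),
        sprintf("(first %d, last %d%s)\n", x$first_round, x$last_round,
                if (length(x$gaps)) paste0("; gaps at ",
                                           paste(x$gaps, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Match parasite genotypes to candidate host progenitors
#'
#' A parasite genotype whose deletion-masked distance to a host genotype is
#' zero ("perfect match except for the large internal deletion") is a
#' candidate product of a deletion event in that host lineage. For each
#' parasite genotype, host genotypes from the same or any earlier sequenced
#' round at masked distance zero are reported, ordered by round proximity
#' (same round first).
#'
#' @param genotypes A [project_genotypes()] table containing both host and
#'   parasite genotypes.
#' @param parasite_class Parasite class label to scan (default: all
#'   non-host classes present).
#' @param host_class Host class label.
#' @return A `data.frame` of candidate origin events: `parasite_id`,
#'   `parasite_round`, `parasite_class`, `host_id`, `host_round`,
#'   `round_lag` (parasite round minus host round).
#' @export
match_parasite_origin <- function(genotypes, parasite_class = NULL,
                                  host_class = "host") {
  stopifnot(is.data.frame(genotypes))
  paras <- genotypes[genotypes$class_label != host_class, , drop = FALSE]
  if (!is.null(parasite_class))
    paras <- paras[paras$class_label %in% parasite_class, , drop = FALSE]
  hosts <- genotypes[genotypes$class_label == host_class, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(paras))) {
    cand <- hosts[hosts$round <= paras$round[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- vapply(cand$vector, genotype_distance, 0L, g2 = paras$vector[i])
    hit <- which(d == 0L)
    if (!length(hit)) next
    cand <- cand[hit, , drop = FALSE]
    lag <- paras$round[i] - cand$round
    o <- order(lag, cand$genotype_id)
    out[[length(out) + 1L]] <- data.frame(
      parasite_id = paras$genotype_id[i],
      parasite_round = paras$round[i],
      parasite_class = paras$class_label[i],
      host_id = cand$genotype_id[o],
      host_round = cand$round[o],
      round_lag = lag[o],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(parasite_id = character(), parasite_round = integer(),
               parasite_class = character(), host_id = character(),
               host_round = integer(), round_lag = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Summarize lineage-level findings as text
#'
#' A headline summary: unique-mutation counts per parasite class,
#' persistence spans of selected mutations, and origin-event counts.
#'
#' @param unique_reports Named list (by parasite class) of
#'   [find_unique_mutations()] results.
#' @param origins A [match_parasite_origin()] result.
#' @return Character vector of report lines.
#' @export
lineage_summary <- function(unique_reports = list(), origins = NULL) {
  lines <- character()
  for (cls in names(unique_reports)) {
    r <- unique_reports[[cls]]
    lines <- c(lines, sprintf("%s: %d unique mutation(s)%s", cls, nrow(r),
                              if (nrow(r)) paste0(" [",
                                paste(r$label, collapse = ", "), "]") else ""))
  }
  if (!is.null(origins)) {
    n_para <- length(unique(origins$parasite_id))
    lines <- c(lines, sprintf(
      "origin candidates: %d parasite genotype(s) match a host genotype at masked distance 0 (%d candidate pair(s))",
      n_para, nrow(origins)))
  }
  lines
}
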