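#' Call mutation events from a pairwise alignment
#'
#' Walks the alignment columns and emits one event per mismatch column
#' (substitution), one event per deleted reference base (a multi-base
#' deletion is decomposed into per-base events), and one event per
#' reference-gap run (an insertion, anchored after the preceding reference
#' position; an insertion before the first reference base is anchored at
#' position 0). Coordinates are 1-based positions on the alignment's
#' reference. A read `N` against a reference base is recorded as a
#' substitution with `alt = "N"`; downstream counting ignores such events
#' but genotype projection uses them to drop ambiguous reads.
#'
#' @param alignment A `pairwise_alignment` (from [align_to_reference()] or
#'   [pairwise_from_gapped()]).
#' @return A `data.frame` of events with columns `site`, `kind`, `ref`,
#'   `alt`, `label`.
#' @export
call_mutations <- function(alignment) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  rc <- strsplit(alignment$ref, "", fixed = TRUE)[[1]]
  qc <- strsplit(alignment$read, "", fixed = TRUE)[[1]]
  stopifnot(length(rc) == length(qc))
  ev <- empty_events()
  pos <- 0L
  ins_anchor <- -1L
  ins_buf <- ""
  flush_ins <- function(ev) {
    if (nzchar(ins_buf))
      ev <- rbind(ev, data.frame(
        site = ins_anchor, kind = "insertion", ref = "", alt = ins_buf,
        label = mutation_label(ins_anchor, "insertion", "", ins_buf),
        stringsAsFactors = FALSE))
    ev
  }
  for (i in seq_along(rc)) {
    r <- rc[i]; q <- qc[i]
    if (r == "-" && q == "-") next  # all-gap column (multiple alignment input)
    if (r != "-") {
      ev <- flush_ins(ev); ins_buf <- ""
      pos <- pos + 1L
      if (q == "-") {
        ev <- rbind(ev, data.frame(
          site = pos, kind = "deletion", ref = r, alt = "",
          label = mutation_label(pos, "deletion", r, ""),
          stringsAsFactors = FALSE))
      } else if (q != r) {
        ev <- rbind(ev, data.frame(
          site = pos, kind = "substitution", ref = r, alt = q,
          label = mutation_label(pos, "substitution", r, q),
          stringsAsFactors = FALSE))
      }
    } else {
      if (!nzchar(ins_buf)) ins_anchor <- pos
      ins_buf <- paste0(ins_buf, q)
    }
  }
  ev <- flush_ins(ev)
  ev[order(ev$site, ev$kind), , drop = FALSE]
}

#' Build a pairwise alignment object from pre-aligned (gapped) sequences
#'
#' For aligned-FASTA input that was produced by an external multiple
#' aligner: both strings must have equal padded length.
#'
#' @param ref Gapped reference string.
#' @param read Gapped read string.
#' @return A `pairwise_alignment` (score `NA`).
#' @export
pairwise_from_gapped <- function(ref, read) {
  ref <- normalize_alphabet(ref); read <- normalize_alphabet(read)
  if (nchar(ref) != nchar(read))
    stop("pre-aligned sequences must have equal padded length (got ",
         nchar(ref), " and ", nchar(read), ")")
  structure(list(ref = ref, read = read, score = NA_integer_),
            class = "pairwise_alignment")
}

#' Lift events from a parasite-class reference to host coordinates
#'
#' Parasite reads are aligned to their (deletion-bearing) class reference;
#' this maps event coordinates back onto the original host reference through
#' the class's retained sites. Sites inside the class deletion window can
#' never appear because they do not exist on the class reference.
#'
#' @param events Event `data.frame` in class-reference coordinates.
#' @param refs A [reference_set()].
#' @param class_label The class the events were called against; `"host"` is
#'   the identity lift.
#' @return The events with `site` and `label` rewritten in host coordinates.
#' @export
lift_events_to_host <- function(events, refs, class_label) {
  if (identical(class_label, "host") || is.null(events) || nrow(events) == 0L)
    return(events)
  ret <- retained_sites(refs, class_label)
  site <- events$site
  lifted <- ifelse(site == 0L, 0L, ret[site])
  if (anyNA(lifted))
    stop("event site beyond the ", class_label, " reference length")
  events$site <- as.integer(lifted)
  events$label <- mutation_label(events$site, events$kind, events$ref, events$alt)
  events
}

# Align every read to its class reference and return per-read event sets in
# host coordinates. Alignments are cached per distinct (class, sequence).
# Pre-aligned (gapped) reads are consumed as-is against the gapped host
# reference `aligned_ref` when provided.
call_read_events <- function(reads, refs, scoring = alignment_scoring(),
                             aligned_ref = NULL) {
  stopifnot(is.data.frame(reads), inherits(refs, "reference_set"))
  n <- nrow(reads)
  out <- vector("list", n)
  if (n == 0L) return(out)
  gapped <- grepl("-", reads$sequence, fixed = TRUE)
  key <- paste(reads$class_label, reads$sequence, sep = "\r")
  first <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (i in which(first)) {
    cls <- reads$class_label[i]
    if (gapped[i]) {
      if (is.null(aligned_ref))
        stop("gapped read '", reads$id[i],
             "' requires an aligned (gapped) host reference")
      aln <- pairwise_from_gapped(aligned_ref, reads$sequence[i])
      ev <- call_mutations(aln)
    } else {
      ref_seq <- refs$sequences[[cls]]
      if (is.null(ref_seq) || is.na(ref_seq))
        stop("no reference for class '", cls, "'")
      aln <- align_to_reference(reads$sequence[i], ref_seq, scoring)
      ev <- lift_events_to_host(call_mutations(aln), refs, cls)
    }
    assign(key[i], ev, envir = cache)
  }
  for (i in seq_len(n)) out[[i]] <- get(key[i], envir = cache)
  out
}

#' Build the per-round, per-class mutation frequency table
#'
#' Aligns every read to its class reference, lifts events to host
#' coordinates, and tabulates, for each (round, class), the frequency of
#' every observed mutation event: `frequency = read_count / depth`, where
#' depth is the number of retained reads of that class in that round (reads
#' cover the full reference). Ambiguous-base events (`alt = "N"`) are not
#' tabulated. A (round, class) group with zero reads contributes no rows.
#'
#' @param reads Read table with `sequence`, `round` and `class_label`
#'   columns (reads labelled `"unclassified"` are ignored).
#' @param refs A [reference_set()].
#' @param scoring Aligner scoring ([alignment_scoring()]).
#' @param aligned_ref Optional gapped host reference for pre-aligned reads.
#' @return A `data.frame` of class `mutation_frequency_table` with columns
#'   `round`, `class_label`, `site`, `kind`, `ref`, `alt`, `label`, `count`,
#'   `depth`, `frequency`.
#' @export
build_frequency_table <- function(reads, refs, scoring = alignment_scoring(),
                                  aligned_ref = NULL) {
  stopifnot(is.data.frame(reads))
  reads <- reads[reads$class_label != "unclassified", , drop = FALSE]
  events <- call_read_events(reads, refs, scoring, aligned_ref)
  rows <- list()
  if (nrow(reads) > 0L) {
    grp <- interaction(reads$round, reads$class_label, drop = TRUE)
    for (g in levels(grp)) {
      idx <- which(grp == g)
      depth <- length(idx)
      evs <- do.call(rbind, events[idx])
      round <- reads$round[idx[1]]
      cls <- reads$class_label[idx[1]]
      if (is.null(evs) || nrow(evs) == 0L) next
      evs <- evs[!(evs$kind == "substitution" & evs$alt == "N"), , drop = FALSE]
      if (nrow(evs) == 0L) next
      agg <- stats::aggregate(list(count = rep(1L, nrow(evs))),
                              by = evs[c("site", "kind", "ref", "alt", "label")],
                              FUN = sum)
      agg$round <- round
      agg$class_label <- cls
      agg$depth <- depth
      agg$frequency <- agg$count / depth
      rows[[length(rows) + 1L]] <- agg
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(), kind = character(), ref = character(),
               alt = character(), label = character(), count = integer(),
               round = integer(), class_label = character(),
               depth = integer(), frequency = numeric(),
               stringsAsFactors = FALSE)
  out <- out[c("round", "class_label", "site", "kind", "ref", "alt",
               "label", "count", "depth", "frequency")]
  out <- out[order(out$round, out$class_label, out$site, out$kind, out$alt), ]
  rownames(out) <- NULL
  class(out) <- c("mutation_frequency_table", "data.frame")
  out
}

#' Identify dominant mutations
#'
#' A mutation is dominant when its population frequency strictly exceeds
#' `threshold` in at least one (round, class) sample — "more than 10%" with
#' the default. Because distinct mutations can hit the same reference site,
#' the set also reports the number of distinct sites.
#'
#' @param table A [build_frequency_table()] result.
#' @param threshold Dominance threshold, strictly between 0 and 1.
#' @return An object of class `dominant_set`: list with `mutations` (unique
#'   event rows ordered by site), `witnesses` (the (round, class) rows that
#'   exceeded the threshold), `sites` (distinct sites), `threshold`.
#' @export
identify_dominant <- function(table, threshold = 0.10) {
  stopifnot(is.data.frame(table))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  hit <- table[table$frequency > threshold, , drop = FALSE]
  muts <- unique(hit[c("site", "kind", "ref", "alt", "label")])
  muts <- muts[order(muts$site, muts$kind, muts$alt), , drop = FALSE]
  rownames(muts) <- NULL
  structure(list(mutations = muts, witnesses = hit,
                 sites = sort(unique(muts$site)), threshold = threshold),
            class = "dominant_set")
}

#' @export
print.dominant_set <- function(x, ...) {
  k <- table(x$mutations$kind)
  cat("<dominant_set>", nrow(x$mutations), "dominant mutations in",
      length(x$sites), "sites (threshold >", x$threshold, ")\n")
  if (nrow(x$mutations))
    cat(" ", paste(names(k), as.integer(k), collapse = ", "), "\n")
  invisible(x)
}

#' Project reads onto genotypes over the dominant mutations
#'
#' Each read is reduced to a presence vector over the dominant mutations:
#' `1` if the read carries the mutation, `0` if not, `-` (masked) when the
#' mutation's site lies inside the read's class deletion window. Reads with
#' an ambiguous base (`N`) at an unmasked dominant site are dropped.
#' Identical vectors are pooled within each (round, class); frequencies are
#' normalized over the group's projected reads before truncation to the
#' `top_n` most frequent genotypes. Ranks break frequency ties by
#' lexicographic vector order.
#'
#' @param reads Read table (`sequence`, `round`, `class_label`).
#' @param refs A [reference_set()].
#' @param dominant A [identify_dominant()] result (or its `mutations` data
#'   frame).
#' @param top_n Genotypes kept per (round, class) after normalization.
#' @param scoring Aligner scoring.
#' @param aligned_ref Optional gapped host reference for pre-aligned reads.
#' @return A `data.frame` of class `genotype_table`: `round`, `class_label`,
#'   `rank`, `vector` (string over `{0,1,-}` in dominant-mutation order),
#'   `frequency`, `n_reads`, `genotype_id`. The dominant mutation labels are
#'   attached as attribute `"mutations"`.
#' @export
project_genotypes <- function(reads, refs, dominant, top_n = 90L,
                              scoring = alignment_scoring(),
                              aligned_ref = NULL) {
  muts <- if (inherits(dominant, "dominant_set")) dominant$mutations else dominant
  stopifnot(is.data.frame(reads))
  reads <- reads[reads$class_label != "unclassified", , drop = FALSE]
  events <- call_read_events(reads, refs, scoring, aligned_ref)
  n_mut <- nrow(muts)
  rows <- list()
  if (nrow(reads) > 0L) {
    # per-class masks over the dominant mutations
    classes <- unique(reads$class_label)
    masks <- lapply(stats::setNames(classes, classes), function(cls) {
      if (cls == "host" || n_mut == 0L) return(rep(FALSE, n_mut))
      w <- refs$windows[[cls]]
      if (is.null(w)) stop("unknown class label: ", cls)
      muts$site >= w[1] & muts$site <= w[2]
    })
    vecs <- character(nrow(reads))
    drop <- logical(nrow(reads))
    for (i in seq_len(nrow(reads))) {
      mask <- masks[[reads$class_label[i]]]
      ev <- events[[i]]
      v <- rep("0", n_mut)
      if (!is.null(ev) && nrow(ev) > 0L) {
        v[muts$label %in% ev$label] <- "1"
        amb <- ev$site[ev$kind == "substitution" & ev$alt == "N"]
        if (length(amb) && any(muts$site %in% amb & !mask)) drop[i] <- TRUE
      }
      v[mask] <- "-"
      vecs[i] <- paste(v, collapse = "")
    }
    reads2 <- reads[!drop, , drop = FALSE]
    vecs <- vecs[!drop]
    if (nrow(reads2) > 0L) {
      grp <- interaction(reads2$round, reads2$class_label, drop = TRUE)
      for (g in levels(grp)) {
        idx <- which(grp == g)
        tab <- table(vecs[idx])
        df <- data.frame(vector = names(tab),
                         n_reads = as.integer(tab),
                         stringsAsFactors = FALSE)
        df$frequency <- df$n_reads / length(idx)
        df <- df[order(-df$frequency, df$vector), , drop = FALSE]
        df$rank <- seq_len(nrow(df))
        df <- df[df$rank <= top_n, , drop = FALSE]
        df$round <- reads2$round[idx[1]]
        df$class_label <- reads2$class_label[idx[1]]
        rows[[length(rows) + 1L]] <- df
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vector = character(), n_reads = integer(),
               frequency = numeric(), rank = integer(), round = integer(),
               class_label = character(), stringsAsFactors = FALSE)
  out$genotype_id <- sprintf("%s_r%03d_rank%d", out$class_label, out$round, out$rank)
  out <- out[c("round", "class_label", "rank", "vector", "frequency",
               "n_reads", "genotype_id")]
  out <- out[order(out$round, out$class_label, out$rank), ]
  rownames(out) <- NULL
  attr(out, "mutations") <- muts$label
  class(out) <- c("genotype_table", "data.frame")
  out
}
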