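#' Default large-deletion windows for the parasite classes
#'
#' The parasite classes are deletion mutants of the host RNA: parasite-alpha
#' lacks the entire replicase gene, parasite-beta lacks roughly its 3' half,
#' and parasite-gamma additionally lacks part of the remaining 5' region.
#' The default windows reproduce the approximate class lengths (~220, ~1070
#' and ~510 nt on a ~2040 nt host) and are scaled proportionally for other
#' host lengths. Windows of different classes may be nested or overlapping,
#' as the real deletions are; every window leaves both termini intact because
#' all species retain the terminal replicase-recognition regions.
#'
#' @param host_length Length of the host reference in nt.
#' @return Named list of `c(start, end)` 1-based inclusive intervals on the
#'   host reference, one per parasite class.
#' @export
default_deletion_windows <- function(host_length = 2040L) {
  stopifnot(is_count(host_length, min = 20L))
  sc <- function(x) max(2L, min(host_length - 1L, as.integer(round(x / 2040 * host_length))))
  list(
    "parasite-alpha" = c(sc(100), sc(1920)),
    "parasite-beta"  = c(sc(1000), sc(1969)),
    "parasite-gamma" = c(sc(440), sc(1969))
  )
}

validate_windows <- function(deletion_windows, host_length) {
  if (length(deletion_windows) == 0L) return(invisible(deletion_windows))
  if (is.null(names(deletion_windows)) || anyDuplicated(names(deletion_windows)))
    stop("deletion windows must be a uniquely named list (one window per parasite class)")
  for (cls in names(deletion_windows)) {
    w <- deletion_windows[[cls]]
    if (length(w) != 2L || any(w != floor(w)))
      stop("window for ", cls, " must be c(start, end) integers")
    if (w[1] > w[2]) stop("window for ", cls, " has start > end")
    if (w[1] < 2L || w[2] > host_length - 1L)
      stop("window for ", cls, " must lie strictly inside the reference, ",
           "leaving both termini intact")
  }
  keys <- vapply(deletion_windows, paste, "", collapse = "-")
  if (anyDuplicated(keys))
    stop("two parasite classes share an identical deletion window; class identity would be ambiguous")
  invisible(deletion_windows)
}

#' Construct a reference set from a host sequence
#'
#' Derives one reference per parasite class by excising that class's deletion
#' window from the host sequence.
#'
#' @param host Host reference sequence (character scalar over A/C/G/T or U).
#' @param deletion_windows Named list of `c(start, end)` windows, as from
#'   [default_deletion_windows()]; may be empty, in which case the set holds
#'   only the host.
#' @return An object of class `reference_set`: list with `host` (character
#'   scalar), `windows`, `sequences` (named character vector, host plus one
#'   entry per parasite class) and `host_length`.
#' @export
reference_set <- function(host, deletion_windows = list()) {
  stopifnot(is.character(host), length(host) == 1L, nzchar(host))
  host <- normalize_alphabet(host)
  L <- nchar(host)
  validate_windows(deletion_windows, L)
  chars <- strsplit(host, "", fixed = TRUE)[[1]]
  seqs <- c(host = host)
  for (cls in names(deletion_windows)) {
    w <- deletion_windows[[cls]]
    seqs[[cls]] <- paste(chars[-(w[1]:w[2])], collapse = "")
  }
  structure(
    list(host = host, windows = deletion_windows, sequences = seqs,
         host_length = L),
    class = "reference_set"
  )
}

#' Generate a random host reference and its parasite-class references
#'
#' Draws a uniform random nucleotide sequence as the host reference and
#' derives the parasite references by excising the class deletion windows.
#' Uses the current RNG state (call `set.seed()` beforehand for
#' reproducibility).
#'
#' @param host_length Host reference length in nt (default 2040, the host
#'   RNA's approximate size).
#' @param deletion_windows Named list of `c(start, end)` windows.
#' @return A [reference_set()] object.
#' @export
generate_reference_set <- function(host_length = 2040L,
                                   deletion_windows = default_deletion_windows(host_length)) {
  stopifnot(is_count(host_length, min = 10L))
  host <- paste(sample(c("A", "C", "G", "T"), host_length, replace = TRUE),
                collapse = "")
  reference_set(host, deletion_windows)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> host:", x$host_length, "nt\n")
  for (cls in names(x$windows)) {
    w <- x$windows[[cls]]
    cat(sprintf("  %-16s window %d-%d  (%d nt reference)\n",
                cls, w[1], w[2], nchar(x$sequences[[cls]])))
  }
  invisible(x)
}

#' Host positions retained by a class
#'
#' @param refs A `reference_set`.
#' @param class_label Class name; `"host"` retains every position.
#' @return Integer vector of 1-based host coordinates present in that class's
#'   reference, in order.
#' @export
retained_sites <- function(refs, class_label) {
  stopifnot(inherits(refs, "reference_set"))
  all_sites <- seq_len(refs$host_length)
  if (identical(class_label, "host")) return(all_sites)
  w <- refs$windows[[class_label]]
  if (is.null(w)) stop("unknown class label: ", class_label)
  all_sites[-(w[1]:w[2])]
}

# Materialize the sequence of a molecule: host reference with the class
# deletion window excised and the molecule's mutation events applied.
# `events` is NULL or a data.frame with columns site, kind, alt
# (host 1-based coordinates; insertions are anchored after `site`).
materialize_sequence <- function(refs, class_label, events = NULL) {
  pos <- retained_sites(refs, class_label)
  chars <- strsplit(refs$host, "", fixed = TRUE)[[1]][pos]
  if (is.null(events) || nrow(events) == 0L)
    return(paste(chars, collapse = ""))
  keep <- rep(TRUE, length(pos))
  ins <- rep("", length(pos))
  idx <- match(events$site, pos)
  if (anyNA(idx))
    stop("event site outside the retained region of class ", class_label)
  for (k in seq_len(nrow(events))) {
    i <- idx[k]
    switch(events$kind[k],
      substitution = { chars[i] <- events$alt[k] },
      deletion = { keep[i] <- FALSE },
      insertion = { ins[i] <- paste0(ins[i], events$alt[k]) },
      stop("unknown event kind: ", events$kind[k])
    )
  }
  paste(paste0(ifelse(keep, chars, ""), ins), collapse = "")
}

#' Canonical mutation label
#'
#' Substitutions are written `C1986U`, deletions `G100del`, insertions
#' `1986insA` (anchored after the named host position). Labels use the RNA
#' alphabet.
#'
#' @param site 1-based host reference position.
#' @param kind One of `"substitution"`, `"insertion"`, `"deletion"`.
#' @param ref Reference base at `site` (ignored for insertions).
#' @param alt Alternate base (substitution) or inserted string (insertion).
#' @return Character vector of labels.
#' @export
mutation_label <- function(site, kind, ref, alt) {
  to_rna <- function(x) chartr("Tt", "Uu", x)
  out <- character(length(site))
  sub <- kind == "substitution"
  del <- kind == "deletion"
  ins <- kind == "insertion"
  out[sub] <- paste0(to_rna(ref[sub]), site[sub], to_rna(alt[sub]))
  out[del] <- paste0(to_rna(ref[del]), site[del], "del")
  out[ins] <- paste0(site[ins], "ins", to_rna(alt[ins]))
  out
}
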