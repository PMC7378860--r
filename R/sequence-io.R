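#' @importFrom Biostrings readDNAStringSet readBStringSet writeXStringSet
#'   BStringSet
NULL

# Internal alphabet is DNA (T); RNA 'U' from the literature or from RNA
# sequence files is normalized to 'T' at parse time, and rendered back as 'U'
# only in mutation labels.
normalize_alphabet <- function(x) toupper(chartr("Uu", "Tt", x))

VALID_CHARS <- c("A", "C", "G", "T", "N", "-")

#' Read sequence records from FASTA/FASTQ/aligned-FASTA
#'
#' Parses a sequence file into a read-record table. Header metadata of the
#' form `key=value` (e.g. `round=13 class=host mol=42 passes=12`) is
#' recovered into columns. RNA `U` is normalized to `T`. For
#' `format = "aligned-fasta"` gap characters (`-`) are retained so that
#' column indices are preserved for downstream mutation calling; plain FASTA
#' and FASTQ records must be gap-free.
#'
#' @param path Path to the sequence file.
#' @param format One of `"fasta"`, `"fastq"`, `"aligned-fasta"`.
#' @return A `data.frame` with columns `id`, `sequence`, `round`,
#'   `class_label`, `mol`, `passes` (missing metadata is `NA`).
#' @export
read_sequences <- function(path, format = c("fasta", "fastq", "aligned-fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path,
                               format = if (format == "fastq") "fastq" else "fasta"),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  headers <- names(set)
  seqs <- normalize_alphabet(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  # validate alphabet record by record so errors name the offender
  allowed <- if (format == "aligned-fasta") VALID_CHARS else setdiff(VALID_CHARS, "-")
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i]))
      stop("empty sequence in record '", ids[i], "'")
    chars <- unique(strsplit(seqs[i], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop("record '", ids[i], "' contains invalid symbol(s): ",
           paste(bad, collapse = ", "))
  }
  meta_field <- function(key) {
    rx <- regexpr(paste0("\\b", key, "=[^[:space:]]+"), headers)
    out <- rep(NA_character_, length(headers))
    hit <- rx != -1L
    out[hit] <- sub(paste0("^.*?", key, "="), "", regmatches(headers, rx))
    out
  }
  to_int <- function(x) suppressWarnings(as.integer(x))
  data.frame(
    id = ids,
    sequence = unname(seqs),
    round = to_int(meta_field("round")),
    class_label = meta_field("class"),
    mol = to_int(meta_field("mol")),
    passes = to_int(meta_field("passes")),
    stringsAsFactors = FALSE)
}

#' Write read records as FASTA
#'
#' Headers carry the metadata fields `round=`, `class=`, `mol=` and
#' `passes=` when present, so that [read_sequences()] round-trips them.
#'
#' @param reads Read-record `data.frame` (as from [read_sequences()] or
#'   [sample_reads()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_read_fasta <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  hdr <- reads$id
  add <- function(hdr, key, val) {
    has <- !is.na(val)
    hdr[has] <- paste0(hdr[has], " ", key, "=", val[has])
    hdr
  }
  if ("round" %in% names(reads)) hdr <- add(hdr, "round", reads$round)
  if ("class_label" %in% names(reads)) hdr <- add(hdr, "class", reads$class_label)
  if ("mol" %in% names(reads)) hdr <- add(hdr, "mol", reads$mol)
  if ("passes" %in% names(reads)) hdr <- add(hdr, "passes", reads$passes)
  set <- Biostrings::BStringSet(reads$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Default length bins for the four RNA species classes
#'
#' Wide brackets around the approximate species sizes: host ~2040 nt,
#' parasite-alpha ~220 nt, parasite-beta ~1070 nt, parasite-gamma ~510 nt.
#'
#' @return A `data.frame` with columns `class_label`, `min_length`,
#'   `max_length` (nt, inclusive).
#' @export
default_length_bins <- function() {
  data.frame(
    class_label = c("host", "parasite-beta", "parasite-gamma", "parasite-alpha"),
    min_length = c(1800L, 900L, 400L, 150L),
    max_length = c(2300L, 1300L, 700L, 350L),
    stringsAsFactors = FALSE)
}

validate_length_bins <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("class_label", "min_length", "max_length") %in% names(bins)))
  if (any(bins$min_length > bins$max_length)) stop("length bin with min > max")
  o <- order(bins$min_length)
  b <- bins[o, ]
  if (nrow(b) > 1L && any(b$min_length[-1] <= b$max_length[-nrow(b)]))
    stop("length bins overlap")
  invisible(bins)
}

#' Classify reads into species classes by length
#'
#' Each read maps to the unique bin containing its (gap-free) length, or to
#' `"unclassified"` when no bin contains it. Classification is total: every
#' read receives exactly one label.
#'
#' @param x A read-record `data.frame` (column `sequence`), a character
#'   vector of sequences, or a numeric vector of lengths.
#' @param bins Length bins as from [default_length_bins()].
#' @return Character vector of class labels. For a `data.frame` input, the
#'   data frame with its `class_label` column filled in.
#' @export
classify_by_length <- function(x, bins = default_length_bins()) {
  validate_length_bins(bins)
  if (is.data.frame(x)) {
    x$class_label <- classify_by_length(x$sequence, bins)
    return(x)
  }
  len <- if (is.numeric(x)) x else nchar(gsub("-", "", x, fixed = TRUE))
  out <- rep("unclassified", length(len))
  for (i in seq_len(nrow(bins))) {
    hit <- len >= bins$min_length[i] & len <= bins$max_length[i]
    out[hit] <- bins$class_label[i]
  }
  out
}

#' Filter reads by consensus pass count
#'
#' Circular-consensus (CCS) pass-count filtering: host reads require at
#' least 5 passes and parasite reads at least 10 by default. Reads without a
#' pass count are retained with a warning, and reads of classes not named in
#' `min_passes_by_class` are retained unfiltered.
#'
#' @param reads Read-record `data.frame` with `passes` and `class_label`
#'   columns.
#' @param min_passes_by_class Named integer vector of per-class thresholds.
#' @return The filtered read table.
#' @export
filter_by_passes <- function(reads,
                             min_passes_by_class = c(
                               "host" = 5L,
                               "parasite-alpha" = 10L,
                               "parasite-beta" = 10L,
                               "parasite-gamma" = 10L)) {
  stopifnot(is.data.frame(reads))
  if (any(min_passes_by_class < 0)) stop("pass-count thresholds must be >= 0")
  if (nrow(reads) == 0L) return(reads)
  no_pass <- is.na(reads$passes)
  if (any(no_pass))
    warning(sum(no_pass), " read(s) lack a pass count and are retained unfiltered")
  thr <- min_passes_by_class[reads$class_label]
  thr[is.na(thr)] <- 0L
  keep <- no_pass | reads$passes >= thr
  reads[keep, , drop = FALSE]
}
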