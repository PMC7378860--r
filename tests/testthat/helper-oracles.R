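# Independent oracles used to cross-check the package's implementations.
# These are written from first principles and never call the code they check.

# Affine-gap global alignment score by top-down recursion over
# (ref consumed, read consumed, previous operation). A gap of length k
# costs gap_open + k * gap_extend.
oracle_align_score <- function(ref, read, match = 1, mismatch = -2,
                               gap_open = -4, gap_extend = -1) {
  a <- strsplit(ref, "", fixed = TRUE)[[1]]
  b <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    key <- paste(i, j, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      s <- if (a[i + 1] == b[j + 1]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < n) {
      cost <- gap_extend + if (last == "X") 0 else gap_open
      best <- max(best, cost + rec(i + 1, j, "X"))
    }
    if (j < m) {
      cost <- gap_extend + if (last == "Y") 0 else gap_open
      best <- max(best, cost + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(0, 0, "S")
}

# Exhaustive enumeration of every global alignment (op strings over M/X/Y),
# scoring gap runs from scratch. Only feasible for very short sequences;
# used to validate oracle_align_score itself.
enumerate_align_score <- function(ref, read, match = 1, mismatch = -2,
                                  gap_open = -4, gap_extend = -1) {
  a <- strsplit(ref, "", fixed = TRUE)[[1]]
  b <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  best <- -Inf
  score_ops <- function(ops) {
    s <- 0; i <- 0; j <- 0; prev <- ""
    for (op in ops) {
      if (op == "M") {
        i <- i + 1; j <- j + 1
        s <- s + if (a[i] == b[j]) match else mismatch
      } else if (op == "X") {
        i <- i + 1
        s <- s + gap_extend + if (prev == "X") 0 else gap_open
      } else {
        j <- j + 1
        s <- s + gap_extend + if (prev == "Y") 0 else gap_open
      }
      prev <- op
    }
    s
  }
  rec <- function(i, j, ops) {
    if (i == n && j == m) {
      best <<- max(best, score_ops(ops))
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(ops, "M"))
    if (i < n) rec(i + 1, j, c(ops, "X"))
    if (j < m) rec(i, j + 1, c(ops, "Y"))
  }
  rec(0, 0, character())
  best
}

# Brute-force dominant-mutation scan: direct counting over reads' known
# event labels, independent of the package's table machinery.
brute_force_dominant <- function(read_labels, groups, threshold) {
  # read_labels: list of character vectors of event labels per read
  # groups: character vector (round:class) per read
  hits <- character()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    depth <- length(idx)
    tab <- table(unlist(read_labels[idx]))
    hits <- union(hits, names(tab)[as.integer(tab) / depth > threshold])
  }
  sort(hits)
}

# Positionwise masked Hamming distance, written independently.
oracle_masked_hamming <- function(v1, v2) {
  a <- strsplit(v1, "", fixed = TRUE)[[1]]
  b <- strsplit(v2, "", fixed = TRUE)[[1]]
  d <- 0L
  for (k in seq_along(a))
    if (a[k] != "-" && b[k] != "-" && a[k] != b[k]) d <- d + 1L
  d
}
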