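#' Sample sequencing reads from a replicator population
#'
#' Draws `n` reads multinomially with probabilities proportional to molecule
#' copy counts, materializes each source molecule's sequence, and flips each
#' base to a uniformly chosen different base with probability
#' `seq_error_rate`. A pass count (mimicking circular-consensus passes) is
#' attached to each read.
#'
#' @param population A [replicator_population()].
#' @param n Number of reads to draw (>= 1).
#' @param seq_error_rate Per-base sequencing error probability.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is restored afterwards.
#' @param mean_passes Mean of the (shifted Poisson) pass-count distribution.
#' @return A `data.frame` read set with columns `id`, `sequence`, `round`,
#'   `class_label`, `mol`, `passes`.
#' @export
sample_reads <- function(population, n, seq_error_rate = 0, seed = NULL,
                         mean_passes = 15) {
  stopifnot(inherits(population, "replicator_population"))
  if (nrow(population$members) == 0L)
    stop("cannot sample reads from an empty population")
  if (!is_count(n)) stop("n must be a positive integer")
  if (!is_prob(seq_error_rate)) stop("seq_error_rate must be in [0, 1]")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  m <- population$members
  idx <- sample.int(nrow(m), n, replace = TRUE, prob = m$copy_count)
  # materialize each distinct source molecule once
  uidx <- unique(idx)
  seqs <- vapply(uidx, function(i)
    materialize_sequence(population$refs, m$class_label[i],
                         population$events[[i]]), "")
  sequence <- seqs[match(idx, uidx)]
  if (seq_error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    for (k in seq_len(n)) {
      L <- nchar(sequence[k])
      n_err <- rbinom(1L, L, seq_error_rate)
      if (n_err > 0L) {
        chars <- strsplit(sequence[k], "", fixed = TRUE)[[1]]
        at <- sample.int(L, n_err)
        for (p in at) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
        sequence[k] <- paste(chars, collapse = "")
      }
    }
  }
  passes <- 1L + rpois(n, max(0, mean_passes - 1))
  data.frame(
    id = sprintf("r%03d_read%06d", population$round, seq_len(n)),
    sequence = sequence,
    round = population$round,
    class_label = m$class_label[idx],
    mol = m$molecule_id[idx],
    passes = passes,
    stringsAsFactors = FALSE)
}
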