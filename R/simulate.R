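#' Serial-transfer simulation configuration
#'
#' Parameters of the droplet replication-dilution cycle the simulator
#' emulates: molecules are partitioned into water-in-oil droplets (Poisson
#' occupancy), replicate within droplets during incubation (hosts
#' autonomously, parasites only alongside at least one host, with a
#' length-dependent replication advantage), acquire point mutations and rare
#' large deletions during replication, and are then carried into the next
#' round by a binomial dilution step. Defaults follow the experimental
#' protocol: 80% of droplets removed per round (`dilution_keep = 0.2`, a
#' five-fold dilution) and an error rate of about 1e-5 per base per
#' replication.
#'
#' @param n_rounds Number of transfer rounds (>= 1).
#' @param host_length Host reference length in nt.
#' @param dilution_keep Fraction of molecules retained by the dilution step.
#' @param substitution_rate Per-base per-replication substitution probability.
#' @param indel_rate Per-base per-replication probability of a 1-nt indel.
#' @param deletion_event_rate Per-replication probability that a new host copy
#'   suffers a large internal deletion, converting it into a parasite class.
#' @param deletion_windows Named list of `c(start, end)` windows defining the
#'   parasite classes (see [default_deletion_windows()]).
#' @param droplet_lambda Mean molecules per droplet.
#' @param replication_factor_host Expected per-round copy number multiplier
#'   for a host molecule in a droplet.
#' @param replication_advantage_exponent Exponent `k` of the parasite length
#'   advantage: a parasite of length `L` replicates with factor
#'   `replication_factor_host * (host_length / L)^k`.
#' @param droplet_capacity Cap on new copies produced within one droplet per
#'   round (the resource limit of the translation mix).
#' @param init_molecules Number of clonal host molecules seeding round 1.
#' @param max_population Guard: configurations whose expected population can
#'   exceed this are rejected before simulation.
#' @param reads_per_round If non-`NULL`, [simulate_serial_transfer()] also
#'   samples this many reads per round (see [sample_reads()]).
#' @param seq_error_rate Per-base sequencing error used when sampling reads.
#' @param mean_passes Mean CCS pass count attached to sampled reads.
#' @param seed Integer RNG seed recorded in the output metadata.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_rounds = 10L,
                              host_length = 2040L,
                              dilution_keep = 0.2,
                              substitution_rate = 1e-5,
                              indel_rate = 1e-6,
                              deletion_event_rate = 1e-4,
                              deletion_windows = default_deletion_windows(host_length),
                              droplet_lambda = 2,
                              replication_factor_host = 5,
                              replication_advantage_exponent = 1,
                              droplet_capacity = 100L,
                              init_molecules = 100L,
                              max_population = 2e5,
                              reads_per_round = NULL,
                              seq_error_rate = 1e-3,
                              mean_passes = 15,
                              seed = 1L) {
  cfg <- list(
    n_rounds = as.integer(n_rounds), host_length = as.integer(host_length),
    dilution_keep = dilution_keep, substitution_rate = substitution_rate,
    indel_rate = indel_rate, deletion_event_rate = deletion_event_rate,
    deletion_windows = deletion_windows, droplet_lambda = droplet_lambda,
    replication_factor_host = replication_factor_host,
    replication_advantage_exponent = replication_advantage_exponent,
    droplet_capacity = as.integer(droplet_capacity),
    init_molecules = as.integer(init_molecules),
    max_population = max_population,
    reads_per_round = if (is.null(reads_per_round)) NULL else as.integer(reads_per_round),
    seq_error_rate = seq_error_rate, mean_passes = mean_passes,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is_count(cfg$n_rounds)) stop("n_rounds must be a positive integer")
  if (!(cfg$dilution_keep > 0 && cfg$dilution_keep < 1))
    stop("dilution_keep must be strictly between 0 and 1")
  for (f in c("substitution_rate", "indel_rate", "deletion_event_rate",
              "seq_error_rate"))
    if (!is_prob(cfg[[f]])) stop(f, " must be a probability in [0, 1]")
  if (!is_count(cfg$init_molecules)) stop("init_molecules must be >= 1")
  if (cfg$droplet_lambda <= 0) stop("droplet_lambda must be positive")
  if (cfg$replication_factor_host < 1)
    stop("replication_factor_host must be >= 1")
  validate_windows(cfg$deletion_windows, cfg$host_length)
  # explosion guard. The long-run trajectory is driven by host growth
  # (parasites replicate only alongside hosts and are droplet-capacity
  # limited); the within-round peak is bounded by the per-droplet capacity.
  # A hard runtime cap backs up this config-time estimate.
  g_host <- cfg$replication_factor_host
  g_peak <- min(max(per_class_replication_factor(cfg)),
                1 + cfg$droplet_capacity / cfg$droplet_lambda)
  n <- cfg$init_molecules
  peak <- n
  for (t in seq_len(cfg$n_rounds)) {
    peak <- max(peak, n * g_peak)
    n <- n * g_host * cfg$dilution_keep
  }
  if (peak > cfg$max_population)
    stop("expected population (", format(peak, digits = 3),
         ") exceeds max_population (", format(cfg$max_population),
         "); lower growth parameters or raise the cap")
  invisible(cfg)
}

# replication factor per class (host plus each configured parasite class)
per_class_replication_factor <- function(cfg) {
  L_host <- cfg$host_length
  f <- c(host = cfg$replication_factor_host)
  for (cls in names(cfg$deletion_windows)) {
    w <- cfg$deletion_windows[[cls]]
    L <- L_host - (w[2] - w[1] + 1L)
    f[[cls]] <- cfg$replication_factor_host *
      (L_host / L)^cfg$replication_advantage_exponent
  }
  f
}

#' Read a simulation configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [simulation_config()]. `deletion_windows` is a named mapping of
#'   `class: [start, end]`.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$deletion_windows))
    raw$deletion_windows <- lapply(raw$deletion_windows, function(w) as.integer(unlist(w)))
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown simulation config fields: ", paste(unknown, collapse = ", "))
  do.call(simulation_config, raw)
}

#' Construct a replicator population
#'
#' One round's molecule pool. `members` rows describe molecules; `events`
#' holds, per molecule, its mutation events in host reference coordinates
#' (`NULL` for an unmutated molecule).
#'
#' @param round Round index.
#' @param members `data.frame` with columns `molecule_id`, `parent_id`,
#'   `class_label`, `copy_count`.
#' @param events List (same length as `nrow(members)`) of event data frames
#'   with columns `site`, `kind`, `ref`, `alt`, `label`, or `NULL`.
#' @param refs The `reference_set` the molecules derive from.
#' @return An object of class `replicator_population`.
#' @export
replicator_population <- function(round, members, events, refs) {
  stopifnot(is.data.frame(members),
            all(c("molecule_id", "parent_id", "class_label", "copy_count")
                %in% names(members)),
            length(events) == nrow(members),
            inherits(refs, "reference_set"))
  if (nrow(members) > 0L && any(members$copy_count < 1L))
    stop("copy_count must be >= 1")
  bad <- setdiff(unique(members$class_label), c("host", names(refs$windows)))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  structure(list(round = round, members = members, events = events, refs = refs),
            class = "replicator_population")
}

#' @export
print.replicator_population <- function(x, ...) {
  tab <- table(x$members$class_label)
  cat("<replicator_population> round", x$round, "-", nrow(x$members),
      "molecules (", paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  invisible(x)
}

# draw `n_mut` per-copy mutation events and merge them into an existing event
# set; returns the updated event data.frame (or NULL if empty)
mutate_events <- function(events, refs, class_label, substitution_rate, indel_rate) {
  pos <- retained_sites(refs, class_label)
  if (!is.null(events) && nrow(events) > 0L) {
    deleted <- events$site[events$kind == "deletion"]
    if (length(deleted)) pos <- setdiff(pos, deleted)
  }
  L <- length(pos)
  n_sub <- rbinom(1L, L, substitution_rate)
  n_ind <- rbinom(1L, L, indel_rate)
  if (n_sub == 0L && n_ind == 0L) return(events)
  host_chars <- strsplit(refs$host, "", fixed = TRUE)[[1]]
  ev <- events %||% empty_events()
  bases <- c("A", "C", "G", "T")
  if (n_sub > 0L) {
    sites <- sample(pos, min(n_sub, L))
    for (s in sites) {
      prev <- which(ev$site == s & ev$kind == "substitution")
      cur <- if (length(prev)) ev$alt[prev[1]] else host_chars[s]
      new <- sample(setdiff(bases, cur), 1L)
      if (length(prev)) ev <- ev[-prev, , drop = FALSE]
      if (new != host_chars[s])
        ev <- rbind(ev, data.frame(
          site = s, kind = "substitution", ref = host_chars[s], alt = new,
          label = mutation_label(s, "substitution", host_chars[s], new),
          stringsAsFactors = FALSE))
    }
  }
  if (n_ind > 0L) {
    sites <- sample(pos, min(n_ind, L))
    for (s in sites) {
      if (stats::runif(1) < 0.5) {  # deletion of one base
        ev <- ev[!(ev$site == s & ev$kind != "insertion"), , drop = FALSE]
        ev <- rbind(ev, data.frame(
          site = s, kind = "deletion", ref = host_chars[s], alt = "",
          label = mutation_label(s, "deletion", host_chars[s], ""),
          stringsAsFactors = FALSE))
      } else {                      # insertion of one base after s
        b <- sample(bases, 1L)
        prev <- which(ev$site == s & ev$kind == "insertion")
        if (length(prev)) {
          ev$alt[prev[1]] <- paste0(ev$alt[prev[1]], b)
          ev$label[prev[1]] <- mutation_label(s, "insertion", "", ev$alt[prev[1]])
        } else {
          ev <- rbind(ev, data.frame(
            site = s, kind = "insertion", ref = "", alt = b,
            label = mutation_label(s, "insertion", "", b),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (nrow(ev) == 0L) NULL else ev[order(ev$site, ev$kind), , drop = FALSE]
}

empty_events <- function() {
  data.frame(site = integer(), kind = character(), ref = character(),
             alt = character(), label = character(), stringsAsFactors = FALSE)
}

# restrict a host event set to the sites a parasite class retains
restrict_events <- function(events, refs, class_label) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  keep <- events$site %in% retained_sites(refs, class_label)
  if (!any(keep)) return(NULL)
  events[keep, , drop = FALSE]
}

#' Simulate a serial-transfer host-parasite replication experiment
#'
#' Runs `config$n_rounds` replication-dilution cycles. Each round: molecules
#' are partitioned into droplets (Poisson occupancy at mean
#' `droplet_lambda`); within each droplet, hosts replicate autonomously and
#' parasites replicate only if the droplet contains at least one host, with
#' offspring counts Poisson-distributed around the class replication factor
#' and capped at `droplet_capacity` new copies per droplet; every new copy
#' acquires substitutions/indels at the configured per-base rates; a new host
#' copy is converted into a parasite class (its deletion window excised) with
#' probability `deletion_event_rate`; finally each molecule survives the
#' five-fold dilution with probability `dilution_keep`. The population
#' returned for each round is the post-incubation, pre-dilution pool (the
#' material a sequencing sample would be drawn from).
#'
#' @param config A [simulation_config()].
#' @param refs Optional [reference_set()]; generated from the config
#'   (deterministically under `config$seed`) when omitted.
#' @return A list with `populations` (list of [replicator_population()], one
#'   per round), `truth` (class `simulation_truth`: `frequencies` data frame
#'   of per-round per-class true mutation frequencies, `deletion_events` data
#'   frame, `parentage` data frame), `refs`, and `reads` (a read set when
#'   `config$reads_per_round` is set, else `NULL`).
#' @export
simulate_serial_transfer <- function(config, refs = NULL) {
  validate_simulation_config(config)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)

  if (is.null(refs))
    refs <- generate_reference_set(config$host_length, config$deletion_windows)
  stopifnot(inherits(refs, "reference_set"))
  if (refs$host_length != config$host_length)
    stop("reference set length does not match config host_length")

  repl_factor <- per_class_replication_factor(config)
  n <- config$init_molecules
  members <- data.frame(
    molecule_id = seq_len(n), parent_id = NA_integer_,
    class_label = "host", copy_count = 1L, stringsAsFactors = FALSE)
  events <- vector("list", n)
  next_id <- n + 1L

  populations <- vector("list", config$n_rounds)
  del_events <- list()
  parentage <- list(data.frame(molecule_id = members$molecule_id,
                               parent_id = NA_integer_, round = 0L))
  freq_rows <- list()
  reads <- if (is.null(config$reads_per_round)) NULL else list()

  for (round in seq_len(config$n_rounds)) {
    N <- nrow(members)
    if (N == 0L) {
      populations[[round]] <- replicator_population(round, members, events, refs)
      next
    }
    # (1) droplet assignment: Poisson occupancy at mean droplet_lambda
    n_droplets <- max(1L, as.integer(round(N / config$droplet_lambda)))
    droplet <- sample.int(n_droplets, N, replace = TRUE)
    has_host <- tapply(members$class_label == "host", droplet, any)

    # (2) replication: offspring counts per molecule, capped per droplet
    lambda <- repl_factor[members$class_label] - 1
    can_replicate <- members$class_label == "host" |
      as.logical(has_host[as.character(droplet)])
    n_off <- ifelse(can_replicate, rpois(N, lambda), 0L)
    # enforce per-droplet capacity by proportional thinning
    tot <- tapply(n_off, droplet, sum)
    over <- names(tot)[tot > config$droplet_capacity]
    for (d in over) {
      i <- which(droplet == as.integer(d) & n_off > 0L)
      budget <- config$droplet_capacity
      scaled <- floor(n_off[i] * budget / sum(n_off[i]))
      n_off[i] <- scaled
    }

    # (3)+(4) create, mutate, and possibly delete the new copies
    parent_idx <- rep(seq_len(N), n_off)
    n_new <- length(parent_idx)
    if (nrow(members) + n_new > config$max_population)
      stop("population exceeded max_population at round ", round)
    if (n_new > 0L) {
      new_members <- data.frame(
        molecule_id = seq.int(next_id, length.out = n_new),
        parent_id = members$molecule_id[parent_idx],
        class_label = members$class_label[parent_idx],
        copy_count = 1L, stringsAsFactors = FALSE)
      next_id <- next_id + n_new
      new_events <- events[parent_idx]
      # large deletions: host copies only
      is_host_copy <- new_members$class_label == "host"
      if (length(config$deletion_windows) > 0L && any(is_host_copy)) {
        hit <- is_host_copy & stats::runif(n_new) < config$deletion_event_rate
        for (i in which(hit)) {
          cls <- sample(names(config$deletion_windows), 1L)
          new_members$class_label[i] <- cls
          new_events[i] <- list(restrict_events(new_events[[i]], refs, cls))
          del_events[[length(del_events) + 1L]] <- data.frame(
            round = round, molecule_id = new_members$molecule_id[i],
            parent_id = new_members$parent_id[i], class_label = cls,
            window_start = config$deletion_windows[[cls]][1],
            window_end = config$deletion_windows[[cls]][2])
        }
      }
      # point mutations on every new copy
      if (config$substitution_rate > 0 || config$indel_rate > 0) {
        for (i in seq_len(n_new)) {
          new_events[i] <- list(mutate_events(
            new_events[[i]], refs, new_members$class_label[i],
            config$substitution_rate, config$indel_rate))
        }
      }
      parentage[[length(parentage) + 1L]] <- data.frame(
        molecule_id = new_members$molecule_id,
        parent_id = new_members$parent_id, round = round)
      members <- rbind(members, new_members)
      events <- c(events, new_events)
    }

    pop <- replicator_population(round, members, events, refs)
    populations[[round]] <- pop
    freq_rows[[round]] <- population_event_frequencies(pop, round)
    if (!is.null(reads))
      reads[[round]] <- sample_reads(pop, config$reads_per_round,
                                     config$seq_error_rate,
                                     mean_passes = config$mean_passes)

    # (5) binomial dilution into the next round
    diluted <- dilute_population(pop, config$dilution_keep)
    members <- diluted$members
    events <- diluted$events
  }

  truth <- structure(list(
    frequencies = do.call(rbind, freq_rows) %||% NULL,
    deletion_events = if (length(del_events)) do.call(rbind, del_events)
                      else data.frame(round = integer(), molecule_id = integer(),
                                      parent_id = integer(), class_label = character(),
                                      window_start = integer(), window_end = integer()),
    parentage = do.call(rbind, parentage),
    seed = config$seed
  ), class = "simulation_truth")

  list(populations = populations, truth = truth, refs = refs,
       reads = if (is.null(reads)) NULL else do.call(rbind, reads))
}

#' Binomial dilution of a population
#'
#' The serial-transfer dilution step: each molecule independently survives
#' with probability `keep` (the five-fold dilution of the protocol keeps
#' 0.2 — 80% of the droplets are removed). The retained count is therefore
#' Binomial(n, keep) distributed.
#'
#' @param population A [replicator_population()].
#' @param keep Survival probability, strictly between 0 and 1.
#' @param seed Optional seed for a reproducible draw.
#' @return The diluted `replicator_population` (same round index).
#' @export
dilute_population <- function(population, keep, seed = NULL) {
  stopifnot(inherits(population, "replicator_population"))
  if (!(is.numeric(keep) && length(keep) == 1L && keep > 0 && keep < 1))
    stop("keep must lie strictly between 0 and 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  mask <- stats::runif(nrow(population$members)) < keep
  replicator_population(population$round,
                        population$members[mask, , drop = FALSE],
                        population$events[mask], population$refs)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# true per-class event frequencies in one round's population, weighted by copies
population_event_frequencies <- function(pop, round) {
  m <- pop$members
  if (nrow(m) == 0L) return(NULL)
  rows <- list()
  for (cls in unique(m$class_label)) {
    idx <- which(m$class_label == cls)
    total <- sum(m$copy_count[idx])
    counts <- new.env(parent = emptyenv())
    for (i in idx) {
      ev <- pop$events[[i]]
      if (is.null(ev) || nrow(ev) == 0L) next
      for (lab in ev$label) {
        cur <- counts[[lab]] %||% 0
        counts[[lab]] <- cur + m$copy_count[i]
      }
    }
    labs <- ls(counts)
    if (length(labs))
      rows[[length(rows) + 1L]] <- data.frame(
        round = round, class_label = cls, label = labs,
        count = vapply(labs, function(l) counts[[l]], 0),
        depth = total,
        frequency = vapply(labs, function(l) counts[[l]], 0) / total,
        row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Write simulation ground truth as TSV files
#'
#' Writes `truth_frequencies.tsv` (per round/class/mutation true frequency),
#' `truth_deletion_events.tsv` and `truth_parentage.tsv` into `dir`.
#'
#' @param truth A `simulation_truth` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "simulation_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("truth_frequencies.tsv",
                            "truth_deletion_events.tsv",
                            "truth_parentage.tsv"))
  write_tsv(truth$frequencies %||% data.frame(), paths[1])
  write_tsv(truth$deletion_events, paths[2])
  write_tsv(truth$parentage, paths[3])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
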