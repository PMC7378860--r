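#' Deletion-masked Hamming distance between two genotype vectors
#'
#' Counts the dominant-mutation positions at which the two presence vectors
#' differ, over positions where both are unmasked. Masked positions
#' (character `-`, sites inside a class's large deletion) contribute zero,
#' so a parasite that perfectly matches a host outside the deletion is at
#' distance zero — "ignoring the large deletion".
#'
#' @param g1,g2 Genotype vector strings over `{0,1,-}` of equal length (as
#'   in the `vector` column of [project_genotypes()]).
#' @return Non-negative integer distance.
#' @export
genotype_distance <- function(g1, g2) {
  if (nchar(g1) != nchar(g2))
    stop("genotype vectors are defined over different dominant-site lists")
  a <- strsplit(g1, "", fixed = TRUE)[[1]]
  b <- strsplit(g2, "", fixed = TRUE)[[1]]
  sum(a != b & a != "-" & b != "-")
}

#' Build the squared-Hamming distance matrix over genotypes
#'
#' Entry (i, j) is the square of the deletion-masked Hamming distance
#' between genotypes i and j.
#'
#' @param genotypes A [project_genotypes()] table (or any data frame with
#'   `vector`, `class_label` columns).
#' @return A list of class `genotype_distance_matrix` with `D` (squared
#'   distances), `hamming` (unsquared), `genotypes` (the input table), and
#'   `cross_class` (logical matrix flagging pairs from different classes).
#' @export
build_distance_matrix <- function(genotypes) {
  stopifnot(is.data.frame(genotypes), nrow(genotypes) >= 1L)
  vecs <- genotypes$vector
  n <- length(vecs)
  L <- unique(nchar(vecs))
  if (length(L) != 1L)
    stop("genotype vectors are defined over different dominant-site lists")
  # matrix encoding: 0/1 values, NA for masked
  M <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    ch <- strsplit(vecs[i], "", fixed = TRUE)[[1]]
    M[i, ] <- match(ch, c("0", "1")) - 1L  # masked '-' becomes NA
  }
  H <- matrix(0L, n, n)
  if (L > 0L) {
    for (i in seq_len(n)) {
      di <- abs(sweep(M, 2L, M[i, ], `-`))
      H[, i] <- as.integer(rowSums(di, na.rm = TRUE))
    }
  }
  cross <- outer(genotypes$class_label, genotypes$class_label, `!=`)
  ids <- genotypes$genotype_id %||% as.character(seq_len(n))
  dimnames(H) <- list(ids, ids)
  structure(list(D = H^2, hamming = H, genotypes = genotypes,
                 cross_class = cross),
            class = "genotype_distance_matrix")
}

#' Principal coordinate embedding of a squared-distance matrix
#'
#' Double-centers the squared-distance matrix into the kernel
#' `K = -1/2 C D C` (C the centering matrix `I - 11'/n`), eigendecomposes
#' K, and places genotype i at `(sqrt(l1) e1i, -sqrt(l2) e2i)` using the two
#' leading eigenvalues/eigenvectors. Because a squared-Hamming D need not be
#' Euclidean, negative eigenvalues can occur; they are excluded from the
#' coordinates and their relative magnitude is reported as a diagnostic.
#' With `coord_scaling = "eigenvalue"` the coordinates use `l_k` itself in
#' place of `sqrt(l_k)`.
#'
#' @param D A `genotype_distance_matrix` or a symmetric non-negative
#'   numeric matrix of squared distances.
#' @param coord_scaling `"sqrt"` (standard principal coordinates) or
#'   `"eigenvalue"`.
#' @return An object of class `pcoa_embedding`: list with `coordinates`
#'   (n x 2 matrix), `eigenvalues`, `vectors`, `kernel`,
#'   `negative_eigenvalue_mass` (sum |negative| / sum |all|),
#'   `second_axis_degenerate`, and the `genotypes` table when available.
#' @export
pcoa_embed <- function(D, coord_scaling = c("sqrt", "eigenvalue")) {
  coord_scaling <- match.arg(coord_scaling)
  genotypes <- NULL
  if (inherits(D, "genotype_distance_matrix")) {
    genotypes <- D$genotypes
    D <- D$D
  }
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (any(D < 0)) stop("D must be non-negative")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  n <- nrow(D)
  Cm <- diag(n) - matrix(1 / n, n, n)
  K <- -0.5 * Cm %*% D %*% Cm
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  lam <- eig$values
  vec <- eig$vectors
  # deterministic sign: first component of largest magnitude made positive
  for (k in seq_len(n)) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  scale_k <- function(l) {
    if (l <= 0) return(0)
    if (coord_scaling == "sqrt") sqrt(l) else l
  }
  x <- scale_k(lam[1]) * vec[, 1]
  degenerate <- n < 2L || lam[2] <= 0
  y <- if (degenerate) rep(0, n) else -scale_k(lam[2]) * vec[, 2]
  neg_mass <- if (sum(abs(lam)) == 0) 0 else sum(abs(lam[lam < 0])) / sum(abs(lam))
  coords <- cbind(x = x, y = y)
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords, eigenvalues = lam, vectors = vec,
                 kernel = K, negative_eigenvalue_mass = neg_mass,
                 second_axis_degenerate = degenerate,
                 coord_scaling = coord_scaling, genotypes = genotypes),
            class = "pcoa_embedding")
}

#' @export
print.pcoa_embedding <- function(x, ...) {
  cat("<pcoa_embedding>", nrow(x$coordinates), "genotypes; lambda1 =",
      signif(x$eigenvalues[1], 4),
      "lambda2 =", signif(x$eigenvalues[min(2, length(x$eigenvalues))], 4),
      "\n  negative-eigenvalue mass:",
      signif(x$negative_eigenvalue_mass, 3), "\n")
  invisible(x)
}

#' Genotype-network edge sets
#'
#' Within-class edges join pairs of genotypes one Hamming distance apart in
#' the same RNA species; cross-class edges join pairs at deletion-masked
#' distance zero in different species ("perfect match ignoring the large
#' deletion") — the candidate parasite-generation events.
#'
#' @param dm A [build_distance_matrix()] result.
#' @return A `data.frame` with columns `id1`, `id2`, `type`
#'   (`"within"`/`"cross"`), `distance`, `class1`, `class2`, `round1`,
#'   `round2`.
#' @export
build_edges <- function(dm) {
  stopifnot(inherits(dm, "genotype_distance_matrix"))
  H <- dm$hamming
  g <- dm$genotypes
  n <- nrow(H)
  ids <- g$genotype_id %||% as.character(seq_len(n))
  rounds <- g$round %||% rep(NA_integer_, n)
  rows <- list()
  if (n >= 2L) {
    pair <- which(upper.tri(H), arr.ind = TRUE)
    d <- H[pair]
    cross <- dm$cross_class[pair]
    within_hit <- !cross & d == 1L
    cross_hit <- cross & d == 0L
    keep <- within_hit | cross_hit
    if (any(keep)) {
      i <- pair[keep, 1]; j <- pair[keep, 2]
      rows <- data.frame(
        id1 = ids[i], id2 = ids[j],
        type = ifelse(cross[keep], "cross", "within"),
        distance = d[keep],
        class1 = g$class_label[i], class2 = g$class_label[j],
        round1 = rounds[i], round2 = rounds[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!is.data.frame(rows))
    rows <- data.frame(id1 = character(), id2 = character(),
                       type = character(), distance = integer(),
                       class1 = character(), class2 = character(),
                       round1 = integer(), round2 = integer(),
                       stringsAsFactors = FALSE)
  rows <- rows[order(rows$type, rows$id1, rows$id2), ]
  rownames(rows) <- NULL
  rows
}
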