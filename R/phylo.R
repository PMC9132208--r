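## Distance phylogenetics: Kimura two-parameter distances, neighbor-joining
## with deterministic tie-breaking and negative-branch clamping, nonparametric
## bootstrap over alignment columns, Robinson-Foulds bipartition distance, and
## a small sequence simulator over trees (used by the power tests).

#' Kimura two-parameter distance between two aligned rows
#'
#' P and Q are transition and transversion proportions over pairwise non-gap
#' columns; d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q).
#'
#' @param seqA,seqB gapped strings of equal length (gaps "-", ambiguous "N"
#'   columns dropped pairwise).
#' @return list with `d`, `P`, `Q`, `n` (compared sites).
#' @export
k2p_distance <- function(seqA, seqB) {
  stopifnot(nchar(seqA) == nchar(seqB))
  a <- seq_chars(seqA); b <- seq_chars(seqB)
  use <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(use)) stop("no shared non-gap columns")
  a <- a[use]; b <- b[use]
  n <- length(a)
  P <- sum(is_transition(a, b)) / n
  Q <- sum(a != b & !is_transition(a, b)) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("distance undefined (saturation)")
  d <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  list(d = d, P = P, Q = Q, n = n)
}

#' K2P distance matrix for an alignment
#'
#' Columns with more than `max_gap_frac` gaps are dropped first (masking
#' surrogate for unalignable regions such as the VNTR core).
#'
#' @param rows named character vector of gapped strings.
#' @param max_gap_frac drop columns with a higher gap fraction (default 0.5).
#' @return list with `d`, `P`, `Q` matrices and `taxa`.
#' @export
k2p_matrix <- function(rows, max_gap_frac = 0.5) {
  rows <- drop_gappy_columns(rows, max_gap_frac)
  taxa <- names(rows)
  k <- length(taxa)
  d <- P <- Q <- matrix(0, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      res <- tryCatch(k2p_distance(rows[[i]], rows[[j]]), error = function(e) e)
      if (inherits(res, "error"))
        stop("distance undefined for pair ", taxa[i], "/", taxa[j], ": ",
             conditionMessage(res))
      d[i, j] <- d[j, i] <- res$d
      P[i, j] <- P[j, i] <- res$P
      Q[i, j] <- Q[j, i] <- res$Q
    }
  }
  list(d = d, P = P, Q = Q, taxa = taxa)
}

drop_gappy_columns <- function(rows, max_gap_frac = 0.5) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  keep <- colMeans(m == "-") <= max_gap_frac
  stats::setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                  names(rows))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration; ties in the Q criterion are broken
#' deterministically by taxon-id order. Negative branch lengths are clamped
#' to 0 with the deficit transferred to the sister edge.
#'
#' @param d symmetric distance matrix with taxa dimnames.
#' @return unrooted tree of class `"phylo"` (ape).
#' @export
nj_tree <- function(d) {
  if (any(!is.finite(d))) stop("undefined distance in matrix")
  taxa <- rownames(d)
  n0 <- length(taxa)
  stopifnot(n0 >= 2)
  if (n0 == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
               tip.label = taxa, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ## active nodes carry an id: 1..n0 are tips, n0+1.. are internals (ape style)
  active <- seq_len(n0)
  next_id <- n0 + 2L  # ape root node is n0+1; create internals from n0+2 upward
  ids <- seq_len(n0)
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  D <- d
  while (length(active) > 3) {
    m <- length(active)
    rs <- rowSums(D)
    qmat <- (m - 2) * D - outer(rs, rs, "+")
    diag(qmat) <- Inf
    ix <- which(qmat == min(qmat), arr.ind = TRUE)
    ix <- ix[ix[, 1] < ix[, 2], , drop = FALSE]
    ix <- ix[order(ix[, 1], ix[, 2]), , drop = FALSE][1, ]  # deterministic
    i <- ix[1]; j <- ix[2]
    vi <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    ## clamp negatives, transfer deficit to the sister edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    new_id <- next_id; next_id <- next_id + 1L
    edges <- rbind(edges, c(new_id, ids[i]), c(new_id, ids[j]))
    lens <- c(lens, vi, vj)
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    ids <- c(ids[keep], new_id)
    active <- c(active[keep], new_id)
  }
  ## final 3 nodes join at the ape root (n0 + 1)
  root <- n0 + 1L
  D3 <- D; id3 <- ids
  v <- c((D3[1, 2] + D3[1, 3] - D3[2, 3]) / 2,
         (D3[1, 2] + D3[2, 3] - D3[1, 3]) / 2,
         (D3[1, 3] + D3[2, 3] - D3[1, 2]) / 2)
  v <- pmax(v, 0)
  edges <- rbind(edges, cbind(root, id3))
  lens <- c(lens, v)
  ## renumber internal nodes into ape's contiguous range
  all_internal <- sort(unique(edges[edges > n0]))
  remap <- stats::setNames(seq(n0 + 1L, n0 + length(all_internal)), all_internal)
  edges_m <- edges
  edges_m[edges_m > n0] <- remap[as.character(edges_m[edges_m > n0])]
  ## ape wants edges parent->child with root first; reorder via cladewise
  tr <- list(edge = edges_m, edge.length = lens, tip.label = taxa,
             Nnode = length(all_internal))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

## non-trivial bipartitions of an unrooted phylo as canonical strings
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    ## canonical side: the one containing the alphabetically first tip
    if (!(tips[1] %in% side)) side <- sort(setdiff(tips, side))
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Count of non-trivial bipartitions present in exactly one of the two trees.
#'
#' @param t1,t2 `"phylo"` trees with identical leaf sets.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf-set mismatch")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Bootstrap support for the K2P/NJ tree of an alignment
#'
#' Columns are resampled with replacement; the support of an internal edge is
#' the percentage of replicate trees containing the same bipartition.
#' Replicates with undefined (saturated) distances are discarded and counted;
#' more than 50% discarded is an error.
#'
#' @param rows named character vector of gapped strings.
#' @param n_replicates bootstrap replicates (default 10,000).
#' @param seed RNG seed.
#' @param max_gap_frac column gap-fraction filter applied before resampling.
#' @return list with `tree` (phylo; `node.comment` holds supports keyed by
#'   bipartition), `supports` (named numeric, percent), `n_discarded`.
#' @export
bootstrap_support <- function(rows, n_replicates = 10000L, seed = 1L,
                              max_gap_frac = 0.5) {
  stopifnot(n_replicates >= 1)
  set.seed(seed)
  rows <- drop_gappy_columns(rows, max_gap_frac)
  base <- nj_tree(k2p_matrix(rows, max_gap_frac = 1)$d)
  ## zero-length internal edges carry no signal: collapse them so identical
  ## sequences yield a star with an empty support vector
  base <- ape::di2multi(base, tol = 1e-12)
  bip <- tree_bipartitions(base)
  if (length(bip) == 0L)
    return(list(tree = base, supports = stats::setNames(numeric(0), character(0)),
                n_discarded = 0L))
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  rownames(m) <- names(rows)
  counts <- stats::setNames(numeric(length(bip)), bip)
  discarded <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_rows <- stats::setNames(apply(m[, cols, drop = FALSE], 1, paste,
                                      collapse = ""), names(rows))
    dm <- tryCatch(k2p_matrix(rep_rows, max_gap_frac = 1)$d,
                   error = function(e) NULL)
    if (is.null(dm)) { discarded <- discarded + 1L; next }
    rb <- tree_bipartitions(nj_tree(dm))
    hit <- intersect(rb, bip)
    counts[hit] <- counts[hit] + 1
  }
  if (discarded > n_replicates / 2) stop("saturated alignment")
  supports <- 100 * counts / (n_replicates - discarded)
  list(tree = base, supports = supports, n_discarded = discarded)
}

#' Simulate sequences on a tree under a two-rate substitution model
#'
#' Evolves a root sequence down a `phylo` tree; the expected number of
#' substitutions per site on a branch equals its length, transitions weighted
#' `kappa`:1 over each transversion. No indels.
#'
#' @param tree `"phylo"` with branch lengths.
#' @param len sequence length (ignored when `root_seq` given).
#' @param root_seq optional root sequence.
#' @param kappa transition/transversion weight.
#' @return named character vector of tip sequences.
#' @export
simulate_on_tree <- function(tree, len = 1000L, root_seq = NULL, kappa = 2) {
  if (is.null(root_seq)) root_seq <- random_dna(len)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- list()
  seqs[[root]] <- root_seq
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    p <- min(0.2, ord$edge.length[e])
    seqs[[child]] <- mutate_sequence(seqs[[par]], p, kappa)$seq
  }
  stats::setNames(unlist(seqs[seq_len(n_tip)]), tree$tip.label)
}
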