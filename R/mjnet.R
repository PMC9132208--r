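## Median-joining haplotype networks (Bandelt et al. style): iterate
## { epsilon-relaxed minimum spanning network; add median (majority-state)
## vectors of connected triplets when they reduce network cost; prune obsolete
## medians } to a fixpoint, with equal site weights and external rooting.

## Hamming distance matrix between haplotype strings (over scored positions)
hap_dist <- function(haps) {
  m <- do.call(rbind, strsplit(haps, "", fixed = TRUE))
  k <- length(haps)
  d <- matrix(0L, k, k)
  if (k >= 2) for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  d
}

## length of a minimum spanning tree of an integer distance matrix (Prim)
mst_length <- function(d) {
  n <- nrow(d)
  if (n <= 1) return(0L)
  used <- c(1L); tot <- 0L
  key <- d[1, ]
  key[1] <- Inf
  for (step in seq_len(n - 1)) {
    v <- which.min(key)
    tot <- tot + key[v]
    used <- c(used, v)
    key <- pmin(key, d[v, ])
    key[used] <- Inf
  }
  tot
}

## epsilon-relaxed minimum spanning network: an edge {u,v} of weight w is
## kept iff u and v lie in different connected components of the graph
## containing every pair at distance < w - epsilon. At epsilon = 0 this is
## the standard minimum spanning network (union of all MSTs); it always
## contains at least one MST. Union-find is rebuilt per weight round (the
## graphs here are small).
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2) return(matrix(integer(0), 0, 2))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  edges <- matrix(integer(0), 0, 2)
  for (uw in unique(w)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in which(w < uw - epsilon)) {
      ru <- find(pairs[e, 1]); rv <- find(pairs[e, 2])
      if (ru != rv) parent[ru] <- rv
    }
    for (e in which(w == uw)) {
      if (find(pairs[e, 1]) != find(pairs[e, 2]))
        edges <- rbind(edges, pairs[e, , drop = FALSE])
    }
  }
  unique(edges)
}

## drop obsolete median (unobserved) nodes: repeatedly remove the node whose
## removal yields the smallest MST length, as long as that does not increase
## the cost — removing a detour node first, never a load-bearing one
prune_medians <- function(set, observed_haps) {
  repeat {
    cur <- mst_length(hap_dist(set))
    idx <- which(!(set %in% observed_haps))
    if (length(idx) == 0L) break
    costs <- vapply(idx, function(i) mst_length(hap_dist(set[-i])), numeric(1))
    o <- order(costs, set[idx])
    if (costs[o[1]] > cur) break
    set <- set[-idx[o[1]]]
  }
  list(set = set, len = mst_length(hap_dist(set)))
}

## majority-state median vector of three haplotypes; ties resolved to the
## state of the first haplotype (deterministic)
median_vector <- function(h1, h2, h3) {
  a <- seq_chars(h1); b <- seq_chars(h2); c3 <- seq_chars(h3)
  out <- a
  for (i in seq_along(a)) {
    states <- c(a[i], b[i], c3[i])
    tab <- table(states)
    if (max(tab) >= 2) out[i] <- names(tab)[which.max(tab)]
  }
  paste(out, collapse = "")
}

#' Build a median-joining haplotype network
#'
#' Equal weight for all positions; gap columns are excluded from scoring by
#' default. Duplicate input haplotypes collapse into one node with
#' multiplicity. Output is invariant under input order (nodes are ordered
#' canonically by haplotype string).
#'
#' @param haplotypes named character vector of aligned haplotype strings
#'   (A/C/G/T and "-").
#' @param epsilon relaxation parameter (default 0).
#' @param include_gaps score gap columns as a fifth state (default FALSE).
#' @return an `mj_net`: list with `nodes` (data.frame `id`, `haplotype`
#'   (scored positions), `observed`, `multiplicity`, `labels`), `edges`
#'   (data.frame `from`, `to`, `weight`), `total_length` (MST length over the
#'   final node set), `scored_positions`, `epsilon`.
#' @export
build_mj_network <- function(haplotypes, epsilon = 0L, include_gaps = FALSE) {
  stopifnot(length(haplotypes) >= 2)
  if (is.null(names(haplotypes)))
    names(haplotypes) <- paste0("h", seq_along(haplotypes))
  haplotypes <- toupper(haplotypes)
  m <- do.call(rbind, strsplit(unname(haplotypes), "", fixed = TRUE))
  ok <- c(DNA_BASES, "-", "0", "1")
  if (!all(m %in% ok)) stop("non-ACGT/gap states in haplotypes")
  keep <- rep(TRUE, ncol(m))
  if (!include_gaps) keep <- colSums(m == "-") == 0
  ## restrict to segregating (variable) scored columns; constant columns
  ## contribute nothing to any distance
  varcol <- apply(m[, keep, drop = FALSE], 2, function(x) length(unique(x)) > 1)
  scored <- which(keep)[varcol]
  hs <- apply(m[, scored, drop = FALSE], 1, paste, collapse = "")
  if (length(scored) == 0L) hs <- rep("", nrow(m))
  ## collapse duplicates
  uniq <- sort(unique(hs))
  mult <- as.integer(table(factor(hs, levels = uniq)))
  labels <- vapply(uniq, function(h)
    paste(names(haplotypes)[hs == h], collapse = ","), character(1))
  if (length(uniq) < 2L) stop("need at least 2 distinct haplotypes")

  nodes <- uniq
  ## candidate medians of every node triplet (the connected-triplet rule of
  ## the classical algorithm, taken at large epsilon, yields this pool);
  ## the three orientations cover per-site ties deterministically
  cands_of <- function(nodes) {
    n <- length(nodes)
    if (n < 3) return(character(0))
    cmb <- utils::combn(n, 3)
    cand <- character(0)
    for (ci in seq_len(ncol(cmb))) {
      u <- cmb[1, ci]; v <- cmb[2, ci]; w <- cmb[3, ci]
      cand <- c(cand, median_vector(nodes[u], nodes[v], nodes[w]),
                median_vector(nodes[v], nodes[u], nodes[w]),
                median_vector(nodes[w], nodes[u], nodes[v]))
    }
    setdiff(unique(cand), nodes)
  }
  ## steepest descent on network cost (MST length over the node set), plus a
  ## joint-pair step at stalls: when no single median improves the cost, try
  ## committing a median TOGETHER with a second median of the extended set —
  ## some Steiner backbones only pay off jointly. The pair search is skipped
  ## on large node sets (quadratic in candidates; stalls on realistic
  ## genealogies happen when the network is already small).
  repeat {
    cur_len <- mst_length(hap_dist(nodes))
    cand <- cands_of(nodes)
    if (length(cand) == 0L) break
    gains <- vapply(cand, function(h)
      cur_len - mst_length(hap_dist(c(nodes, h))), numeric(1))
    if (max(gains) > 0) {
      nodes <- sort(c(nodes, cand[order(-gains, cand)][1]))
      next
    }
    best <- prune_medians(nodes, uniq)
    improved <- FALSE
    if (length(nodes) <= 40L && length(cand) <= 120L) {
      for (h in sort(cand)) {
        n2 <- sort(c(nodes, h))
        cand2 <- cands_of(n2)
        for (x in sort(cand2)) {
          p <- prune_medians(sort(unique(c(n2, x))), uniq)
          if (p$len < best$len) { best <- p; improved <- TRUE }
        }
      }
    }
    if (!improved) break
    nodes <- sort(best$set)
  }
  ## final pruning of obsolete medians (cheapest-removal-first, to fixpoint)
  nodes <- prune_medians(nodes, uniq)$set
  observed <- nodes %in% uniq
  d <- hap_dist(nodes)
  edges <- msn_edges(d, epsilon)
  node_df <- data.frame(id = seq_along(nodes), haplotype = nodes,
                        observed = observed,
                        multiplicity = ifelse(observed,
                                              mult[match(nodes, uniq)], 0L),
                        labels = ifelse(observed,
                                        labels[match(nodes, uniq)], ""),
                        stringsAsFactors = FALSE)
  edge_df <- if (nrow(edges)) data.frame(
    from = pmin(edges[, 1], edges[, 2]), to = pmax(edges[, 1], edges[, 2]),
    weight = d[edges]) else data.frame(from = integer(0), to = integer(0),
                                       weight = integer(0))
  edge_df <- edge_df[order(edge_df$from, edge_df$to), , drop = FALSE]
  rownames(edge_df) <- NULL
  structure(list(nodes = node_df, edges = edge_df,
                 total_length = mst_length(d), scored_positions = scored,
                 epsilon = epsilon, root_id = NULL),
            class = "mj_net")
}

#' @export
print.mj_net <- function(x, ...) {
  cat(sprintf("mj_net: %d nodes (%d observed, %d median), %d edges, total length %d\n",
              nrow(x$nodes), sum(x$nodes$observed), sum(!x$nodes$observed),
              nrow(x$edges), x$total_length))
  invisible(x)
}

#' Root a median-joining network on an external haplotype
#'
#' The root is the network node with minimum Hamming distance to the outgroup
#' haplotype (scored positions only); the outgroup attaches by an edge
#' labelled with that distance and flagged not-to-scale. Ties are reported
#' and broken toward the lowest node id, with a warning.
#'
#' @param net an `mj_net`.
#' @param outgroup_haplotype haplotype string aligned to the input columns
#'   (full alignment coordinates; the network's scored positions are used).
#' @return the network with `root_id`, `root_distance`, `root_candidates`,
#'   `root_edge_to_scale = FALSE` set.
#' @export
root_network <- function(net, outgroup_haplotype) {
  og <- seq_chars(toupper(outgroup_haplotype))[net$scored_positions]
  if (anyNA(og)) stop("outgroup haplotype shorter than the alignment")
  dists <- vapply(net$nodes$haplotype, function(h)
    sum(seq_chars(h) != og), integer(1))
  best <- which(dists == min(dists))
  if (length(best) > 1)
    warning("tie between candidate root nodes: ",
            paste(net$nodes$id[best], collapse = ", "),
            "; lowest id chosen")
  net$root_id <- net$nodes$id[best[1]]
  net$root_distance <- unname(min(dists))
  net$root_candidates <- net$nodes$id[best]
  net$root_edge_to_scale <- FALSE
  net
}

#' Export a network as DOT
#'
#' @param net an `mj_net`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mjnet_dot <- function(net, path) {
  lines <- c("graph mjnet {")
  for (i in seq_len(nrow(net$nodes))) {
    n <- net$nodes[i, ]
    shape <- if (n$observed) "circle" else "point"
    lab <- if (n$observed) sprintf("%s (x%d)", n$labels, n$multiplicity) else ""
    lines <- c(lines, sprintf("  n%d [shape=%s,label=\"%s\"];", n$id, shape, lab))
  }
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    lines <- c(lines, sprintf("  n%d -- n%d [label=\"%d\"];", e$from, e$to,
                              e$weight))
  }
  if (!is.null(net$root_id))
    lines <- c(lines, sprintf(
      "  root [shape=box]; root -- n%d [style=dashed,label=\"%d (not to scale)\"];",
      net$root_id, net$root_distance))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
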