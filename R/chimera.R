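## Subfamily segmentation of composite elements along their consensus,
## inter-subfamily chimera detection, and the circular-intermediate
## integration signature (reciprocal chimeras with swapped inner/outer TSD
## association). Classification uses diagnostic sites only — robust inside
## the unalignable VNTR, which is excluded from scoring by default.

#' Segment an element by subfamily along its consensus
#'
#' Each diagnostic site of the subfamily pair is scored for its A vs B state
#' along the element; maximal runs of same-state sites become segments; runs
#' supported by fewer than `min_support` sites are merged into their
#' neighbours (majority subfamily, with a "mosaic below resolution" warning
#' when everything collapses); the switch point between adjacent segments is
#' the midpoint of the flanking diagnostic sites.
#'
#' @param element_seq element sequence, consensus orientation.
#' @param library a `consensus_library`.
#' @param pair character(2): the subfamily pair, e.g. `c("SVA_B","SVA_D")`.
#' @param consensus_offset 0-based consensus coordinate of the element's
#'   first base (e.g. > 0 for a 5'-truncated element).
#' @param min_support minimum diagnostic sites per segment (default 3).
#' @param exclude_vntr drop diagnostic sites inside the VNTR span
#'   (default TRUE; the library marks the domain).
#' @return a `chimera_segment`: list with `segments` (data.frame `subfamily`,
#'   `cons_start`, `cons_end`, `support`), `switch_points` (consensus
#'   coordinates), `site_states` (per-site calls).
#' @export
segment_by_subfamily <- function(element_seq, library, pair,
                                 consensus_offset = 0L, min_support = 3L,
                                 exclude_vntr = TRUE) {
  ds <- diag_sites_for(library, pair[1], pair[2])
  if (exclude_vntr) {
    v <- library$vntr_span
    ds <- ds[ds$pos < v[1] | ds$pos >= v[2], , drop = FALSE]
  }
  el <- seq_chars(element_seq)
  n <- length(el)
  ## element base at consensus position p sits at index p - offset + 1
  idx <- ds$pos - consensus_offset + 1L
  inside <- idx >= 1L & idx <= n
  ds <- ds[inside, , drop = FALSE]
  idx <- idx[inside]
  state <- ifelse(el[idx] == ds$stateA, pair[1],
                  ifelse(el[idx] == ds$stateB, pair[2], NA))
  scorable <- !is.na(state)
  ds <- ds[scorable, , drop = FALSE]
  state <- state[scorable]
  if (length(state) < 2L) stop("unclassifiable: <2 scorable diagnostic sites")

  ## maximal runs of same-state sites
  runs <- rle(state)
  seg <- data.frame(subfamily = runs$values,
                    from = cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)],
                    support = runs$lengths, stringsAsFactors = FALSE)
  seg$to <- seg$from + seg$support - 1L
  ## merge short runs into neighbours until all segments reach min_support
  ## (or only one segment remains); when the element is mosaic below
  ## resolution everything merges to the majority subfamily
  mosaic <- all(seg$support < min_support) && nrow(seg) > 1L
  while (nrow(seg) > 1L && any(seg$support < min_support)) {
    i <- which.min(seg$support)
    nb <- if (i == 1L) 2L else if (i == nrow(seg)) i - 1L else
      if (seg$support[i - 1L] >= seg$support[i + 1L]) i - 1L else i + 1L
    j <- min(i, nb)
    seg$subfamily[j] <- seg$subfamily[nb]  # absorbed into the larger run
    seg$to[j] <- seg$to[max(i, nb)]
    seg$support[j] <- seg$support[j] + seg$support[max(i, nb)]
    seg <- seg[-max(i, nb), , drop = FALSE]
    ## merging can create same-subfamily neighbours; collapse them
    k <- 1L
    while (k < nrow(seg)) {
      if (seg$subfamily[k] == seg$subfamily[k + 1L]) {
        seg$to[k] <- seg$to[k + 1L]
        seg$support[k] <- seg$support[k] + seg$support[k + 1L]
        seg <- seg[-(k + 1L), , drop = FALSE]
      } else k <- k + 1L
    }
  }
  if (mosaic && nrow(seg) == 1L) {
    maj <- names(sort(table(state), decreasing = TRUE))[1]
    seg$subfamily <- maj
    warning("mosaic below resolution; merged to majority subfamily ", maj)
  }
  rownames(seg) <- NULL
  seg$cons_start <- ds$pos[seg$from]
  seg$cons_end <- ds$pos[seg$to]
  switch_points <- if (nrow(seg) > 1L)
    as.integer((ds$pos[seg$to[-nrow(seg)]] + ds$pos[seg$from[-1L]]) / 2)
  else integer(0)
  structure(list(
    segments = seg[, c("subfamily", "cons_start", "cons_end", "support")],
    switch_points = switch_points,
    site_states = data.frame(pos = ds$pos, state = state,
                             stringsAsFactors = FALSE)),
    class = "chimera_segment")
}

#' Detect subfamily-chimeric elements in an annotated genome
#'
#' Runs [segment_by_subfamily()] over every annotated element of the pair's
#' family and returns only multi-segment (chimeric) calls, each with
#' orientation-normalized subfamily order (minus-strand elements are
#' reverse-complemented into consensus orientation first).
#'
#' @param annotations annotation data.frame.
#' @param genome named character vector of contigs.
#' @param library a `consensus_library`.
#' @param pair subfamily pair (default the library's first two).
#' @param family restrict to annotations of this family (default "SVA").
#' @param ... passed to [segment_by_subfamily()].
#' @return list of chimera calls; each is the `chimera_segment` augmented
#'   with `interval` (genome coordinates) and `order` (subfamily sequence,
#'   5' to 3' on the consensus).
#' @export
detect_chimera <- function(annotations, genome, library,
                           pair = names(library$entries)[1:2],
                           family = "SVA", ...) {
  ann <- annotations[annotations$family == family, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ann))) {
    a <- ann[i, ]
    s <- gslice(genome, a$contig_id, a$start, a$end)
    if (a$strand == "-") s <- revcomp(s)
    call <- tryCatch(
      segment_by_subfamily(s, library, pair,
                           consensus_offset = a$consensus_start - 1L, ...),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(call) || nrow(call$segments) < 2L) next
    call$interval <- interval(a$contig_id, a$start, a$end, a$strand)
    call$order <- call$segments$subfamily
    out[[length(out) + 1L]] <- call
  }
  out
}

## duplicated prefix/suffix pair of an interior interval (inner TSDs sit just
## inside the interval's edges, adjacent to the flanking elements)
detect_inner_tsd <- function(genome, contig_id, start, end, min_len = 5L,
                             max_mismatch_frac = 0.2, max_len = 30L,
                             max_offset = 5L) {
  s <- genome[[contig_id]]
  w <- min(max_len + max_offset, floor((end - start) / 2))
  left <- seq_chars(substr(s, start + 1L, start + w))
  right <- seq_chars(substr(s, end - w + 1L, end))
  best <- NULL
  for (l in seq(min(max_len, w), min_len)) {
    for (o1 in 0:min(max_offset, w - l)) {
      a <- left[seq(o1 + 1L, o1 + l)]
      for (o2 in 0:min(max_offset, w - l)) {
        b <- right[seq(w - o2 - l + 1L, w - o2)]
        mm <- sum(a != b)
        if (mm > floor(max_mismatch_frac * l)) next
        cand <- list(l = l, mm = mm, off = o1 + o2, o1 = o1, o2 = o2)
        if (is.null(best) || cand$l > best$l ||
            (cand$l == best$l && (cand$mm < best$mm ||
             (cand$mm == best$mm && cand$off < best$off)))) best <- cand
      }
    }
    if (!is.null(best) && best$l == l) break
  }
  if (is.null(best)) return(NULL)
  structure(list(
    left = interval(contig_id, start + best$o1, start + best$o1 + best$l),
    right = interval(contig_id, end - best$o2 - best$l, end - best$o2),
    length = best$l, mismatches = best$mm), class = "tsd_call")
}

#' Call the circular-intermediate integration signature
#'
#' A positive verdict requires (i) the two flanking chimeras to have
#' reciprocal subfamily orders (X->Y and Y->X), (ii) an outer TSD pair
#' flanking the whole cassette with both copies adjacent to subfamily-X ends,
#' and (iii) an inner TSD pair bordering the interior segment with both
#' copies adjacent to subfamily-Y ends. Exactly one TSD pair found gives
#' "partial"; otherwise "negative".
#'
#' @param genome named character vector of contigs.
#' @param chimeras list of exactly two chimera calls (from [detect_chimera()])
#'   flanking an interior segment, upstream first.
#' @param tsd_args list of arguments passed to [detect_tsd()] /
#'   the inner-TSD search (e.g. `min_len`).
#' @return a `circular_signature_call`: list with `verdict`
#'   ("positive"/"partial"/"negative"), `outer_tsd`, `inner_tsd`,
#'   `reciprocal`, `outer_subfamily`, `inner_subfamily`, `locus`, `notes`.
#' @export
detect_circular_signature <- function(genome, chimeras, tsd_args = list()) {
  if (length(chimeras) != 2L) stop("not a candidate cassette: need exactly 2 flanking chimeras")
  up <- chimeras[[1]]; down <- chimeras[[2]]
  if (up$interval$start > down$interval$start) { tmp <- up; up <- down; down <- tmp }
  notes <- character(0)
  ## subfamily order along the genome (minus-strand elements are segmented in
  ## consensus orientation; flip them back so adjacency is physical)
  genome_order <- function(x)
    if (identical(x$interval$strand, "-")) rev(x$order) else x$order
  ord_up <- genome_order(up); ord_dn <- genome_order(down)
  reciprocal <- length(ord_up) == 2L && length(ord_dn) == 2L &&
    identical(ord_up, rev(ord_dn))
  outer_sf <- ord_up[1]
  inner_sf <- ord_up[length(ord_up)]
  if (!reciprocal) notes <- c(notes, "subfamily orders not reciprocal")
  contig <- up$interval$contig_id
  cassette <- list(contig_id = contig, start = up$interval$start,
                   end = down$interval$end)
  outer <- do.call(detect_tsd, c(list(genome = genome, insertion = cassette),
                                 tsd_args))
  inner <- do.call(detect_inner_tsd,
                   c(list(genome = genome, contig_id = contig,
                          start = up$interval$end,
                          end = down$interval$start), tsd_args))
  if (is.null(outer)) notes <- c(notes, "no outer TSD pair")
  if (is.null(inner)) notes <- c(notes, "no inner TSD pair")
  verdict <- if (reciprocal && !is.null(outer) && !is.null(inner)) "positive"
  else if (reciprocal && (!is.null(outer) || !is.null(inner))) "partial"
  else "negative"
  structure(list(verdict = verdict, outer_tsd = outer, inner_tsd = inner,
                 reciprocal = reciprocal, outer_subfamily = outer_sf,
                 inner_subfamily = inner_sf,
                 locus = interval(contig, cassette$start, cassette$end),
                 notes = notes),
            class = "circular_signature_call")
}
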