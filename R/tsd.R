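## Target-site duplication detection, breakpoint junction characterization,
## breakpoint clustering, and the repeat-overlap census.

#' Detect a target-site duplication flanking an insertion
#'
#' Searches `max_window` bp on each side of the insertion for the
#' highest-scoring pair of near-identical substrings, one ending at (or within
#' `max_offset` of) the insertion 5' edge and one starting at/near the 3'
#' edge. Score order: longest, then fewest mismatches, then closest to the
#' junction (TSDs are junction-adjacent by mechanism).
#'
#' @param genome named character vector of contigs.
#' @param insertion list/interval with `contig_id`, `start`, `end`
#'   (0-based half-open span of the inserted sequence).
#' @param max_window flank search window (bp).
#' @param min_len minimum reported TSD length.
#' @param max_mismatch_frac maximum mismatches as a fraction of TSD length.
#' @param max_offset how far a TSD copy may sit from the insertion edge.
#' @param back_offset how far BEFORE the nominal 3' edge the right TSD copy
#'   may begin (default 0). A TSD following a polyA tail is ambiguous when
#'   it starts with adenines — those bases are absorbed into the apparent
#'   polyA run — so callers that delimit the insertion by the polyA end pass
#'   the trailing A-run length here.
#' @return a `tsd_call` (list with `left`, `right` intervals, `length`,
#'   `mismatches`) or `NULL` when no pair of length >= `min_len` qualifies.
#' @export
detect_tsd <- function(genome, insertion, max_window = 100L, min_len = 5L,
                       max_mismatch_frac = 0.2, max_offset = 10L,
                       back_offset = 0L) {
  s <- genome[[insertion$contig_id]]
  n <- nchar(s)
  if (insertion$start <= 0L || insertion$end >= n)
    stop("insertion at contig edge: no flank to search")
  back <- min(back_offset, insertion$end - insertion$start)
  wl <- min(max_window, insertion$start)
  wr <- min(max_window + back, n - insertion$end + back)
  left <- substr(s, insertion$start - wl + 1L, insertion$start)  # ends at 5' edge
  right <- substr(s, insertion$end - back + 1L,
                  insertion$end - back + wr)                     # 3' edge - back
  lch <- seq_chars(left); rch <- seq_chars(right)
  best <- NULL
  max_l <- min(wl, wr)
  for (l in seq(max_l, min_len)) {
    for (o1 in 0:min(max_offset, wl - l)) {
      a <- lch[seq(wl - o1 - l + 1L, wl - o1)]
      for (o2 in 0:min(max_offset + back, wr - l)) {
        mm <- sum(a != rch[seq(o2 + 1L, o2 + l)])
        if (mm > floor(max_mismatch_frac * l)) next
        dist <- o1 + abs(o2 - back)
        cand <- list(l = l, mm = mm, off = dist, o1 = o1, o2 = o2 - back)
        if (is.null(best) || cand$l > best$l ||
            (cand$l == best$l && (cand$mm < best$mm ||
             (cand$mm == best$mm && cand$off < best$off)))) best <- cand
      }
    }
    if (!is.null(best) && best$l == l) break  # longer l already exhausted
  }
  if (is.null(best)) return(NULL)
  structure(list(
    left = interval(insertion$contig_id,
                    insertion$start - best$o1 - best$l, insertion$start - best$o1),
    right = interval(insertion$contig_id,
                     insertion$end + best$o2, insertion$end + best$o2 + best$l),
    length = best$l, mismatches = best$mm), class = "tsd_call")
}

#' Characterize a rearrangement junction against its two donors
#'
#' `left_donor_seq` is the source sequence aligned at the LEFT end of
#' `observed_junction_seq` (it extends through and past the breakpoint in its
#' source locus); `right_donor_seq` is aligned at the RIGHT end and extends
#' back past the breakpoint. With k the longest common prefix of observed and
#' left donor and r the longest common suffix of observed and right donor:
#' microhomology = k + r - len(observed) when non-negative; otherwise the
#' unattributable interior becomes `inserted_seq`. Interior bases mappable to
#' two or more of `other_donors` mark the junction complex.
#'
#' @param left_donor_seq,right_donor_seq donor sequences (see above).
#' @param observed_junction_seq sequence of the junction region as emitted.
#' @param other_donors optional character vector of third-party loci used to
#'   attribute inserted fragments.
#' @param min_fragment minimum exact match to attribute a fragment.
#' @return a `junction_call`: list with `microhomology_len`, `inserted_seq`,
#'   `complexity` ("simple"/"complex"), `breakpoint_left`, `breakpoint_right`
#'   (0-based offsets in the observed string bracketing the transition).
#' @export
characterize_junction <- function(left_donor_seq, right_donor_seq,
                                  observed_junction_seq,
                                  other_donors = character(0),
                                  min_fragment = 8L) {
  obs <- observed_junction_seq
  k <- common_prefix_len(obs, left_donor_seq)
  r <- common_suffix_len(obs, right_donor_seq)
  if (k == 0L || r == 0L)
    stop("donors not found at the ends of the observed junction string")
  n <- nchar(obs)
  mh <- k + r - n
  if (mh >= 0L) {
    call <- list(microhomology_len = mh, inserted_seq = "",
                 breakpoint_left = n - r, breakpoint_right = k)
  } else {
    ins <- substr(obs, k + 1L, n - r)
    call <- list(microhomology_len = 0L, inserted_seq = ins,
                 breakpoint_left = k, breakpoint_right = n - r)
  }
  hit_donors <- 0L
  if (nzchar(call$inserted_seq) && length(other_donors) &&
      nchar(call$inserted_seq) >= min_fragment) {
    frag <- call$inserted_seq
    for (d in other_donors) {
      pieces <- substring(frag, seq_len(max(1L, nchar(frag) - min_fragment + 1L)),
                          pmin(nchar(frag),
                               seq_len(max(1L, nchar(frag) - min_fragment + 1L)) +
                                 min_fragment - 1L))
      if (any(vapply(unique(pieces[nchar(pieces) >= min_fragment]),
                     function(p) grepl(p, d, fixed = TRUE) ||
                       grepl(p, revcomp(d), fixed = TRUE), logical(1))))
        hit_donors <- hit_donors + 1L
    }
  }
  call$complexity <- if (hit_donors >= 2L) "complex" else "simple"
  structure(call, class = "junction_call")
}

#' Cluster duplication-copy breakpoints into independent sites
#'
#' Single-linkage clustering of one side's breakpoint coordinates (ancestral
#' coordinate system) at the given tolerance; the cluster coordinate is the
#' median of its members.
#'
#' @param copies data.frame with columns `name`, `bp5`, `bp3` (ancestral
#'   coordinates; NA when a copy lacks a breakpoint on a side).
#' @param side `"5"` or `"3"`.
#' @param tolerance_bp single-linkage gap tolerance (default 20).
#' @return a `breakpoint_census`: list with `side`, `clusters` (data.frame
#'   `coord`, `n`, `members`), `n_skipped`.
#' @export
cluster_breakpoints <- function(copies, side = c("5", "3"), tolerance_bp = 20L) {
  side <- match.arg(side)
  bp <- if (side == "5") copies$bp5 else copies$bp3
  names(bp) <- copies$name
  skipped <- names(bp)[is.na(bp)]
  if (length(skipped))
    warning("copies without a ", side, "' breakpoint skipped: ",
            paste(skipped, collapse = ", "))
  bp <- bp[!is.na(bp)]
  if (length(bp) == 0L)
    return(structure(list(side = side,
                          clusters = data.frame(coord = numeric(0), n = integer(0),
                                                members = character(0)),
                          n_skipped = length(skipped)),
                     class = "breakpoint_census"))
  o <- order(bp, names(bp))
  bp <- bp[o]
  cl <- cumsum(c(1L, diff(bp) > tolerance_bp))
  clusters <- do.call(rbind, lapply(split(seq_along(bp), cl), function(ix)
    data.frame(coord = stats::median(bp[ix]), n = length(ix),
               members = paste(names(bp)[ix], collapse = ","),
               stringsAsFactors = FALSE)))
  rownames(clusters) <- NULL
  structure(list(side = side, clusters = clusters, n_skipped = length(skipped)),
            class = "breakpoint_census")
}

#' Repeat-overlap census of independent breakpoints
#'
#' Assigns each clustered breakpoint the family of the annotation containing
#' it (point-in-interval on half-open intervals of the ancestral coordinate
#' system), or "none", and counts per class.
#'
#' @param census a `breakpoint_census`.
#' @param annotations annotation data.frame on the ancestral contig.
#' @param ancestral_contig restrict annotations to this contig id (optional).
#' @return named integer vector of counts per class (including "none").
#' @export
repeat_overlap_census <- function(census, annotations, ancestral_contig = NULL) {
  if (!is.null(ancestral_contig))
    annotations <- annotations[annotations$contig_id == ancestral_contig, ,
                               drop = FALSE]
  classes <- vapply(census$clusters$coord, function(x) {
    hit <- which(annotations$start <= x & x < annotations$end)
    if (length(hit)) annotations$family[hit[1]] else "none"
  }, character(1))
  tab <- table(classes)
  stats::setNames(as.integer(tab), names(tab))
}
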