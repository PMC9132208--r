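## Scanner for insertions flanked by large direct repeats.
##
## Semantics (shared with the brute-force oracle used in the tests): on each
## diagonal d of the contig-vs-itself comparison, the candidate pair is the
## maximum-scoring subarray of the match/mismatch vector (+1 match, -3
## mismatch; ties broken to the first end, then the first start), with both
## ends trimmed until their terminal 8 positions are all matches ("clean
## ends" — a hit never bleeds into flanking unique sequence, because 8
## consecutive chance matches have probability 4^-8-ish). The pair is
## reported if, after trimming, length >= min_len, identity >= min_identity,
## the copies do not overlap, and the insert between them is at most
## max_insert. One candidate per diagonal; overlapping hits across diagonals
## are merged to the best (identity, then length). The implementation visits
## only diagonals holding an exact seed_k-mer seed — any pair in the
## reportable regime contains one with near certainty.

MATCH_SCORE <- 1L
MISMATCH_SCORE <- -3L
CLEAN_END <- 8L

## maximum-scoring subarray of score vector v (first-maximum tie-break);
## returns c(a, b) 1-based or NULL if all-negative
max_scoring_subarray <- function(v) {
  S <- cumsum(v)
  S0 <- c(0, S[-length(S)])
  M <- cummin(S0)
  gain <- S - M
  b <- which.max(gain)
  if (gain[b] <= 0) return(NULL)
  a <- which(S0[seq_len(b)] == M[b])[1]
  c(a, b)
}

## trim interval ends until the terminal CLEAN_END positions are all matches
clean_trim <- function(eq, a, b) {
  k <- CLEAN_END
  while (b - a + 1L >= k && !all(eq[(b - k + 1L):b])) b <- b - 1L
  while (b - a + 1L >= k && !all(eq[a:(a + k - 1L)])) a <- a + 1L
  if (b - a + 1L < k) return(NULL)
  c(a, b)
}

## candidate pair on one diagonal; eq is the full match vector for offset d
diagonal_candidate <- function(eq, d, min_len, min_identity, max_insert) {
  v <- ifelse(eq, MATCH_SCORE, MISMATCH_SCORE)
  ab <- max_scoring_subarray(v)
  if (is.null(ab)) return(NULL)
  a <- ab[1]; b <- ab[2]
  if (b - a + 1L > d) b <- a + d - 1L     # copies must not overlap
  ab <- clean_trim(eq, a, b)
  if (is.null(ab)) return(NULL)
  a <- ab[1]; b <- ab[2]
  L <- b - a + 1L
  if (L < min_len) return(NULL)
  gap <- d - L
  if (gap < 0L || gap > max_insert) return(NULL)
  mism <- sum(!eq[a:b])
  identity <- 1 - mism / L
  if (identity < min_identity) return(NULL)
  list(a = a, b = b, d = d, L = L, identity = identity)
}

#' Find insertions flanked by large direct repeats in one contig
#'
#' Reports same-orientation repeat pairs of length >= `min_len` and identity
#' >= `min_identity` separated by an insert of at most `max_insert` bp
#' (see the semantics note in the source: one maximum-scoring, clean-ended
#' candidate per diagonal). Inverted repeats are never reported; N bases
#' never match, so masked regions cannot seed or extend a hit.
#'
#' @param contig_seq DNA string.
#' @param contig_id contig name for reported intervals.
#' @param min_len minimum repeat length (>= 1000, the SD regime).
#' @param min_identity minimum repeat identity (>= 0.9).
#' @param max_insert maximum insert length between the copies.
#' @param seed_k exact seed length.
#' @return list of `flank_hit` objects: `left_repeat`, `right_repeat`,
#'   `insert` intervals (0-based half-open), `repeat_length`, `identity`,
#'   `orientation` ("direct"), `junctions` (filled by the pipeline when
#'   donors are known), `predicted_nahr_product` (the single chimeric repeat
#'   copy left behind by NAHR deletion of the insert).
#' @export
find_direct_repeat_flanks <- function(contig_seq, contig_id = "contig",
                                      min_len = 1000L, min_identity = 0.9,
                                      max_insert = 50000L, seed_k = 16L) {
  stopifnot(min_len >= 1000L, min_identity >= 0.9)
  n <- nchar(contig_seq)
  if (n < 2L * min_len) return(list())
  ch <- seq_chars(contig_seq)
  valid <- ch %in% DNA_BASES
  starts <- seq_len(n - seed_k + 1L)
  kmers <- substring(contig_seq, starts, starts + seed_k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  dups <- unique(kmers[ok][duplicated(kmers[ok])])
  if (length(dups) == 0L) return(list())
  sel <- ok & kmers %in% dups
  grp <- split(starts[sel], kmers[sel])
  diags <- integer(0)
  for (pos in grp) {
    pos <- sort(pos)
    cmb <- utils::combn(pos, 2)
    diags <- c(diags, cmb[2, ] - cmb[1, ])
  }
  diags <- sort(unique(diags))
  ## feasibility: some L with max(min_len, d - max_insert) <= min(d, n - d)
  diags <- diags[pmax(min_len, diags - max_insert) <= pmin(diags, n - diags)]
  cands <- list()
  for (d in diags) {
    tmax <- n - d
    eq <- ch[seq_len(tmax)] == ch[seq_len(tmax) + d] &
      valid[seq_len(tmax)] & valid[seq_len(tmax) + d]
    cand <- diagonal_candidate(eq, d, min_len, min_identity, max_insert)
    if (!is.null(cand)) cands[[length(cands) + 1L]] <- cand
  }
  if (length(cands) == 0L) return(list())
  ## merge overlapping candidates across diagonals: best identity, then
  ## length, then leftmost, then smallest offset
  df <- do.call(rbind, lapply(cands, as.data.frame))
  df <- df[order(-df$identity, -df$L, df$a, df$d), , drop = FALSE]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    hi <- df[i, ]
    if (nrow(kept)) {
      clash <- (kept$a <= hi$a + hi$L - 1 & kept$a + kept$L - 1 >= hi$a) |
        (kept$a + kept$d <= hi$a + hi$d + hi$L - 1 &
           kept$a + kept$d + kept$L - 1 >= hi$a + hi$d)
      if (any(clash)) next
    }
    kept <- rbind(kept, hi)
  }
  lapply(seq_len(nrow(kept)), function(i) {
    h <- kept[i, ]
    left <- interval(contig_id, h$a - 1L, h$a - 1L + h$L)
    right <- interval(contig_id, h$a - 1L + h$d, h$a - 1L + h$d + h$L)
    lseq <- substr(contig_seq, left$start + 1L, left$end)
    rseq <- substr(contig_seq, right$start + 1L, right$end)
    half <- h$L %/% 2L
    structure(list(
      left_repeat = left, right_repeat = right,
      insert = interval(contig_id, left$end, right$start),
      repeat_length = h$L, identity = h$identity, orientation = "direct",
      junctions = list(),
      predicted_nahr_product = paste0(substr(lseq, 1, half),
                                      substr(rseq, half + 1L, h$L))),
      class = "flank_hit")
  })
}

#' Windowed genome scan for direct-repeat-flanked insertions
#'
#' Applies [find_direct_repeat_flanks()] within nonoverlapping windows
#' (default 0.5 Mb, the classical screening granularity), each extended by a
#' seam margin of `max_insert + 2 * min_len` so structures straddling a seam
#' are still seen; hits are deduplicated across seams by coordinate
#' identity. When `sd_intervals` is given the scan is restricted to windows
#' overlapping their neighbourhoods.
#'
#' @param genome named character vector of contigs.
#' @param sd_intervals optional data.frame (`contig_id`, `start`, `end`)
#'   restricting the scan.
#' @param window_size window width (default 500,000).
#' @param min_len,max_insert as in [find_direct_repeat_flanks()].
#' @param ... passed to [find_direct_repeat_flanks()].
#' @return list of `flank_hit` objects in genome coordinates.
#' @export
scan_windows <- function(genome, sd_intervals = NULL, window_size = 500000L,
                         min_len = 1000L, max_insert = 50000L, ...) {
  stopifnot(window_size > 2L * min_len)
  margin <- max_insert + 2L * min_len
  out <- list()
  seen <- character(0)
  for (cid in names(genome)) {
    n <- nchar(genome[[cid]])
    win_starts <- seq(0L, max(0L, n - 1L), by = window_size)
    for (ws in win_starts) {
      we <- min(n, ws + window_size + margin)
      if (!is.null(sd_intervals)) {
        sd <- sd_intervals[sd_intervals$contig_id == cid, , drop = FALSE]
        if (!nrow(sd) || !any(sd$start < we + margin & sd$end > ws - margin))
          next
      }
      sub <- substr(genome[[cid]], ws + 1L, we)
      hits <- find_direct_repeat_flanks(sub, contig_id = cid,
                                        min_len = min_len,
                                        max_insert = max_insert, ...)
      for (h in hits) {
        for (f in c("left_repeat", "right_repeat", "insert")) {
          h[[f]]$start <- h[[f]]$start + ws
          h[[f]]$end <- h[[f]]$end + ws
        }
        key <- paste(cid, h$left_repeat$start, h$right_repeat$end)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- h
      }
    }
  }
  out
}
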