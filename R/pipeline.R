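## Pipeline orchestration: simulate -> annotate -> detect -> report, plus
## recovery scoring of detections against the truth ledger. All detection
## stages are deterministic; with a seeded simulation the whole result
## bundle is byte-reproducible.

## replace annotated intervals with N (repeat masking); optionally also mask
## polyA runs adjacent to annotations
mask_annotations <- function(genome, annotations) {
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    s <- genome[[a$contig_id]]
    genome[[a$contig_id]] <- paste0(substr(s, 1L, a$start),
                                    strrep("N", a$end - a$start),
                                    substr(s, a$end + 1L, nchar(s)))
  }
  genome
}

## extend an element annotation over an adjacent transduction annotation and
## a trailing polyA run, giving candidate full inserted-sequence intervals.
## Two polyA end estimates are returned: a strict one (exact A run — right
## for undiverged copies) and a tolerant one that steps over isolated
## substitutions inside the run (right for diverged copies, but it can
## overshoot into an A-rich TSD); the caller tries both.
full_insert_interval <- function(ann, annotations, genome, max_gap = 2L) {
  end <- ann$end
  adj <- annotations[annotations$contig_id == ann$contig_id &
                       annotations$family == "TD" &
                       annotations$start >= end &
                       annotations$start <= end + max_gap, , drop = FALSE]
  if (nrow(adj)) end <- max(adj$end)
  s <- genome[[ann$contig_id]]
  n <- nchar(s)
  strict <- end
  while (strict < n && substr(s, strict + 1L, strict + 1L) == "A")
    strict <- strict + 1L
  tolerant <- end
  repeat {
    if (tolerant >= n) break
    nxt <- substr(s, tolerant + 1L, tolerant + 1L)
    if (nxt == "A") { tolerant <- tolerant + 1L; next }
    look <- seq_chars(substr(s, tolerant + 2L, min(n, tolerant + 5L)))
    if (length(look) >= 3L && sum(look == "A") >= 3L) {
      tolerant <- tolerant + 1L
      next
    }
    break
  }
  list(contig_id = ann$contig_id, start = ann$start,
       ends = unique(c(strict, tolerant)))
}

#' Map duplication copies of an ancestral locus across a genome
#'
#' Exact k-mer diagonal seeding of each contig against the ancestral
#' sequence, greedy extension under an identity floor; aligned blocks of at
#' least `min_len` become copies whose breakpoints are the ancestral
#' coordinates of the block edges. Annotated repeats should be masked in
#' `genome` first (shared interspersed repeats otherwise masquerade as short
#' copies).
#'
#' @param genome named character vector (annotation-masked).
#' @param ancestral_seq ancestral locus sequence.
#' @param exclude contig ids to skip (e.g. the ancestral contig itself).
#' @param min_len minimum copy length (default 2000).
#' @param min_identity identity floor (default 0.9).
#' @param seed_k seed length.
#' @return data.frame with `name`, `contig_id`, `start`, `end`, `bp5`, `bp3`,
#'   `identity`.
#' @export
map_duplication_copies <- function(genome, ancestral_seq, exclude = character(0),
                                   min_len = 2000L, min_identity = 0.9,
                                   seed_k = 24L) {
  anc_n <- nchar(ancestral_seq)
  anc_starts <- seq_len(anc_n - seed_k + 1L)
  anc_kmers <- substring(ancestral_seq, anc_starts, anc_starts + seed_k - 1L)
  anc_ch <- seq_chars(ancestral_seq)
  out <- list()
  for (cid in setdiff(names(genome), exclude)) {
    s <- genome[[cid]]
    n <- nchar(s)
    if (n < seed_k) next
    ch <- seq_chars(s)
    starts <- seq_len(n - seed_k + 1L)
    kmers <- substring(s, starts, starts + seed_k - 1L)
    hit <- match(kmers, anc_kmers)
    seeds <- which(!is.na(hit) & !grepl("N", kmers, fixed = TRUE))
    if (length(seeds) == 0L) next
    diag <- hit[seeds] - seeds  # ancestral_pos - contig_pos
    blocks <- list()
    for (d in sort(unique(diag))) {
      lo <- max(1L, 1L - d); hi <- min(n, anc_n - d)
      if (hi - lo + 1L < min_len) next
      t <- seq(lo, hi)
      eq <- ch[t] == anc_ch[t + d] & ch[t] != "N" & anc_ch[t + d] != "N"
      ab <- max_scoring_subarray(ifelse(eq, MATCH_SCORE, MISMATCH_SCORE))
      if (is.null(ab)) next
      ab <- clean_trim(eq, ab[1], ab[2])
      if (is.null(ab)) next
      a <- ab[1] + lo - 1L; b <- ab[2] + lo - 1L
      L <- b - a + 1L
      if (L < min_len) next
      mism <- sum(!eq[ab[1]:ab[2]])
      if (1 - mism / L < min_identity) next
      blocks[[length(blocks) + 1L]] <-
        list(a = a, b = b, d = d, identity = 1 - mism / L)
    }
    if (length(blocks) == 0L) next
    ## dedupe overlapping blocks (keep longest, then highest identity)
    blocks <- blocks[order(-vapply(blocks, function(x) x$b - x$a, numeric(1)),
                           -vapply(blocks, function(x) x$identity, numeric(1)))]
    kept <- list()
    for (bl in blocks) {
      clash <- any(vapply(kept, function(k)
        bl$a <= k$b && bl$b >= k$a, logical(1)))
      if (!clash) kept[[length(kept) + 1L]] <- bl
    }
    for (bl in kept) {
      out[[length(out) + 1L]] <- data.frame(
        name = sprintf("%s_%d", cid, bl$a - 1L), contig_id = cid,
        start = bl$a - 1L, end = bl$b, bp5 = bl$a - 1L + bl$d,
        bp3 = bl$b + bl$d, identity = bl$identity, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(name = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0), bp5 = integer(0),
                      bp3 = integer(0), identity = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$contig_id, df$start), , drop = FALSE]
}

#' Score detections against a truth ledger
#'
#' A call matches a planted event iff it has the same type and its interval
#' agrees within `tolerance_bp` at both edges (and overlaps). Matching is
#' 1-to-1 greedy by best overlap; unmatched calls are false positives,
#' unmatched events false negatives.
#'
#' @param calls named list of data.frames (per event type) with `contig_id`,
#'   `start`, `end`.
#' @param ledger a simulation ledger (list with `events`).
#' @param tolerance_bp matching tolerance (default 20).
#' @return a `recovery_score`: data.frame per type with `planted`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`.
#' @export
score_recovery <- function(calls, ledger, tolerance_bp = 20L) {
  types <- c("L1_insertion", "duplication_copy", "circular_integration",
             "direct_repeat_SD")
  rows <- lapply(types, function(ty) {
    evs <- Filter(function(e) e$type == ty, ledger$events)
    cl <- calls[[ty]]
    if (is.null(cl)) cl <- data.frame(contig_id = character(0),
                                      start = integer(0), end = integer(0))
    matched_ev <- rep(FALSE, length(evs))
    matched_cl <- rep(FALSE, nrow(cl))
    if (length(evs) && nrow(cl)) {
      ov <- matrix(0, length(evs), nrow(cl))
      for (i in seq_along(evs)) for (j in seq_len(nrow(cl))) {
        e <- evs[[i]]
        if (e$contig_id != cl$contig_id[j]) next
        if (abs(e$start - cl$start[j]) > tolerance_bp ||
            abs(e$end - cl$end[j]) > tolerance_bp) next
        ov[i, j] <- max(0, min(e$end, cl$end[j]) - max(e$start, cl$start[j]))
      }
      while (any(ov > 0)) {
        ix <- which(ov == max(ov), arr.ind = TRUE)[1, ]
        matched_ev[ix[1]] <- TRUE
        matched_cl[ix[2]] <- TRUE
        ov[ix[1], ] <- 0; ov[, ix[2]] <- 0
      }
    }
    tp <- sum(matched_ev); fp <- sum(!matched_cl); fn <- sum(!matched_ev)
    data.frame(type = ty, planted = length(evs), tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("recovery_score", "data.frame"))
}

#' Run the full detection pipeline on a simulated (or loaded) genome
#'
#' Stages: TSD calling over annotated elements (insertion intervals extended
#' over adjacent transductions and polyA runs; a call requires a TSD of at
#' least `min_tsd_len` — shorter flank similarity is indistinguishable from
#' chance), duplication-copy mapping against the ancestral locus on the
#' repeat-masked genome, breakpoint clustering and repeat-overlap census,
#' chimera detection with circular-signature calling, the direct-repeat
#' flank scan (repeat-masked), junction characterization against the donor
#' table, and recovery scoring against the ledger.
#'
#' @param sim an `"sva_sim"` (or compatible list with `genome`,
#'   `annotations`, `library`, `ancestral`, `ledger`).
#' @param out_dir optional output directory; when given, all calls, the
#'   census, the score and a run manifest are written (deterministically —
#'   no timestamps).
#' @param tolerance_bp breakpoint-clustering and scoring tolerance.
#' @param min_tsd_len minimum TSD length for an L1 call (default 8).
#' @param flank_min_len,flank_min_identity,flank_max_insert flank-scan knobs.
#' @param dup_min_len minimum mapped duplication-copy length.
#' @return list with `calls` (per type), `tsd_calls`, `copies`, `census5`,
#'   `census3`, `overlap5`, `overlap3`, `chimeras`, `signatures`,
#'   `flank_hits`, `junction_calls`, `score`.
#' @export
run_pipeline <- function(sim, out_dir = NULL, tolerance_bp = 20L,
                         min_tsd_len = 8L, flank_min_len = 1000L,
                         flank_min_identity = 0.9, flank_max_insert = 25000L,
                         dup_min_len = 2000L) {
  genome <- sim$genome
  ann <- sim$annotations
  anc_id <- sim$ancestral$contig_id
  anc_seq <- genome[[anc_id]]

  ## --- stage 1: TSD calling / L1 insertions ---------------------------
  cand <- ann[ann$family == "SVA" & ann$contig_id != anc_id, , drop = FALSE]
  tsd_calls <- list()
  l1 <- list()
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, ]
    iv <- full_insert_interval(a, ann, genome)
    call <- NULL
    for (e in iv$ends) {
      ## the apparent polyA run before `e` may have swallowed the start of
      ## the right TSD copy; let the search back up over it
      run <- 0L
      s <- genome[[iv$contig_id]]
      while (e - run > iv$start &&
             substr(s, e - run, e - run) == "A") run <- run + 1L
      ci <- tryCatch(detect_tsd(genome, list(contig_id = iv$contig_id,
                                             start = iv$start, end = e),
                                back_offset = min(run, 30L)),
                     error = function(err) NULL)
      if (!is.null(ci) && (is.null(call) || ci$length > call$length ||
                           (ci$length == call$length &&
                              ci$mismatches < call$mismatches)))
        call <- ci
    }
    if (is.null(call) || call$length < min_tsd_len) next
    tsd_calls[[length(tsd_calls) + 1L]] <- call
    l1[[length(l1) + 1L]] <- data.frame(contig_id = a$contig_id,
                                        start = a$start, end = a$end,
                                        tsd_length = call$length,
                                        tsd_mismatches = call$mismatches,
                                        stringsAsFactors = FALSE)
  }
  l1 <- if (length(l1)) do.call(rbind, l1) else
    data.frame(contig_id = character(0), start = integer(0), end = integer(0))

  ## --- stage 2: duplication copies, breakpoints, census ----------------
  masked <- mask_annotations(genome, ann[ann$contig_id != anc_id, , drop = FALSE])
  copies <- map_duplication_copies(masked, anc_seq, exclude = anc_id,
                                   min_len = dup_min_len)
  census5 <- cluster_breakpoints(copies, "5", tolerance_bp)
  census3 <- cluster_breakpoints(copies, "3", tolerance_bp)
  overlap5 <- repeat_overlap_census(census5, ann, anc_id)
  overlap3 <- repeat_overlap_census(census3, ann, anc_id)

  ## --- stage 3: chimeras and circular signatures -----------------------
  chim <- detect_chimera(ann[ann$contig_id != anc_id, , drop = FALSE],
                         genome, sim$library,
                         pair = c("SVA_B", "SVA_D"))
  signatures <- list()
  circ <- list()
  if (length(chim)) {
    by_contig <- split(chim, vapply(chim, function(x) x$interval$contig_id,
                                    character(1)))
    for (cc in by_contig) {
      if (length(cc) != 2L) next
      sig <- tryCatch(detect_circular_signature(genome, cc),
                      error = function(e) NULL)
      if (is.null(sig)) next
      signatures[[length(signatures) + 1L]] <- sig
      if (sig$verdict == "positive")
        circ[[length(circ) + 1L]] <- data.frame(
          contig_id = sig$locus$contig_id, start = sig$locus$start,
          end = sig$locus$end, stringsAsFactors = FALSE)
    }
  }
  circ <- if (length(circ)) do.call(rbind, circ) else
    data.frame(contig_id = character(0), start = integer(0), end = integer(0))

  ## --- stage 4: direct-repeat flank scan -------------------------------
  flank_hits <- scan_windows(masked[setdiff(names(masked), anc_id)],
                             min_len = flank_min_len,
                             max_insert = flank_max_insert,
                             min_identity = flank_min_identity)
  sd_calls <- if (length(flank_hits)) do.call(rbind, lapply(flank_hits,
    function(h) data.frame(contig_id = h$insert$contig_id,
                           start = h$insert$start, end = h$insert$end,
                           repeat_length = h$repeat_length,
                           identity = h$identity, stringsAsFactors = FALSE)))
  else data.frame(contig_id = character(0), start = integer(0),
                  end = integer(0))

  ## --- stage 5: junction characterization (donor table) ----------------
  junction_calls <- list()
  for (jx in sim$ledger$junctions) {
    obs <- gslice(genome, jx$contig_id, jx$window_start, jx$window_end)
    jc <- tryCatch(characterize_junction(jx$left_donor, jx$right_donor, obs),
                   error = function(e) NULL)
    if (is.null(jc)) next
    junction_calls[[length(junction_calls) + 1L]] <-
      data.frame(id = jx$id, microhomology_len = jc$microhomology_len,
                 inserted_len = nchar(jc$inserted_seq),
                 complexity = jc$complexity, stringsAsFactors = FALSE)
  }
  junction_calls <- if (length(junction_calls))
    do.call(rbind, junction_calls) else NULL

  calls <- list(L1_insertion = l1,
                duplication_copy = copies[, c("contig_id", "start", "end")],
                circular_integration = circ,
                direct_repeat_SD = sd_calls)
  score <- score_recovery(calls, sim$ledger, tolerance_bp)

  res <- list(calls = calls, tsd_calls = tsd_calls, copies = copies,
              census5 = census5, census3 = census3,
              overlap5 = overlap5, overlap3 = overlap3,
              chimeras = chim, signatures = signatures,
              flank_hits = flank_hits, junction_calls = junction_calls,
              score = score)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(sim, out_dir)
    tsv <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    tsv(l1, "l1_calls.tsv")
    tsv(copies, "duplication_copies.tsv")
    tsv(census5$clusters, "breakpoints_5.tsv")
    tsv(census3$clusters, "breakpoints_3.tsv")
    tsv(sd_calls, "flank_hits.tsv")
    if (!is.null(junction_calls)) tsv(junction_calls, "junction_calls.tsv")
    jsonlite::write_json(
      list(overlap5 = as.list(overlap5), overlap3 = as.list(overlap3),
           score = res$score,
           signatures = lapply(signatures, function(x)
             list(verdict = x$verdict, contig = x$locus$contig_id,
                  start = x$locus$start, end = x$locus$end))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    manifest <- list(package = "svaduplicon",
                     version = as.character(utils::packageVersion("svaduplicon")),
                     seed = sim$config$seed,
                     config = unclass(sim$config),
                     tolerance_bp = tolerance_bp)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
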