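## Diagnostic-site partitioning, recombination-interval bracketing, the
## split-tree incongruence test, and the gene-conversion concordance control.
##
## The inference consumed from the trees is topological, so the maximum
## likelihood trees of the original analyses are approximated by
## neighbor-joining under K2P; concordance is decided on group-monophyly
## patterns, which are robust to unresolved nodes.

#' Partition alignment columns into diagnostic-site classes
#'
#' For each column the derived state is defined relative to the outgroup.
#' A column is "A_specific" ("B_specific") if every member of that group
#' carries one common derived state and no member of the other group carries
#' any derived state; "shared_derived" if at least one member of each group
#' shares the same derived state; otherwise "uninformative". Columns where
#' the outgroup is gapped are skipped and counted. Ungapped positions are
#' reported on the reference row (first group-A row by default).
#'
#' @param aln an `"msa"` with exactly two in-groups and an outgroup.
#' @param focal_group label treated as group A (default: first sorted label).
#' @param ref_row row id whose ungapped coordinates position the classes
#'   (default: first group-A row).
#' @param tol_missing_frac fraction of group members allowed to be gapped in
#'   a column before it is declared uninformative (default 0).
#' @param share_min_frac minimum fraction of EACH group that must carry the
#'   common derived state for a shared-derived call (default 0.5, "most/all
#'   of the copies" — a single parallel substitution in one member of the
#'   other group is homoplasy, not shared ancestry).
#' @return a `site_partition`: list with `sites` (data.frame `col`, `pos`
#'   ungapped 0-based on ref row, `class`), `n_skipped_outgroup_gap`,
#'   `groups`, `focal_group`.
#' @export
partition_diagnostic_sites <- function(aln, focal_group = NULL, ref_row = NULL,
                                       tol_missing_frac = 0,
                                       share_min_frac = 0.5) {
  stopifnot(inherits(aln, "msa"), !is.null(aln$outgroup_id))
  ingroup <- setdiff(names(aln$rows), aln$outgroup_id)
  glab <- aln$groups[ingroup]
  labs <- sort(unique(glab))
  if (length(labs) != 2L) stop("exactly two in-groups required, got: ",
                               paste(labs, collapse = ", "))
  A <- if (is.null(focal_group)) labs[1] else focal_group
  B <- setdiff(labs, A)
  if (is.null(ref_row)) ref_row <- ingroup[glab == A][1]
  m <- do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  og <- m[aln$outgroup_id, ]
  refmap <- ungapped_map(aln$rows[[ref_row]])
  a_rows <- ingroup[glab == A]; b_rows <- ingroup[glab == B]
  classify <- function(col) {
    anc <- og[col]
    if (!(anc %in% DNA_BASES)) return("outgroup_gap")
    av <- m[a_rows, col]; bv <- m[b_rows, col]
    a_ok <- av %in% DNA_BASES; b_ok <- bv %in% DNA_BASES
    if (mean(!a_ok) > tol_missing_frac || mean(!b_ok) > tol_missing_frac)
      return("uninformative")
    av <- av[a_ok]; bv <- bv[b_ok]
    a_der <- unique(av[av != anc]); b_der <- unique(bv[bv != anc])
    both <- intersect(a_der, b_der)
    for (st in both) {
      if (mean(av == st) >= share_min_frac && mean(bv == st) >= share_min_frac)
        return("shared_derived")
    }
    if (length(both) > 0) return("uninformative")
    if (length(a_der) == 1 && all(av == a_der) && length(b_der) == 0)
      return("A_specific")
    if (length(b_der) == 1 && all(bv == b_der) && length(a_der) == 0)
      return("B_specific")
    "uninformative"
  }
  cls <- vapply(seq_len(ncol(m)), classify, character(1))
  skipped <- sum(cls == "outgroup_gap")
  keep <- cls != "outgroup_gap"
  sites <- data.frame(col = which(keep), pos = refmap[keep], class = cls[keep],
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, n_skipped_outgroup_gap = skipped,
                 groups = stats::setNames(glab, ingroup),
                 focal_group = A, other_group = B, ref_row = ref_row),
            class = "site_partition")
}

#' Bracket the recombination interval from a site partition
#'
#' The interval runs from the last focal-group-specific substitution that
#' precedes the first shared-derived substitution, to that first
#' shared-derived substitution (ungapped reference coordinates);
#' length = end - start.
#'
#' @param partition a `site_partition`.
#' @return list with `start`, `end`, `length`, `found` (FALSE with all-NA
#'   coordinates when the required ordering does not exist — not an error).
#' @export
locate_recombination_interval <- function(partition) {
  s <- partition$sites
  shared <- s$pos[s$class == "shared_derived"]
  aspec <- s$pos[s$class == "A_specific"]
  if (length(shared) == 0L || length(aspec) == 0L)
    return(list(start = NA_integer_, end = NA_integer_,
                length = NA_integer_, found = FALSE))
  end <- min(shared)
  before <- aspec[aspec < end]
  if (length(before) == 0L)
    return(list(start = NA_integer_, end = NA_integer_,
                length = NA_integer_, found = FALSE))
  start <- max(before)
  list(start = start, end = end, length = end - start, found = TRUE)
}

## monophyly of a set of tips on an unrooted tree rooted at the outgroup
group_monophyletic <- function(tree, tips, outgroup) {
  if (length(tips) <= 1L) return(TRUE)
  rooted <- tryCatch(ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
                     error = function(e) NULL)
  if (is.null(rooted)) return(NA)
  ape::is.monophyletic(rooted, tips)
}

## columns of a gapped matrix restricted by ungapped ref positions
split_columns <- function(aln, split_point, ref_row) {
  refmap <- ungapped_map(aln$rows[[ref_row]])
  ref_ch <- seq_chars(aln$rows[[ref_row]])
  ## a column belongs left if its reference coordinate < split_point
  pos <- refmap
  list(left = which(pos < split_point), right = which(pos >= split_point))
}

subset_msa_cols <- function(aln, cols) {
  m <- do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
  rows <- stats::setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                          names(aln$rows))
  msa(rows, aln$groups, aln$outgroup_id)
}

count_variable_columns <- function(rows) {
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  sum(apply(m, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    length(unique(col)) >= 2
  }))
}

#' Split-tree incongruence test
#'
#' Builds K2P/NJ trees on the alignment columns left and right of
#' `split_point` (ungapped coordinates of the reference row; default the
#' midpoint of the recombination interval). The verdict is "discordant" iff
#' the group-monophyly pattern differs between the two trees; the RF distance
#' is reported as auxiliary evidence.
#'
#' @param aln an `"msa"` with two in-groups and an outgroup.
#' @param split_point ungapped reference coordinate; `NULL` to use the
#'   midpoint of [locate_recombination_interval()].
#' @param min_informative minimum variable columns required per side.
#' @param focal_group,ref_row passed to [partition_diagnostic_sites()].
#' @return a `split_test_result`: list with `tree5`, `tree3`, `rf`,
#'   `verdict`, `monophyly` (2x2 logical), `split_point`.
#' @export
split_tree_test <- function(aln, split_point = NULL, min_informative = 4L,
                            focal_group = NULL, ref_row = NULL) {
  part <- partition_diagnostic_sites(aln, focal_group, ref_row)
  if (is.null(split_point)) {
    iv <- locate_recombination_interval(part)
    if (!iv$found) stop("no recombination interval and no split_point given")
    split_point <- as.integer((iv$start + iv$end) / 2)
  }
  ref_row <- part$ref_row
  ungapped_len <- sum(seq_chars(aln$rows[[ref_row]]) != "-")
  if (split_point <= 0 || split_point >= ungapped_len)
    stop("split_point must lie strictly inside the ungapped element span")
  cols <- split_columns(aln, split_point, ref_row)
  halves <- lapply(cols, function(cc) subset_msa_cols(aln, cc))
  for (h in halves)
    if (count_variable_columns(h$rows) < min_informative)
      stop("segment too short")
  trees <- lapply(halves, function(h) nj_tree(k2p_matrix(h$rows)$d))
  glab <- part$groups
  groups <- list(A = names(glab)[glab == part$focal_group],
                 B = names(glab)[glab == part$other_group])
  mono <- sapply(trees, function(tr) c(
    A = group_monophyletic(tr, groups$A, aln$outgroup_id),
    B = group_monophyletic(tr, groups$B, aln$outgroup_id)))
  verdict <- if (identical(mono[, 1], mono[, 2])) "concordant" else "discordant"
  structure(list(tree5 = trees[[1]], tree3 = trees[[2]],
                 rf = rf_distance(trees[[1]], trees[[2]]),
                 verdict = verdict, monophyly = mono,
                 split_point = split_point),
            class = "split_test_result")
}

#' Gene-conversion concordance control over downstream segments
#'
#' Each segment's K2P/NJ tree is compared with a reference topology (the
#' 3'-element tree) on the group-monophyly pattern. The verdict is
#' "gene conversion not supported" iff every segment is concordant with the
#' reference; otherwise "gene conversion possible", with the discordant
#' segments flagged.
#'
#' @param aln_segments list of `"msa"` objects sharing taxa and groups.
#' @param reference_tree `"phylo"` reference (e.g. `tree3` of a
#'   [split_tree_test()]); `NULL` builds it from the last segment.
#' @return list with `verdict`, `per_segment` (data.frame `segment`,
#'   `concordant`), `reference_monophyly`.
#' @export
segment_concordance_test <- function(aln_segments, reference_tree = NULL) {
  stopifnot(length(aln_segments) >= 1)
  taxa <- lapply(aln_segments, function(a) sort(names(a$rows)))
  if (length(unique(vapply(taxa, paste, character(1), collapse = ","))) != 1L)
    stop("taxa mismatch across segments")
  if (length(aln_segments) < 2L)
    warning("single-segment control is weak")
  a1 <- aln_segments[[1]]
  glab <- a1$groups[setdiff(names(a1$rows), a1$outgroup_id)]
  labs <- sort(unique(glab))
  groups <- lapply(labs, function(l) names(glab)[glab == l])
  names(groups) <- labs
  if (is.null(reference_tree)) {
    last <- aln_segments[[length(aln_segments)]]
    reference_tree <- nj_tree(k2p_matrix(last$rows)$d)
  }
  ref_mono <- vapply(groups, function(g)
    group_monophyletic(reference_tree, g, a1$outgroup_id), logical(1))
  per <- vapply(seq_along(aln_segments), function(i) {
    tr <- nj_tree(k2p_matrix(aln_segments[[i]]$rows)$d)
    mono <- vapply(groups, function(g)
      group_monophyletic(tr, g, a1$outgroup_id), logical(1))
    identical(mono, ref_mono)
  }, logical(1))
  verdict <- if (all(per)) "gene conversion not supported" else
    "gene conversion possible"
  list(verdict = verdict,
       per_segment = data.frame(segment = seq_along(aln_segments),
                                concordant = per),
       reference_monophyly = ref_mono)
}
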