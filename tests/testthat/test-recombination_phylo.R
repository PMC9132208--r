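test_that("k2p_distance matches the closed form on the worked cases", {
  r <- k2p_distance("AAAA", "AAAA")
  expect_equal(c(r$d, r$P, r$Q), c(0, 0, 0))
  r1 <- k2p_distance("AAAA", "AGAA")   # one transition
  expect_equal(r1$P, 0.25)
  expect_equal(r1$Q, 0)
  expect_equal(r1$d, -0.5 * log(0.5), tolerance = 1e-12)
  r2 <- k2p_distance("AAAA", "ACAA")   # one transversion
  expect_equal(r2$Q, 0.25)
  expect_equal(r2$d, -0.5 * log(0.75) - 0.25 * log(0.5), tolerance = 1e-12)
  expect_error(k2p_distance("AAAA", "CCCC"), "saturation")
  expect_error(k2p_distance("----", "AAAA"), "non-gap")
})

test_that("k2p_distance equals the closed form on random defined pairs", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(50:200, 1)
    a <- chars(rand_seq(n))
    b <- a
    nm <- sample(0:floor(n / 5), 1)
    idx <- sample(n, nm)
    for (j in idx) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    ## independent recomputation of P and Q by explicit pair typing
    ts_pairs <- c("AG", "GA", "CT", "TC")
    pr <- paste0(a, b)
    P <- mean(pr %in% ts_pairs)
    Q <- mean(a != b & !(pr %in% ts_pairs))
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
      expect_error(k2p_distance(sa, sb), "saturation")
    } else {
      r <- k2p_distance(sa, sb)
      expect_equal(r$d, -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
                   tolerance = 1e-12)
      expect_gte(r$d, 0)
    }
  }
})

test_that("nj_tree handles the small closed-form cases", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 0.3)
  d3 <- matrix(2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d3) <- 0
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), c(1, 1, 1))
  ## additive 4-taxon case ((A:1,B:2):1,(C:3,D:1))
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  d4 <- ape::cophenetic.phylo(tr)
  t4 <- nj_tree(d4)
  expect_equal(rf_distance(t4, ape::unroot(tr)), 0)
  tip_len <- t4$edge.length[match(seq_along(t4$tip.label), t4$edge[, 2])]
  expect_equal(stats::setNames(tip_len, t4$tip.label)[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 3, D = 1))
  dm <- d4; dm[1, 2] <- NA
  expect_error(nj_tree(dm), "undefined")
})

test_that("nj reconstructs random additive trees exactly", {
  set.seed(32)
  for (i in 1:25) {
    ntaxa <- sample(6:10, 1)
    tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.1, 1))
    t2 <- nj_tree(ape::cophenetic.phylo(tr))
    expect_equal(rf_distance(t2, ape::unroot(tr)), 0)
  }
})

test_that("rf_distance counts symmetric bipartition differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "mismatch")
  ## symmetry + agreement with phangorn on random pairs
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    a <- ape::rtree(n); b <- ape::rtree(n)
    b$tip.label <- sample(a$tip.label)
    expect_equal(rf_distance(a, b), rf_distance(b, a))
    expect_equal(rf_distance(a, b),
                 as.integer(phangorn::RF.dist(ape::unroot(a), ape::unroot(b))))
  }
})

test_that("bootstrap_support behaves on degenerate and planted inputs", {
  rows <- c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT", d = "ACGTACGT")
  bs <- bootstrap_support(rows, n_replicates = 10, seed = 1)
  expect_length(bs$supports, 0)
  ## two clearly separated 4-taxon clades: central edge support >= 99
  set.seed(34)
  base <- rand_seq(400)
  mk <- function(muts) {
    ch <- chars(base)
    for (p in muts) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  clade_sites <- 1:20
  rows2 <- c(a1 = mk(c(clade_sites, 101)), a2 = mk(c(clade_sites, 102)),
             a3 = mk(c(clade_sites, 103)), a4 = mk(c(clade_sites, 104)),
             b1 = mk(201), b2 = mk(202), b3 = mk(203), b4 = mk(204))
  bs2 <- bootstrap_support(rows2, n_replicates = 1000, seed = 9)
  central <- "a1|a2|a3|a4"
  expect_true(central %in% names(bs2$supports))
  expect_gte(bs2$supports[[central]], 99)
  ## fixed seed => identical supports
  bs3 <- bootstrap_support(rows2, n_replicates = 1000, seed = 9)
  expect_identical(bs2$supports, bs3$supports)
  ## the documented default matches the published protocol
  expect_equal(eval(formals(bootstrap_support)$n_replicates), 10000L)
})

test_that("partition_diagnostic_sites classifies a hand-built alignment", {
  ##            1234567890
  rows <- c(A1 = "ACGTACGTAA",
            A2 = "ACGTACGTAA",
            B1 = "AGGTACGAAA",
            B2 = "AGGTACGAAA",
            OUT = "ACGTACGAAA")
  ## col 2: B-specific (G derived in both B, A rows ancestral C? no:
  ## outgroup C at col2 -> A rows carry C (ancestral), B rows carry G)
  ## col 8: A-specific (A rows T derived, B rows A ancestral)
  aln <- msa(rows, groups = c(A1 = "g16", A2 = "g16", B1 = "g13", B2 = "g13"),
             outgroup_id = "OUT")
  part <- partition_diagnostic_sites(aln, focal_group = "g16")
  cls <- stats::setNames(part$sites$class, part$sites$col)
  expect_identical(cls[["2"]], "B_specific")
  expect_identical(cls[["8"]], "A_specific")
  expect_true(all(cls[setdiff(names(cls), c("2", "8"))] == "uninformative"))
  ## outgroup identical to all rows: everything uninformative
  same <- c(A1 = "ACGT", B1 = "ACGT", OUT = "ACGT")
  aln2 <- msa(same, groups = c(A1 = "g16", B1 = "g13"), outgroup_id = "OUT")
  part2 <- partition_diagnostic_sites(aln2)
  expect_true(all(part2$sites$class == "uninformative"))
  ## outgroup gap columns are skipped and counted
  gap <- c(A1 = "AC", A2 = "AC", B1 = "AC", OUT = "A-")
  aln3 <- msa(gap, groups = c(A1 = "g16", A2 = "g16", B1 = "g13"),
              outgroup_id = "OUT")
  part3 <- partition_diagnostic_sites(aln3)
  expect_equal(part3$n_skipped_outgroup_gap, 1L)
})

test_that("locate_recombination_interval brackets the signal", {
  mk_part <- function(pos, class) structure(
    list(sites = data.frame(col = seq_along(pos), pos = pos, class = class)),
    class = "site_partition")
  ## mirrors the published bracketing arithmetic: 426 - 120 = 306
  p <- mk_part(c(50, 120, 426, 500),
               c("A_specific", "A_specific", "shared_derived",
                 "shared_derived"))
  iv <- locate_recombination_interval(p)
  expect_true(iv$found)
  expect_equal(iv$length, 306L)
  ## adjacent sites give the minimal interval
  p2 <- mk_part(c(7, 8), c("A_specific", "shared_derived"))
  expect_equal(locate_recombination_interval(p2)$length, 1L)
  ## no A-specific site before the first shared site: no interval, no error
  p3 <- mk_part(c(10, 20), c("shared_derived", "A_specific"))
  expect_false(locate_recombination_interval(p3)$found)
})

test_that("split_tree_test separates recombinant from clonal histories", {
  set.seed(35)
  n <- 15
  disc <- contain <- logical(n)
  for (i in seq_len(n)) {
    rec <- sim_groups_alignment(recombinant = TRUE)
    out_r <- split_tree_test(rec$aln, split_point = rec$switch_point)
    disc[i] <- out_r$verdict == "discordant"
    iv <- locate_recombination_interval(partition_diagnostic_sites(rec$aln))
    contain[i] <- iv$found && iv$start <= rec$switch_point &&
      rec$switch_point <= iv$end
  }
  expect_gte(sum(disc), 13)
  expect_gte(sum(contain), 13)
  conc <- vapply(1:10, function(i) {
    con <- sim_groups_alignment(recombinant = FALSE)
    split_tree_test(con$aln, split_point = con$switch_point)$verdict
  }, character(1))
  expect_lte(sum(conc == "discordant"), 1)
})

test_that("split_tree_test degenerate inputs behave per contract", {
  set.seed(36)
  con <- sim_groups_alignment(recombinant = FALSE, seg_len = 200)
  ## identical left/right alignments: concordant with rf 0
  rows <- con$aln$rows
  half <- vapply(rows, function(r) substr(r, 1, 200), character(1))
  dbl <- stats::setNames(paste0(half, half), names(rows))
  aln <- msa(dbl, con$aln$groups, "OUT")
  res <- split_tree_test(aln, split_point = 200)
  expect_identical(res$verdict, "concordant")
  expect_equal(res$rf, 0)
  expect_error(split_tree_test(aln, split_point = 0), "strictly inside")
  expect_error(split_tree_test(aln, split_point = 2), "segment too short")
})

test_that("segment concordance control flags converted segments only", {
  set.seed(37)
  con <- sim_groups_alignment(recombinant = FALSE, seg_len = 300)
  segs <- list(con$aln, sim_groups_alignment(FALSE, seg_len = 300)$aln)
  ref <- nj_tree(k2p_matrix(con$aln$rows)$d)
  res <- segment_concordance_test(segs, ref)
  expect_identical(res$verdict, "gene conversion not supported")
  ## a segment with swapped clade assignment is flagged discordant
  swapped <- sim_groups_alignment(TRUE, seg_len = 800)$aln
  rows_sw <- vapply(swapped$rows, function(r)
    substr(r, 801, 1600), character(1))  # the nested-topology half
  seg_bad <- msa(stats::setNames(rows_sw, names(swapped$rows)),
                 swapped$groups, "OUT")
  res2 <- segment_concordance_test(list(con$aln, seg_bad), ref)
  expect_identical(res2$verdict, "gene conversion possible")
  expect_false(res2$per_segment$concordant[2])
  expect_warning(segment_concordance_test(list(con$aln), ref), "single-segment")
})
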