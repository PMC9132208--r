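test_that("detect_tsd finds exact and mismatched planted TSDs", {
  set.seed(21)
  tsd <- rand_seq(12)
  g <- c(x = paste0(rand_seq(200), tsd, rand_seq(300), tsd, rand_seq(200)))
  call <- detect_tsd(g, list(contig_id = "x", start = 212, end = 512))
  expect_equal(call$length, 12)
  expect_equal(call$mismatches, 0)
  expect_equal(call$left$start, 200)
  expect_equal(call$right$start, 512)
  ## one mismatch within the 0.2 fraction still recovered at length 8
  t8 <- "ACGTTGCA"
  t8m <- "ACGATGCA"
  g2 <- c(x = paste0(rand_seq(100), t8, rand_seq(150), t8m, rand_seq(100)))
  call2 <- detect_tsd(g2, list(contig_id = "x", start = 108, end = 258),
                      min_len = 5)
  expect_equal(call2$length, 8)
  expect_equal(call2$mismatches, 1)
})

test_that("detect_tsd returns NULL without shared flank sequence and errors at edges", {
  g <- c(x = paste0(strrep("A", 100), strrep("G", 100), strrep("C", 100)))
  expect_null(detect_tsd(g, list(contig_id = "x", start = 100, end = 200)))
  expect_error(detect_tsd(g, list(contig_id = "x", start = 0, end = 200)),
               "flank")
})

test_that("detect_tsd agrees with the exhaustive flank-pair oracle", {
  set.seed(22)
  n_loci <- 500
  ok <- logical(n_loci)
  for (i in seq_len(n_loci)) {
    tl <- sample(5:12, 1)
    tsd <- rand_seq(tl)
    tsd2 <- chars(tsd)
    if (tl >= 8) {  # sometimes plant one mismatch
      p <- sample(tl, 1)
      tsd2[p] <- sample(setdiff(c("A", "C", "G", "T"), tsd2[p]), 1)
    }
    g <- c(x = paste0(rand_seq(20), tsd, rand_seq(60),
                      paste(tsd2, collapse = ""), rand_seq(20)))
    iv <- list(contig_id = "x", start = 20 + tl, end = 20 + tl + 60)
    call <- detect_tsd(g, iv, max_window = 20, max_offset = 20)
    orc <- oracle_tsd(g, iv, max_window = 20)
    if (is.null(call)) ok[i] <- is.null(orc)
    else ok[i] <- !is.null(orc) && call$length == orc["l"] &&
        call$mismatches == orc["mm"]
  }
  expect_true(all(ok))
})

test_that("detect_tsd is invariant under reverse-complementing the locus", {
  set.seed(23)
  for (i in 1:10) {
    tsd <- rand_seq(10)
    g <- c(x = paste0(rand_seq(150), tsd, rand_seq(400), tsd, rand_seq(150)))
    iv <- list(contig_id = "x", start = 160, end = 560)
    call <- detect_tsd(g, iv)
    rc <- c(x = revcomp(g[["x"]]))
    L <- nchar(g[["x"]])
    iv_rc <- list(contig_id = "x", start = L - iv$end, end = L - iv$start)
    call_rc <- detect_tsd(rc, iv_rc)
    expect_equal(call_rc$length, call$length)
    expect_equal(call_rc$mismatches, call$mismatches)
    ## left/right swap under the lift; the junction-distance sum is
    ## preserved (the o1/o2 split of a tied pair may swap)
    off <- (iv$start - call$left$end) + (call$right$start - iv$end)
    off_rc <- (iv_rc$start - call_rc$left$end) +
      (call_rc$right$start - iv_rc$end)
    expect_equal(off_rc, off)
  }
})

test_that("characterize_junction classifies the documented cases", {
  ## single GATC at the junction: 4 bp microhomology
  obs <- "TTGATCAA"
  call <- characterize_junction("TTGATC", "GATCAA", obs)
  expect_equal(call$microhomology_len, 4L)
  expect_identical(call$inserted_seq, "")
  ## interior bases matching neither donor become the insertion
  obs2 <- paste0("AACCGGTT", "TATATAT", "GGCCAATT")
  call2 <- characterize_junction("AACCGGTTC", "CGGCCAATT", obs2)
  expect_equal(call2$microhomology_len, 0L)
  expect_identical(call2$inserted_seq, "TATATAT")
  expect_identical(call2$complexity, "simple")
  expect_error(characterize_junction("GGGGG", "CCCCC", "TTTTTTT"), "donors")
})

test_that("inserted fragments mapping to two donors mark complexity", {
  set.seed(24)
  left <- rand_seq(30)
  right <- rand_seq(30)
  fragA <- rand_seq(10); fragB <- rand_seq(10)
  ins <- paste0(fragA, fragB)
  obs <- paste0(left, ins, right)
  ld <- paste0(left, "A")  # continuation that mismatches ins start
  if (substr(ins, 1, 1) == "A") ld <- paste0(left, "C")
  rd <- paste0("A", right)
  if (substr(ins, nchar(ins), nchar(ins)) == "A") rd <- paste0("C", right)
  donorA <- paste0(rand_seq(20), fragA, rand_seq(20))
  donorB <- paste0(rand_seq(20), fragB, rand_seq(20))
  call <- characterize_junction(ld, rd, obs,
                                other_donors = c(donorA, donorB))
  expect_identical(call$complexity, "complex")
  call1 <- characterize_junction(ld, rd, obs, other_donors = donorA)
  expect_identical(call1$complexity, "simple")
})

test_that("cluster_breakpoints applies single linkage with median coordinates", {
  cp <- data.frame(name = c("a", "b"), bp5 = c(1000, 1003), bp3 = c(NA, NA))
  cen <- suppressWarnings(cluster_breakpoints(cp, "5", 20))
  expect_equal(nrow(cen$clusters), 1L)
  expect_equal(cen$clusters$coord, 1001.5)
  cp2 <- data.frame(name = c("a", "b", "c"), bp5 = c(1000, 1030, 2000),
                    bp3 = NA)
  cen2 <- suppressWarnings(cluster_breakpoints(cp2, "5", 20))
  expect_equal(nrow(cen2$clusters), 3L)
  ## a copy without a breakpoint on the requested side warns and is counted
  cp3 <- data.frame(name = c("a", "b"), bp5 = c(100, NA), bp3 = NA)
  expect_warning(cen3 <- cluster_breakpoints(cp3, "5", 20), "skipped")
  expect_equal(cen3$n_skipped, 1L)
})

test_that("cluster count is monotone non-increasing in tolerance", {
  set.seed(25)
  cp <- data.frame(name = paste0("c", 1:40),
                   bp5 = sample(0:5000, 40), bp3 = NA)
  tols <- c(0, 5, 20, 100, 500, 5000)
  counts <- vapply(tols, function(tol)
    nrow(cluster_breakpoints(cp, "5", tol)$clusters), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1L)
})

test_that("repeat_overlap_census uses half-open point-in-interval", {
  ann <- repeat_annotation("anc", 400L, 600L, "+", "SVA", "SVA_A")
  cen <- list(side = "3",
              clusters = data.frame(coord = c(500, 600), n = c(1, 1),
                                    members = c("a", "b")))
  counts <- repeat_overlap_census(cen, ann)
  expect_equal(counts[["SVA"]], 1L)
  expect_equal(counts[["none"]], 1L)  # 600 not contained in [400, 600)
})

test_that("breakpoint census recovers the planted independent sites", {
  sim <- small_sim()
  copies <- do.call(rbind, lapply(
    Filter(function(e) e$type == "duplication_copy", sim$ledger$events),
    function(e) data.frame(name = e$name, bp5 = e$bp5, bp3 = e$bp3)))
  cen5 <- cluster_breakpoints(copies, "5", 20)
  cen3 <- cluster_breakpoints(copies, "3", 20)
  expect_equal(nrow(cen5$clusters), length(sim$ancestral$bp5))
  expect_equal(nrow(cen3$clusters), length(sim$ancestral$bp3))
  counts3 <- repeat_overlap_census(cen3, sim$annotations,
                                   sim$ancestral$contig_id)
  truth3 <- table(sim$ancestral$bp3_class)
  expect_equal(counts3[sort(names(truth3))],
               stats::setNames(as.integer(truth3[sort(names(truth3))]),
                               sort(names(truth3))))
})
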