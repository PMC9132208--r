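test_that("segment_by_subfamily calls pure and chimeric elements", {
  lib <- small_library()
  D <- lib$entries[["SVA_D"]]$seq
  B <- lib$entries[["SVA_B"]]$seq
  pure <- segment_by_subfamily(D, lib, c("SVA_B", "SVA_D"))
  expect_equal(nrow(pure$segments), 1)
  expect_identical(pure$segments$subfamily, "SVA_D")
  expect_length(pure$switch_points, 0)
  ## constructive chimera: D below the switch, B above it
  sw <- 700L
  chim <- paste0(substr(D, 1, sw), substr(B, sw + 1, nchar(B)))
  call <- segment_by_subfamily(chim, lib, c("SVA_B", "SVA_D"))
  expect_equal(nrow(call$segments), 2)
  expect_identical(call$segments$subfamily, c("SVA_D", "SVA_B"))
  ds <- call$site_states
  last_d <- max(ds$pos[ds$state == "SVA_D" & ds$pos < sw])
  first_b <- min(ds$pos[ds$state == "SVA_B" & ds$pos >= sw])
  expect_equal(call$switch_points, as.integer((last_d + first_b) / 2))
  ## switch-point localization error bounded by the diagnostic-site gap
  expect_lte(abs(call$switch_points - sw), first_b - last_d)
})

test_that("mosaics below resolution merge with a warning; junk errors", {
  lib <- small_library()
  B <- chars(lib$entries[["SVA_B"]]$seq)
  ds <- lib$diagnostic_sites[["SVA_B|SVA_D"]]
  ## flip every second diagnostic site to the D state: alternating runs
  mosaic <- B
  flip <- seq(2, nrow(ds), by = 2)
  mosaic[ds$pos[flip] + 1L] <- ds$stateB[flip]
  expect_warning(
    call <- segment_by_subfamily(paste(mosaic, collapse = ""), lib,
                                 c("SVA_B", "SVA_D")),
    "mosaic below resolution")
  expect_equal(nrow(call$segments), 1)
  ## an element matching neither state anywhere is unclassifiable
  junk <- B
  junk[ds$pos + 1L] <- vapply(seq_len(nrow(ds)), function(i)
    setdiff(c("A", "C", "G", "T"), c(ds$stateA[i], ds$stateB[i]))[1],
    character(1))
  expect_error(segment_by_subfamily(paste(junk, collapse = ""), lib,
                                    c("SVA_B", "SVA_D")),
               "unclassifiable")
})

test_that("detect_chimera reports reciprocal chimeras and normalizes strand", {
  set.seed(51)
  lib <- small_library()
  B <- lib$entries[["SVA_B"]]$seq
  D <- lib$entries[["SVA_D"]]$seq
  sw <- 700L
  up <- paste0(substr(B, 1, sw), substr(D, sw + 1, nchar(D)))
  dn <- paste0(substr(D, 1, sw), substr(B, sw + 1, nchar(B)))
  L <- nchar(B)
  pieces <- c(rand_seq(500), B, rand_seq(500), D, rand_seq(500), up,
              rand_seq(500), revcomp(dn), rand_seq(500))
  g <- c(x = paste(pieces, collapse = ""))
  starts <- cumsum(c(0, nchar(pieces)))[1:8]
  ann <- repeat_annotation(
    "x", starts[c(2, 4, 6, 8)], starts[c(2, 4, 6, 8)] + L,
    strand = c("+", "+", "+", "-"), family = "SVA",
    subfamily = c("SVA_B", "SVA_D", "SVA_B", "SVA_D"))
  calls <- detect_chimera(ann, g, lib, pair = c("SVA_B", "SVA_D"))
  expect_length(calls, 2)
  orders <- lapply(calls, `[[`, "order")
  expect_true(any(vapply(orders, identical, logical(1), c("SVA_B", "SVA_D"))))
  expect_true(any(vapply(orders, identical, logical(1), c("SVA_D", "SVA_B"))))
  ## pure-element genome: empty result
  expect_length(detect_chimera(ann[1:2, ], g, lib), 2 - 2)
})

test_that("detect_circular_signature validates the planted cassette", {
  set.seed(52)
  lib <- small_library()
  g <- c(x = rand_seq(15000))
  res <- plant_circular_integration(g, lib, "x", 6000,
                                    donor_interior = rand_seq(2500))
  sim_like <- list(genome = res$genome, annotations = res$annotations)
  chim <- detect_chimera(res$annotations, res$genome, lib, pair = c("SVA_B", "SVA_D"))
  expect_length(chim, 2)
  sig <- detect_circular_signature(res$genome, chim)
  expect_identical(sig$verdict, "positive")
  expect_identical(sig$outer_subfamily, "SVA_B")
  expect_identical(sig$inner_subfamily, "SVA_D")
  expect_equal(sig$outer_tsd$length, 12)
  expect_equal(sig$inner_tsd$length, 12)
  expect_error(detect_circular_signature(res$genome, chim[1]),
               "not a candidate")
})

test_that("ablating the inner TSD degrades the verdict to partial", {
  set.seed(53)
  lib <- small_library()
  g <- c(x = rand_seq(15000))
  res <- plant_circular_integration(g, lib, "x", 6000,
                                    donor_interior = rand_seq(2500))
  ev <- res$event
  gg <- res$genome
  ## overwrite both inner TSD copies with unrelated sequence
  for (iv in list(ev$inner_tsd_left, ev$inner_tsd_right)) {
    s <- gg[["x"]]
    gg[["x"]] <- paste0(substr(s, 1, iv[1]), strrep("C", iv[2] - iv[1]),
                        substr(s, iv[2] + 1, nchar(s)))
  }
  gg[["x"]] <- paste0(substr(gg[["x"]], 1, ev$inner_tsd_left[1]),
                      rand_seq(ev$inner_tsd_left[2] - ev$inner_tsd_left[1]),
                      substr(gg[["x"]], ev$inner_tsd_left[2] + 1,
                             nchar(gg[["x"]])))
  chim <- detect_chimera(res$annotations, gg, lib, pair = c("SVA_B", "SVA_D"))
  sig <- detect_circular_signature(gg, chim)
  expect_identical(sig$verdict, "partial")
})

test_that("non-reciprocal flanking elements are negative", {
  lib <- small_library()
  fake <- function(contig, start, end, ord) {
    structure(list(segments = data.frame(subfamily = ord),
                   switch_points = integer(0),
                   interval = list(contig_id = contig, start = start,
                                   end = end, strand = "+"),
                   order = ord), class = "chimera_segment")
  }
  g <- c(x = rand_seq(5000))
  ## tandem duplication of one pure element: both "flanks" are pure B
  sig <- detect_circular_signature(g, list(fake("x", 1000, 2200, "SVA_B"),
                                           fake("x", 3000, 4200, "SVA_B")))
  expect_identical(sig$verdict, "negative")
  expect_false(sig$reciprocal)
})

test_that("reversing the locus exchanges the subfamily roles", {
  set.seed(54)
  lib <- small_library()
  g <- c(x = rand_seq(15000))
  res <- plant_circular_integration(g, lib, "x", 6000,
                                    donor_interior = rand_seq(2500))
  sigf <- detect_circular_signature(
    res$genome, detect_chimera(res$annotations, res$genome, lib, pair = c("SVA_B", "SVA_D")))
  ## reverse-complement the contig; lift the annotations
  L <- nchar(res$genome[["x"]])
  grc <- c(x = revcomp(res$genome[["x"]]))
  ann <- res$annotations
  new_start <- L - ann$end
  ann$end <- L - ann$start
  ann$start <- new_start
  ann$strand <- ifelse(ann$strand == "+", "-", "+")
  sigr <- detect_circular_signature(grc, detect_chimera(ann, grc, lib, pair = c("SVA_B", "SVA_D")))
  expect_identical(sigr$verdict, "positive")
  expect_identical(sigr$outer_subfamily, sigf$outer_subfamily)
  expect_identical(sigr$inner_subfamily, sigf$inner_subfamily)
})
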