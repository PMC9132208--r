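test_that("element library plants the documented domain structure", {
  lib <- small_library()
  dom <- lib$base_domains
  expect_identical(dom$domain, c("hexamer", "Alu-like", "VNTR", "SINE-R"))
  ## domains tile the consensus without overlap
  expect_equal(dom$start[-1], dom$end[-4])
  hex <- substr(lib$entries[[1]]$seq, dom$start[1] + 1, dom$end[1])
  expect_identical(hex, strrep("TCTCCC", nchar(hex) / 6))
})

test_that("diagnostic sites count equals the planted Hamming separation", {
  lib0 <- make_element_library(seed = 3, n_subfamilies = 2,
                               n_diagnostic_sites = 0)
  expect_identical(lib0$entries[[1]]$seq, lib0$entries[[2]]$seq)
  expect_equal(nrow(lib0$diagnostic_sites[[1]]), 0L)
  lib <- make_element_library(seed = 3, n_subfamilies = 2,
                              n_diagnostic_sites = 20)
  ## direct count oracle: hamming distance between the two consensi
  h <- sum(chars(lib$entries[[1]]$seq) != chars(lib$entries[[2]]$seq))
  expect_equal(h, 20L)
  expect_equal(nrow(lib$diagnostic_sites[["SVA_A|SVA_B"]]), 20L)
  expect_error(make_element_library(seed = 3, n_diagnostic_sites = 1e6),
               "non-VNTR")
})

test_that("mutate_sequence respects the rate and never introduces indels", {
  set.seed(9)
  s <- rand_seq(20000)
  r <- mutate_sequence(s, 0.02, kappa = 2)
  expect_equal(nchar(r$seq), nchar(s))
  nsub <- sum(chars(r$seq) != chars(s))
  expect_equal(nsub, length(r$sites))
  ## within 3 sigma of Binomial(20000, 0.02)
  expect_lt(abs(nsub - 400), 3 * sqrt(20000 * 0.02 * 0.98))
  expect_identical(mutate_sequence(s, 0)$seq, s)
})

test_that("plant_l1_insertion leaves identical TSDs and ordered structure", {
  set.seed(4)
  lib <- small_library()
  g <- c(x = rand_seq(6000))
  res <- plant_l1_insertion(g, lib, "x", 3000, subfamily = "SVA_B",
                            with_transduction = TRUE, tsd_length = 12,
                            polyA_len = 20)
  ev <- res$event
  left <- substr(res$genome[["x"]], ev$tsd_left[1] + 1, ev$tsd_left[2])
  right <- substr(res$genome[["x"]], ev$tsd_right[1] + 1, ev$tsd_right[2])
  expect_identical(left, right)
  ## insert ends polyA, preceded by the transduction, preceded by SINE-R 3'
  ins <- substr(res$genome[["x"]], ev$insert_start + 1, ev$insert_end)
  expect_identical(substr(ins, nchar(ins) - 19, nchar(ins)), strrep("A", 20))
  td <- lib$entries[["SVA_B"]]$transduction
  expect_identical(substr(ins, nchar(ins) - 20 - nchar(td) + 1,
                          nchar(ins) - 20), td)
  el <- lib$entries[["SVA_B"]]$seq
  expect_identical(substr(ins, 1, nchar(el)), el)
  expect_error(plant_l1_insertion(g, lib, "x", 10000), "out of bounds")
})

test_that("detect_tsd recovers all planted TSD intervals exactly at mu 0", {
  set.seed(11)
  lib <- small_library()
  g <- c(x = rand_seq(460000))
  events <- list()
  off <- 0
  for (i in 1:100) {
    site <- i * 4500 + off
    tl <- sample(8:16, 1)
    res <- plant_l1_insertion(g, lib, "x", site, subfamily = "SVA_B",
                              truncate5 = 200, tsd_length = tl,
                              polyA_len = sample(8:30, 1))
    g <- res$genome
    events[[i]] <- res$event
    off <- off + (res$event$tsd_right[2] - res$event$tsd_left[1]) - tl
  }
  ok <- vapply(events, function(ev) {
    call <- detect_tsd(g, list(contig_id = "x", start = ev$insert_start,
                               end = ev$insert_end))
    !is.null(call) && call$length == ev$tsd_length &&
      call$left$start == ev$tsd_left[1] && call$right$start == ev$tsd_right[1]
  }, logical(1))
  expect_true(all(ok))
})

test_that("plant_duplication_block enforces the SD regime and mutates at mu", {
  set.seed(12)
  anc <- rand_seq(30000)
  g <- c(t1 = rand_seq(4000))
  expect_error(plant_duplication_block(g, anc, 1000, 1500, "t1", 2000),
               "1 kb")
  res0 <- plant_duplication_block(g, anc, 2000, 22000, "t1", 2000, mu = 0)
  copy <- substr(res0$genome[["t1"]], res0$event$start + 1, res0$event$end)
  expect_identical(copy, substr(anc, 2001, 22000))
  res2 <- plant_duplication_block(g, anc, 2000, 22000, "t1", 2000, mu = 0.02)
  copy2 <- substr(res2$genome[["t1"]], res2$event$start + 1, res2$event$end)
  nsub <- sum(chars(copy2) != chars(substr(anc, 2001, 22000)))
  expect_lt(abs(nsub - 400), 3 * sqrt(20000 * 0.02 * 0.98))
})

test_that("duplication junction donors reproduce the planted signature", {
  set.seed(13)
  anc <- rand_seq(30000)
  for (i in 1:20) {
    g <- c(t1 = rand_seq(4000))
    mh3 <- if (i %% 4 == 0) NA else sample(1:4, 1)
    res <- plant_duplication_block(g, anc, 2000, 22000, "t1", 2000,
                                   mh5 = sample(1:4, 1), mh3 = mh3,
                                   ins3_len = sample(4:10, 1))
    for (jx in res$junctions) {
      obs <- substr(res$genome[["t1"]], jx$window_start + 1, jx$window_end)
      call <- characterize_junction(jx$left_donor, jx$right_donor, obs)
      expect_equal(call$microhomology_len, jx$mh)
      expect_equal(nchar(call$inserted_seq), jx$inserted_len)
    }
  }
})

test_that("plant_circular_integration emits the reciprocal cassette", {
  set.seed(14)
  lib <- small_library()
  g <- c(x = rand_seq(15000))
  pre_site <- substr(g[["x"]], 6001, 6012)
  res <- plant_circular_integration(g, lib, "x", 6000,
                                    donor_interior = rand_seq(2500),
                                    pair = c("SVA_B", "SVA_D"))
  ev <- res$event
  gg <- res$genome[["x"]]
  sl <- function(iv) substr(gg, iv[1] + 1, iv[2])
  ## outer TSD pair duplicates the pre-integration site sequence
  expect_identical(sl(ev$outer_tsd_left), pre_site)
  expect_identical(sl(ev$outer_tsd_right), pre_site)
  expect_identical(sl(ev$inner_tsd_left), sl(ev$inner_tsd_right))
  ## reciprocal chimeras switch at the same consensus coordinate
  expect_identical(ev$switch_point_up, ev$switch_point_down)
  s <- ev$switch_point_up
  B <- lib$entries[["SVA_B"]]$seq; D <- lib$entries[["SVA_D"]]$seq
  expect_identical(sl(ev$chimera_up),
                   paste0(substr(B, 1, s), substr(D, s + 1, nchar(D))))
  expect_identical(sl(ev$chimera_down),
                   paste0(substr(D, 1, s), substr(B, s + 1, nchar(B))))
  expect_error(plant_circular_integration(g, lib, "x", 6000, rand_seq(100),
                                          pair = c("SVA_B", "SVA_X")),
               "subfamily")
})

test_that("plant_direct_repeat_sd honors identity and the SD definition", {
  set.seed(15)
  g <- c(x = rand_seq(30000))
  expect_error(plant_direct_repeat_sd(g, "x", 5000, rand_seq(2000),
                                      flank_length = 500), "1 kb")
  expect_error(plant_direct_repeat_sd(g, "x", 5000, rand_seq(2000),
                                      identity = 0.85), "identity")
  res <- plant_direct_repeat_sd(g, "x", 5000, rand_seq(3000),
                                flank_length = 4000, identity = 1.0)
  ev <- res$event
  gg <- res$genome[["x"]]
  L <- substr(gg, ev$left_repeat[1] + 1, ev$left_repeat[2])
  R <- substr(gg, ev$right_repeat[1] + 1, ev$right_repeat[2])
  expect_identical(L, R)
  res2 <- plant_direct_repeat_sd(g, "x", 5000, rand_seq(3000),
                                 flank_length = 4000, identity = 0.95)
  expect_lt(abs(res2$event$realized_mismatches - 200),
            3 * sqrt(4000 * 0.05 * 0.95))
})

test_that("simulation is deterministic and self-consistent", {
  cfg <- sim_config(seed = 77, n_l1 = 3, n_duplication_copies = 5, n_bp5 = 3,
                    n_bp3 = 3, n_cassettes = 1, n_flanked_sd = 1,
                    tsd_length_range = c(8, 16))
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$ledger, s2$ledger)
  expect_true(audit_ledger(s1))
  ## ledger coordinates always inside the genome; annotations in bounds
  expect_true(all(s1$annotations$end <=
                    nchar(s1$genome)[s1$annotations$contig_id]))
})

test_that("write_simulation emits a readable text bundle", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  g <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(g, sim$genome)
  ann <- parse_repeatmasker_out(file.path(dir, "annotations.out"))
  expect_equal(nrow(ann), nrow(sim$annotations))
  expect_equal(ann$start, sim$annotations$start)
  led <- jsonlite::read_json(file.path(dir, "ledger.json"))
  expect_equal(length(led$events), length(sim$ledger$events))
})
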