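## Synthetic-genome simulator: plants every structure the detectors infer —
## L1-mediated element insertions with TSDs, polyA tails and 3' transductions;
## duplication copies of a core-duplicon locus with breakpoint-junction
## microhomology; reciprocal-chimera circular-integration cassettes; and
## SD inserts flanked by large direct repeats — and emits a machine-readable
## truth ledger. Substitutions are per-site i.i.d. (transitions kappa-weighted)
## and there are no indels outside junction features, so every ledger
## coordinate is exact.

rand_in <- function(range) {
  if (range[1] == range[2]) return(as.integer(range[1]))
  sample(seq(range[1], range[2]), 1)
}

guard_base <- function(avoid) sample(setdiff(DNA_BASES, avoid), 1)

rotate_string <- function(s, r) {
  n <- nchar(s)
  r <- r %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1, n), substr(s, 1, r))
}

## Build donor source sequences realizing an exact junction signature.
## The emitted genome around the seam is left_tail ++ inserted ++ right_head;
## the left donor extends past the breakpoint with a continuation C and the
## right donor extends back with a pre-context P, constructed so the maximal
## donor overlap equals mh exactly (guard bases block longer overlaps).
sim_junction_donors <- function(left_tail, right_head, mh = 0L, inserted = "",
                                ctx = 12L) {
  stopifnot(mh == 0L || inserted == "")
  if (inserted == "") {
    cont <- if (mh > 0) substr(right_head, 1L, mh) else ""
    g1 <- guard_base(substr(right_head, mh + 1L, mh + 1L))
    C <- paste0(cont, g1, random_dna(ctx))
    g2 <- guard_base(substr(left_tail, nchar(left_tail), nchar(left_tail)))
    P <- paste0(random_dna(ctx), g2)
  } else {
    C <- paste0(guard_base(substr(inserted, 1L, 1L)), random_dna(ctx))
    P <- paste0(random_dna(ctx),
                guard_base(substr(inserted, nchar(inserted), nchar(inserted))))
  }
  list(left_donor = paste0(left_tail, C), right_donor = paste0(P, right_head))
}

#' Generate one synthetic junction with known signature
#'
#' Emits an observed junction string together with its two donor source
#' sequences, such that [characterize_junction()]'s ground truth is known:
#' microhomology of exactly `mh` (when `inserted_len` is 0) or an inserted
#' run of `inserted_len` unattributable bases (with `mh` 0).
#'
#' @param mh planted microhomology length.
#' @param inserted_len planted inserted-nucleotide run length.
#' @param flank bases of emitted context on each side of the seam.
#' @return list with `observed`, `left_donor`, `right_donor`, `mh`,
#'   `inserted_seq`.
#' @export
sim_junction <- function(mh = 0L, inserted_len = 0L, flank = 40L) {
  left_tail <- random_dna(flank)
  right_head <- random_dna(flank)
  ins <- if (inserted_len > 0) random_dna(inserted_len) else ""
  if (inserted_len > 0) mh <- 0L
  d <- sim_junction_donors(left_tail, right_head, mh, ins)
  ## guard interior ends against accidental attribution to the emitted flanks
  list(observed = paste0(left_tail, ins, right_head),
       left_donor = d$left_donor, right_donor = d$right_donor,
       mh = as.integer(mh), inserted_seq = ins)
}

#' Simulation configuration
#'
#' Defaults state the simulated world: a ~20 kb core duplicon, TSDs of
#' L1-mediated insertions, 1-4 nt junction microhomologies, ~4 kb
#' direct-repeat flanks, and neutral per-copy divergence `mu` under a
#' two-rate model. Identical configs produce byte-identical output.
#'
#' @param seed mandatory RNG seed (no wall-clock seeding).
#' @param n_l1,n_duplication_copies,n_cassettes,n_flanked_sd event counts.
#' @param n_bp5,n_bp3 distinct independent breakpoints on each side.
#' @param core_duplicon_length core length (default 20,000).
#' @param mu per-copy substitution rate in \[0, 0.2\].
#' @param kappa transition/transversion weight.
#' @param tsd_length_range,transduction_length_range,microhomology_range,polyA_range sampling ranges.
#' @param direct_repeat_flank_length,flank_identity direct-repeat flank regime.
#' @param cassette_tsd_length TSD length at circular-integration cassettes.
#' @param l1_spacing spacing between L1 insertion sites (kept above the
#'   flank scanner's insert ceiling so near-identical elements are never
#'   reported as direct-repeat pairs).
#' @param n_diagnostic_sites per-subfamily diagnostic substitutions in the
#'   element library.
#' @return validated config list of class `"sim_config"`.
#' @export
sim_config <- function(seed,
                       n_l1 = 20L, n_duplication_copies = 30L,
                       n_bp5 = 9L, n_bp3 = 9L,
                       n_cassettes = 2L, n_flanked_sd = 4L,
                       core_duplicon_length = 20000L,
                       mu = 0, kappa = 2,
                       tsd_length_range = c(4L, 20L),
                       transduction_length_range = c(100L, 400L),
                       microhomology_range = c(1L, 4L),
                       polyA_range = c(8L, 30L),
                       direct_repeat_flank_length = 4000L,
                       flank_identity = 1.0,
                       cassette_tsd_length = 12L,
                       l1_spacing = 30000L,
                       n_diagnostic_sites = 20L) {
  stopifnot(!missing(seed), mu >= 0, mu <= 0.2, kappa > 0,
            tsd_length_range[1] <= tsd_length_range[2],
            microhomology_range[1] <= microhomology_range[2],
            direct_repeat_flank_length >= 1000,
            flank_identity >= 0.9, flank_identity <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Build a simulation config from a flat key=value file
#'
#' Unknown keys are rejected (schema validation); `seed` is mandatory.
#'
#' @param path config file path (see [read_config()] for the format).
#' @return a `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  vals <- read_config(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!"seed" %in% names(vals)) stop("missing input section: seed")
  do.call(sim_config, vals)
}

#' Plant an L1-mediated element insertion with TSD
#'
#' The inserted sequence is element (optionally 5'-truncated) + optional 3'
#' transduction + polyA; a target-site duplication of the sampled length is
#' left on both flanks (the right copy carries any planted mismatches and,
#' with `mu > 0`, neutral divergence along with the insert).
#'
#' @param genome named character vector.
#' @param library a `consensus_library`.
#' @param contig_id,site insertion point (0-based; insert goes after the
#'   TSD at `[site, site + tsd_length)`).
#' @param subfamily element subfamily.
#' @param with_transduction append the library's 3' transduction.
#' @param truncate5 bases removed from the element 5' end.
#' @param tsd_length,tsd_mismatches,polyA_len feature sizes.
#' @param mu,kappa divergence applied to the inserted copy.
#' @return list with `genome`, `event` (truth record), `annotations` rows.
#' @export
plant_l1_insertion <- function(genome, library, contig_id, site,
                               subfamily = names(library$entries)[1],
                               with_transduction = FALSE, truncate5 = 0L,
                               tsd_length = 12L, tsd_mismatches = 0L,
                               polyA_len = 16L, mu = 0, kappa = 2) {
  s <- genome[[contig_id]]
  n <- nchar(s)
  if (site < 0 || site + tsd_length > n) stop("site out of bounds")
  entry <- library$entries[[subfamily]]
  element <- substr(entry$seq, truncate5 + 1L, nchar(entry$seq))
  td <- if (with_transduction) entry$transduction else ""
  insert <- paste0(element, td, strrep("A", polyA_len))
  tsd <- substr(s, site + 1L, site + tsd_length)
  tsd_right <- tsd
  if (tsd_mismatches > 0) {
    ch <- seq_chars(tsd_right)
    pos <- sample(length(ch), tsd_mismatches)
    for (p in pos) ch[p] <- mutate_base(ch[p], kappa)
    tsd_right <- paste(ch, collapse = "")
  }
  mob <- mutate_sequence(paste0(insert, tsd_right), mu, kappa)$seq
  newseq <- paste0(substr(s, 1L, site + tsd_length), mob,
                   substr(s, site + tsd_length + 1L, n))
  genome[[contig_id]] <- newseq
  el_start <- site + tsd_length
  el_end <- el_start + nchar(element)
  td_end <- el_end + nchar(td)
  ins_end <- el_start + nchar(insert)
  event <- list(type = "L1_insertion", contig_id = contig_id,
                start = el_start, end = el_end,
                insert_start = el_start, insert_end = ins_end,
                tsd_left = c(site, site + tsd_length),
                tsd_right = c(ins_end, ins_end + tsd_length),
                tsd_length = tsd_length, tsd_mismatches = tsd_mismatches,
                tsd_seq = tsd, subfamily = subfamily,
                with_transduction = with_transduction,
                truncate5 = truncate5, polyA_len = polyA_len)
  ann <- repeat_annotation(contig_id, el_start, el_end, "+", "SVA", subfamily,
                           consensus_start = truncate5 + 1L,
                           consensus_end = nchar(entry$seq),
                           divergence_pct = 100 * mu)
  if (with_transduction)
    ann <- rbind(ann, repeat_annotation(contig_id, el_end, td_end, "+",
                                        "TD", paste0(subfamily, "_TD"),
                                        divergence_pct = 100 * mu))
  list(genome = genome, event = event, annotations = ann)
}

#' Plant a duplication copy of an ancestral locus
#'
#' The copy is the ancestral slice `[bp5, bp3)` mutated at rate `mu` under
#' the two-rate model; each junction carries either a microhomology sampled
#' from `microhomology_range` or an inserted-nucleotide run, realized
#' exactly by construction of the donor source sequences (and a couple of
#' free background bases), and recorded in the truth ledger.
#'
#' @param genome named character vector.
#' @param ancestral_seq ancestral locus sequence (its own coordinate system).
#' @param bp5,bp3 breakpoints (0-based, half-open slice; `bp3 - bp5 >= 1000`,
#'   the segmental-duplication regime).
#' @param contig_id,site target insertion point.
#' @param name copy name for the ledger.
#' @param mh5,mh3 microhomology lengths (mh3 = NA plants an
#'   inserted-nucleotide junction of length `ins3_len` instead).
#' @param ins3_len inserted-run length at the 3' junction when `mh3` is NA.
#' @param mu,kappa divergence of the copy.
#' @return list with `genome`, `event`, `junctions` (donor records).
#' @export
plant_duplication_block <- function(genome, ancestral_seq, bp5, bp3,
                                    contig_id, site, name = "copy",
                                    mh5 = 2L, mh3 = 2L, ins3_len = 7L,
                                    mu = 0, kappa = 2) {
  if (bp3 - bp5 < 1000L) stop("breakpoint interval shorter than 1 kb (not an SD)")
  stopifnot(bp5 >= 41, bp3 + 41 <= nchar(ancestral_seq))
  s <- genome[[contig_id]]
  n <- nchar(s)
  if (site < 41 || site > n - 41) stop("site out of bounds")
  copy <- substr(ancestral_seq, bp5 + 1L, bp3)
  copy <- mutate_sequence(copy, mu, kappa)$seq
  W <- 40L
  ch_s <- seq_chars(s)

  ## 5' junction: right donor = ancestral context (fixed); left donor = the
  ## pre-integration target continuation (free). mh5 realized on the
  ## continuation side; guard the flank base before the seam.
  if (ch_s[site] == substr(ancestral_seq, bp5, bp5))
    ch_s[site] <- guard_base(ch_s[site])
  left_tail5 <- paste(ch_s[seq(site - W + 1L, site)], collapse = "")
  cont5 <- paste0(substr(copy, 1L, mh5),
                  guard_base(substr(copy, mh5 + 1L, mh5 + 1L)),
                  random_dna(12L))
  jx5 <- list(left_donor = paste0(left_tail5, cont5),
              right_donor = substr(ancestral_seq, bp5 - 11L, bp5 + W),
              mh = mh5, inserted_len = 0L)

  ## 3' junction: left donor = ancestral continuation past bp3 (fixed);
  ## right donor = original target continuation (free). Either mh3 bases of
  ## the background after the seam are set to the ancestral continuation, or
  ## an unattributable run is inserted.
  ins3 <- ""
  if (is.na(mh3)) {
    ins3 <- random_dna(ins3_len)
    if (substr(ins3, 1L, 1L) == substr(ancestral_seq, bp3 + 1L, bp3 + 1L))
      ins3 <- paste0(guard_base(substr(ancestral_seq, bp3 + 1L, bp3 + 1L)),
                     substr(ins3, 2L, nchar(ins3)))
    if (substr(ins3, ins3_len, ins3_len) == ch_s[site + 1L])
      ins3 <- paste0(substr(ins3, 1L, ins3_len - 1L),
                     guard_base(ch_s[site + 1L]))
    mh3_real <- 0L
  } else {
    anc_cont <- substr(ancestral_seq, bp3 + 1L, bp3 + mh3)
    ch_s[seq(site + 1L, site + mh3)] <- seq_chars(anc_cont)
    if (ch_s[site + mh3 + 1L] == substr(ancestral_seq, bp3 + mh3 + 1L,
                                        bp3 + mh3 + 1L))
      ch_s[site + mh3 + 1L] <- guard_base(ch_s[site + mh3 + 1L])
    mh3_real <- mh3
  }
  ## right-donor pre-context guard: base before the target continuation must
  ## not extend the overlap into the copy
  pre3 <- paste0(random_dna(11L),
                 guard_base(if (nzchar(ins3))
                   substr(ins3, nchar(ins3), nchar(ins3))
                   else substr(copy, nchar(copy), nchar(copy))))
  right_head3 <- paste(ch_s[seq(site + 1L, site + W)], collapse = "")
  jx3 <- list(left_donor = substr(ancestral_seq, bp3 - W + 1L, bp3 + 12L),
              right_donor = paste0(pre3, right_head3),
              mh = mh3_real, inserted_len = nchar(ins3))

  s2 <- paste(ch_s, collapse = "")
  newseq <- paste0(substr(s2, 1L, site), copy, ins3,
                   substr(s2, site + 1L, n))
  genome[[contig_id]] <- newseq
  copy_start <- site
  copy_end <- site + nchar(copy)
  seam3 <- copy_end + nchar(ins3)
  event <- list(type = "duplication_copy", name = name, contig_id = contig_id,
                start = copy_start, end = copy_end,
                bp5 = bp5, bp3 = bp3, mu = mu,
                mh5 = mh5, mh3 = if (is.na(mh3)) NA_integer_ else mh3,
                ins3_len = nchar(ins3))
  junctions <- list(
    c(list(id = paste0(name, "_j5"), contig_id = contig_id, seam = copy_start,
           window_start = copy_start - W, window_end = copy_start + W,
           event_type = "duplication_copy", event_name = name, side = "5"),
      jx5),
    c(list(id = paste0(name, "_j3"), contig_id = contig_id, seam = copy_end,
           window_start = copy_end - W, window_end = seam3 + W,
           event_type = "duplication_copy", event_name = name, side = "3"),
      jx3))
  list(genome = genome, event = event, junctions = junctions)
}

#' Plant a circular-intermediate integration cassette
#'
#' Emits `[outer-left TSD][X5'|Y3' chimera][inner-left TSD][rotated donor
#' segment][inner-right TSD][Y5'|X3' chimera][outer-right TSD]`: reciprocal
#' subfamily chimeras with swapped TSD association and a circularly permuted
#' donor segment — the signature of reintegration of a circular intermediate
#' by recombination between two elements of different subfamilies.
#'
#' @param genome named character vector.
#' @param library a `consensus_library`.
#' @param contig_id,site target insertion point.
#' @param donor_interior interior (donor-locus) sequence carried by the
#'   circle.
#' @param pair character(2): `c(outer, inner)` subfamilies, e.g.
#'   `c("SVA_B", "SVA_D")`.
#' @param switch_point 0-based consensus coordinate of the recombination
#'   switch (default: 70% into the SINE-R, its 3' part).
#' @param tsd_length outer/inner TSD length (default 12).
#' @param rotation circular permutation offset of the donor segment.
#' @param mu,kappa divergence applied to the inserted cassette.
#' @return list with `genome`, `event`, `annotations`.
#' @export
plant_circular_integration <- function(genome, library, contig_id, site,
                                       donor_interior,
                                       pair = c("SVA_B", "SVA_D"),
                                       switch_point = NULL, tsd_length = 12L,
                                       rotation = NULL, mu = 0, kappa = 2) {
  if (!all(pair %in% names(library$entries)))
    stop("donor lacks the required subfamily elements: ",
         paste(setdiff(pair, names(library$entries)), collapse = ", "))
  X <- library$entries[[pair[1]]]$seq   # outer subfamily
  Y <- library$entries[[pair[2]]]$seq   # inner subfamily
  dom <- library$base_domains
  sr <- dom[dom$domain == "SINE-R", ]
  if (is.null(switch_point))
    switch_point <- as.integer(sr$start + 0.7 * (sr$end - sr$start))
  s <- genome[[contig_id]]
  n <- nchar(s)
  if (site < 1 || site + tsd_length > n) stop("site out of bounds")
  if (is.null(rotation)) rotation <- rand_in(c(1L, nchar(donor_interior) - 1L))
  up <- paste0(substr(X, 1L, switch_point), substr(Y, switch_point + 1L, nchar(Y)))
  down <- paste0(substr(Y, 1L, switch_point), substr(X, switch_point + 1L, nchar(X)))
  inner_tsd <- random_dna(tsd_length)
  interior <- rotate_string(donor_interior, rotation)
  outer_tsd <- substr(s, site + 1L, site + tsd_length)
  cassette <- paste0(up, inner_tsd, interior, inner_tsd, down)
  mob <- mutate_sequence(paste0(cassette, outer_tsd), mu, kappa)$seq
  newseq <- paste0(substr(s, 1L, site + tsd_length), mob,
                   substr(s, site + tsd_length + 1L, n))
  genome[[contig_id]] <- newseq
  p0 <- site + tsd_length            # cassette start (after outer-left TSD)
  up_iv <- c(p0, p0 + nchar(up))
  itl <- c(up_iv[2], up_iv[2] + tsd_length)
  int_iv <- c(itl[2], itl[2] + nchar(interior))
  itr <- c(int_iv[2], int_iv[2] + tsd_length)
  dn_iv <- c(itr[2], itr[2] + nchar(down))
  otr <- c(dn_iv[2], dn_iv[2] + tsd_length)
  event <- list(type = "circular_integration", contig_id = contig_id,
                start = up_iv[1], end = dn_iv[2],
                outer_tsd_left = c(site, site + tsd_length),
                outer_tsd_right = otr,
                inner_tsd_left = itl, inner_tsd_right = itr,
                chimera_up = up_iv, chimera_down = dn_iv,
                interior = int_iv, rotation = rotation,
                switch_point_up = switch_point, switch_point_down = switch_point,
                outer_subfamily = pair[1], inner_subfamily = pair[2],
                tsd_length = tsd_length)
  ann <- rbind(
    repeat_annotation(contig_id, up_iv[1], up_iv[2], "+", "SVA", pair[1],
                      consensus_end = nchar(X), divergence_pct = 100 * mu),
    repeat_annotation(contig_id, dn_iv[1], dn_iv[2], "+", "SVA", pair[2],
                      consensus_end = nchar(Y), divergence_pct = 100 * mu))
  list(genome = genome, event = event, annotations = ann)
}

#' Plant an insert flanked by large direct repeats
#'
#' Structure `[repeat L][insert][repeat R]` with R a mutated copy of L at the
#' stated identity; the L|insert junction carries a sampled microhomology and
#' the insert|R junction either a microhomology or an inserted run of
#' unrelated bases. Inverted-orientation pairs are never emitted.
#'
#' @param genome named character vector.
#' @param contig_id,site insertion point.
#' @param insert_seq the duplicated segment placed between the repeats.
#' @param flank_length repeat length (>= 1000).
#' @param identity repeat identity in \[0.9, 1\].
#' @param mh1,mh2 junction microhomologies (mh2 = NA plants an inserted run
#'   of `ins2_len` bases at the insert|R junction).
#' @param ins2_len inserted-run length when `mh2` is NA.
#' @param name event name.
#' @param kappa transition weight for flank divergence.
#' @return list with `genome`, `event`, `junctions`.
#' @export
plant_direct_repeat_sd <- function(genome, contig_id, site, insert_seq,
                                   flank_length = 4000L, identity = 1.0,
                                   mh1 = 2L, mh2 = 2L, ins2_len = 7L,
                                   name = "sd", kappa = 2) {
  if (flank_length < 1000L) stop("flank_length below 1 kb (not a large direct repeat)")
  if (identity < 0.9 || identity > 1) stop("identity outside the SD regime [0.9, 1]")
  s <- genome[[contig_id]]
  n <- nchar(s)
  if (site < 0 || site > n) stop("site out of bounds")
  L <- random_dna(flank_length)
  R <- mutate_sequence(L, 1 - identity, kappa)$seq
  W <- 40L
  ins2 <- ""
  if (is.na(mh2)) { ins2 <- random_dna(ins2_len); mh2_real <- 0L } else mh2_real <- mh2
  jx1 <- c(sim_junction_donors(substr(L, flank_length - W + 1L, flank_length),
                               substr(insert_seq, 1L, W), mh1, ""),
           list(mh = mh1, inserted_len = 0L))
  jx2 <- c(sim_junction_donors(substr(insert_seq, nchar(insert_seq) - W + 1L,
                                      nchar(insert_seq)),
                               substr(R, 1L, W),
                               if (is.na(mh2)) 0L else mh2, ins2),
           list(mh = mh2_real, inserted_len = nchar(ins2)))
  cassette <- paste0(L, insert_seq, ins2, R)
  newseq <- paste0(substr(s, 1L, site), cassette, substr(s, site + 1L, n))
  genome[[contig_id]] <- newseq
  l_iv <- c(site, site + flank_length)
  i_iv <- c(l_iv[2], l_iv[2] + nchar(insert_seq))
  r_start <- i_iv[2] + nchar(ins2)
  r_iv <- c(r_start, r_start + flank_length)
  event <- list(type = "direct_repeat_SD", name = name, contig_id = contig_id,
                start = i_iv[1], end = i_iv[2],
                left_repeat = l_iv, right_repeat = r_iv,
                flank_length = flank_length, identity = identity,
                realized_mismatches = hamming(L, R),
                mh1 = mh1, mh2 = if (is.na(mh2)) NA_integer_ else mh2,
                ins2_len = nchar(ins2))
  junctions <- list(
    c(list(id = paste0(name, "_j1"), contig_id = contig_id, seam = l_iv[2],
           window_start = l_iv[2] - W, window_end = l_iv[2] + W,
           event_type = "direct_repeat_SD", event_name = name, side = "5"),
      jx1),
    c(list(id = paste0(name, "_j2"), contig_id = contig_id, seam = i_iv[2],
           window_start = i_iv[2] - W, window_end = r_start + W,
           event_type = "direct_repeat_SD", event_name = name, side = "3"),
      jx2))
  list(genome = genome, event = event, junctions = junctions)
}

## sample k coordinates inside [lo, hi) pairwise separated by >= min_gap
sample_separated <- function(k, lo, hi, min_gap = 100L) {
  for (try in 1:200) {
    x <- sort(sample(seq(lo, hi - 1L), k))
    if (k == 1L || min(diff(x)) >= min_gap) return(x)
  }
  stop("cannot sample ", k, " separated coordinates in [", lo, ",", hi, ")")
}

#' Simulate a full synthetic genome with truth ledger
#'
#' Builds an ancestral-locus contig (core duplicon with annotated repeats, an
#' element + 3' transduction at the core 3' end), an L1-insertion contig,
#' one contig per duplication copy (so near-identical copies never share a
#' contig), cassette contigs and direct-repeat-SD contigs, plants every
#' event type, and records everything in the ledger.
#'
#' @param config a [sim_config()].
#' @return object of class `"sva_sim"`: list with `genome`, `ledger`
#'   (`events`, `junctions`), `annotations`, `library`, `ancestral`
#'   (contig id, core interval, breakpoint tables), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lib <- make_element_library(seed = sample.int(1e6, 1), n_subfamilies = 4,
                              n_diagnostic_sites = config$n_diagnostic_sites)
  sva_len <- nchar(lib$entries[[1]]$seq)
  td_len <- nchar(lib$entries[[1]]$transduction)
  events <- list()
  junctions <- list()
  anns <- empty_annotations()
  genome <- character(0)

  ## --- ancestral contig -------------------------------------------------
  anc_id <- "chrA"
  anc_len <- 40000L
  core <- c(10000L, 10000L + config$core_duplicon_length)
  anc <- random_dna(anc_len)
  sva_start <- core[2] - 2000L
  anc <- paste0(substr(anc, 1, sva_start),
                lib$entries[["SVA_A"]]$seq, lib$entries[["SVA_A"]]$transduction,
                substr(anc, sva_start + sva_len + td_len + 1L, anc_len))
  anc <- substr(anc, 1, anc_len)
  genome[anc_id] <- anc
  anc_ann <- rbind(
    repeat_annotation(anc_id, 1000L, 2500L, "+", "UBE3App", "UBE3App"),
    repeat_annotation(anc_id, 5000L, 5300L, "+", "Alu", "AluY"),
    repeat_annotation(anc_id, sva_start, sva_start + sva_len, "+", "SVA",
                      "SVA_A", consensus_end = sva_len),
    repeat_annotation(anc_id, sva_start + sva_len,
                      sva_start + sva_len + td_len, "+", "TD", "SVA_A_TD"),
    repeat_annotation(anc_id, 31000L, 31300L, "+", "Alu", "AluSx"),
    repeat_annotation(anc_id, 33500L, 33800L, "+", "Alu", "AluSg"))
  anns <- rbind(anns, anc_ann)

  ## breakpoints: 5' side in the upstream flank (UBE3App / Alu / unique),
  ## 3' side concentrated in the element (5), Alus (2) and unique (2),
  ## mirroring the observed census proportions
  pick_inside <- function(ann_row, k) sample_separated(
    k, ann_row$start + 30L, ann_row$end - 30L, 100L)
  n5u <- min(2L, config$n_bp5)
  n5a <- min(2L, config$n_bp5 - n5u)
  n5n <- config$n_bp5 - n5u - n5a
  bp5 <- sort(c(if (n5u) pick_inside(anc_ann[1, ], n5u),   # UBE3App
                if (n5a) pick_inside(anc_ann[2, ], n5a),   # Alu 5'
                if (n5n) sample_separated(n5n, 6000L, 9500L)))
  bp5_class <- vapply(bp5, function(x) {
    hit <- which(anc_ann$start <= x & x < anc_ann$end)
    if (length(hit)) anc_ann$family[hit[1]] else "none"
  }, character(1))
  n3s <- max(1L, round(5 / 9 * config$n_bp3))       # element-internal share
  n3a <- min(2L, config$n_bp3 - n3s)
  n3n <- config$n_bp3 - n3s - n3a
  bp3 <- sort(c(pick_inside(anc_ann[3, ], n3s),     # SVA
                if (n3a >= 1) pick_inside(anc_ann[5, ], 1L),   # AluSx
                if (n3a >= 2) pick_inside(anc_ann[6, ], 1L),   # AluSg
                if (n3n) sample_separated(n3n, 35000L, 39000L)))
  bp3_class <- vapply(bp3, function(x) {
    hit <- which(anc_ann$start <= x & x < anc_ann$end)
    if (length(hit)) anc_ann$family[hit[1]] else "none"
  }, character(1))
  stopifnot(length(bp5) == config$n_bp5, length(bp3) == config$n_bp3)

  ## --- L1 insertions ----------------------------------------------------
  l1_id <- "chrL"
  genome[l1_id] <- random_dna((config$n_l1 + 1L) * config$l1_spacing)
  offset <- 0L
  subfams <- rep(c("SVA_B", "SVA_D"), length.out = config$n_l1)
  for (i in seq_len(config$n_l1)) {
    site <- i * config$l1_spacing + offset
    tl <- rand_in(config$tsd_length_range)
    trunc <- if (i %% 3 == 0) rand_in(c(100L, 600L)) else 0L
    pa <- rand_in(config$polyA_range)
    res <- plant_l1_insertion(genome, lib, l1_id, site,
                              subfamily = subfams[i],
                              with_transduction = i %% 2 == 0,
                              truncate5 = trunc, tsd_length = tl,
                              tsd_mismatches = 0L, polyA_len = pa,
                              mu = config$mu, kappa = config$kappa)
    genome <- res$genome
    events[[length(events) + 1L]] <- res$event
    anns <- rbind(anns, res$annotations)
    offset <- offset + (res$event$tsd_right[2] - res$event$tsd_left[1]) -
      res$event$tsd_length
  }

  ## --- duplication copies ----------------------------------------------
  ## every distinct breakpoint used at least once
  n_cp <- config$n_duplication_copies
  a5 <- c(seq_len(config$n_bp5),
          sample(config$n_bp5, n_cp - config$n_bp5, replace = TRUE))
  a3 <- c(seq_len(config$n_bp3),
          sample(config$n_bp3, n_cp - config$n_bp3, replace = TRUE))
  a5 <- sample(a5); a3 <- sample(a3)
  for (i in seq_len(n_cp)) {
    cid <- sprintf("chrD%02d", i)
    genome[cid] <- random_dna(16000L)
    mh3 <- if (i %% 5 == 0) NA else rand_in(config$microhomology_range)
    res <- plant_duplication_block(
      genome, anc, bp5[a5[i]], bp3[a3[i]], cid, 8000L,
      name = sprintf("copy_%02d", i),
      mh5 = rand_in(config$microhomology_range), mh3 = mh3,
      ins3_len = rand_in(c(4L, 10L)),
      mu = config$mu, kappa = config$kappa)
    genome <- res$genome
    res$event$bp5_class <- bp5_class[a5[i]]
    res$event$bp3_class <- bp3_class[a3[i]]
    events[[length(events) + 1L]] <- res$event
    junctions <- c(junctions, res$junctions)
  }

  ## --- circular-integration cassettes ----------------------------------
  for (i in seq_len(config$n_cassettes)) {
    cid <- sprintf("chrC%d", i)
    genome[cid] <- random_dna(20000L)
    res <- plant_circular_integration(
      genome, lib, cid, 8000L, donor_interior = random_dna(3000L),
      pair = c("SVA_B", "SVA_D"), tsd_length = config$cassette_tsd_length,
      mu = config$mu, kappa = config$kappa)
    genome <- res$genome
    events[[length(events) + 1L]] <- res$event
    anns <- rbind(anns, res$annotations)
  }

  ## --- direct-repeat-flanked SDs ---------------------------------------
  for (i in seq_len(config$n_flanked_sd)) {
    cid <- sprintf("chrF%d", i)
    genome[cid] <- random_dna(30000L)
    mh2 <- if (i %% 2 == 0) NA else rand_in(config$microhomology_range)
    res <- plant_direct_repeat_sd(
      genome, cid, 12000L, insert_seq = random_dna(config$core_duplicon_length),
      flank_length = config$direct_repeat_flank_length,
      identity = config$flank_identity,
      mh1 = rand_in(config$microhomology_range), mh2 = mh2,
      ins2_len = rand_in(c(4L, 10L)), name = sprintf("sd_%d", i),
      kappa = config$kappa)
    genome <- res$genome
    events[[length(events) + 1L]] <- res$event
    junctions <- c(junctions, res$junctions)
  }

  structure(list(genome = genome,
                 ledger = list(events = events, junctions = junctions),
                 annotations = anns, library = lib,
                 ancestral = list(contig_id = anc_id, core = core,
                                  bp5 = bp5, bp5_class = bp5_class,
                                  bp3 = bp3, bp3_class = bp3_class),
                 config = config),
            class = "sva_sim")
}

#' @export
print.sva_sim <- function(x, ...) {
  cat(sprintf("sva_sim: %d contigs (%.2f Mb), %d events, %d junction records\n",
              length(x$genome), sum(nchar(x$genome)) / 1e6,
              length(x$ledger$events), length(x$ledger$junctions)))
  invisible(x)
}

#' Audit a simulation's ledger against its emitted genome
#'
#' Slices every recorded feature back out of the genome and checks
#' self-consistency: intervals in bounds, TSD copies identical up to the
#' planted mismatch count (at `mu` 0), direct-repeat flanks at the planted
#' identity, cassette structure reciprocal. Errors on first violation.
#'
#' @param sim an `"sva_sim"`.
#' @return TRUE, invisibly.
#' @export
audit_ledger <- function(sim) {
  g <- sim$genome
  mu <- sim$config$mu
  for (ev in sim$ledger$events) {
    n <- nchar(g[[ev$contig_id]])
    stopifnot(ev$start >= 0, ev$end <= n, ev$start <= ev$end)
    if (ev$type == "L1_insertion" && mu == 0) {
      l <- gslice(g, ev$contig_id, ev$tsd_left[1], ev$tsd_left[2])
      r <- gslice(g, ev$contig_id, ev$tsd_right[1], ev$tsd_right[2])
      if (hamming(l, r) > ev$tsd_mismatches)
        stop("TSD audit failed for event at ", ev$start)
    }
    if (ev$type == "direct_repeat_SD") {
      l <- gslice(g, ev$contig_id, ev$left_repeat[1], ev$left_repeat[2])
      r <- gslice(g, ev$contig_id, ev$right_repeat[1], ev$right_repeat[2])
      if (hamming(l, r) != ev$realized_mismatches)
        stop("direct-repeat audit failed for ", ev$name)
    }
    if (ev$type == "circular_integration" && mu == 0) {
      ol <- gslice(g, ev$contig_id, ev$outer_tsd_left[1], ev$outer_tsd_left[2])
      or <- gslice(g, ev$contig_id, ev$outer_tsd_right[1], ev$outer_tsd_right[2])
      il <- gslice(g, ev$contig_id, ev$inner_tsd_left[1], ev$inner_tsd_left[2])
      ir <- gslice(g, ev$contig_id, ev$inner_tsd_right[1], ev$inner_tsd_right[2])
      if (ol != or || il != ir) stop("cassette TSD audit failed")
    }
  }
  for (jx in sim$ledger$junctions) {
    if (mu > 0) break
    obs <- gslice(g, jx$contig_id, jx$window_start, jx$window_end)
    call <- characterize_junction(jx$left_donor, jx$right_donor, obs)
    if (call$microhomology_len != jx$mh ||
        nchar(call$inserted_seq) != jx$inserted_len)
      stop("junction audit failed for ", jx$id)
  }
  invisible(TRUE)
}

#' Write a simulation to disk
#'
#' Emits genome FASTA, annotations (BED6 and RepeatMasker-style .out), the
#' truth ledger as JSON, junction-donor table as TSV, and the config.
#'
#' @param sim an `"sva_sim"`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_bed(sim$annotations, file.path(dir, "annotations.bed"),
            contig_lengths = nchar(sim$genome))
  write_repeatmasker_out(sim$annotations, sim$genome,
                         file.path(dir, "annotations.out"))
  jsonlite::write_json(
    list(events = sim$ledger$events,
         ancestral = sim$ancestral),
    file.path(dir, "ledger.json"), auto_unbox = TRUE, digits = NA, null = "null")
  jx <- sim$ledger$junctions
  if (length(jx)) {
    df <- do.call(rbind, lapply(jx, function(j) as.data.frame(
      j[c("id", "contig_id", "seam", "window_start", "window_end",
          "left_donor", "right_donor", "mh", "inserted_len",
          "event_type", "event_name", "side")])))
    utils::write.table(df, file.path(dir, "junctions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cfg <- sim$config
  writeLines(vapply(names(unclass(cfg)), function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")), character(1)),
    file.path(dir, "config.txt"))
  invisible(dir)
}
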