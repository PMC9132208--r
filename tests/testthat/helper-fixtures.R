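# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; nothing is read from disk.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# lazily-built small simulation shared across test files (mu = 0)
.fixture_env <- new.env()

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 42, n_l1 = 6, n_duplication_copies = 10,
                      n_bp5 = 4, n_bp3 = 5, n_cassettes = 1, n_flanked_sd = 2,
                      tsd_length_range = c(8, 16), mu = 0)
    .fixture_env$sim <- simulate_genome(cfg)
  }
  .fixture_env$sim
}

small_library <- function() {
  if (is.null(.fixture_env$lib))
    .fixture_env$lib <- make_element_library(seed = 7, n_subfamilies = 4,
                                             n_diagnostic_sites = 20)
  .fixture_env$lib
}

# ---- brute-force TSD oracle: enumerate ALL flank substring pairs ----------
oracle_tsd <- function(genome, insertion, max_window = 20L, min_len = 5L,
                       max_mismatch_frac = 0.2) {
  s <- genome[[insertion$contig_id]]
  n <- nchar(s)
  wl <- min(max_window, insertion$start)
  wr <- min(max_window, n - insertion$end)
  left <- chars(substr(s, insertion$start - wl + 1L, insertion$start))
  right <- chars(substr(s, insertion$end + 1L, insertion$end + wr))
  best <- NULL
  for (o1 in 0:(wl - min_len)) for (o2 in 0:(wr - min_len)) {
    for (l in min_len:min(wl - o1, wr - o2)) {
      a <- left[(wl - o1 - l + 1):(wl - o1)]
      b <- right[(o2 + 1):(o2 + l)]
      mm <- sum(a != b)
      if (mm > floor(max_mismatch_frac * l)) next
      cand <- c(l = l, mm = mm, off = o1 + o2)
      better <- is.null(best) || cand["l"] > best["l"] ||
        (cand["l"] == best["l"] && (cand["mm"] < best["mm"] ||
          (cand["mm"] == best["mm"] && cand["off"] < best["off"])))
      if (better) best <- cand
    }
  }
  best
}

# ---- brute-force junction oracle: overlap scan over all suffix/prefix ----
oracle_junction <- function(left_donor, right_donor, observed) {
  n <- nchar(observed)
  k <- 0L
  for (t in seq_len(min(n, nchar(left_donor))))
    if (substr(observed, 1, t) == substr(left_donor, 1, t)) k <- t else break
  r <- 0L
  for (t in seq_len(min(n, nchar(right_donor)))) {
    if (substr(observed, n - t + 1L, n) ==
        substr(right_donor, nchar(right_donor) - t + 1L, nchar(right_donor)))
      r <- t else break
  }
  mh <- k + r - n
  if (mh >= 0) list(mh = mh, ins = 0L)
  else list(mh = 0L, ins = n - r - k)
}

# ---- quadratic brute-force direct-repeat oracle (all diagonals, scalar) ---
oracle_flank_hits <- function(seq, min_len = 1000L, min_identity = 0.9,
                              max_insert = 50000L) {
  n <- nchar(seq)
  ch <- chars(seq)
  valid <- ch %in% c("A", "C", "G", "T")
  cands <- list()
  for (d in seq_len(n - 1L)) {
    if (max(min_len, d - max_insert) > min(d, n - d)) next
    tmax <- n - d
    eq <- ch[seq_len(tmax)] == ch[seq_len(tmax) + d] &
      valid[seq_len(tmax)] & valid[seq_len(tmax) + d]
    # scalar Kadane with first-maximum tie-break
    bestgain <- 0; besta <- 0L; bestb <- 0L
    S <- 0; minS <- 0; argmin <- 0L
    curbesta <- 1L
    for (t in seq_len(tmax)) {
      S <- S + if (eq[t]) 1 else -3
      if (S - minS > bestgain) { bestgain <- S - minS; besta <- argmin + 1L
                                 bestb <- t }
      if (S < minS) { minS <- S; argmin <- t }
    }
    if (bestgain <= 0) next
    a <- besta; b <- bestb
    if (b - a + 1L > d) b <- a + d - 1L
    k <- 8L
    while (b - a + 1L >= k && !all(eq[(b - k + 1L):b])) b <- b - 1L
    while (b - a + 1L >= k && !all(eq[a:(a + k - 1L)])) a <- a + 1L
    if (b - a + 1L < k) next
    L <- b - a + 1L
    if (L < min_len) next
    gap <- d - L
    if (gap < 0 || gap > max_insert) next
    mism <- sum(!eq[a:b])
    identity <- 1 - mism / L
    if (identity < min_identity) next
    cands[[length(cands) + 1L]] <- data.frame(a = a, b = b, d = d, L = L,
                                              identity = identity)
  }
  if (!length(cands)) return(NULL)
  df <- do.call(rbind, cands)
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
  rownames(kept) <- NULL
  kept
}

# ---- exact Steiner length oracle (Dreyfus-Wagner over the median closure,
#      binary site encoding) ------------------------------------------------
.pc_tab <- vapply(0:1023, function(x) {
  s <- 0L
  while (x > 0) { s <- s + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  s
}, integer(1))

popcount <- function(x) .pc_tab[x + 1L]

hap_to_bits <- function(h) {
  ch <- chars(h)
  states <- sort(unique(ch))
  stopifnot(length(states) <= 2)
  sum(bitwShiftL(as.integer(ch == states[length(states)]), seq_along(ch) - 1L))
}

haps_to_bits <- function(haps) {
  m <- do.call(rbind, strsplit(haps, "", fixed = TRUE))
  vapply(seq_along(haps), function(i) {
    bits <- vapply(seq_len(ncol(m)), function(j) {
      states <- sort(unique(m[, j]))
      as.integer(m[i, j] == states[length(states)])
    }, integer(1))
    sum(bitwShiftL(bits, seq_along(bits) - 1L))
  }, integer(1))
}

median_closure_bits <- function(terms) {
  V <- unique(terms)
  repeat {
    n <- length(V)
    if (n < 3 || n > 400) break
    new <- integer(0)
    cmb <- utils::combn(n, 3)
    for (ci in seq_len(ncol(cmb))) {
      i <- cmb[1, ci]; j <- cmb[2, ci]; k <- cmb[3, ci]
      new <- c(new, bitwOr(bitwOr(bitwAnd(V[i], V[j]), bitwAnd(V[i], V[k])),
                           bitwAnd(V[j], V[k])))
    }
    new <- setdiff(unique(new), V)
    if (!length(new)) break
    V <- c(V, new)
  }
  V
}

oracle_steiner_length <- function(terms) {
  terms <- unique(terms)
  t <- length(terms)
  if (t == 2) return(popcount(bitwXor(terms[1], terms[2])))
  V <- median_closure_bits(terms)
  nv <- length(V)
  D <- outer(V, V, function(a, b) popcount(bitwXor(a, b)))
  ti <- match(terms, V)
  full <- bitwShiftL(1L, t) - 1L
  dp <- matrix(Inf, full, nv)
  for (i in seq_len(t)) dp[bitwShiftL(1L, i - 1L), ] <- D[ti[i], ]
  for (mask in seq_len(full)) {
    if (popcount(mask) < 2) next
    m <- rep(Inf, nv)
    sub <- bitwAnd(mask - 1L, mask)
    while (sub > 0) {
      other <- bitwXor(mask, sub)
      if (other > 0) m <- pmin(m, dp[sub, ] + dp[other, ])
      sub <- bitwAnd(sub - 1L, mask)
    }
    dp[mask, ] <- pmin(dp[mask, ], apply(D + m, 2, min))
  }
  min(dp[full, ti])
}

# genealogy-style haplotype instance: mutations on a random tree of lineages,
# with optional recurrent hits of the same site
gen_haplotype_instance <- function(n_hap, n_sites, n_recurrent = 0L) {
  haps <- list(rep("A", n_sites))
  while (length(haps) < n_hap) {
    h <- haps[[sample(length(haps), 1)]]
    for (k in seq_len(sample(1:2, 1))) {
      p <- sample(n_sites, 1)
      h[p] <- if (h[p] == "A") "T" else "A"
    }
    haps[[length(haps) + 1L]] <- h
  }
  for (k in seq_len(n_recurrent)) {
    i <- sample(length(haps), 1)
    p <- sample(n_sites, 1)
    haps[[i]][p] <- if (haps[[i]][p] == "A") "T" else "A"
  }
  unique(vapply(haps, paste, character(1), collapse = ""))
}

# MST length over haplotype strings (Prim, independent of the package's)
oracle_mst_length <- function(haps) {
  k <- length(haps)
  if (k < 2) return(0L)
  m <- do.call(rbind, strsplit(haps, "", fixed = TRUE))
  d <- matrix(0L, k, k)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k))
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  intree <- 1L
  key <- d[1, ]; key[1] <- Inf
  tot <- 0L
  for (s in seq_len(k - 1)) {
    v <- which.min(key)
    tot <- tot + key[v]
    key <- pmin(key, d[v, ])
    key[c(intree, v)] <- Inf
    intree <- c(intree, v)
  }
  tot
}

# ---- phylogenetic simulation helpers -------------------------------------
# two-group alignment with a planted recombination switch (or not)
sim_groups_alignment <- function(recombinant, n_per_group = 5, seg_len = 1000,
                                 tip = 0.002, stem = 0.0075, nest = 0.0075) {
  a_tips <- paste0("A", seq_len(n_per_group))
  b_tips <- paste0("B", seq_len(n_per_group))
  tipstr <- function(x) paste(sprintf("%s:%f", x, tip), collapse = ",")
  ## clonal history: the two groups are sister clades under long stems
  t1 <- ape::read.tree(text = sprintf("((%s):%f,(%s):%f,OUT:%f);",
                                      tipstr(a_tips), stem,
                                      tipstr(b_tips), stem, 0))
  ## recombinant 3' history: the B clade is nested INSIDE the A radiation
  ## (sister to a structured A subgroup), under a shared stem that yields
  ## shared-derived substitutions in both groups
  k <- ceiling(n_per_group / 2)
  t2 <- ape::read.tree(text = sprintf(
    "(((%s):%f,((%s):%f,(%s):%f):%f):%f,OUT:%f);",
    tipstr(a_tips[seq_len(k)]), nest,
    tipstr(a_tips[seq(k + 1, n_per_group)]), nest,
    tipstr(b_tips), nest, nest, stem, 0))
  seg5 <- simulate_on_tree(t1, len = seg_len)
  seg3 <- simulate_on_tree(if (recombinant) t2 else t1, len = seg_len)
  rows <- paste0(seg5[c(a_tips, b_tips, "OUT")],
                 seg3[c(a_tips, b_tips, "OUT")])
  names(rows) <- c(a_tips, b_tips, "OUT")
  ## label order matters: "A16" sorts first and is the focal group
  groups <- stats::setNames(rep(c("A16", "B13"), each = n_per_group),
                            c(a_tips, b_tips))
  list(aln = msa(rows, groups, "OUT"), switch_point = seg_len)
}

# full-size acceptance world (criterion 1/2); cached per mu
acceptance_sim <- function(mu) {
  key <- paste0("acc", mu * 100)
  if (is.null(.fixture_env[[key]])) {
    cfg <- sim_config(seed = 20220516, mu = mu, tsd_length_range = c(8, 16))
    .fixture_env[[key]] <- simulate_genome(cfg)
  }
  .fixture_env[[key]]
}

acceptance_run <- function(mu) {
  key <- paste0("accrun", mu * 100)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_pipeline(acceptance_sim(mu))
  .fixture_env[[key]]
}
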