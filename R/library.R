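## Consensus library for composite retrotransposons: a base consensus with the
## four-domain structure (TCTCCC hexamer repeats, Alu-like body, VNTR of
## 30-50 bp units, SINE-R), plus subfamily consensi that differ from the base
## at recorded diagnostic sites. Diagnostic sites never fall in the VNTR,
## whose internal repetitiveness makes it unalignable in real data.

#' Build a consensus library of composite-element subfamilies
#'
#' The base consensus carries the canonical four-domain layout: a run of
#' TCTCCC hexamers, an ~300 bp Alu-like domain, a VNTR of near-identical
#' 30-50 bp units, and an ~500 bp SINE-R. The first subfamily is the base
#' itself; every further subfamily differs from the base at exactly
#' `n_diagnostic_sites` positions, all outside the VNTR, recorded per
#' subfamily pair in `diagnostic_sites`.
#'
#' @param seed RNG seed (mandatory; reproducibility).
#' @param n_subfamilies number of subfamilies, >= 2.
#' @param n_diagnostic_sites substitutions separating each non-base subfamily
#'   from the base.
#' @param subfamily_names optional character vector of names (default
#'   SVA_A, SVA_B, ...).
#' @param hexamer_copies number of TCTCCC units at the 5' end.
#' @param alu_like_length,sine_r_length domain lengths (bp).
#' @param vntr_unit_length,vntr_copies VNTR unit size range and copy number.
#' @param transduction_length length of the 3' transduction sequence attached
#'   to the library (genomic sequence co-mobilized past the element polyA).
#' @return object of class `"consensus_library"`: list with `entries`
#'   (per-subfamily `seq`, `domains`, `transduction`), `diagnostic_sites`
#'   (per ordered pair "A|B": data.frame pos (0-based on consensus), stateA,
#'   stateB), `base_domains`, `vntr_span`.
#' @export
make_element_library <- function(seed, n_subfamilies = 2, n_diagnostic_sites = 20,
                                 subfamily_names = NULL,
                                 hexamer_copies = 5, alu_like_length = 300,
                                 sine_r_length = 500, vntr_unit_length = c(30, 50),
                                 vntr_copies = 10, transduction_length = 300) {
  stopifnot(n_subfamilies >= 2)
  set.seed(seed)
  hexamer <- strrep("TCTCCC", hexamer_copies)
  alu_like <- random_dna(alu_like_length)
  unit_len <- sample(seq(vntr_unit_length[1], vntr_unit_length[2]), 1)
  unit <- random_dna(unit_len)
  ## near-identical units: one substitution per unit copy after the first
  vntr_units <- c(unit, vapply(seq_len(vntr_copies - 1), function(i) {
    ch <- seq_chars(unit)
    p <- sample(length(ch), 1)
    ch[p] <- mutate_base(ch[p], 2)
    paste(ch, collapse = "")
  }, character(1)))
  vntr <- paste(vntr_units, collapse = "")
  sine_r <- random_dna(sine_r_length)
  base <- paste0(hexamer, alu_like, vntr, sine_r)

  b <- cumsum(c(0L, nchar(hexamer), nchar(alu_like), nchar(vntr), nchar(sine_r)))
  domains <- data.frame(domain = c("hexamer", "Alu-like", "VNTR", "SINE-R"),
                        start = b[1:4], end = b[2:5], stringsAsFactors = FALSE)
  vntr_span <- c(b[3], b[4])
  non_vntr <- c(seq_len(b[3]), seq(b[4] + 1L, b[5]))  # 1-based positions
  if (n_diagnostic_sites > length(non_vntr))
    stop("n_diagnostic_sites exceeds non-VNTR consensus length")

  if (is.null(subfamily_names))
    subfamily_names <- paste0("SVA_", LETTERS[seq_len(n_subfamilies)])
  transduction <- random_dna(transduction_length)

  ## disjoint site sets so every pair of subfamilies differs at all its sites
  pool <- sample(non_vntr)
  entries <- list()
  site_sets <- list()
  entries[[subfamily_names[1]]] <- list(seq = base, domains = domains,
                                        transduction = transduction)
  site_sets[[subfamily_names[1]]] <- integer(0)
  used <- 0L
  for (i in seq(2, n_subfamilies)) {
    if (used + n_diagnostic_sites > length(pool))
      stop("n_diagnostic_sites exceeds non-VNTR consensus length")
    sites <- if (n_diagnostic_sites > 0)
      sort(pool[used + seq_len(n_diagnostic_sites)]) else integer(0)
    used <- used + n_diagnostic_sites
    ch <- seq_chars(base)
    for (p in sites) ch[p] <- mutate_base(ch[p], 2)
    entries[[subfamily_names[i]]] <- list(seq = paste(ch, collapse = ""),
                                          domains = domains,
                                          transduction = transduction)
    site_sets[[subfamily_names[i]]] <- sites
  }

  diagnostic_sites <- list()
  for (i in seq_len(n_subfamilies - 1)) {
    for (j in seq(i + 1, n_subfamilies)) {
      a <- subfamily_names[i]; bn <- subfamily_names[j]
      pos <- sort(union(site_sets[[a]], site_sets[[bn]]))
      if (length(pos)) {
        sa <- seq_chars(entries[[a]]$seq)[pos]
        sb <- seq_chars(entries[[bn]]$seq)[pos]
        keep <- sa != sb
        diagnostic_sites[[paste(a, bn, sep = "|")]] <-
          data.frame(pos = pos[keep] - 1L, stateA = sa[keep], stateB = sb[keep],
                     stringsAsFactors = FALSE)
      } else {
        diagnostic_sites[[paste(a, bn, sep = "|")]] <-
          data.frame(pos = integer(0), stateA = character(0),
                     stateB = character(0), stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(entries = entries, diagnostic_sites = diagnostic_sites,
                 base_domains = domains, vntr_span = vntr_span),
            class = "consensus_library")
}

#' @export
print.consensus_library <- function(x, ...) {
  cat(sprintf("consensus_library: %d subfamilies (%s), consensus %d bp\n",
              length(x$entries), paste(names(x$entries), collapse = ", "),
              nchar(x$entries[[1]]$seq)))
  invisible(x)
}

## diagnostic sites for an unordered subfamily pair, with states oriented
## so stateA belongs to `a`
diag_sites_for <- function(library, a, b) {
  key <- paste(a, b, sep = "|")
  if (!is.null(library$diagnostic_sites[[key]])) return(library$diagnostic_sites[[key]])
  key2 <- paste(b, a, sep = "|")
  ds <- library$diagnostic_sites[[key2]]
  if (is.null(ds)) stop("no diagnostic sites recorded for pair ", a, "/", b)
  data.frame(pos = ds$pos, stateA = ds$stateB, stateB = ds$stateA,
             stringsAsFactors = FALSE)
}
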