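#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Strict reverse complement over the \{A,C,G,T,N\} alphabet. An involution:
#' `revcomp(revcomp(x)) == x`.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## split a DNA string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## vectorized substring sampling of random DNA
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## is `b` a transition partner of `a`? (A<->G, C<->T)
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

## pick a substitute base: transitions get weight kappa, each transversion 1
mutate_base <- function(base, kappa) {
  partners <- setdiff(DNA_BASES, base)
  w <- ifelse(is_transition(base, partners), kappa, 1)
  sample(partners, 1, prob = w)
}

#' Mutate a sequence under a two-rate substitution model
#'
#' Per-site i.i.d. substitutions at rate `mu`; at a substituted site the
#' transition is chosen with weight `kappa` against 1 for each of the two
#' transversions. No indels, so coordinates are preserved exactly.
#'
#' @param seq DNA string.
#' @param mu per-site substitution probability in \[0, 0.2\].
#' @param kappa transition/transversion weight, > 0.
#' @return list with `seq` (mutated string) and `sites` (0-based positions hit).
#' @export
mutate_sequence <- function(seq, mu, kappa = 2) {
  stopifnot(mu >= 0, mu <= 0.2, kappa > 0)
  if (mu == 0 || nchar(seq) == 0L) {
    return(list(seq = seq, sites = integer(0)))
  }
  ch <- seq_chars(seq)
  hit <- which(stats::runif(length(ch)) < mu & ch %in% DNA_BASES)
  for (i in hit) ch[i] <- mutate_base(ch[i], kappa)
  list(seq = paste(ch, collapse = ""), sites = hit - 1L)
}

## 0-based half-open interval constructor (plain list; data.frames hold batches)
interval <- function(contig_id, start, end, strand = "+") {
  stopifnot(start >= 0, start <= end, strand %in% c("+", "-"))
  list(contig_id = contig_id, start = as.integer(start), end = as.integer(end),
       strand = strand)
}

## slice genome sequence by 0-based half-open coordinates
gslice <- function(genome, contig_id, start, end) {
  substr(genome[[contig_id]], start + 1L, end)
}

## insert `insert` into string `s` at 0-based position `pos` (before s[pos])
str_insert <- function(s, pos, insert) {
  paste0(substr(s, 1L, pos), insert, substr(s, pos + 1L, nchar(s)))
}

## hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(seq_chars(a) != seq_chars(b))
}

## longest common prefix length of two strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- seq_chars(substr(a, 1, n)); cb <- seq_chars(substr(b, 1, n))
  neq <- which(ca != cb)
  if (length(neq) == 0L) n else neq[1] - 1L
}

## longest common suffix length
common_suffix_len <- function(a, b) {
  common_prefix_len(paste(rev(seq_chars(a)), collapse = ""),
                    paste(rev(seq_chars(b)), collapse = ""))
}
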