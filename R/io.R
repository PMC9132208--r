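## Readers/writers for the standard plain-text formats every module consumes.
## Internal coordinates are 0-based half-open everywhere; 1-based formats
## (RepeatMasker .out) are converted at the boundary.

#' Read a multi-record FASTA file of DNA contigs
#'
#' Sequences are case-folded to upper case and U is mapped to T. Characters
#' outside \{A,C,G,T,N\} are rejected with the 0-based offset of the first
#' offender within its record.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase DNA string per record,
#'   in file order. Names are the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0L || !any(hdr)) stop("no records in ", path)
  if (!hdr[1]) stop("malformed FASTA: sequence before first header")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids)) stop("duplicate contig id: ", ids[duplicated(ids)][1])
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1), collapse = "")
  out <- character(length(ids))
  names(out) <- ids
  present <- as.integer(names(seqs))
  out[present] <- seqs
  out <- toupper(out)
  out <- chartr("U", "T", out)
  bad <- regexpr("[^ACGTN]", out)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character '%s' in record '%s' at offset %d",
                 substr(out[i], bad[i], bad[i]), ids[i], bad[i] - 1L))
  }
  if (any(!nzchar(out))) stop("empty sequence for record '", ids[!nzchar(out)][1], "'")
  names(out) <- ids
  out
}

#' Write contigs to FASTA
#'
#' @param genome named character vector of DNA strings.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    writeLines(paste0(">", id), con)
    s <- genome[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## empty annotation table with the canonical column set
empty_annotations <- function() {
  data.frame(contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), family = character(0),
             subfamily = character(0), consensus_start = integer(0),
             consensus_end = integer(0), divergence_pct = numeric(0),
             stringsAsFactors = FALSE)
}

#' Construct a repeat-annotation table
#'
#' The in-memory form of a set of repeat intervals: one row per annotated
#' repeat, 0-based half-open genome coordinates, 1-based inclusive consensus
#' coordinates (the RepeatMasker convention for positions on the subfamily
#' consensus).
#'
#' @param contig_id,start,end,strand interval fields (0-based half-open).
#' @param family repeat family (e.g. "SVA", "Alu", "L1").
#' @param subfamily subfamily name (e.g. "SVA_D").
#' @param consensus_start,consensus_end 1-based positions on the consensus.
#' @param divergence_pct percent divergence from consensus, in \[0, 100\].
#' @return data.frame with one row per annotation.
#' @export
repeat_annotation <- function(contig_id, start, end, strand = "+",
                              family = "SVA", subfamily = family,
                              consensus_start = 1L,
                              consensus_end = pmax(1L, end - start),
                              divergence_pct = 0) {
  stopifnot(all(start >= 0), all(start <= end),
            all(consensus_start <= consensus_end),
            all(divergence_pct >= 0 & divergence_pct <= 100))
  data.frame(contig_id = contig_id, start = as.integer(start),
             end = as.integer(end), strand = strand, family = family,
             subfamily = subfamily,
             consensus_start = as.integer(consensus_start),
             consensus_end = as.integer(consensus_end),
             divergence_pct = divergence_pct, stringsAsFactors = FALSE)
}

#' Parse a RepeatMasker .out file
#'
#' Accepts the standard dialect: three header lines followed by
#' whitespace-separated hit lines. 1-based inclusive query coordinates are
#' converted to 0-based half-open; orientation "C" maps to strand "-", for
#' which the repeat coordinates are given as (left) end begin and are
#' reordered. The class/family column is split on "/" into family;
#' the repeat name column becomes the subfamily.
#'
#' @param path path to a .out file.
#' @return annotation data.frame (see [repeat_annotation()]).
#' @export
parse_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a RepeatMasker .out file (needs 3 header lines)")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 14L)
      stop(sprintf("malformed .out line %d: expected >=14 columns, got %d",
                   i + 3L, length(f)))
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    unparen <- function(x) as.integer(gsub("[()]", "", x))
    if (strand == "+") {
      cs <- unparen(f[12]); ce <- unparen(f[13])
    } else {
      ## minus-strand layout: (left) end begin
      cs <- unparen(f[14]); ce <- unparen(f[13])
    }
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    family <- if (length(cf) > 1) cf[2] else cf[1]
    data.frame(contig_id = f[5], start = as.integer(f[6]) - 1L,
               end = as.integer(f[7]), strand = strand, family = family,
               subfamily = f[10], consensus_start = cs, consensus_end = ce,
               divergence_pct = as.numeric(f[2]), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(empty_annotations()), rows))
}

#' Write annotations as a RepeatMasker-style .out file
#'
#' Inverse of [parse_repeatmasker_out()] on the fields the package uses;
#' the round trip reproduces begin/end exactly.
#'
#' @param annotations annotation data.frame.
#' @param genome named character vector (for the (left) field).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(annotations, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family   begin end (left)  ID",
    ""), con)
  if (nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      a <- annotations[i, ]
      qleft <- nchar(genome[[a$contig_id]]) - a$end
      clen <- a$consensus_end  # consensus length unknown; (left) emitted as 0
      if (a$strand == "+") {
        rep_cols <- sprintf("%d %d (0)", a$consensus_start, a$consensus_end)
        ori <- "+"
      } else {
        rep_cols <- sprintf("(0) %d %d", a$consensus_end, a$consensus_start)
        ori <- "C"
      }
      writeLines(sprintf("%5d %6.1f %4.1f %4.1f %s %d %d (%d) %s %s %s/%s %s %d",
                         1000L, a$divergence_pct, 0, 0, a$contig_id,
                         a$start + 1L, a$end, qleft, ori, a$subfamily,
                         a$family, a$family, rep_cols, i), con)
    }
  }
  invisible(path)
}

#' Write annotations to BED6
#'
#' name = family:subfamily; score = round(divergence_pct * 10);
#' 0-based half-open coordinates.
#'
#' @param annotations annotation data.frame.
#' @param path output path.
#' @param contig_lengths optional named integer vector; when given, intervals
#'   out of contig bounds raise an error.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotations, path, contig_lengths = NULL) {
  if (!is.null(contig_lengths) && nrow(annotations)) {
    len <- contig_lengths[annotations$contig_id]
    if (any(is.na(len)) || any(annotations$end > len))
      stop("annotation interval out of contig bounds")
  }
  if (nrow(annotations) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t%d\t%s",
                   annotations$contig_id, annotations$start, annotations$end,
                   annotations$family, annotations$subfamily,
                   as.integer(round(annotations$divergence_pct * 10)),
                   annotations$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file into an annotation table
#'
#' @param path BED6 path (name column "family:subfamily").
#' @return annotation data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_annotations())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  fam <- do.call(rbind, lapply(strsplit(f[, 4], ":", fixed = TRUE), function(x)
    c(x[1], if (length(x) > 1) x[2] else x[1])))
  repeat_annotation(contig_id = f[, 1], start = as.integer(f[, 2]),
                    end = as.integer(f[, 3]), strand = f[, 6],
                    family = fam[, 1], subfamily = fam[, 2],
                    divergence_pct = as.numeric(f[, 5]) / 10)
}

#' Read an aligned FASTA plus group labels into an alignment object
#'
#' @param path aligned FASTA (rows equal gapped length; gaps "-").
#' @param groups named character vector or two-column data.frame (id, group)
#'   mapping every row id to a group label.
#' @param outgroup_id id of the outgroup row.
#' @return object of class `"msa"`: list with `rows` (named character vector of
#'   gapped strings), `groups`, `outgroup_id`.
#' @export
read_alignment <- function(path, groups, outgroup_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1), collapse = "")
  names(seqs) <- ids
  if (is.data.frame(groups)) groups <- stats::setNames(groups[[2]], groups[[1]])
  msa(toupper(seqs), groups, outgroup_id)
}

#' Construct a multiple-alignment object
#'
#' @param rows named character vector of equal-length gapped strings.
#' @param groups named character vector mapping row ids to group labels.
#' @param outgroup_id id of the outgroup row (must be present in `rows`).
#' @return object of class `"msa"`.
#' @export
msa <- function(rows, groups = NULL, outgroup_id = NULL) {
  stopifnot(length(unique(nchar(rows))) == 1L, !is.null(names(rows)))
  if (!is.null(outgroup_id) && !outgroup_id %in% names(rows))
    stop("outgroup '", outgroup_id, "' not among alignment rows")
  if (!is.null(groups) && !all(names(rows) %in% c(names(groups), outgroup_id)))
    stop("every non-outgroup row needs a group label")
  structure(list(rows = rows, groups = groups, outgroup_id = outgroup_id),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows x %d columns; outgroup: %s\n", length(x$rows),
              nchar(x$rows[1]), x$outgroup_id %||% "<none>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## per-row map from gapped column (1-based) to ungapped coordinate (0-based
## half-open start of the base; gap columns get the coordinate of the next base)
ungapped_map <- function(gapped_row) {
  ch <- seq_chars(gapped_row)
  cumsum(ch != "-") - 1L
}

#' Read a flat key=value config file
#'
#' One `key = value` pair per line; `#` comments; values parsed as integer,
#' numeric, logical or string; comma-separated values become vectors.
#'
#' @param path config path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) {
      if (all(num == round(num))) as.integer(num) else num
    } else if (all(parts %in% c("true", "false", "TRUE", "FALSE"))) {
      toupper(parts) == "TRUE"
    } else parts
  }
  out
}
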