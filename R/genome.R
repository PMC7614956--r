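#' Read a genome from a FASTA file
#'
#' Loads named DNA sequences and normalizes them for downstream guide design:
#' sequences are uppercased and RNA-style `U` is mapped to `T`. Any character
#' outside `A`, `C`, `G`, `T`, `N` is rejected with the offending record named.
#'
#' @param path Path to a FASTA file.
#' @return A `genome` object: a named character vector of uppercase DNA
#'   sequences, one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  x <- as.character(seqs)
  # FASTA headers keep only the first word, as aligners do
  names(x) <- sub("\\s.*$", "", names(seqs))
  as_genome(x)
}

#' Construct a genome object from named sequences
#'
#' @param x Named character vector of DNA sequences.
#' @return A validated `genome` object (uppercase, U mapped to T).
#' @export
as_genome <- function(x) {
  if (length(x) == 0L) stop("no records: a genome needs at least one sequence")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("every genome sequence needs a name")
  if (anyDuplicated(names(x)))
    stop("duplicate sequence names: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    rec <- names(x)[bad][1L]
    ch <- regmatches(x[bad][1L], regexpr("[^ACGTN]", x[bad][1L]))
    stop("record '", rec, "' contains invalid character '", ch,
         "': only A, C, G, T, N allowed")
  }
  if (any(!nzchar(x)))
    stop("record '", names(x)[!nzchar(x)][1L], "' is empty")
  structure(x, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "sequence(s),",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  n <- min(length(x), 6L)
  for (i in seq_len(n))
    cat(" ", names(x)[i], ":", nchar(x[[i]]), "bp\n")
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' Write a genome to FASTA
#'
#' @param genome A `genome` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

FEATURE_TYPES <- c("ORF", "SUT", "CUT")

#' Read a TSS-anchored feature annotation (BED-like TSV)
#'
#' Expects six whitespace- or tab-separated columns: chrom, start, end,
#' feature_id, feature_type, strand. Coordinates on disk are BED-style
#' (0-based, half-open); in memory the package uses 1-based closed intervals.
#' The transcription start site (TSS) is derived from the span: the leftmost
#' base for `+` features, the rightmost for `-` features.
#'
#' @param path Path to the annotation file. Lines starting with `#` or a
#'   `track` line are skipped.
#' @return A `data.frame` with columns `feature_id`, `feature_type`, `chrom`,
#'   `strand`, `tss`, `start`, `end` (1-based closed).
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature annotation not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L) stop("no feature records in ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  ncol_ok <- lengths(parts) >= 6L
  if (any(!ncol_ok))
    stop("line ", which(!ncol_ok)[1L], ": expected 6 columns ",
         "(chrom start end feature_id feature_type strand)")
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start0) || anyNA(end0))
    stop("non-integer coordinates in ", path)
  bad <- start0 >= end0
  if (any(bad))
    stop("feature '", m[bad, 4][1L], "': start >= end (BED half-open expected)")
  type <- m[, 5]
  if (any(!type %in% FEATURE_TYPES))
    stop("unknown feature_type '", setdiff(type, FEATURE_TYPES)[1L],
         "': must be one of ", paste(FEATURE_TYPES, collapse = ", "))
  strand <- m[, 6]
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(m[, 4]))
    stop("duplicate feature_id: ", m[, 4][duplicated(m[, 4])][1L])
  feats <- data.frame(
    feature_id = m[, 4],
    feature_type = type,
    chrom = m[, 1],
    strand = strand,
    # BED [start0, end0) -> 1-based closed [start0+1, end0]
    start = start0 + 1L,
    end = end0,
    stringsAsFactors = FALSE
  )
  feats$tss <- ifelse(feats$strand == "+", feats$start, feats$end)
  feats[, c("feature_id", "feature_type", "chrom", "strand", "tss",
            "start", "end")]
}

#' Write a feature annotation back to BED-like TSV
#'
#' Inverse of [read_features()]: 1-based closed spans are written as BED
#' 0-based half-open coordinates.
#'
#' @param features Feature `data.frame` as returned by [read_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  out <- data.frame(
    chrom = features$chrom,
    start = features$start - 1L,
    end = features$end,
    feature_id = features$feature_id,
    feature_type = features$feature_type,
    strand = features$strand
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

ORIENTATION_CLASSES <- c("antisense_overlapping", "divergent", "convergent",
                         "tandem_upstream", "tandem_downstream",
                         "sense_overlapping")

#' Classify the orientation of a feature relative to a query position
#'
#' Classifies a neighboring feature by strand and position relative to a
#' strand-aware query point (typically a guide's cut site). Classes:
#' \describe{
#'   \item{antisense_overlapping}{opposite strand, span contains the query}
#'   \item{divergent}{opposite strand, not overlapping, transcribing away
#'     from the query (bidirectional-promoter candidate)}
#'   \item{convergent}{opposite strand, not overlapping, transcribing toward
#'     the query}
#'   \item{sense_overlapping}{same strand, span contains the query}
#'   \item{tandem_upstream}{same strand, feature TSS downstream of the query
#'     in the query's transcriptional direction (query sits upstream)}
#'   \item{tandem_downstream}{same strand, feature TSS upstream of the query}
#' }
#' The classification is total: every strand pair and relative position maps
#' to exactly one class.
#'
#' For features whose span intersects the neighbor window, a TSS "pointing
#' apart" necessarily lies within window/2 of the query (the TSS sits at the
#' window-proximal span end), so the divergent class needs no explicit
#' distance guard.
#'
#' @param position Query genomic coordinate (1-based).
#' @param query_strand Query strand, `"+"` or `"-"`.
#' @param f_start,f_end Feature span, 1-based closed.
#' @param f_strand Feature strand.
#' @param f_tss Feature TSS coordinate.
#' @return One of the class labels above.
#' @export
classify_orientation <- function(position, query_strand, f_start, f_end,
                                 f_strand, f_tss) {
  overlaps <- f_start <= position && position <= f_end
  same <- f_strand == query_strand
  if (same) {
    if (overlaps) return("sense_overlapping")
    # position of the feature TSS in the query's transcriptional direction
    ahead <- if (query_strand == "+") f_tss > position else f_tss < position
    return(if (ahead) "tandem_upstream" else "tandem_downstream")
  }
  if (overlaps) return("antisense_overlapping")
  # opposite strand, not overlapping: transcribing away -> shared promoter
  away <- if (f_strand == "+") f_tss > position else f_tss < position
  if (away) "divergent" else "convergent"
}

#' Find and classify features near a genomic position
#'
#' Reports every feature whose span intersects the closed window of `window`
#' bp centred on `position`, classified by orientation relative to the query
#' strand (see [classify_orientation()]). Used to interpret hits on long
#' non-coding RNAs (SUTs/CUTs) through their neighboring genes.
#'
#' @param position Query genomic coordinate (1-based), e.g. a guide cut site.
#' @param chrom Chromosome of the query.
#' @param features Feature `data.frame` (see [read_features()]).
#' @param window Window width in bp centred on `position` (default 1000).
#' @param query_strand Strand of the query (default `"+"`).
#' @return A `data.frame` with one row per hit: feature columns plus
#'   `distance` (signed, feature TSS minus query in the query's
#'   transcriptional orientation) and `orientation`.
#' @export
neighbor_features <- function(position, chrom, features, window = 1000,
                              query_strand = c("+", "-")) {
  query_strand <- match.arg(query_strand)
  if (window <= 0) stop("window must be positive")
  half <- window / 2
  lo <- position - half
  hi <- position + half
  hit <- features$chrom == chrom & features$start <= hi & features$end >= lo
  res <- features[hit, , drop = FALSE]
  if (nrow(res) == 0L) {
    res$distance <- numeric(0)
    res$orientation <- character(0)
    rownames(res) <- NULL
    return(res)
  }
  res$distance <- if (query_strand == "+") res$tss - position else position - res$tss
  res$orientation <- vapply(seq_len(nrow(res)), function(i) {
    classify_orientation(position, query_strand,
                         res$start[i], res$end[i],
                         res$strand[i], res$tss[i])
  }, character(1))
  rownames(res) <- NULL
  res
}
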