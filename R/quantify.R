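#' Read a sample sheet mapping inline barcodes to samples
#'
#' The sheet is a TSV with header columns `sample_id`, `barcode` (4-6 nt),
#' `screen_id`, `fraction` (`high` or `low`), `replicate`. Barcodes must be
#' unique and prefix-free (no barcode may be a prefix of another), so that a
#' read prefix identifies at most one sample.
#'
#' @param path TSV path, or a `data.frame` with those columns.
#' @return Validated sample sheet `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) path
           else utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  need <- c("sample_id", "barcode", "screen_id", "fraction", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  sheet$barcode <- toupper(sheet$barcode)
  if (any(nchar(sheet$barcode) < 4L | nchar(sheet$barcode) > 6L))
    stop("barcodes must be 4-6 nt")
  if (any(grepl("[^ACGT]", sheet$barcode)))
    stop("barcodes must be over A, C, G, T")
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sheet")
  if (anyDuplicated(sheet$barcode))
    stop("duplicate barcode in sheet")
  for (i in seq_len(nrow(sheet))) for (j in seq_len(nrow(sheet))) {
    if (i != j && startsWith(sheet$barcode[j], sheet$barcode[i]))
      stop("barcode set is not prefix-free: '", sheet$barcode[i],
           "' is a prefix of '", sheet$barcode[j], "'")
  }
  if (any(!sheet$fraction %in% c("high", "low")))
    stop("fraction must be 'high' or 'low'")
  sheet
}

read_fastq_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    as.character(Biostrings::readDNAStringSet(x, format = "fastq"))
  else as.character(x)
}

#' Demultiplex reads by inline barcode prefix
#'
#' Assigns each read to the unique sample whose barcode exactly matches the
#' read prefix and trims the barcode; reads matching no barcode are counted
#' as `no_barcode`. Barcodes are matched at the read start only.
#'
#' @param reads FASTQ path (gzip allowed) or character vector of read
#'   sequences.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @return List with `reads`: named list of per-sample character vectors
#'   (barcode-trimmed), and `no_barcode`: count of unassigned reads.
#' @export
demultiplex <- function(reads, sheet) {
  sheet <- read_sample_sheet(sheet)
  seqs <- read_fastq_seqs(reads)
  assigned <- rep(NA_integer_, length(seqs))
  for (i in seq_len(nrow(sheet))) {
    hit <- is.na(assigned) & startsWith(seqs, sheet$barcode[i])
    assigned[hit] <- i
  }
  per_sample <- lapply(seq_len(nrow(sheet)), function(i) {
    idx <- which(assigned == i)
    substring(seqs[idx], nchar(sheet$barcode[i]) + 1L)
  })
  names(per_sample) <- sheet$sample_id
  list(reads = per_sample, no_barcode = sum(is.na(assigned)))
}

#' Count library guides in demultiplexed reads
#'
#' For each read, the first exact occurrence of the constant flank is
#' located and the 20 nt that follow are looked up exactly in the guide
#' library; a hit increments that guide's count, anything else (flank
#' missing, truncated read, unknown 20-mer) increments the sample's
#' `no_guide` counter. Exact matching replaces alignment: library guides are
#' mutually >= 3 mismatches apart by construction, so a sequencing error
#' yields `no_guide` rather than a miscount.
#'
#' @param demux Result of [demultiplex()], or a named list of per-sample
#'   read vectors.
#' @param library Guide library `data.frame` (`guide_id`, `protospacer`) or
#'   named character vector of 20-mers.
#' @param flank Constant sequence directly 5' of the guide in each read.
#' @param sheet Sample sheet carrying fraction/replicate metadata; required
#'   when `demux` is a bare list.
#' @return A `count_table` object (see [count_table()]).
#' @export
count_guides <- function(demux, library, flank, sheet) {
  if (is.data.frame(library)) {
    guides <- library$protospacer
    names(guides) <- library$guide_id
  } else {
    guides <- library
    if (is.null(names(guides))) names(guides) <- paste0("g", seq_along(guides))
  }
  if (anyDuplicated(guides))
    stop("library 20-mers must be unique (run the off-target filter first)")
  per_sample <- if (is.list(demux) && !is.null(demux$reads)) demux$reads else demux
  sheet <- read_sample_sheet(sheet)
  if (!setequal(names(per_sample), sheet$sample_id))
    stop("demultiplexed samples do not match the sample sheet")
  per_sample <- per_sample[sheet$sample_id]
  lookup <- seq_along(guides)
  names(lookup) <- guides
  counts <- matrix(0L, nrow = length(guides), ncol = nrow(sheet),
                   dimnames = list(names(guides), sheet$sample_id))
  no_guide <- integer(nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    rd <- per_sample[[j]]
    if (length(rd) == 0L) next
    pos <- regexpr(flank, rd, fixed = TRUE)
    ins <- substring(rd, pos + nchar(flank), pos + nchar(flank) + 19L)
    ins[pos < 0 | nchar(ins) < 20L] <- NA
    idx <- lookup[ins]
    hit <- !is.na(idx)
    no_guide[j] <- sum(!hit)
    if (any(hit)) {
      tab <- tabulate(idx[hit], nbins = length(guides))
      counts[, j] <- counts[, j] + tab
    }
  }
  count_table(counts, sheet, no_guide = no_guide)
}

#' Construct a guide count table
#'
#' The central container for screen readout: an integer matrix of guides by
#' samples together with the sample sheet and per-sample unassigned-read
#' counters.
#'
#' @param counts Integer matrix, rownames = guide ids, colnames = sample
#'   ids.
#' @param samples Sample sheet `data.frame` matching the columns.
#' @param no_guide,no_barcode Per-sample unassigned counters (optional).
#' @return A `count_table` object.
#' @export
count_table <- function(counts, samples, no_guide = integer(ncol(counts)),
                        no_barcode = integer(ncol(counts))) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), samples$sample_id))
    stop("count columns and sample sheet disagree")
  structure(list(counts = counts, samples = samples,
                 no_guide = no_guide, no_barcode = no_barcode),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "guides x", ncol(x$counts),
      "samples\n")
  cat("  fractions:", paste(sprintf("%s=%d", names(table(x$samples$fraction)),
                                    table(x$samples$fraction)),
                            collapse = ", "), "\n")
  cat("  total assigned reads:", sum(x$counts), "\n")
  invisible(x)
}

#' Write / read a count table TSV
#'
#' The TSV carries the sample sheet in `#`-prefixed header lines so the file
#' round-trips without a side file.
#'
#' @param table A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly (write); a `count_table` (read).
#' @export
write_count_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- apply(table$samples, 1, function(r)
    paste0("#sample\t", paste(r, collapse = "\t")))
  writeLines(paste0("#fields\t", paste(names(table$samples), collapse = "\t")),
             con)
  writeLines(hdr, con)
  utils::write.table(data.frame(guide_id = rownames(table$counts),
                                table$counts, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  fields <- strsplit(sub("^#fields\t", "", hdr[startsWith(hdr, "#fields")]),
                     "\t")[[1]]
  rows <- strsplit(sub("^#sample\t", "", hdr[startsWith(hdr, "#sample")]),
                   "\t")
  samples <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(samples) <- fields
  rownames(samples) <- NULL
  samples$replicate <- as.integer(samples$replicate)
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  counts <- as.matrix(body[, -1, drop = FALSE])
  rownames(counts) <- body$guide_id
  storage.mode(counts) <- "integer"
  count_table(counts, samples)
}
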