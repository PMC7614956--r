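#' Oligo cassette layout
#'
#' Describes the fixed scaffold of a four-guide synthesis oligo: flanking
#' priming sequences, a left and right BspQI (type II-S, GCTCTTC) site, and
#' internal spacers carrying the recognition sequence on both strands so a
#' single digest releases every guide without leaving recognition-site scars
#' on the guide fragments. With the defaults, one oligo is
#' 11 + 11 + 4x20 + 3x22 + 11 + 11 = 190 bp.
#'
#' @param left_flank,right_flank Outer priming/handle sequences.
#' @param left_site,right_site Terminal recognition-site segments.
#' @param internal_spacer Spacer between guide slots; must carry the
#'   recognition sequence on both strands.
#' @param guides_per_oligo Guide slots per oligo.
#' @param recognition Enzyme recognition sequence (BspQI/SapI family).
#' @return A `cassette_layout` list, length-checked.
#' @export
cassette_layout <- function(left_flank = "TCAGTCGATCG",
                            left_site = "GCTCTTCAAGG",
                            internal_spacer = "GTTAGAAGAGCGCTCTTCTAGG",
                            right_site = "GTTCGAAGAGC",
                            right_flank = "GCTAGCTCCAT",
                            guides_per_oligo = 4L,
                            recognition = "GCTCTTC") {
  up <- function(x) chartr("u", "U", toupper(x))
  layout <- list(left_flank = up(left_flank), left_site = up(left_site),
                 internal_spacer = up(internal_spacer),
                 right_site = up(right_site), right_flank = up(right_flank),
                 guides_per_oligo = as.integer(guides_per_oligo),
                 recognition = up(recognition))
  rc <- revcomp(layout$recognition)
  has_both <- grepl(layout$recognition, layout$internal_spacer, fixed = TRUE) &&
    grepl(rc, layout$internal_spacer, fixed = TRUE)
  if (!has_both)
    stop("internal_spacer must carry the recognition sequence on both strands")
  n <- layout$guides_per_oligo
  layout$oligo_len <- nchar(layout$left_flank) + nchar(layout$left_site) +
    20L * n + nchar(layout$internal_spacer) * (n - 1L) +
    nchar(layout$right_site) + nchar(layout$right_flank)
  class(layout) <- "cassette_layout"
  layout
}

#' Pack guides into synthesis oligos
#'
#' Consumes 20-mers in order, `guides_per_oligo` per oligo, assembling
#' `left_flank . left_site . g1 . spacer . g2 . spacer . g3 . spacer . g4 .
#' right_site . right_flank`. A partial final oligo is completed with a
#' fixed filler 20-mer (`ACGTACGTACACGTACGTAC`), flagged in the manifest;
#' fillers never enter a guide library. Guides containing the recognition
#' sequence on either strand are rejected by name (an internal site would
#' shred the cassette on digestion).
#'
#' @param guides Character vector of 20-nt guide sequences (A/C/G/T), or a
#'   guide library `data.frame` with `protospacer` (and optionally
#'   `guide_id`).
#' @param layout A [cassette_layout()].
#' @return A `data.frame` manifest with columns `oligo_id`, `slot`,
#'   `guide_id`, `guide_seq`, `is_filler`, plus attribute `"oligos"`: the
#'   named character vector of assembled oligos. Access oligos with
#'   [oligo_sequences()].
#' @export
pack_oligos <- function(guides, layout = cassette_layout()) {
  if (is.data.frame(guides)) {
    ids <- if ("guide_id" %in% names(guides)) guides$guide_id
           else paste0("guide_", seq_len(nrow(guides)))
    guides <- guides$protospacer
  } else {
    ids <- if (!is.null(names(guides)) && all(nzchar(names(guides))))
      names(guides) else paste0("guide_", seq_along(guides))
  }
  guides <- toupper(guides)
  if (length(guides) == 0L) stop("no guides to pack")
  if (any(nchar(guides) != 20L))
    stop("guide '", ids[nchar(guides) != 20L][1L], "' is not 20 nt")
  if (any(grepl("[^ACGT]", guides)))
    stop("guide '", ids[grepl("[^ACGT]", guides)][1L],
         "' contains characters outside A, C, G, T")
  rec <- layout$recognition
  rc <- revcomp(rec)
  bad <- grepl(rec, guides, fixed = TRUE) | grepl(rc, guides, fixed = TRUE)
  if (any(bad))
    stop("guide '", ids[bad][1L], "' contains the ", rec,
         " recognition site (either strand) and cannot be packed")
  filler <- "ACGTACGTACACGTACGTAC"
  k <- layout$guides_per_oligo
  n_oligo <- ceiling(length(guides) / k)
  n_fill <- n_oligo * k - length(guides)
  all_seqs <- c(guides, rep(filler, n_fill))
  all_ids <- c(ids, rep("filler", n_fill))
  is_filler <- c(rep(FALSE, length(guides)), rep(TRUE, n_fill))
  oligo_idx <- rep(seq_len(n_oligo), each = k)
  oligos <- vapply(seq_len(n_oligo), function(i) {
    g <- all_seqs[oligo_idx == i]
    paste0(layout$left_flank, layout$left_site,
           paste(g, collapse = layout$internal_spacer),
           layout$right_site, layout$right_flank)
  }, character(1))
  names(oligos) <- sprintf("oligo_%03d", seq_len(n_oligo))
  manifest <- data.frame(
    oligo_id = names(oligos)[oligo_idx],
    slot = rep(seq_len(k), n_oligo),
    guide_id = all_ids,
    guide_seq = all_seqs,
    is_filler = is_filler,
    stringsAsFactors = FALSE
  )
  attr(manifest, "oligos") <- oligos
  class(manifest) <- c("oligo_pool", "data.frame")
  manifest
}

#' Assembled oligo sequences of a packed pool
#'
#' @param pool Result of [pack_oligos()].
#' @return Named character vector of oligo sequences.
#' @export
oligo_sequences <- function(pool) attr(pool, "oligos")

#' Write an oligo pool as FASTA plus TSV manifest
#'
#' @param pool Result of [pack_oligos()].
#' @param fasta_path Output FASTA of oligos.
#' @param manifest_path Optional TSV manifest path (oligo_id, slot, guide_id,
#'   is_filler).
#' @return `fasta_path`, invisibly.
#' @export
write_oligo_pool <- function(pool, fasta_path, manifest_path = NULL) {
  oligos <- oligo_sequences(pool)
  dss <- Biostrings::DNAStringSet(oligos)
  Biostrings::writeXStringSet(dss, fasta_path)
  if (!is.null(manifest_path))
    utils::write.table(as.data.frame(pool), manifest_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Simulate the type II-S restriction digest of an oligo
#'
#' Finds every occurrence of the recognition sequence on either strand and
#' places one double-strand breakpoint per site: for a top-strand occurrence
#' the breakpoint falls one base after the site's 3' end (downstream cut of
#' an outside-cutting enzyme), for a bottom-strand occurrence (recognition
#' reverse complement on the top strand starting at `s`) one base before
#' `s`. Fragments are the intervals between successive breakpoints and tile
#' the oligo exactly. BspQI's 3-nt 5' overhangs are not modeled; a single
#' breakpoint per site suffices to decide guide release.
#'
#' @param oligo An oligo sequence.
#' @param recognition Recognition sequence (default BspQI, `GCTCTTC`).
#' @param library Optional character vector of known guide 20-mers; a
#'   fragment containing one gets it as its `guide_core`. Without a library,
#'   a fragment whose trimmed interior (3 nt off each end, the residual
#'   spacer bases) is exactly 20 nt yields that interior as the core.
#' @return A `data.frame` of fragments: `start`, `end` (1-based closed on
#'   the oligo), `sequence`, `guide_core` (`NA` when none).
#' @export
digest_oligo <- function(oligo, recognition = "GCTCTTC", library = NULL) {
  oligo <- toupper(oligo)
  if (grepl("[^ACGT]", oligo)) stop("oligo must be over A, C, G, T")
  rc <- revcomp(recognition)
  find_all <- function(pat) {
    s <- unlist(gregexpr(paste0("(?=", pat, ")"), oligo, perl = TRUE))
    s[s > 0]
  }
  top <- find_all(recognition)
  bottom <- find_all(rc)
  L <- nchar(oligo)
  # breakpoints as "number of bases to the left of the cut"
  bp_top <- top + nchar(recognition) # cut after one downstream base
  bp_bottom <- bottom - 2L           # one base before the rc occurrence
  breaks <- sort(unique(c(bp_top, bp_bottom)))
  breaks <- breaks[breaks > 0 & breaks < L]
  bounds <- c(0L, breaks, L)
  frags <- data.frame(
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1],
    stringsAsFactors = FALSE
  )
  frags$sequence <- substring(oligo, frags$start, frags$end)
  core_of <- function(seq) {
    if (!is.null(library)) {
      hit <- library[vapply(library, function(g) grepl(g, seq, fixed = TRUE),
                            logical(1))]
      return(if (length(hit)) hit[1L] else NA_character_)
    }
    if (nchar(seq) == 26L) return(substr(seq, 4L, 23L))
    NA_character_
  }
  frags$guide_core <- vapply(frags$sequence, core_of, character(1),
                             USE.NAMES = FALSE)
  frags
}

#' Digest every oligo of a pool and collect released guides
#'
#' @param pool Result of [pack_oligos()], or a character vector of oligos.
#' @param recognition Recognition sequence (default `GCTCTTC`).
#' @param library Optional known guide set passed to [digest_oligo()].
#' @return Character vector of released guide cores (with multiplicity),
#'   in oligo order.
#' @export
digest_pool <- function(pool, recognition = "GCTCTTC", library = NULL) {
  oligos <- if (is.character(pool)) pool else oligo_sequences(pool)
  unlist(lapply(oligos, function(o) {
    f <- digest_oligo(o, recognition, library)
    f$guide_core[!is.na(f$guide_core)]
  }), use.names = FALSE)
}
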