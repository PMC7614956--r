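#' Guide design parameters
#'
#' Collects the promoter-window and bin-selection parameters for SpCas9 guide
#' design. Defaults follow the library design used for genome-scale CRISPRa/
#' CRISPRi screening in yeast: candidate guides are taken from 400 bp upstream
#' to 100 bp downstream of each feature's TSS; when a promoter offers six or
#' more candidates, the 300 bp immediately upstream of the TSS is divided into
#' six 50-bp bins and the best-scoring guide is taken from each bin.
#'
#' @param window_upstream Upstream extent of the candidate window, bp.
#' @param window_downstream Downstream extent, bp.
#' @param bin_region Width of the binned promoter region upstream of the TSS.
#' @param bin_width Width of one bin, bp; `bin_region` must be divisible by it.
#' @param max_per_feature Maximum guides selected per feature.
#' @param pam PAM in IUPAC code (SpCas9: `"NGG"`).
#' @param protospacer_len Protospacer length, nt.
#' @return A `design_params` list.
#' @export
design_params <- function(window_upstream = 400, window_downstream = 100,
                          bin_region = 300, bin_width = 50,
                          max_per_feature = 6, pam = "NGG",
                          protospacer_len = 20) {
  if (bin_region %% bin_width != 0)
    stop("bin_region must be divisible by bin_width")
  if (window_upstream < bin_region)
    stop("window_upstream must cover the bin region")
  structure(list(window_upstream = window_upstream,
                 window_downstream = window_downstream,
                 bin_region = bin_region, bin_width = bin_width,
                 max_per_feature = max_per_feature, pam = pam,
                 protospacer_len = protospacer_len),
            class = "design_params")
}

# IUPAC code -> regex character class
iupac_regex <- function(pam) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pam), "")[[1]]
  if (any(!chars %in% names(map))) stop("invalid IUPAC PAM: ", pam)
  paste(map[chars], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Scan a genome for PAM-adjacent protospacer sites
#'
#' Enumerates every protospacer with an NGG PAM immediately 3' of it, on both
#' strands of every chromosome. Sites whose protospacer or PAM contains `N`
#' are excluded. Coordinates are 1-based closed over the protospacer on the
#' top strand; `cut_site` is the genomic coordinate of the protospacer's 17th
#' base (the blunt-cut reference point 3 bp 5' of the PAM).
#'
#' @param genome A `genome` object.
#' @param params A [design_params()] list.
#' @return A `data.frame` with columns `chrom`, `strand`, `start`, `end`,
#'   `protospacer`, `pam_seq`, `cut_site`, sorted by (chrom, start, strand).
#' @export
scan_pam_sites <- function(genome, params = design_params()) {
  plen <- params$protospacer_len
  pam_re <- iupac_regex(params$pam)
  pam_len <- nchar(params$pam)
  one_chrom <- function(chrom) {
    seq <- genome[[chrom]]
    L <- nchar(seq)
    out <- list()
    # top strand: protospacer [s, s+plen-1], PAM [s+plen, s+plen+pam_len-1]
    re <- sprintf("(?=[ACGT]{%d}%s)", plen, pam_re)
    s <- unlist(gregexpr(re, seq, perl = TRUE))
    s <- s[s > 0]
    if (length(s)) {
      proto <- substring(seq, s, s + plen - 1L)
      pam <- substring(seq, s + plen, s + plen + pam_len - 1L)
      out$plus <- data.frame(chrom = chrom, strand = "+", start = s,
                             end = s + plen - 1L, protospacer = proto,
                             pam_seq = pam, cut_site = s + plen - 4L,
                             stringsAsFactors = FALSE)
    }
    # bottom strand: search the reverse complement, map coordinates back
    rc <- revcomp(seq)
    s2 <- unlist(gregexpr(re, rc, perl = TRUE))
    s2 <- s2[s2 > 0]
    if (length(s2)) {
      proto <- substring(rc, s2, s2 + plen - 1L)
      pam <- substring(rc, s2 + plen, s2 + plen + pam_len - 1L)
      # rc position p corresponds to top-strand position L - p + 1
      start <- L - (s2 + plen - 1L) + 1L
      out$minus <- data.frame(chrom = chrom, strand = "-", start = start,
                              end = start + plen - 1L, protospacer = proto,
                              pam_seq = pam,
                              cut_site = start + 3L,
                              stringsAsFactors = FALSE)
    }
    out
  }
  parts <- unlist(lapply(names(genome), one_chrom), recursive = FALSE)
  if (length(parts) == 0L || sum(vapply(parts, nrow, 0L)) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      protospacer = character(0), pam_seq = character(0),
                      cut_site = integer(0)))
  }
  sites <- do.call(rbind, parts)
  sites <- sites[order(match(sites$chrom, names(genome)), sites$start,
                       sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Default deterministic on-target score
#'
#' A self-contained placeholder for machine-learned on-target activity
#' scorers: `clamp(1 - 2*|gc - 0.5| - 0.25*H, 0, 1)` where `gc` is the G+C
#' fraction of the 20-mer and `H` is 1 if the protospacer contains a
#' homopolymer run of 5 or more, else 0. Any function mapping a protospacer
#' to `[0, 1]` can be injected wherever a `scorer` argument is accepted.
#'
#' @param protospacer Character vector of 20-nt protospacers over A/C/G/T.
#' @return Numeric scores in `[0, 1]`.
#' @export
default_score <- function(protospacer) {
  if (any(nchar(protospacer) != 20L))
    stop("protospacer must be 20 nt")
  if (any(grepl("[^ACGT]", protospacer)))
    stop("protospacer must be over A, C, G, T")
  gc <- (nchar(gsub("[AT]", "", protospacer))) / 20
  run <- grepl("A{5}|C{5}|G{5}|T{5}", protospacer)
  pmin(1, pmax(0, 1 - 2 * abs(gc - 0.5) - 0.25 * as.numeric(run)))
}

#' Assign PAM sites to a feature's promoter window
#'
#' A site becomes a candidate for a feature when its cut site falls within
#' `[-window_upstream, +window_downstream]` of the feature's TSS, measured in
#' the feature's transcriptional orientation (negative = upstream). Offsets
#' in `[-bin_region, 0)` receive a bin index
#' `floor((offset + bin_region) / bin_width)`; offsets outside the binned
#' region get `NA`.
#'
#' @param feature One row of a feature `data.frame` (see [read_features()]).
#' @param sites Site table from [scan_pam_sites()] on the same genome.
#' @param params A [design_params()] list.
#' @param scorer Function protospacer -> score in `[0,1]`
#'   (default [default_score()]).
#' @return A `data.frame` of guide candidates with `feature_id`,
#'   `tss_offset`, `bin_index`, `score`, `offtarget_ok` (initialized `NA`)
#'   added to the site columns.
#' @export
candidates_for_feature <- function(feature, sites, params = design_params(),
                                   scorer = default_score) {
  stopifnot(nrow(feature) == 1L)
  on_chrom <- sites$chrom == feature$chrom
  s <- sites[on_chrom, , drop = FALSE]
  offset <- if (feature$strand == "+") s$cut_site - feature$tss
            else feature$tss - s$cut_site
  keep <- offset >= -params$window_upstream & offset <= params$window_downstream
  s <- s[keep, , drop = FALSE]
  offset <- offset[keep]
  bin <- ifelse(offset >= -params$bin_region & offset < 0,
                floor((offset + params$bin_region) / params$bin_width), NA)
  s$feature_id <- rep(feature$feature_id, nrow(s))
  s$tss_offset <- offset
  s$bin_index <- as.integer(bin)
  s$score <- if (nrow(s)) scorer(s$protospacer) else numeric(0)
  s$offtarget_ok <- rep(NA, nrow(s))
  rownames(s) <- NULL
  s
}

#' Select up to six guides per feature by promoter bins
#'
#' If a feature has fewer than `max_per_feature` candidates, all are kept.
#' Otherwise the binned promoter region is used: from each bin the
#' highest-scoring candidate is selected (candidates outside the binned
#' region are ineligible in this mode). Score ties break toward the smaller
#' `|tss_offset|`, then the lexicographically smaller protospacer, so
#' libraries are reproducible.
#'
#' @param candidates Candidate `data.frame` for a single feature
#'   (see [candidates_for_feature()]), normally pre-filtered for off-targets.
#' @param params A [design_params()] list.
#' @return The selected subset, at most `max_per_feature` rows.
#' @export
select_guides <- function(candidates, params = design_params()) {
  if (nrow(candidates) == 0L) return(candidates)
  if (length(unique(candidates$feature_id)) != 1L)
    stop("select_guides expects candidates for a single feature")
  if (nrow(candidates) < params$max_per_feature) return(candidates)
  binned <- candidates[!is.na(candidates$bin_index), , drop = FALSE]
  if (nrow(binned) == 0L)
    return(binned)
  picks <- lapply(split(seq_len(nrow(binned)), binned$bin_index), function(idx) {
    b <- binned[idx, , drop = FALSE]
    ord <- order(-b$score, abs(b$tss_offset), b$protospacer)
    b[ord[1L], , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  out <- out[order(out$bin_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Design a guide library across an annotation
#'
#' Convenience wrapper running [scan_pam_sites()], [candidates_for_feature()],
#' off-target filtering ([filter_offtargets()]) and [select_guides()] over all
#' features.
#'
#' @param genome A `genome` object.
#' @param features Feature `data.frame`.
#' @param params A [design_params()] list.
#' @param scorer Scoring function (default [default_score()]).
#' @param min_mm Minimum permitted mismatch distance to any other genomic
#'   site or candidate (default 3); `0` disables off-target filtering.
#' @param exclude_motifs Motifs that disqualify a protospacer for synthesis
#'   (default: the BspQI recognition sequence on either strand, which would
#'   shred the oligo cassette); `character(0)` disables the screen.
#' @return A `data.frame` of selected guides for all features, with a
#'   `guide_id` column `<feature_id>_g<k>`.
#' @export
design_library <- function(genome, features, params = design_params(),
                           scorer = default_score, min_mm = 3,
                           exclude_motifs = c("GCTCTTC", "GAAGAGC")) {
  sites <- scan_pam_sites(genome, params)
  cand <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    candidates_for_feature(features[i, , drop = FALSE], sites, params, scorer)
  }))
  if (is.null(cand) || nrow(cand) == 0L)
    stop("no candidate guides found in any promoter window")
  for (m in exclude_motifs)
    cand <- cand[!grepl(m, cand$protospacer, fixed = TRUE), , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("no candidate guides left after the synthesis-motif screen")
  if (min_mm > 0) {
    index <- build_site_index(genome, params)
    cand <- filter_offtargets(cand, index, min_mm = min_mm)
    cand <- cand[cand$offtarget_ok, , drop = FALSE]
  } else {
    cand$offtarget_ok <- TRUE
  }
  sel <- do.call(rbind, lapply(split(cand, cand$feature_id), select_guides,
                               params = params))
  sel <- sel[order(match(sel$feature_id, features$feature_id),
                   sel$tss_offset), , drop = FALSE]
  counts <- ave(seq_len(nrow(sel)), sel$feature_id, FUN = seq_along)
  sel$guide_id <- paste0(sel$feature_id, "_g", counts)
  rownames(sel) <- NULL
  sel
}

#' Write a guide library as TSV
#'
#' @param library Guide `data.frame` from [design_library()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_guide_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a guide library TSV written by [write_guide_library()]
#'
#' @param path TSV path.
#' @return Guide `data.frame`.
#' @export
read_guide_library <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write protospacers as FASTA
#'
#' @param library Guide `data.frame` with `guide_id` and `protospacer`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_guide_fasta <- function(library, path) {
  dss <- Biostrings::DNAStringSet(library$protospacer)
  names(dss) <- library$guide_id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
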