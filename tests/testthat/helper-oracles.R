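# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles are deliberately naive (position-by-position, O(n^2)) and
# share no code with the implementation paths they check.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_str <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# position-by-position double-strand NGG scan
brute_pam_scan <- function(seq, chrom = "chr1") {
  L <- nchar(seq)
  rows <- list()
  for (s in seq_len(L)) {
    if (s + 22 <= L) {
      proto <- substr(seq, s, s + 19)
      pam <- substr(seq, s + 20, s + 22)
      if (!grepl("[^ACGT]", paste0(proto, pam)) &&
          substr(pam, 2, 3) == "GG") {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, strand = "+", start = s, end = s + 19,
          protospacer = proto, pam_seq = pam, cut_site = s + 16,
          stringsAsFactors = FALSE)
      }
    }
    # minus strand: top-strand window [s-3, s+19] read as revcomp
    if (s - 3 >= 1 && s + 19 <= L) {
      win <- substr(seq, s - 3, s + 19)
      if (!grepl("[^ACGT]", win)) {
        rcw <- rc_str(win)
        proto <- substr(rcw, 1, 20)
        pam <- substr(rcw, 21, 23)
        if (substr(pam, 2, 3) == "GG") {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = chrom, strand = "-", start = s, end = s + 19,
            protospacer = proto, pam_seq = pam, cut_site = s + 3,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), ]
}

# O(n^2) off-target filter: full pairwise Hamming against all genomic sites
# and all other candidates
brute_offtarget_keep <- function(candidates, sites, min_mm = 3) {
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    ci <- candidates[i, ]
    dmin <- Inf
    for (j in seq_len(nrow(sites))) {
      sj <- sites[j, ]
      same_loc <- sj$chrom == ci$chrom && sj$start == ci$start &&
        sj$strand == ci$strand
      if (same_loc) next
      dmin <- min(dmin, hamming_str(ci$protospacer, sj$protospacer))
    }
    ok <- dmin >= min_mm
    if (ok) for (j in seq_len(nrow(candidates))) {
      cj <- candidates[j, ]
      same_loc <- cj$chrom == ci$chrom && cj$start == ci$start &&
        cj$strand == ci$strand
      if (same_loc) next
      if (hamming_str(ci$protospacer, cj$protospacer) < min_mm) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  keep
}

# hand transcription of the Benjamini-Hochberg step-up
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

write_tmp_fasta <- function(records) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), path)
  path
}

make_feature <- function(feature_id = "GENE1", type = "ORF", chrom = "chr1",
                         strand = "+", tss = 500, len = 200) {
  span <- if (strand == "+") c(tss, tss + len - 1) else c(tss - len + 1, tss)
  data.frame(feature_id = feature_id, feature_type = type, chrom = chrom,
             strand = strand, tss = tss, start = span[1], end = span[2],
             stringsAsFactors = FALSE)
}

unit_factors <- function(n, ids = NULL) {
  f <- structure(list(factors = rep(1, n), effective_sizes = rep(1, n)),
                 class = "norm_factors")
  if (!is.null(ids)) names(f$factors) <- names(f$effective_sizes) <- ids
  f
}
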