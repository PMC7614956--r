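# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed: the RNG state is saved and restored around each call.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy genome with plantable promoter PAM sites
#'
#' Generates one random chromosome carrying `n_features` non-overlapping
#' TSS-anchored features (types cycled over ORF/SUT/CUT, strands
#' alternating), and plants at least `promoter_pam_min` NGG protospacer
#' sites with cut sites inside each promoter's binned region (300 bp
#' upstream of the TSS, spread across bins), so the design pipeline has
#' material to work with. Planted protospacers are random 20-mers, which
#' with overwhelming probability sit far apart in Hamming distance and
#' survive the off-target filter.
#'
#' @param n_features Number of features.
#' @param promoter_pam_min Minimum planted PAM sites per promoter (<= 12).
#' @param length Chromosome length, bp; must fit the features (roughly
#'   700 bp per feature plus margins).
#' @param seed Integer seed.
#' @return List with `genome` (a `genome` object) and `features`
#'   (a feature `data.frame`).
#' @export
simulate_genome <- function(n_features, promoter_pam_min = 6, length = 20000,
                            seed = 1) {
  slot <- 700L # upstream window + downstream window + spacing margin
  if (promoter_pam_min > 12)
    stop("at most 12 sites fit a 300-bp promoter without overlap")
  if (length < n_features * slot + 200L)
    stop("genome too short to pack ", n_features, " features: need >= ",
         n_features * slot + 200L, " bp")
  with_seed(seed, {
    seq <- strsplit(random_dna(length), "")[[1]]
    feats <- vector("list", n_features)
    for (i in seq_len(n_features)) {
      base <- 100L + (i - 1L) * slot
      strand <- if (i %% 2L == 1L) "+" else "-"
      # tss placed so [-400, +100] stays inside the slot on either strand
      tss <- if (strand == "+") base + 420L else base + 180L
      span_len <- 150L + sample.int(100L, 1L)
      span <- if (strand == "+") c(tss, tss + span_len - 1L)
              else c(tss - span_len + 1L, tss)
      feats[[i]] <- data.frame(
        feature_id = sprintf("FEAT%03d", i),
        feature_type = c("ORF", "SUT", "CUT")[(i - 1L) %% 3L + 1L],
        chrom = "chr1", strand = strand, tss = tss,
        start = span[1], end = span[2], stringsAsFactors = FALSE
      )
      if (promoter_pam_min > 0) {
        # cut-site offsets spread across the six 50-bp bins
        offs <- -300L + 25L * (seq_len(promoter_pam_min) - 1L) * 2L +
          sample.int(10L, promoter_pam_min, replace = TRUE)
        for (o in offs) {
          cut <- if (strand == "+") tss + o else tss - o
          proto <- random_dna(20L)
          if (strand == "+") {
            s0 <- cut - 16L # protospacer start so base 17 sits at the cut
            seq[s0:(s0 + 19L)] <- strsplit(proto, "")[[1]]
            seq[(s0 + 20L):(s0 + 22L)] <- c("A", "G", "G")
          } else {
            s0 <- cut - 3L # minus-strand protospacer interval start
            top <- strsplit(revcomp(paste0(proto, "AGG")), "")[[1]]
            seq[(s0 - 3L):(s0 + 19L)] <- top
          }
        }
      }
    }
    genome <- as_genome(c(chr1 = paste(seq, collapse = "")))
    features <- do.call(rbind, feats)
    features <- features[, c("feature_id", "feature_type", "chrom", "strand",
                             "tss", "start", "end")]
    list(genome = genome, features = features)
  })
}

#' Screen count simulation parameters
#'
#' @param n_guides Number of guides.
#' @param n_samples_per_group Replicates per fraction (high/low).
#' @param mean_depth Expected baseline count per guide.
#' @param dispersion NB dispersion phi (variance `mu + phi mu^2`); 0 gives
#'   Poisson counts.
#' @param spike_fraction Fraction of guides with a true effect.
#' @param spike_log2fc True log2 fold change (high over low) of spiked
#'   guides; applied symmetrically (`x 2^(l/2)` up, `x 2^(-l/2)` down) so
#'   library sizes stay comparable.
#' @param seed Integer seed.
#' @return A `screen_sim_params` list.
#' @export
screen_sim_params <- function(n_guides = 2000, n_samples_per_group = 4,
                              mean_depth = 200, dispersion = 0.15,
                              spike_fraction = 0, spike_log2fc = 4,
                              seed = 1) {
  stopifnot(n_guides > 0, n_samples_per_group > 0, mean_depth > 0,
            dispersion >= 0, spike_fraction >= 0, spike_fraction <= 1)
  structure(list(n_guides = n_guides,
                 n_samples_per_group = n_samples_per_group,
                 mean_depth = mean_depth, dispersion = dispersion,
                 spike_fraction = spike_fraction,
                 spike_log2fc = spike_log2fc, seed = seed),
            class = "screen_sim_params")
}

#' Simulate a screen count table with spiked enrichment
#'
#' Draws guide counts from a negative binomial (variance `mu + phi mu^2`)
#' with per-guide baseline abundances log-normally scattered around
#' `mean_depth`; a random `spike_fraction` of guides carries a true
#' `spike_log2fc` between the high and low fractions, applied symmetrically
#' in the means. Returns the table together with the ground-truth spike
#' labels.
#'
#' @param params A [screen_sim_params()] list.
#' @return List with `table` (a `count_table`) and `truth` (logical vector,
#'   `TRUE` for spiked guides).
#' @export
simulate_screen_counts <- function(params = screen_sim_params()) {
  p <- params
  with_seed(p$seed, {
    n <- p$n_guides
    k <- p$n_samples_per_group
    base <- p$mean_depth * exp(stats::rnorm(n, 0, 0.25) - 0.25^2 / 2)
    n_spike <- round(p$spike_fraction * n)
    truth <- rep(FALSE, n)
    truth[sample.int(n, n_spike)] <- TRUE
    mu_hi <- base * ifelse(truth, 2^(p$spike_log2fc / 2), 1)
    mu_lo <- base * ifelse(truth, 2^(-p$spike_log2fc / 2), 1)
    draw <- function(mu) {
      if (p$dispersion < 1e-12) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), size = 1 / p$dispersion, mu = mu)
    }
    counts <- cbind(
      matrix(draw(rep(mu_hi, k)), nrow = n),
      matrix(draw(rep(mu_lo, k)), nrow = n)
    )
    ids <- sprintf("guide_%05d", seq_len(n))
    rownames(counts) <- ids
    samples <- data.frame(
      sample_id = c(paste0("high_", seq_len(k)), paste0("low_", seq_len(k))),
      barcode = make_barcodes(2L * k),
      screen_id = "sim",
      fraction = rep(c("high", "low"), each = k),
      replicate = rep(seq_len(k), 2L),
      stringsAsFactors = FALSE
    )
    colnames(counts) <- samples$sample_id
    names(truth) <- ids
    list(table = count_table(counts, samples), truth = truth)
  })
}

# fixed-length 5-mers over a 4-letter alphabet are automatically prefix-free
make_barcodes <- function(n) {
  alpha <- c("A", "C", "G", "T")
  combos <- expand.grid(alpha, alpha, alpha, alpha, alpha,
                        stringsAsFactors = FALSE)
  if (n > nrow(combos)) stop("too many barcodes requested")
  unname(apply(combos[seq_len(n), , drop = FALSE], 1, paste, collapse = ""))
}

#' Simulate FASTQ reads from a known count table
#'
#' Emits exactly `counts[i, j]` reads of
#' `barcode_j . flank . guide_i . adapter`, deterministically shuffled, with
#' constant base quality. Counting the result with [demultiplex()] and
#' [count_guides()] recovers the table exactly.
#'
#' @param table A `count_table`.
#' @param library Guide library (`data.frame` with `guide_id`/`protospacer`,
#'   or named character vector) covering the table's guides.
#' @param flank Constant sequence placed 5' of the guide.
#' @param adapter Constant 3' sequence (default a short Illumina-style
#'   adapter stub).
#' @param seed Integer seed for the shuffle.
#' @param path Optional FASTQ output path; written when not `NULL`.
#' @return Character vector of read sequences (invisible when `path` is
#'   given).
#' @export
simulate_reads <- function(table, library, flank = "GTTTAAGAGCTAAGCTG",
                           adapter = "AGATCGGAAGAG", seed = 1, path = NULL) {
  if (is.data.frame(library)) {
    lib <- library$protospacer
    names(lib) <- library$guide_id
  } else lib <- library
  ids <- rownames(table$counts)
  if (any(!ids %in% names(lib)))
    stop("library does not cover all table guides")
  with_seed(seed, {
    reads <- character(0)
    for (j in seq_len(ncol(table$counts))) {
      bc <- table$samples$barcode[j]
      cnt <- table$counts[, j]
      if (sum(cnt) == 0) next
      reads <- c(reads, paste0(bc, flank, rep(lib[ids], cnt), adapter))
    }
    reads <- if (length(reads)) sample(reads) else character(0)
    if (!is.null(path)) {
      write_fastq(reads, path)
      return(invisible(reads))
    }
    reads
  })
}

#' Write read sequences as FASTQ
#'
#' @param reads Character vector of read sequences.
#' @param path Output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    recs <- paste0("@read_", seq_along(reads), "\n", reads, "\n+\n",
                   strrep("I", nchar(reads)))
    writeLines(recs, con)
  }
  invisible(path)
}
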