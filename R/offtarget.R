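# Hamming machinery over fixed-length protospacers.
# Sites are compared in protospacer orientation (strand-normalized 20-mers);
# the PAM is excluded and indels are not considered.

# bytes-per-column matrix for vectorized Hamming distance
proto_byte_matrix <- function(protos, len = 20L) {
  if (length(protos) == 0L) return(matrix(raw(0), nrow = len, ncol = 0))
  matrix(unlist(lapply(protos, charToRaw), use.names = FALSE), nrow = len)
}

hamming_to_many <- function(query, mat) {
  if (ncol(mat) == 0L) return(integer(0))
  q <- charToRaw(query)
  colSums(mat != q)
}

# pigeonhole segments: a 20-mer within 2 mismatches of another must share at
# least one of three segments (7 + 7 + 6) exactly
SEED_SEGMENTS <- list(c(1L, 7L), c(8L, 14L), c(15L, 20L))

#' Build the genome-wide index of PAM-adjacent protospacer sites
#'
#' Indexes every NGG-adjacent 20-mer in the genome (both strands, see
#' [scan_pam_sites()]) for off-target queries: an exact hash keyed on the
#' full 20-mer resolves distance-0 duplicates, and a partitioned (pigeonhole)
#' seed index over three protospacer segments restricts Hamming computation
#' for distance <= 2 queries to a small candidate pool. A linear scan over
#' all sites remains available via `seed = FALSE` arguments downstream and in
#' tests as the brute-force oracle.
#'
#' @param genome A `genome` object.
#' @param params [design_params()] controlling PAM and protospacer length.
#' @return A `site_index` object with the site table (`sites`), total site
#'   count (`total_sites`), the byte matrix and the seed environments.
#' @export
build_site_index <- function(genome, params = design_params()) {
  sites <- scan_pam_sites(genome, params)
  plen <- params$protospacer_len
  mat <- proto_byte_matrix(sites$protospacer, plen)
  exact <- new.env(parent = emptyenv(), size = max(16L, nrow(sites)))
  for (i in seq_len(nrow(sites))) {
    k <- sites$protospacer[i]
    exact[[k]] <- c(exact[[k]], i)
  }
  seeds <- lapply(SEED_SEGMENTS, function(seg) {
    env <- new.env(parent = emptyenv(), size = max(16L, nrow(sites)))
    if (nrow(sites)) {
      key <- substring(sites$protospacer, seg[1], seg[2])
      for (i in seq_len(nrow(sites)))
        env[[key[i]]] <- c(env[[key[i]]], i)
    }
    env
  })
  structure(list(sites = sites, total_sites = nrow(sites), byte_matrix = mat,
                 exact = exact, seeds = seeds, protospacer_len = plen,
                 format_version = 1L),
            class = "site_index")
}

#' @export
print.site_index <- function(x, ...) {
  cat("site_index:", x$total_sites, "PAM-adjacent sites,",
      length(ls(x$exact)), "distinct protospacers\n")
  invisible(x)
}

#' Save / load a site index cache
#'
#' Serializes the index (with a format-version field checked on load) so a
#' genome need only be scanned once per analysis.
#'
#' @param index A `site_index`.
#' @param path Cache file path.
#' @return `path` (save) or the restored `site_index` (load).
#' @export
save_site_index <- function(index, path) {
  stopifnot(inherits(index, "site_index"))
  saveRDS(index, path)
  invisible(path)
}

#' @rdname save_site_index
#' @export
load_site_index <- function(path) {
  index <- readRDS(path)
  if (!inherits(index, "site_index") || !identical(index$format_version, 1L))
    stop("not a version-1 site index cache: ", path)
  index
}

# candidate pool of site rows within <= 2 mismatches (superset), via seeds
seed_pool <- function(index, protospacer) {
  idx <- integer(0)
  for (k in seq_along(SEED_SEGMENTS)) {
    seg <- SEED_SEGMENTS[[k]]
    key <- substr(protospacer, seg[1], seg[2])
    idx <- c(idx, index$seeds[[k]][[key]])
  }
  unique(idx)
}

#' Minimum mismatch distance from a guide to any other indexed site
#'
#' Returns the minimum Hamming distance between the guide's 20-mer and every
#' indexed protospacer, excluding the guide's own originating location once
#' (a second identical location still counts and yields 0). Returns `Inf`
#' when the index holds no other site.
#'
#' The seed index answers "is there a site within < `cap` mismatches"
#' exactly for `cap` <= 3 (pigeonhole guarantee); beyond the seed pool the
#' full scan supplies the exact minimum when requested.
#'
#' @param guide One candidate row (with `protospacer`, `chrom`, `strand`,
#'   `start`) or a plain protospacer string with `chrom`/`strand`/`start`
#'   given separately.
#' @param index A `site_index` for the same genome.
#' @param exact_min If `TRUE` (default) compute the exact minimum by full
#'   scan when the seed pool holds no hit below 3; if `FALSE`, return `3`
#'   as a floor ("at least 3"), sufficient for filtering.
#' @return Integer distance (0 = an identical site elsewhere), or `Inf`.
#' @export
min_mismatch_to_others <- function(guide, index, exact_min = TRUE) {
  proto <- guide$protospacer
  own <- which(index$sites$chrom == guide$chrom &
               index$sites$strand == guide$strand &
               index$sites$start == guide$start)
  if (length(own) == 0L)
    stop("guide location ", guide$chrom, ":", guide$start, guide$strand,
         " absent from index: index built from a different genome?")
  if (!identical(index$sites$protospacer[own[1L]], proto))
    stop("guide sequence disagrees with the indexed site at its location")
  own <- own[1L]
  if (index$total_sites <= 1L) return(Inf)
  pool <- setdiff(seed_pool(index, proto), own)
  if (length(pool)) {
    d <- hamming_to_many(proto, index$byte_matrix[, pool, drop = FALSE])
    if (min(d) < 3L) return(as.integer(min(d)))
  }
  if (!exact_min) return(3L)
  d <- hamming_to_many(proto, index$byte_matrix[, -own, drop = FALSE])
  as.integer(min(d))
}

#' Flag guides with genomic or mutual off-target conflicts
#'
#' A candidate passes when (i) no other genomic PAM-adjacent site lies within
#' fewer than `min_mm` mismatches of its protospacer, and (ii) no other
#' candidate in the input (across all features) lies within fewer than
#' `min_mm` mismatches. Conflicting candidate pairs are removed
#' symmetrically: both members fail. All candidates are returned with
#' `offtarget_ok` set; callers subset as needed.
#'
#' @param candidates Candidate `data.frame` (any number of features).
#' @param index A `site_index` built from the same genome.
#' @param min_mm Minimum permitted mismatch distance (default 3).
#' @param use_seed Use the pigeonhole seed index (default `TRUE`); `FALSE`
#'   forces the quadratic scan, kept as the testing oracle.
#' @return `candidates` with `offtarget_ok` filled in.
#' @export
filter_offtargets <- function(candidates, index, min_mm = 3,
                              use_seed = TRUE) {
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$offtarget_ok <- logical(0)
    return(candidates)
  }
  if (min_mm > 3 && use_seed)
    use_seed <- FALSE # seed pigeonhole only certifies distances below 3
  genome_ok <- vapply(seq_len(n), function(i) {
    g <- candidates[i, , drop = FALSE]
    d <- min_mismatch_to_others(g, index, exact_min = !use_seed)
    d >= min_mm
  }, logical(1))
  # mutual conflicts among candidates (strand-normalized protospacers)
  mat <- proto_byte_matrix(candidates$protospacer, index$protospacer_len)
  mutual_ok <- rep(TRUE, n)
  loc <- paste(candidates$chrom, candidates$start, candidates$strand)
  for (i in seq_len(n)) {
    d <- hamming_to_many(candidates$protospacer[i], mat)
    conflict <- d < min_mm & loc != loc[i]
    if (any(conflict)) mutual_ok[i] <- FALSE
  }
  candidates$offtarget_ok <- genome_ok & mutual_ok
  candidates
}
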