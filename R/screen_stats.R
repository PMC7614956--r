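# Negative-binomial readout statistics for high-vs-low sorted fractions.
# Variance convention: Var(Y) = mu + phi * mu^2 (phi = 0 is Poisson).

nb_loglik_rows <- function(y, mu, phi) {
  if (phi < 1e-10) {
    ll <- stats::dpois(y, lambda = mu, log = TRUE)
  } else {
    ll <- stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
  }
  ll[y == 0 & mu == 0] <- 0
  rowSums(ll)
}

# One-group NB mean fit with offsets, vectorized over guides (Fisher-scoring
# on log-mean; the score equation only involves y through sums, so augmented
# non-integer counts are handled too).
nb_fit_means <- function(y, s, phi, tol = 1e-10, max_iter = 200L) {
  y <- as.matrix(y)
  m <- rowSums(y) / sum(s)
  pos <- which(m > 0)
  if (length(pos)) {
    beta <- log(m[pos])
    yp <- y[pos, , drop = FALSE]
    for (iter in seq_len(max_iter)) {
      mu <- exp(beta) %o% s
      denom <- 1 + phi * mu
      score <- rowSums((yp - mu) / denom)
      info <- rowSums(mu / denom)
      step <- pmax(pmin(score / info, 5), -5)
      beta <- beta + step
      if (max(abs(step)) < tol) break
    }
    m[pos] <- exp(beta)
  }
  m
}

as_count_matrix <- function(table) {
  if (inherits(table, "count_table")) table$counts else as.matrix(table)
}

groups_from <- function(table, groups) {
  if (is.null(groups) && inherits(table, "count_table"))
    groups <- table$samples$fraction
  groups <- as.character(groups)
  if (!all(groups %in% c("high", "low")))
    stop("groups must be 'high'/'low' fraction labels")
  if (length(unique(groups)) != 2L)
    stop("both a high and a low fraction are required")
  groups
}

#' Remove guides below a counts-per-million threshold
#'
#' Keeps guides whose CPM exceeds `min_cpm` in at least a fraction
#' `min_samples` of samples. Screens recover only part of the designed pool
#' at usable depth; this gate defines which guides enter the statistics.
#'
#' @param table A `count_table` (or bare matrix).
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Minimum fraction of samples above threshold
#'   (default 0.5).
#' @return Filtered `count_table` (or matrix), with attributes `n_kept` and
#'   `kept_fraction` of the incoming pool.
#' @export
low_count_filter <- function(table, min_cpm = 1, min_samples = 0.5) {
  y <- as_count_matrix(table)
  if (nrow(y) == 0L || ncol(y) == 0L) stop("empty count table")
  cpm <- t(t(y) / colSums(y)) * 1e6
  keep <- rowMeans(cpm > min_cpm) >= min_samples
  out <- if (inherits(table, "count_table")) {
    count_table(y[keep, , drop = FALSE], table$samples,
                no_guide = table$no_guide, no_barcode = table$no_barcode)
  } else {
    y[keep, , drop = FALSE]
  }
  attr(out, "n_kept") <- sum(keep)
  attr(out, "kept_fraction") <- mean(keep)
  out
}

#' RLE (median-of-ratios) normalization factors
#'
#' Per sample, the factor is the median over all-positive guides of the
#' ratio of the guide's count to its across-sample geometric mean, rescaled
#' so the factors have geometric mean 1. Effective library sizes, used as
#' GLM offsets downstream, are the factors multiplied by the geometric mean
#' of the column sums (so they are proportional to the median-of-ratios
#' size factors and on the scale of the observed depths).
#'
#' @param table A `count_table` or matrix.
#' @return A `norm_factors` object: `factors` (geometric mean 1) and
#'   `effective_sizes`, both named by sample.
#' @export
rle_norm_factors <- function(table) {
  y <- as_count_matrix(table)
  if (ncol(y) == 1L) {
    nf <- structure(list(factors = c(1), effective_sizes = colSums(y)),
                    class = "norm_factors")
    names(nf$factors) <- colnames(y)
    return(nf)
  }
  allpos <- rowSums(y > 0) == ncol(y)
  if (!any(allpos))
    stop("no guide has positive counts in every sample; ",
         "apply low_count_filter() first")
  logy <- log(y[allpos, , drop = FALSE])
  loggeo <- rowMeans(logy)
  raw <- exp(apply(logy - loggeo, 2, stats::median))
  factors <- raw / exp(mean(log(raw)))
  eff <- factors * exp(mean(log(colSums(y))))
  structure(list(factors = factors, effective_sizes = eff),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("RLE normalization factors (geometric mean 1):\n")
  print(round(x$factors, 4))
  invisible(x)
}

phi_grid_default <- function(n = 21L) exp(seq(log(1e-4), log(4), length.out = n))

# Cox-Reid adjusted profile log-likelihood of the full (group-means) model,
# summed over guides; the adjustment is -0.5 * log of the per-group Fisher
# information (X'WX is block diagonal for a one-factor design).
apl_total <- function(phi, y, s, groups, per_guide = FALSE) {
  lv <- unique(groups)
  acc <- numeric(nrow(y))
  for (g in lv) {
    cols <- groups == g
    m <- nb_fit_means(y[, cols, drop = FALSE], s[cols], phi)
    mu <- m %o% s[cols]
    ll <- nb_loglik_rows(y[, cols, drop = FALSE], mu, phi)
    w <- rowSums(mu / (1 + phi * mu))
    acc <- acc + ll - 0.5 * log(w)
  }
  if (per_guide) acc else sum(acc)
}

golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f(x2) }
    else { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f(x1) }
  }
  (a + b) / 2
}

#' Estimate the negative-binomial dispersion
#'
#' The common dispersion maximizes the Cox-Reid adjusted profile likelihood
#' of the two-group model over a log-spaced grid on `[1e-4, 4]`, refined by
#' golden-section search to a tolerance of 1e-4. Optional tagwise values
#' shrink each guide's own adjusted profile likelihood toward the common
#' value with weight `prior_df` (as `prior_df` grows, tagwise estimates
#' collapse onto the common one). Guides with an all-zero group are excluded
#' from estimation.
#'
#' @param table A `count_table` or matrix.
#' @param groups `high`/`low` labels per sample (default: the table's
#'   sample sheet fractions).
#' @param factors [rle_norm_factors()] result (computed if `NULL`).
#' @param tagwise Also compute per-guide dispersions (default `FALSE`).
#' @param prior_df Shrinkage weight for tagwise estimation (default 10).
#' @param grid_size Number of grid points (default 21).
#' @return A `dispersion_estimate` object: `common`, optional `tagwise`,
#'   `prior_df`.
#' @export
estimate_dispersion <- function(table, groups = NULL, factors = NULL,
                                tagwise = FALSE, prior_df = 10,
                                grid_size = 21L) {
  y <- as_count_matrix(table)
  groups <- groups_from(table, groups)
  if (ncol(y) < 2L) stop("dispersion estimation needs at least two samples")
  if (is.null(factors)) factors <- rle_norm_factors(table)
  s <- factors$effective_sizes
  ok <- rowSums(y[, groups == "high", drop = FALSE]) > 0 &
        rowSums(y[, groups == "low", drop = FALSE]) > 0
  yy <- y[ok, , drop = FALSE]
  if (nrow(yy) == 0L) stop("no guide has counts in both groups")
  grid <- phi_grid_default(grid_size)
  vals <- vapply(grid, apl_total, numeric(1), y = yy, s = s, groups = groups)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  common <- golden_max(function(p) apl_total(p, yy, s, groups), lo, hi)
  est <- list(common = common, tagwise = NULL, prior_df = prior_df)
  if (tagwise) {
    per <- vapply(grid, apl_total, numeric(nrow(yy)), y = yy, s = s,
                  groups = groups, per_guide = TRUE)
    if (is.null(dim(per))) per <- matrix(per, nrow = 1L)
    shared <- colMeans(per)
    tw_ok <- grid[apply(per + prior_df * rep(shared, each = nrow(per)), 1,
                        which.max)]
    tw <- rep(common, nrow(y))
    tw[ok] <- tw_ok
    names(tw) <- rownames(y)
    est$tagwise <- tw
  }
  structure(est, class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat("NB dispersion: common phi =", signif(x$common, 4))
  if (!is.null(x$tagwise))
    cat(", tagwise range [", signif(min(x$tagwise), 3), ",",
        signif(max(x$tagwise), 3), "] (prior_df =", x$prior_df, ")")
  cat("\n")
  invisible(x)
}

#' Per-guide NB GLM likelihood-ratio tests (high vs low)
#'
#' Fits, per guide, a log-link negative-binomial GLM with the effective
#' library size as offset: full model intercept + fraction, reduced model
#' intercept only. The statistic `2 * (l_full - l_reduced)` is referred to a
#' chi-square with 1 df. The reported `log2fc` (high over low) adds a prior
#' count of 0.125 (scaled by relative library size) to stabilize zero
#' counts; the test itself uses the raw counts. All-zero guides are not
#' fitted and report `p = 1`, `log2fc = 0`.
#'
#' @param table A `count_table` or matrix.
#' @param groups `high`/`low` labels (default from the sample sheet).
#' @param factors [rle_norm_factors()] result (computed if `NULL`).
#' @param dispersion A `dispersion_estimate`, a bare numeric phi, or `NULL`
#'   to estimate the common dispersion first.
#' @param prior_count Prior count for fold-change reporting (default 0.125).
#' @return A `data.frame` with `guide_id`, `log2fc`, `lr_stat`, `p_value`,
#'   `fdr` (Benjamini-Hochberg), `enriched` (log2fc > 3 and FDR < 0.05 by
#'   default; re-flag with [call_enriched()]).
#' @export
glm_lrt <- function(table, groups = NULL, factors = NULL, dispersion = NULL,
                    prior_count = 0.125) {
  y <- as_count_matrix(table)
  groups <- groups_from(table, groups)
  if (is.null(factors)) factors <- rle_norm_factors(table)
  s <- factors$effective_sizes
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(table, groups, factors)
  phi <- if (inherits(dispersion, "dispersion_estimate")) {
    if (is.null(dispersion$tagwise)) rep(dispersion$common, nrow(y))
    else dispersion$tagwise
  } else rep(as.numeric(dispersion), nrow(y))
  hi <- groups == "high"
  lo <- groups == "low"
  n <- nrow(y)
  lr <- numeric(n); log2fc <- numeric(n)
  nonzero <- rowSums(y) > 0
  # fits grouped by phi value so each call stays vectorized over guides
  for (p in unique(phi[nonzero])) {
    rows <- which(nonzero & phi == p)
    yy <- y[rows, , drop = FALSE]
    m_hi <- nb_fit_means(yy[, hi, drop = FALSE], s[hi], p)
    m_lo <- nb_fit_means(yy[, lo, drop = FALSE], s[lo], p)
    m_all <- nb_fit_means(yy, s, p)
    ll_full <- nb_loglik_rows(yy[, hi, drop = FALSE], m_hi %o% s[hi], p) +
      nb_loglik_rows(yy[, lo, drop = FALSE], m_lo %o% s[lo], p)
    ll_red <- nb_loglik_rows(yy, m_all %o% s, p)
    lr[rows] <- pmax(0, 2 * (ll_full - ll_red))
    # prior-augmented refit for reporting
    prior <- prior_count * s / mean(s)
    ya <- yy + rep(prior, each = nrow(yy))
    a_hi <- nb_fit_means(ya[, hi, drop = FALSE], s[hi], p)
    a_lo <- nb_fit_means(ya[, lo, drop = FALSE], s[lo], p)
    log2fc[rows] <- log2(a_hi / a_lo)
  }
  p_value <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  p_value[!nonzero] <- 1
  res <- data.frame(
    guide_id = if (!is.null(rownames(y))) rownames(y)
               else paste0("g", seq_len(n)),
    log2fc = log2fc,
    lr_stat = lr,
    p_value = p_value,
    stringsAsFactors = FALSE
  )
  res$fdr <- bh_adjust(res$p_value)
  res <- call_enriched(res)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` with the input-domain
#' check the screen pipeline relies on.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return FDR values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Flag significantly enriched guides
#'
#' A guide is enriched when `log2fc > lfc_threshold` and
#' `fdr < fdr_threshold`, both strict inequalities.
#'
#' @param results Result `data.frame` from [glm_lrt()].
#' @param lfc_threshold log2 fold-change threshold (default 3).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return `results` with the `enriched` flag (re)computed.
#' @export
call_enriched <- function(results, lfc_threshold = 3, fdr_threshold = 0.05) {
  results$enriched <- results$log2fc > lfc_threshold &
    results$fdr < fdr_threshold
  results
}

#' Summarize guide results to genes by representative guide
#'
#' Per gene, among guides with `log2fc > lfc_threshold` and
#' `fdr < fdr_threshold` (a laxer gate than the enrichment call, default FDR
#' 0.3), the guide with the maximal fold change is selected as
#' representative. Genes with no passing guide are omitted.
#'
#' @param results Result `data.frame` from [glm_lrt()].
#' @param guide_to_gene Named character vector mapping `guide_id` to gene
#'   id; must cover every result row.
#' @param lfc_threshold log2 fold-change gate (default 3).
#' @param fdr_threshold FDR gate (default 0.3).
#' @return `data.frame` with `gene_id`, `representative_guide`,
#'   `representative_log2fc`, `representative_fdr`, ordered by gene.
#' @export
summarize_genes <- function(results, guide_to_gene, lfc_threshold = 3,
                            fdr_threshold = 0.3) {
  if (any(!results$guide_id %in% names(guide_to_gene)))
    stop("guide_to_gene must map every tested guide")
  pass <- results$log2fc > lfc_threshold & results$fdr < fdr_threshold
  r <- results[pass, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(gene_id = character(0),
                      representative_guide = character(0),
                      representative_log2fc = numeric(0),
                      representative_fdr = numeric(0)))
  r$gene_id <- unname(guide_to_gene[r$guide_id])
  pick <- lapply(split(r, r$gene_id), function(g) {
    g[order(-g$log2fc, g$fdr, g$guide_id)[1L], , drop = FALSE]
  })
  out <- do.call(rbind, pick)
  out <- data.frame(gene_id = out$gene_id,
                    representative_guide = out$guide_id,
                    representative_log2fc = out$log2fc,
                    representative_fdr = out$fdr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Droplet screen design
#'
#' @param n_droplets Number of screened droplets.
#' @param lam Poisson cell-loading mean (cells per droplet, default 0.4).
#' @param library_size Number of guides in the designed library.
#' @return A `screen_design` list.
#' @export
screen_design <- function(n_droplets, lam = 0.4, library_size) {
  if (n_droplets < 0) stop("n_droplets must be >= 0")
  if (lam <= 0) stop("lam must be positive")
  if (library_size <= 0) stop("library_size must be positive")
  structure(list(n_droplets = n_droplets, lam = lam,
                 library_size = library_size), class = "screen_design")
}

#' Fold coverage of a droplet screen
#'
#' Droplets times the Poisson loading mean (expected screened cells),
#' divided by the library size.
#'
#' @param design A [screen_design()], or the droplet count if `lam` and
#'   `library_size` are supplied.
#' @param lam,library_size Used when `design` is a bare droplet count.
#' @return Fold coverage (real).
#' @export
fold_coverage <- function(design, lam = 0.4, library_size = NULL) {
  if (!inherits(design, "screen_design")) {
    if (is.null(library_size)) stop("library_size is required")
    design <- screen_design(design, lam, library_size)
  }
  design$n_droplets * design$lam / design$library_size
}

#' Poisson droplet occupancy probabilities
#'
#' For loading mean `lam`: probability of an empty droplet, exactly one
#' cell, and more than one cell.
#'
#' @param lam Poisson mean cells per droplet (> 0).
#' @return Named numeric vector `(empty, single, multiple)`, summing to 1.
#' @export
droplet_occupancy <- function(lam) {
  if (lam <= 0) stop("lam must be positive")
  c(empty = exp(-lam), single = lam * exp(-lam),
    multiple = 1 - (1 + lam) * exp(-lam))
}

#' Percent of the designed guide pool recovered at usable depth
#'
#' @param n_surviving Guides passing the low-count filter.
#' @param n_designed Designed library size.
#' @return Percentage (0-100).
#' @export
guide_pool_coverage <- function(n_surviving, n_designed) {
  if (n_designed <= 0) stop("n_designed must be positive")
  100 * n_surviving / n_designed
}

#' Fit the full screen readout in one call
#'
#' High-level entry point: low-count filtering, RLE normalization, common
#' (optionally tagwise) dispersion estimation, per-guide NB LRTs, BH
#' adjustment and enrichment calls, returned as a single model-style object
#' with `print()` and `summary()` methods.
#'
#' @param table A `count_table`.
#' @param groups `high`/`low` labels (default from the sample sheet).
#' @param lfc_threshold,fdr_threshold Enrichment gates (defaults 3, 0.05).
#' @param min_cpm,min_samples Low-count filter settings (see
#'   [low_count_filter()]); `min_cpm = NULL` disables filtering.
#' @param tagwise,prior_df Dispersion options (see [estimate_dispersion()]).
#' @return A `screen_test` object: `results`, `factors`, `dispersion`,
#'   `thresholds`, `n_input`, `n_tested`.
#' @export
screen_test <- function(table, groups = NULL, lfc_threshold = 3,
                        fdr_threshold = 0.05, min_cpm = 1,
                        min_samples = 0.5, tagwise = FALSE, prior_df = 10) {
  n_input <- nrow(as_count_matrix(table))
  if (!is.null(min_cpm))
    table <- low_count_filter(table, min_cpm, min_samples)
  groups <- groups_from(table, groups)
  factors <- rle_norm_factors(table)
  disp <- estimate_dispersion(table, groups, factors, tagwise = tagwise,
                              prior_df = prior_df)
  results <- glm_lrt(table, groups, factors, disp)
  results <- call_enriched(results, lfc_threshold, fdr_threshold)
  structure(list(results = results, factors = factors, dispersion = disp,
                 thresholds = c(lfc = lfc_threshold, fdr = fdr_threshold),
                 n_input = n_input, n_tested = nrow(results)),
            class = "screen_test")
}

#' @export
print.screen_test <- function(x, ...) {
  cat("Pooled screen enrichment test (NB GLM LRT, high vs low fraction)\n")
  cat("  guides tested:", x$n_tested, "of", x$n_input, "input",
      sprintf("(%.1f%% of pool)\n", 100 * x$n_tested / x$n_input))
  cat("  common dispersion:", signif(x$dispersion$common, 4), "\n")
  cat(sprintf("  enriched [log2FC > %g, FDR < %g]: %d guides\n",
              x$thresholds["lfc"], x$thresholds["fdr"],
              sum(x$results$enriched)))
  invisible(x)
}

#' @export
summary.screen_test <- function(object, n = 10L, ...) {
  print(object)
  top <- object$results[order(object$results$fdr,
                              -object$results$log2fc), , drop = FALSE]
  cat("\nTop guides:\n")
  print(utils::head(top, n), row.names = FALSE)
  invisible(object$results)
}

#' Write guide test results as TSV
#'
#' @param results Result `data.frame` (or `screen_test` object).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "screen_test")) results <- results$results
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
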