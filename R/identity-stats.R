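#' Transcript length summary
#'
#' Computes the count, minimum, maximum, mean, standard deviation and total
#' of transcript lengths, plus a fixed-width histogram with left-closed,
#' right-open bins starting at 0.
#'
#' @param transcripts Transcript data frame (from [read_fasta()] or the
#'   simulator) with a `sequence` column, or a numeric vector of lengths in
#'   bp.
#' @param bin_width Histogram bin width in bp (default 500).
#' @param sample_sd Use the sample (n-1 denominator) standard deviation
#'   (default) or, when `FALSE`, the population standard deviation.
#' @return An object of class `length_summary`: list with `n`, `min_bp`,
#'   `max_bp`, `mean_bp`, `sd_bp`, `total_bp` and `histogram` (data frame
#'   with `bin_start`, `bin_end`, `count`; bins `[start, end)` covering
#'   `[0, max]`).
#' @export
length_summary <- function(transcripts, bin_width = 500L, sample_sd = TRUE) {
  len <- if (is.data.frame(transcripts)) nchar(transcripts$sequence) else as.numeric(transcripts)
  if (length(len) == 0L) stop("no transcripts to summarise", call. = FALSE)
  stopifnot(bin_width >= 1)
  n <- length(len)
  m <- sum(len) / n
  sd_bp <- if (n == 1L) 0 else {
    ss <- sum((len - m)^2)
    sqrt(ss / (if (sample_sd) n - 1L else n))
  }
  breaks <- seq(0L, (max(len) %/% bin_width + 1L) * bin_width, by = bin_width)
  counts <- tabulate(findInterval(len, breaks), nbins = length(breaks) - 1L)
  structure(list(n = n,
                 min_bp = min(len), max_bp = max(len),
                 mean_bp = m, sd_bp = sd_bp,
                 total_bp = sum(len),
                 histogram = data.frame(bin_start = breaks[-length(breaks)],
                                        bin_end = breaks[-1L],
                                        count = counts)),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("Length summary: n = %d, min = %d, max = %d, mean = %.1f, sd = %.1f, total = %.0f bp\n",
              x$n, x$min_bp, x$max_bp, x$mean_bp, x$sd_bp, x$total_bp))
  invisible(x)
}

#' Mean percent identity over a set of ortholog pairs
#'
#' Unweighted arithmetic mean of per-pair percent identity: every ortholog
#' pair counts as one observation regardless of alignment length, matching
#' the use of gene counts as `n` in [two_proportion_ztest()].
#'
#' @param pairs Ortholog-pair data frame carrying a `pct_identity` column
#'   (nucleotide level) and optionally a `protein_identity` column, or a
#'   bare numeric vector of percent identities.
#' @param level `"nucleotide"` (uses `pct_identity`) or `"protein"` (uses
#'   `protein_identity`).
#' @return Mean percent identity (scalar in \[0, 100\]).
#' @export
mean_identity <- function(pairs, level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  x <- if (is.data.frame(pairs)) {
    col <- if (level == "nucleotide") "pct_identity" else "protein_identity"
    if (!col %in% names(pairs)) {
      stop("pairs carry no ", level, " identity column '", col, "'",
           call. = FALSE)
    }
    pairs[[col]]
  } else {
    as.numeric(pairs)
  }
  if (length(x) == 0L) stop("empty pair set", call. = FALSE)
  if (anyNA(x)) {
    stop("pair set contains missing ", level, " identities", call. = FALSE)
  }
  sum(x) / length(x)
}

#' Two-proportion z-test (pooled variance)
#'
#' The classical z-score for comparing two population proportions with the
#' pooled estimate `p = (p1*n1 + p2*n2) / (n1 + n2)` and
#' `z = (p1 - p2) / sqrt(p*(1-p)*(1/n1 + 1/n2))`, without continuity
#' correction. The one-tailed p-value tests the alternative `p1 > p2` (order
#' the arguments accordingly); the two-tailed p-value is
#' `2 * min(p_one, 1 - p_one)`.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @param n1,n2 Sample sizes (positive integers).
#' @param tail `"two"` (default) or `"one"`.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return Object of class `prop_ztest`: list with `p1`, `p2`, `n1`, `n2`,
#'   `z`, `p_value`, `p_one_tailed`, `p_two_tailed`, `tail`, `alpha`.
#' @export
two_proportion_ztest <- function(p1, p2, n1, n2, tail = c("two", "one"),
                                 alpha = 0.05) {
  tail <- match.arg(tail)
  stopifnot(length(p1) == 1L, length(p2) == 1L,
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 1, n2 >= 1)
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    stop("degenerate pooled proportion (", pooled,
         "): variance is zero", call. = FALSE)
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p_one <- stats::pnorm(z, lower.tail = FALSE)
  # equals 2 * min(p_one, 1 - p_one), computed tail-stably for extreme z
  p_two <- 2 * stats::pnorm(-abs(z))
  structure(list(p1 = p1, p2 = p2, n1 = n1, n2 = n2, z = z,
                 p_value = if (tail == "one") p_one else p_two,
                 p_one_tailed = p_one, p_two_tailed = p_two,
                 tail = tail, alpha = alpha),
            class = "prop_ztest")
}

#' @export
print.prop_ztest <- function(x, ...) {
  cat(sprintf("Two-proportion z-test: p1 = %.5f (n1 = %d), p2 = %.5f (n2 = %d)\n",
              x$p1, as.integer(x$n1), x$p2, as.integer(x$n2)))
  cat(sprintf("  z = %.4f, %s-tailed p = %.6g (alpha = %g)\n",
              x$z, x$tail, x$p_value, x$alpha))
  invisible(x)
}

#' Partition conservation-ranked genes into k subsets
#'
#' Splits a list of genes, pre-sorted by decreasing identity, into `k`
#' contiguous partitions. The first partition receives
#' `floor(N/k) + N mod k` genes and each remaining partition `floor(N/k)`,
#' so concatenating the partitions restores the input exactly (e.g. 6,952
#' genes in 10 partitions: 697 then nine of 695).
#'
#' @param ordered_genes Character vector of gene ids sorted by decreasing
#'   identity (ties broken by identifier), or a data frame with columns
#'   `gene` and `identity` in that order.
#' @param k Number of partitions (`N >= k >= 1`).
#' @return Object of class `partition_set`: list with `k`, `n`, `sizes` and
#'   `partitions` — a list of `k` elements, each a list with `index`,
#'   `members` (character vector) and `identity_range` (`c(max, min)` within
#'   the partition, `NA` when identities were not supplied).
#' @export
partition_by_conservation <- function(ordered_genes, k = 10L) {
  if (is.data.frame(ordered_genes)) {
    genes <- as.character(ordered_genes$gene)
    identity <- as.numeric(ordered_genes$identity)
  } else {
    genes <- as.character(ordered_genes)
    identity <- rep(NA_real_, length(genes))
  }
  n <- length(genes)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (n < k) {
    stop("cannot split ", n, " genes into ", k, " partitions", call. = FALSE)
  }
  base <- n %/% k
  sizes <- c(base + n %% k, rep(base, k - 1L))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  parts <- lapply(seq_len(k), function(i) {
    idx <- starts[[i]]:ends[[i]]
    list(index = i,
         members = genes[idx],
         identity_range = c(max = identity[idx][1L],
                            min = identity[idx][length(idx)]))
  })
  structure(list(k = k, n = n, sizes = sizes, partitions = parts),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  cat("Conservation partitions: ", x$n, " genes in ", x$k,
      " partitions (sizes ", paste(unique(x$sizes), collapse = "/"), ")\n",
      sep = "")
  invisible(x)
}

#' Gene-by-species percent-identity matrix
#'
#' Builds the tabular form of a cross-species identity heatmap: one row per
#' gene of interest present in at least one species' ortholog-pair set, one
#' column per species, cells holding percent identity (`NA` when the gene
#' has no pair in that species). Rows are sorted by decreasing identity in
#' the `order_by` species column (missing values last, ties broken by gene
#' id).
#'
#' @param genes A `gene_set`, or character vector of focal gene/transcript
#'   ids.
#' @param pairs_by_species Named list of ortholog-pair data frames (see
#'   [reciprocal_best_hits()]).
#' @param order_by Species column used to order the rows (must be a name of
#'   `pairs_by_species`).
#' @param level Identity level to extract: `"nucleotide"` (`pct_identity`)
#'   or `"protein"` (`protein_identity`).
#' @return Numeric matrix (genes x species) with row and column names.
#' @export
identity_matrix <- function(genes, pairs_by_species, order_by,
                            level = c("nucleotide", "protein")) {
  level <- match.arg(level)
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- unique(as.character(genes))
  stopifnot(is.list(pairs_by_species), !is.null(names(pairs_by_species)))
  if (!order_by %in% names(pairs_by_species)) {
    stop("order_by species '", order_by, "' is not configured", call. = FALSE)
  }
  col <- if (level == "nucleotide") "pct_identity" else "protein_identity"
  m <- sapply(pairs_by_species, function(pairs) {
    if (!col %in% names(pairs)) return(rep(NA_real_, length(genes)))
    pairs[[col]][match(genes, pairs$focal_id)]
  })
  m <- matrix(m, nrow = length(genes),
              dimnames = list(genes, names(pairs_by_species)))
  present <- rowSums(!is.na(m)) > 0L
  if (!any(present)) {
    stop("gene set is disjoint from every species' pair set", call. = FALSE)
  }
  m <- m[present, , drop = FALSE]
  ord <- order(-m[, order_by], rownames(m), method = "radix",
               na.last = TRUE)
  m[ord, , drop = FALSE]
}
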