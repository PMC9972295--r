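#' One-sided (enrichment tail) Fisher exact test
#'
#' Computes `P(X >= a)` where `X` is hypergeometric with population size
#' `N = a+b+c+d`, `K = a+c` successes and `n = a+b` draws — the upper-tail
#' Fisher exact p-value for over-representation in a 2x2 table
#' (`a` = genes in the set with the term, `b` = set genes without it,
#' `c` = background-minus-set genes with it, `d` = the rest).
#'
#' The function is vectorised over tables. Internally tables are grouped by
#' their margins; each group's log probability mass is evaluated once via
#' `lchoose`, rescaled at the distribution mode, and tail-summed by an exact
#' reverse cumulative sum, so the computation is stable for p-values far
#' below double underflow of individual terms' naive products.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectors are recycled to
#'   a common length).
#' @return Vector of upper-tail p-values in \[0, 1\].
#' @examples
#' fisher_exact_greater(5, 5, 5, 85)
#' sum(dhyper(5:10, 10, 90, 10))   # enumeration cross-check
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  if (any(a < 0 | b < 0 | c < 0 | d < 0) ||
      any(a != floor(a) | b != floor(b) | c != floor(c) | d != floor(d))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  p <- numeric(len)
  p[N == 0] <- 1   # empty table: P(X >= 0) = 1

  todo <- which(N > 0)
  if (length(todo) == 0L) return(p)

  key <- if (max(N) < 94906L) {
    # exact numeric key below 2^53
    (N[todo] * 94906 + K[todo]) * 94906 + n[todo]
  } else {
    paste(N[todo], K[todo], n[todo], sep = ":")
  }
  for (g in split(todo, key)) {
    i1 <- g[[1L]]
    Ng <- N[[i1]]; Kg <- K[[i1]]; ng <- n[[i1]]
    lo <- max(0, Kg + ng - Ng)
    hi <- min(Kg, ng)
    x <- lo:hi
    lpmf <- lchoose(Kg, x) + lchoose(Ng - Kg, ng - x) - lchoose(Ng, ng)
    scale <- max(lpmf)
    tail <- rev(cumsum(rev(exp(lpmf - scale))))
    ltail <- scale + log(tail)
    idx <- a[g] - lo + 1
    pv <- ifelse(a[g] > hi, 0,
                 exp(ltail[pmax(idx, 1)]))
    p[g] <- pmin(pv, 1)
  }
  p
}

#' Bonferroni adjustment
#'
#' Elementwise `min(1, m * p)` with `m = length(pvals)`; a thin wrapper
#' around [stats::p.adjust()] kept for a uniform enrichment interface.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
adjust_bonferroni <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "bonferroni")
}

#' Benjamini-Hochberg (false discovery rate) adjustment
#'
#' Step-up FDR adjustment: with p sorted ascending,
#' `q_i = min over j >= i of min(1, p_j * m / j)`, returned in input order.
#' Wrapper around [stats::p.adjust()].
#'
#' @inheritParams adjust_bonferroni
#' @return Adjusted p-values in input order.
#' @export
adjust_benjamini_hochberg <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Annotation-term enrichment of a gene set
#'
#' Tests every annotation term for over-representation in a gene set against
#' the annotation's background universe using the one-sided Fisher exact
#' test, with Bonferroni and Benjamini-Hochberg multiple-testing adjustment.
#' Genes outside the background are dropped before testing (their count is
#' reported with a message). Terms overlapping the set in fewer than
#' `min_count` genes are excluded, and the multiple-testing universe `m` is
#' the number of terms passing that filter in this run.
#'
#' @param genes A `gene_set` or character vector of gene ids.
#' @param annotation An [annotation_table()].
#' @param min_count Minimum overlap (`a`) for a term to be tested
#'   (default 2).
#' @param ease Use the EASE variant (Fisher with one success removed from
#'   the observed overlap, i.e. `P(X >= a - 1)`), the conservative score
#'   DAVID reports. Default `FALSE` (plain Fisher).
#' @return Data frame of class `enrichment_result`, sorted by ascending
#'   p-value (ties by term id), with columns `term_id`, `term_name`,
#'   `count`, `percent` (`100 * count / |mapped gene set|`), `p_value`,
#'   `bonferroni`, `benjamini`.
#' @export
enrich <- function(genes, annotation, min_count = 2L, ease = FALSE) {
  stopifnot(inherits(annotation, "annotation_table"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  genes <- unique(as.character(genes))
  mapped <- intersect(genes, annotation$background)
  dropped <- length(genes) - length(mapped)
  if (dropped > 0L) {
    message("enrich: dropped ", dropped, " gene(s) outside the background")
  }
  if (length(mapped) == 0L) {
    stop("gene set does not intersect the annotation background",
         call. = FALSE)
  }
  if (length(annotation$terms) == 0L) {
    stop("annotation table contains no terms", call. = FALSE)
  }
  N <- length(annotation$background)
  set_size <- length(mapped)
  aa <- vapply(annotation$terms, function(tg) sum(mapped %in% tg), numeric(1))
  KK <- lengths(annotation$terms)   # term genes all lie in background
  keep <- aa >= min_count
  res <- data.frame(term_id = names(annotation$terms)[keep],
                    term_name = unname(annotation$term_names[keep]),
                    count = as.integer(aa[keep]),
                    percent = 100 * aa[keep] / set_size,
                    stringsAsFactors = FALSE)
  a <- aa[keep]
  b <- set_size - a
  cc <- KK[keep] - a
  dd <- N - KK[keep] - b
  a_obs <- if (ease) pmax(a - 1, 0) else a
  res$p_value <- fisher_exact_greater(a_obs, b + (a - a_obs), cc, dd)
  res$bonferroni <- adjust_bonferroni(res$p_value)
  res$benjamini <- adjust_benjamini_hochberg(res$p_value)
  res <- res[order(res$p_value, res$term_id, method = "radix"), , drop = FALSE]
  row.names(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Per-partition enrichment against the full background
#'
#' Runs [enrich()] for every conservation partition, each tested against the
#' annotation's complete background universe ("partition versus rest of
#' genome"), so the term universe `m` is determined by the same annotation
#' in every run.
#'
#' @param partitions A `partition_set` from [partition_by_conservation()].
#' @param annotation An [annotation_table()].
#' @inheritParams enrich
#' @return Named list (`partition_01`, ...) of `enrichment_result` data
#'   frames.
#' @export
enrich_partitions <- function(partitions, annotation, min_count = 2L,
                              ease = FALSE) {
  stopifnot(inherits(partitions, "partition_set"))
  res <- lapply(partitions$partitions, function(p) {
    enrich(p$members, annotation, min_count = min_count, ease = ease)
  })
  names(res) <- sprintf("partition_%02d", seq_along(res))
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment: ", nrow(x), " term(s) tested\n", sep = "")
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 10), digits = 4,
                     row.names = FALSE)
    if (nrow(x) > 10) cat("  ... and", nrow(x) - 10, "more\n")
  }
  invisible(x)
}
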