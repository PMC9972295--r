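#' Single best subject per query from a BLAST hit table
#'
#' Reduces a hit table for one query-species/subject-species direction to at
#' most one subject per query. Hits failing the e-value cutoff are discarded;
#' multiple HSPs for the same query-subject pair are represented by their
#' single best HSP; the winning subject per query maximises bit score with a
#' deterministic tie-break chain: lower e-value, then higher percent
#' identity, then lexicographically smaller subject id.
#'
#' @param hits Hit data frame as returned by [read_blast_tab()]. All hits
#'   are assumed to share one query species and one subject species.
#' @param evalue_cutoff Retain hits with `evalue <= evalue_cutoff`
#'   (default `1e-5`).
#' @return A best-hit map: data frame with one row per query and columns
#'   `query_id`, `subject_id`, `bitscore`, `evalue`, `pct_identity`.
#' @export
best_hits <- function(hits, evalue_cutoff = 1e-5) {
  stopifnot(is.data.frame(hits))
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      pct_identity = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)

  ord <- order(hits$query_id, hits$subject_id, -hits$bitscore, hits$evalue,
               -hits$pct_identity, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  # best HSP represents each query-subject pair
  pair_key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  hits <- hits[!duplicated(pair_key), , drop = FALSE]
  # best subject per query
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue,
               -hits$pct_identity, hits$subject_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
  data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
             bitscore = hits$bitscore, evalue = hits$evalue,
             pct_identity = hits$pct_identity, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Reciprocal best hits ("blast-back") between two species
#'
#' A focal transcript `f` and reference gene `r` form an ortholog pair iff
#' `f`'s best subject in the forward direction is `r` and `r`'s best subject
#' in the reverse direction is `f`. The resulting relation is one-to-one in
#' both coordinates by construction. The identity and score attached to a
#' pair are taken from the forward (focal to reference) direction.
#'
#' @param fwd Best-hit map for the focal-to-reference direction
#'   (from [best_hits()]).
#' @param rev Best-hit map for the reference-to-focal direction.
#' @return Data frame of ortholog pairs with columns `focal_id`,
#'   `reference_id`, `bitscore`, `evalue`, `pct_identity`.
#' @export
reciprocal_best_hits <- function(fwd, rev) {
  stopifnot(is.data.frame(fwd), is.data.frame(rev))
  if (nrow(fwd) == 0L || nrow(rev) == 0L) {
    return(data.frame(focal_id = character(0), reference_id = character(0),
                      bitscore = numeric(0), evalue = numeric(0),
                      pct_identity = numeric(0), stringsAsFactors = FALSE))
  }
  back <- rev$subject_id[match(fwd$subject_id, rev$query_id)]
  keep <- !is.na(back) & back == fwd$query_id
  pairs <- data.frame(focal_id = fwd$query_id[keep],
                      reference_id = fwd$subject_id[keep],
                      bitscore = fwd$bitscore[keep],
                      evalue = fwd$evalue[keep],
                      pct_identity = fwd$pct_identity[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  # one-to-one by construction; assert it anyway
  stopifnot(!anyDuplicated(pairs$focal_id), !anyDuplicated(pairs$reference_id))
  pairs
}

#' Priority-cascade non-redundant ortholog assignment
#'
#' Assigns each focal transcript to the first reference species, in priority
#' order, for which it has a reciprocal-best-hit pair. Each focal transcript
#' therefore appears at most once in the output, and the output covers the
#' union of the per-species focal-id sets (the non-redundant ortholog set).
#'
#' @param pairs_by_species Named list of ortholog-pair data frames from
#'   [reciprocal_best_hits()], one per reference species.
#' @param priority Character vector listing every name of `pairs_by_species`
#'   exactly once, highest priority first (default: the names in their
#'   current order).
#' @return Assignment data frame with columns `focal_id`,
#'   `reference_species`, `reference_id`, `priority_rank` (1 = highest
#'   priority species) and `pct_identity`, ordered by rank then focal id.
#' @export
cascade_assign <- function(pairs_by_species, priority = names(pairs_by_species)) {
  stopifnot(is.list(pairs_by_species), !is.null(names(pairs_by_species)))
  if (!setequal(priority, names(pairs_by_species)) ||
      anyDuplicated(priority) || length(priority) != length(pairs_by_species)) {
    stop("priority must list every species of pairs_by_species exactly once",
         call. = FALSE)
  }
  for (sp in names(pairs_by_species)) {
    dup <- anyDuplicated(pairs_by_species[[sp]]$focal_id)
    if (dup) {
      stop("duplicate focal_id '", pairs_by_species[[sp]]$focal_id[[dup]],
           "' in pair set for species '", sp,
           "' (input must be one-to-one)", call. = FALSE)
    }
  }
  assigned <- character(0)
  out <- vector("list", length(priority))
  for (k in seq_along(priority)) {
    sp <- priority[[k]]
    pairs <- pairs_by_species[[sp]]
    take <- !(pairs$focal_id %in% assigned)
    out[[k]] <- data.frame(focal_id = pairs$focal_id[take],
                           reference_species = rep(sp, sum(take)),
                           reference_id = pairs$reference_id[take],
                           priority_rank = rep(k, sum(take)),
                           pct_identity = pairs$pct_identity[take],
                           stringsAsFactors = FALSE)
    assigned <- c(assigned, pairs$focal_id[take])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$priority_rank, res$focal_id, method = "radix"), ,
             drop = FALSE]
  row.names(res) <- NULL
  res
}

#' One-to-one orthologs shared across every reference species
#'
#' Intersects the per-species reciprocal-best-hit pair sets on the focal
#' identifier: a focal transcript is retained exactly when it has a pair in
#' every species, and each species' partner id and identity are attached.
#'
#' @inheritParams cascade_assign
#' @return Data frame with column `focal_id` followed, for each species
#'   `<sp>`, by `<sp>_id` and `<sp>_identity`; one row per shared ortholog,
#'   ordered by focal id. The row count is bounded above by the smallest
#'   per-species pair count.
#' @export
shared_orthologs <- function(pairs_by_species) {
  stopifnot(is.list(pairs_by_species), length(pairs_by_species) > 0L,
            !is.null(names(pairs_by_species)))
  ids <- Reduce(intersect, lapply(pairs_by_species, `[[`, "focal_id"))
  ids <- sort(ids)
  res <- data.frame(focal_id = ids, stringsAsFactors = FALSE)
  for (sp in names(pairs_by_species)) {
    pairs <- pairs_by_species[[sp]]
    i <- match(ids, pairs$focal_id)
    res[[paste0(sp, "_id")]] <- pairs$reference_id[i]
    res[[paste0(sp, "_identity")]] <- pairs$pct_identity[i]
  }
  res
}

#' Score ortholog recovery against a planted truth
#'
#' Compares a cascade assignment with the simulator's planted ortholog map.
#' An assignment is correct when the assigned reference id equals the true
#' ortholog of that focal transcript in the assigned species. Recall is
#' measured against the focal transcripts that have at least one surviving
#' (non-dropped) reference ortholog in the truth.
#'
#' @param assignments Assignment data frame from [cascade_assign()].
#' @param truth A `synthetic_truth` object from [evolve_species()] /
#'   [simulate_orthology_study()].
#' @return List with elements `precision`, `recall`, `n_assigned`,
#'   `n_correct` and `n_recoverable`.
#' @export
score_recovery <- function(assignments, truth) {
  stopifnot(is.data.frame(assignments), inherits(truth, "synthetic_truth"))
  orth <- truth$orthologs   # focal_id x species matrix of reference ids
  i <- match(assignments$focal_id, rownames(orth))
  expected <- orth[cbind(i, match(assignments$reference_species, colnames(orth)))]
  correct <- !is.na(expected) & expected == assignments$reference_id
  recoverable <- rownames(orth)[rowSums(!is.na(orth)) > 0L]
  n_assigned <- nrow(assignments)
  list(precision = if (n_assigned) sum(correct) / n_assigned else NA_real_,
       recall = if (length(recoverable)) {
         sum(correct & assignments$focal_id %in% recoverable) / length(recoverable)
       } else NA_real_,
       n_assigned = n_assigned,
       n_correct = sum(correct),
       n_recoverable = length(recoverable))
}
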