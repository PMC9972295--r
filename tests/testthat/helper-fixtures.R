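# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorised implementations.

tiny_config <- function(...) {
  defaults <- list(n_genes = 30L, cds_length_codons = c(mean = 120, sd = 25),
                   seed = 42L, noise_rate = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

random_hit_table <- function(n, n_queries = 20L, n_subjects = 15L) {
  data.frame(
    query_id = sprintf("q%02d", sample.int(n_queries, n, replace = TRUE)),
    subject_id = sprintf("s%02d", sample.int(n_subjects, n, replace = TRUE)),
    pct_identity = round(stats::runif(n, 60, 100), 2),
    aln_length = sample(100:2000, n, replace = TRUE),
    mismatches = sample(0:50, n, replace = TRUE),
    gap_opens = sample(0:3, n, replace = TRUE),
    qstart = rep(1L, n), qend = sample(100:2000, n, replace = TRUE),
    sstart = rep(1L, n), send = sample(100:2000, n, replace = TRUE),
    evalue = 10^(-sample(0:60, n, replace = TRUE)),
    bitscore = sample(5:200, n, replace = TRUE) * 2,
    stringsAsFactors = FALSE
  )
}

# Exhaustive per-query argmax: scans every hit, no sorting machinery shared
# with best_hits().
oracle_best_hits <- function(hits, evalue_cutoff = 1e-5) {
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    hq <- hits[hits$query_id == q, , drop = FALSE]
    # collapse HSPs: best row per subject
    best_by_subject <- list()
    for (s in unique(hq$subject_id)) {
      hs <- hq[hq$subject_id == s, , drop = FALSE]
      best <- hs[1L, ]
      if (nrow(hs) > 1L) for (i in 2:nrow(hs)) {
        cand <- hs[i, ]
        if (hit_beats(cand, best)) best <- cand
      }
      best_by_subject[[s]] <- best
    }
    winner <- NULL
    for (s in sort(names(best_by_subject))) {
      cand <- best_by_subject[[s]]
      if (is.null(winner) || hit_beats(cand, winner)) winner <- cand
    }
    out[[q]] <- winner
  }
  if (length(out) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0)))
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res[, c("query_id", "subject_id", "bitscore", "evalue", "pct_identity")]
}

# strict "better hit" comparison: bitscore, then evalue, then identity, then
# subject id (the caller iterates subjects in ascending order, so equality on
# all keys keeps the incumbent = smaller subject id)
hit_beats <- function(cand, best) {
  if (cand$bitscore != best$bitscore) return(cand$bitscore > best$bitscore)
  if (cand$evalue != best$evalue) return(cand$evalue < best$evalue)
  if (cand$pct_identity != best$pct_identity) {
    return(cand$pct_identity > best$pct_identity)
  }
  cand$subject_id < best$subject_id
}

# set-comprehension RBH oracle over all (f, r) combinations
oracle_rbh <- function(fwd, rev) {
  keep <- logical(nrow(fwd))
  for (i in seq_len(nrow(fwd))) {
    f <- fwd$query_id[[i]]; r <- fwd$subject_id[[i]]
    j <- which(rev$query_id == r)
    keep[[i]] <- length(j) == 1L && rev$subject_id[[j]] == f
  }
  fwd[keep, c("query_id", "subject_id")]
}

# random one-to-one pair sets keyed by focal id, for cascade/shared tests
random_pair_sets <- function(species, focal_pool, p_present = 0.6) {
  out <- list()
  for (sp in species) {
    take <- focal_pool[stats::runif(length(focal_pool)) < p_present]
    out[[sp]] <- data.frame(
      focal_id = take,
      reference_id = paste0(sp, "_", take),
      bitscore = stats::runif(length(take), 100, 1000),
      evalue = 10^(-stats::runif(length(take), 10, 60)),
      pct_identity = round(stats::runif(length(take), 70, 100), 2),
      stringsAsFactors = FALSE)
  }
  out
}

write_temp_lines <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
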