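#' Simulation configuration for the synthetic ortholog benchmark
#'
#' Bundles and validates every knob of the multi-species transcript
#' simulator. The defaults emulate the observed characteristics of a
#' shrew-like focal transcriptome against four mammalian reference species:
#' per-species divergence chosen so expected nucleotide identities are
#' roughly 88.6 (human), 85.94 (mouse), 88.0 (dog) and 88.7 (ferret)
#' percent; a synonymous substitution bias that places amino-acid identity
#' near 90 percent for the most diverged species; CDS lengths of
#' 492 +/- 150 codons with 75 bp untranslated flanks (so mean transcript
#' length after fragmentation is about 1.5 kb); fragmented transcripts no
#' shorter than 201 bp; and moderate per-species ortholog dropout.
#'
#' @param n_genes Number of ancestral genes.
#' @param focal Focal species label.
#' @param divergence Named vector of per-site substitution probabilities in
#'   \[0, 0.5\], one per reference species (names define the species set).
#' @param synonymous_bias Fraction of CDS substitutions forced synonymous,
#'   in \[0, 1\].
#' @param paralog_rate Per-gene probability of a duplicated (paralogous)
#'   copy in each reference species.
#' @param paralog_extra_divergence Additional divergence applied to paralog
#'   copies beyond the species divergence.
#' @param fragment_rate Probability that a focal transcript is truncated to
#'   a random window.
#' @param min_fragment_bp Minimum emitted fragment length (>= 201).
#' @param dropout_rate Per-species per-gene probability that the reference
#'   ortholog is missing; scalar or named per-species vector.
#' @param cds_length_codons `c(mean, sd)` of CDS length in codons (start and
#'   stop codons included).
#' @param min_cds_codons Lower truncation of the CDS length draw.
#' @param utr_bp Untranslated flank length added on each side of the CDS.
#' @param noise_rate Expected number of spurious alignment hits per focal
#'   transcript per species per direction.
#' @param n_terms Number of background annotation terms planted by the
#'   study-level generator.
#' @param base_rate Background per-gene term-membership probability.
#' @param enriched_fold Fold over-representation of the planted enriched
#'   term (>= 1).
#' @param enriched_set_size Size of the planted term's target gene subset.
#' @param seed Integer seed; all stage-level randomness is derived from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       focal = "shrew",
                       divergence = c(human = 0.114, mouse = 0.14063,
                                      dog = 0.120, ferret = 0.113),
                       synonymous_bias = 0.72,
                       paralog_rate = 0.05,
                       paralog_extra_divergence = 0.08,
                       fragment_rate = 0.15,
                       min_fragment_bp = 201L,
                       dropout_rate = 0.15,
                       cds_length_codons = c(mean = 492, sd = 150),
                       min_cds_codons = 67L,
                       utr_bp = 75L,
                       noise_rate = 0.05,
                       n_terms = 50L,
                       base_rate = 0.05,
                       enriched_fold = 10,
                       enriched_set_size = 50L,
                       seed = 1L) {
  species <- names(divergence)
  if (is.null(species) || anyDuplicated(c(focal, species))) {
    stop("divergence must be a named vector with unique species labels",
         call. = FALSE)
  }
  if (length(dropout_rate) == 1L) {
    dropout_rate <- stats::setNames(rep(dropout_rate, length(species)), species)
  }
  dropout_rate <- dropout_rate[species]
  probs <- c(divergence, synonymous_bias, paralog_rate, fragment_rate,
             dropout_rate, base_rate)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("all rates and probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(divergence > 0.5)) {
    stop("per-site divergence must not exceed 0.5", call. = FALSE)
  }
  if (min_fragment_bp < 201L) {
    stop("min_fragment_bp must be at least 201", call. = FALSE)
  }
  if (enriched_fold < 1) stop("enriched_fold must be >= 1", call. = FALSE)
  stopifnot(n_genes >= 0, min_cds_codons >= 3, utr_bp >= 0,
            cds_length_codons[["mean"]] > 0, cds_length_codons[["sd"]] >= 0,
            noise_rate >= 0, n_terms >= 0, enriched_set_size >= 0)
  structure(list(n_genes = as.integer(n_genes), focal = focal,
                 species = species, divergence = divergence,
                 synonymous_bias = synonymous_bias,
                 paralog_rate = paralog_rate,
                 paralog_extra_divergence = paralog_extra_divergence,
                 fragment_rate = fragment_rate,
                 min_fragment_bp = as.integer(min_fragment_bp),
                 dropout_rate = dropout_rate,
                 cds_length_codons = cds_length_codons,
                 min_cds_codons = as.integer(min_cds_codons),
                 utr_bp = as.integer(utr_bp),
                 noise_rate = noise_rate,
                 n_terms = as.integer(n_terms), base_rate = base_rate,
                 enriched_fold = enriched_fold,
                 enriched_set_size = as.integer(enriched_set_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# --- genetic-code tables -----------------------------------------------------

.codon_cache <- new.env(parent = emptyenv())

# Precomputed per-(codon, position) substitution options, built once from
# Biostrings::GENETIC_CODE. Keys are (codon_index - 1) * 3 + position.
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  bases <- c("A", "C", "G", "T")
  nkey <- length(codons) * 3L
  syn_n <- integer(nkey); nonsyn_n <- integer(nkey)
  syn_mat <- matrix(NA_character_, nkey, 3L)
  nonsyn_mat <- matrix(NA_character_, nkey, 3L)
  degen_pos <- vector("list", length(codons))
  for (ci in seq_along(codons)) {
    cod <- strsplit(codons[[ci]], "")[[1L]]
    for (pos in 1:3) {
      key <- (ci - 1L) * 3L + pos
      syn <- character(0); nonsyn <- character(0)
      for (bb in setdiff(bases, cod[[pos]])) {
        alt <- cod; alt[[pos]] <- bb
        alt_aa <- gc[[paste0(alt, collapse = "")]]
        if (alt_aa == aa[[ci]]) {
          if (alt_aa != "*") syn <- c(syn, bb)
        } else if (alt_aa != "*") {
          nonsyn <- c(nonsyn, bb)
        }
      }
      syn_n[[key]] <- length(syn)
      nonsyn_n[[key]] <- length(nonsyn)
      if (length(syn)) syn_mat[key, seq_along(syn)] <- syn
      if (length(nonsyn)) nonsyn_mat[key, seq_along(nonsyn)] <- nonsyn
    }
    degen_pos[[ci]] <- which(syn_n[(ci - 1L) * 3L + 1:3] > 0L)
  }
  alt_mat <- t(vapply(bases, function(bb) setdiff(bases, bb), character(3)))
  rownames(alt_mat) <- bases
  sense <- codons[aa != "*"]
  .codon_cache$tab <- list(codons = codons, aa = aa,
                           stop_codons = codons[aa == "*"],
                           sense_codons = sense,
                           syn_n = syn_n, syn_mat = syn_mat,
                           nonsyn_n = nonsyn_n, nonsyn_mat = nonsyn_mat,
                           degen_pos = degen_pos, alt_mat = alt_mat)
  .codon_cache$tab
}

# Translate `n_codons` codons of `seq` starting at `start` (1-based).
# Vectorised codon lookup against the standard genetic code.
translate_codons <- function(seq, start, n_codons) {
  if (n_codons <= 0L) return("")
  tab <- codon_tables()
  s <- seq.int(start, by = 3L, length.out = n_codons)
  cods <- substring(seq, s, s + 2L)
  paste0(tab$aa[match(cods, tab$codons)], collapse = "")
}

# --- ancestral genes ---------------------------------------------------------

#' Generate ancestral gene transcripts
#'
#' Draws `n_genes` random coding sequences — start codon, random sense
#' codons with no internal stop, stop codon — with CDS lengths from the
#' configured (truncated) normal distribution, flanked by random
#' untranslated sequence. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `ancestral_genes`: list with `transcripts` (data
#'   frame of `transcript_id`, `sequence`), `genes` (data frame of
#'   `gene_id`, `cds_start`, `n_codons`, `length`) and `config`.
#' @export
generate_ancestral_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tab <- codon_tables()
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  ncod <- pmax(config$min_cds_codons,
               round(stats::rnorm(n, config$cds_length_codons[["mean"]],
                                  config$cds_length_codons[["sd"]])))
  seqs <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    body <- sample(tab$sense_codons, ncod[[i]] - 2L, replace = TRUE)
    stopc <- sample(tab$stop_codons, 1L)
    utr5 <- paste0(sample(bases, config$utr_bp, replace = TRUE), collapse = "")
    utr3 <- paste0(sample(bases, config$utr_bp, replace = TRUE), collapse = "")
    seqs[[i]] <- paste0(utr5, paste0(c("ATG", body, stopc), collapse = ""), utr3)
  }
  structure(list(transcripts = data.frame(transcript_id = gene_id,
                                          sequence = seqs,
                                          stringsAsFactors = FALSE),
                 genes = data.frame(gene_id = gene_id,
                                    cds_start = rep(config$utr_bp + 1L, n),
                                    n_codons = as.integer(ncod),
                                    length = nchar(seqs),
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "ancestral_genes")
}

# Per-gene mutation metadata, reused across species.
gene_mutation_meta <- function(seq, cds_start, n_codons) {
  tab <- codon_tables()
  n_sense <- n_codons - 1L             # exclude the terminal stop codon
  s <- seq.int(cds_start, by = 3L, length.out = n_sense)
  cods <- substring(seq, s, s + 2L)
  ci <- match(cods, tab$codons)
  site_key <- rep((ci - 1L) * 3L, each = 3L) + rep(1:3, n_sense)
  cds_sites <- seq.int(cds_start, cds_start + 3L * n_sense - 1L)
  degen <- cds_sites[tab$syn_n[site_key] > 0L]
  Lt <- nchar(seq)
  neutral <- setdiff(seq_len(Lt), cds_sites)
  list(Lt = Lt, cds_sites = cds_sites, site_key = site_key,
       degen_sites = degen, neutral_sites = neutral)
}

# sample() without the length-1 surprise
sample_int <- function(x, k) x[sample.int(length(x), k)]

# Mutate one transcript at per-site divergence `d` with synonymous bias `b`.
# Exactly n_sub ~ Binomial(Lt, d) distinct sites change, each to a different
# base, so expected nucleotide identity to the ancestor is 1 - d. A fraction
# `b` of CDS-landing substitutions is redirected to degenerate sites and made
# synonymous (purifying selection); the rest are amino-acid-changing where
# possible and never create an internal stop codon.
mutate_transcript <- function(chars, meta, d, b) {
  tab <- codon_tables()
  n_sub <- stats::rbinom(1L, meta$Lt, d)
  if (n_sub == 0L) return(chars)
  n_cds <- length(meta$cds_sites)
  m <- stats::rbinom(1L, n_sub, n_cds / meta$Lt)
  m <- min(m, n_cds)
  m <- max(m, n_sub - length(meta$neutral_sites))
  n_syn <- min(round(b * m), length(meta$degen_sites))

  syn_sites <- sample_int(meta$degen_sites, n_syn)
  nonsyn_sites <- sample_int(setdiff(meta$cds_sites, syn_sites), m - n_syn)
  neutral_sites <- sample_int(meta$neutral_sites, n_sub - m)

  if (n_syn > 0L) {
    key <- meta$site_key[match(syn_sites, meta$cds_sites)]
    pick <- floor(stats::runif(n_syn) * tab$syn_n[key]) + 1L
    chars[syn_sites] <- tab$syn_mat[cbind(key, pick)]
  }
  if (length(nonsyn_sites) > 0L) {
    key <- meta$site_key[match(nonsyn_sites, meta$cds_sites)]
    nn <- tab$nonsyn_n[key]
    use_syn <- nn == 0L            # e.g. fourfold-degenerate third positions
    pick <- integer(length(key))
    pick[!use_syn] <- floor(stats::runif(sum(!use_syn)) * nn[!use_syn]) + 1L
    pick[use_syn] <- floor(stats::runif(sum(use_syn)) * tab$syn_n[key[use_syn]]) + 1L
    newb <- character(length(key))
    newb[!use_syn] <- tab$nonsyn_mat[cbind(key[!use_syn], pick[!use_syn])]
    newb[use_syn] <- tab$syn_mat[cbind(key[use_syn], pick[use_syn])]
    chars[nonsyn_sites] <- newb
  }
  if (length(neutral_sites) > 0L) {
    cur <- match(chars[neutral_sites], c("A", "C", "G", "T"))
    pick <- floor(stats::runif(length(neutral_sites)) * 3) + 1L
    chars[neutral_sites] <- tab$alt_mat[cbind(cur, pick)]
  }
  chars
}

#' Evolve reference-species copies of the ancestral genes
#'
#' Produces the focal transcript set (identical to the ancestor: the
#' configured divergences are total pairwise divergences on a star
#' phylogeny) and, per reference species, ortholog copies mutated at the
#' species' divergence with the configured synonymous bias, with per-gene
#' dropout and optional further-diverged paralog duplicates. Every event is
#' recorded in the returned truth object.
#'
#' @param ancestral An `ancestral_genes` object from
#'   [generate_ancestral_genes()].
#' @param config The same [sim_config()].
#' @return List with `focal` (transcript data frame, ids
#'   `<focal>_<gene>`), `references` (named list of per-species transcript
#'   data frames, orthologs plus paralogs) and `truth` (class
#'   `synthetic_truth`: `genes` metadata, `orthologs` focal-by-species id
#'   matrix with `NA` for dropouts, `paralogs` data frame, `fragments`
#'   placeholder, `config`).
#' @export
evolve_species <- function(ancestral, config) {
  stopifnot(inherits(ancestral, "ancestral_genes"), inherits(config, "sim_config"))
  if (nrow(ancestral$transcripts) == 0L) {
    stop("ancestral gene set is empty", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  genes <- ancestral$genes
  n <- nrow(genes)
  focal_id <- paste0(config$focal, "_", genes$gene_id)
  focal <- data.frame(transcript_id = focal_id,
                      sequence = ancestral$transcripts$sequence,
                      stringsAsFactors = FALSE)
  meta <- lapply(seq_len(n), function(i) {
    gene_mutation_meta(focal$sequence[[i]], genes$cds_start[[i]],
                       genes$n_codons[[i]])
  })
  chars <- strsplit(focal$sequence, "")

  orthologs <- matrix(NA_character_, n, length(config$species),
                      dimnames = list(focal_id, config$species))
  paralogs <- list()
  references <- list()
  for (sp in config$species) {
    d <- config$divergence[[sp]]
    keep <- stats::runif(n) >= config$dropout_rate[[sp]]
    ids <- character(0); seqs <- character(0)
    for (i in which(keep)) {
      mut <- mutate_transcript(chars[[i]], meta[[i]], d, config$synonymous_bias)
      rid <- paste0(sp, "_", genes$gene_id[[i]])
      ids <- c(ids, rid)
      seqs <- c(seqs, paste0(mut, collapse = ""))
      orthologs[i, sp] <- rid
      if (stats::runif(1) < config$paralog_rate) {
        pmut <- mutate_transcript(mut, meta[[i]],
                                  config$paralog_extra_divergence,
                                  config$synonymous_bias)
        pid <- paste0(rid, "_p1")
        ids <- c(ids, pid)
        seqs <- c(seqs, paste0(pmut, collapse = ""))
        paralogs[[length(paralogs) + 1L]] <-
          data.frame(species = sp, gene_id = genes$gene_id[[i]],
                     paralog_id = pid, stringsAsFactors = FALSE)
      }
    }
    references[[sp]] <- data.frame(transcript_id = ids, sequence = seqs,
                                   stringsAsFactors = FALSE)
  }
  truth <- structure(
    list(genes = data.frame(gene_id = genes$gene_id, focal_id = focal_id,
                            cds_start = genes$cds_start,
                            n_codons = genes$n_codons,
                            full_length = genes$length,
                            stringsAsFactors = FALSE),
         orthologs = orthologs,
         paralogs = if (length(paralogs)) do.call(rbind, paralogs) else
           data.frame(species = character(0), gene_id = character(0),
                      paralog_id = character(0), stringsAsFactors = FALSE),
         fragments = data.frame(focal_id = character(0),
                                full_length = integer(0), start = integer(0),
                                end = integer(0), stringsAsFactors = FALSE),
         species = config$species, config = config),
    class = "synthetic_truth")
  list(focal = focal, references = references, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$genes), "genes,",
      length(x$species), "reference species,",
      nrow(x$paralogs), "paralogs,", nrow(x$fragments), "fragments\n")
  invisible(x)
}

#' Truncate focal transcripts into assembly-like fragments
#'
#' With probability `fragment_rate` each focal transcript is replaced by a
#' uniform-random window of itself of length at least `min_fragment_bp`
#' (window length uniform on `[min_fragment_bp, full length]`, start uniform
#' among valid offsets). Identifiers are preserved and every truncation is
#' recorded in the returned fragment map.
#'
#' @param focal_transcripts Focal transcript data frame.
#' @param config A [sim_config()].
#' @return List with `transcripts` (same shape, sequences possibly
#'   truncated) and `fragment_map` (data frame `focal_id`, `full_length`,
#'   `start`, `end`, one row per truncated transcript).
#' @export
fragment_focal <- function(focal_transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  lens <- nchar(focal_transcripts$sequence)
  if (any(lens < config$min_fragment_bp)) {
    stop("min_fragment_bp exceeds the length of some transcripts",
         call. = FALSE)
  }
  frag <- stats::runif(length(lens)) < config$fragment_rate
  map <- data.frame(focal_id = character(0), full_length = integer(0),
                    start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE)
  out <- focal_transcripts
  for (i in which(frag)) {
    L <- lens[[i]]
    flen <- config$min_fragment_bp + sample.int(L - config$min_fragment_bp + 1L, 1L) - 1L
    s <- sample.int(L - flen + 1L, 1L)
    out$sequence[[i]] <- substr(out$sequence[[i]], s, s + flen - 1L)
    map <- rbind(map, data.frame(focal_id = out$transcript_id[[i]],
                                 full_length = L, start = s,
                                 end = s + flen - 1L,
                                 stringsAsFactors = FALSE))
  }
  list(transcripts = out, fragment_map = map)
}

# Alignment window of a focal transcript on the shared coordinate system.
fragment_window <- function(truth, focal_id) {
  j <- match(focal_id, truth$fragments$focal_id)
  if (is.na(j)) {
    c(1L, truth$genes$full_length[[match(focal_id, truth$genes$focal_id)]])
  } else {
    c(truth$fragments$start[[j]], truth$fragments$end[[j]])
  }
}

# Score surrogates: only the ordering matters downstream. These are not
# calibrated to BLAST statistics.
surrogate_scores <- function(matches, mismatches) {
  bitscore <- pmax(0, 2 * matches - 3 * mismatches)
  evalue <- 1e9 * 2^(-bitscore)
  list(bitscore = bitscore, evalue = evalue)
}

hit_row <- function(qid, sid, matches, len, qstart, qend, sstart, send) {
  sc <- surrogate_scores(matches, len - matches)
  data.frame(query_id = qid, subject_id = sid,
             pct_identity = round(100 * matches / len, 2),
             aln_length = as.integer(len),
             mismatches = as.integer(len - matches), gap_opens = 0L,
             qstart = as.integer(qstart), qend = as.integer(qend),
             sstart = as.integer(sstart), send = as.integer(send),
             evalue = sc$evalue, bitscore = sc$bitscore,
             stringsAsFactors = FALSE)
}

#' Emit synthetic alignment hit tables
#'
#' Stands in for an all-vs-all BLAST run on the simulated sequences: emits,
#' per reference species and per direction, one hit for every true homolog
#' pair (orthologs and paralogs) with percent identity computed exactly by
#' positionwise comparison over the aligned window, a bit-score surrogate
#' that is a deterministic monotone function of matches, and an e-value
#' surrogate monotone decreasing in the bit score — plus seeded spurious
#' hits at the configured rate. At the protein level the aligned window is
#' the in-frame codon overlap of the (possibly fragmented) focal transcript
#' with the CDS, compared on translated residues.
#'
#' @param sim A simulation state as returned by [evolve_species()] (with
#'   `focal` possibly replaced by [fragment_focal()] output and `truth`
#'   updated accordingly).
#' @param level `"nucleotide"` or `"protein"`.
#' @param noise Expected spurious hits per focal transcript per species per
#'   direction (default from the config).
#' @return Named list (per species) of lists with `fwd` and `rev` hit data
#'   frames in [read_blast_tab()] column layout.
#' @export
emit_hit_tables <- function(sim, level = c("nucleotide", "protein"),
                            noise = sim$truth$config$noise_rate) {
  level <- match.arg(level)
  truth <- sim$truth
  config <- truth$config
  set.seed(config$seed + 3L + (level == "protein"))
  focal_seq <- stats::setNames(sim$focal$sequence, sim$focal$transcript_id)
  out <- list()
  for (sp in config$species) {
    ref_seq <- stats::setNames(sim$references[[sp]]$sequence,
                               sim$references[[sp]]$transcript_id)
    n_genes <- nrow(truth$genes)
    qs <- vector("list", n_genes); ss <- vector("list", n_genes)
    mm <- vector("list", n_genes); ll <- vector("list", n_genes)
    a1 <- vector("list", n_genes); a2 <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      fid <- truth$genes$focal_id[[i]]
      rid <- truth$orthologs[fid, sp]
      subjects <- c(if (!is.na(rid)) rid,
                    truth$paralogs$paralog_id[truth$paralogs$species == sp &
                                              truth$paralogs$gene_id == truth$genes$gene_id[[i]]])
      if (length(subjects) == 0L) next
      win <- fragment_window(truth, fid)
      if (level == "nucleotide") {
        q <- utf8ToInt(focal_seq[[fid]])
        len <- length(q)
        matches <- vapply(subjects, function(sid) {
          sum(q == utf8ToInt(substr(ref_seq[[sid]], win[[1L]], win[[2L]])))
        }, numeric(1))
        span <- win
      } else {
        cw <- codon_overlap(truth, i, win)
        if (is.null(cw)) next
        nc <- cw[[2L]] - cw[[1L]] + 1L
        qaa <- utf8ToInt(translate_codons(
          focal_seq[[fid]],
          truth$genes$cds_start[[i]] + 3L * (cw[[1L]] - 1L) - win[[1L]] + 1L, nc))
        len <- length(qaa)
        matches <- vapply(subjects, function(sid) {
          sum(qaa == utf8ToInt(translate_codons(
            ref_seq[[sid]], truth$genes$cds_start[[i]] + 3L * (cw[[1L]] - 1L), nc)))
        }, numeric(1))
        span <- cw
      }
      k <- length(subjects)
      qs[[i]] <- rep(fid, k); ss[[i]] <- subjects
      mm[[i]] <- matches; ll[[i]] <- rep(len, k)
      a1[[i]] <- rep(span[[1L]], k); a2[[i]] <- rep(span[[2L]], k)
    }
    qv <- unname(unlist(qs)); sv <- unname(unlist(ss))
    mv <- unname(unlist(mm)); lv <- unname(unlist(ll))
    s1 <- unname(unlist(a1)); s2 <- unname(unlist(a2))
    if (is.null(qv)) {
      fwd <- empty_hit_table(); rev <- empty_hit_table()
    } else {
      sc <- surrogate_scores(mv, lv - mv)
      pid <- round(100 * mv / lv, 2)
      fwd <- data.frame(query_id = unname(qv), subject_id = unname(sv),
                        pct_identity = pid, aln_length = as.integer(lv),
                        mismatches = as.integer(lv - mv), gap_opens = 0L,
                        qstart = 1L, qend = as.integer(lv),
                        sstart = as.integer(s1), send = as.integer(s2),
                        evalue = sc$evalue, bitscore = sc$bitscore,
                        stringsAsFactors = FALSE)
      rev <- data.frame(query_id = unname(sv), subject_id = unname(qv),
                        pct_identity = pid, aln_length = as.integer(lv),
                        mismatches = as.integer(lv - mv), gap_opens = 0L,
                        qstart = as.integer(s1), qend = as.integer(s2),
                        sstart = 1L, send = as.integer(lv),
                        evalue = sc$evalue, bitscore = sc$bitscore,
                        stringsAsFactors = FALSE)
    }
    if (noise > 0 && nrow(sim$focal) > 0L && length(ref_seq) > 0L) {
      fwd <- rbind(fwd, spurious_hits(names(focal_seq), names(ref_seq), noise))
      rev <- rbind(rev, spurious_hits(names(ref_seq), names(focal_seq), noise))
    }
    out[[sp]] <- list(fwd = fwd, rev = rev)
  }
  out
}

# Fully-contained codon range [j_min, j_max] of gene i's sense codons within
# transcript window `win`; NULL when no complete codon fits.
codon_overlap <- function(truth, i, win) {
  cds_start <- truth$genes$cds_start[[i]]
  n_sense <- truth$genes$n_codons[[i]] - 1L
  j_min <- max(1L, ceiling((win[[1L]] - cds_start) / 3) + 1L)
  j_max <- min(n_sense, (win[[2L]] - cds_start + 1L) %/% 3L)
  if (j_max < j_min) NULL else c(j_min, j_max)
}

# Low-identity short random alignments modelling off-target hits.
spurious_hits <- function(queries, subjects, rate) {
  n <- stats::rpois(1L, rate * length(queries))
  if (n == 0L) return(empty_hit_table())
  len <- sample(50:150, n, replace = TRUE)
  pid <- stats::runif(n, 60, 75)
  matches <- round(pid * len / 100)
  do.call(rbind, lapply(seq_len(n), function(k) {
    hit_row(sample(queries, 1L), sample(subjects, 1L), matches[[k]],
            len[[k]], 1L, len[[k]], 1L, len[[k]])
  }))
}

#' Plant an annotation table with a known enrichment signal
#'
#' Generates `n_terms` background terms whose gene membership is uniform
#' Bernoulli at `base_rate`, plus optional enriched terms whose target
#' subset is over-represented at the stated fold (membership probability
#' `min(1, fold * base_rate)` inside the target, `base_rate` outside).
#' `fold = 1` is indistinguishable from background by construction.
#'
#' @param genes Character vector of background gene identifiers.
#' @param n_terms Number of background terms.
#' @param base_rate Background membership probability.
#' @param enriched Named list: term id -> `list(genes = <target subset>,
#'   fold = <fold >= 1>)`.
#' @param seed Integer seed.
#' @return An [annotation_table()] whose background is `genes`.
#' @export
plant_annotations <- function(genes, n_terms = 50L, base_rate = 0.05,
                              enriched = list(), seed = 1L) {
  set.seed(seed)
  genes <- as.character(genes)
  for (e in enriched) {
    if (is.null(e$fold) || e$fold < 1) {
      stop("enrichment fold must be >= 1", call. = FALSE)
    }
    if (!all(e$genes %in% genes)) {
      stop("enriched target genes must belong to the background",
           call. = FALSE)
    }
  }
  terms <- list()
  if (n_terms > 0L) {
    for (t in seq_len(n_terms)) {
      members <- genes[stats::runif(length(genes)) < base_rate]
      if (length(members) == 0L) members <- sample(genes, 1L)
      terms[[sprintf("T%03d", t)]] <- members
    }
  }
  for (tid in names(enriched)) {
    e <- enriched[[tid]]
    p <- ifelse(genes %in% e$genes, pmin(1, e$fold * base_rate), base_rate)
    members <- genes[stats::runif(length(genes)) < p]
    if (length(members) == 0L) members <- sample(e$genes, 1L)
    terms[[tid]] <- members
  }
  if (length(terms) == 0L) {
    return(annotation_table(stats::setNames(list(), character(0)),
                            background = genes))
  }
  annotation_table(terms, background = genes)
}

#' Run the complete synthetic study generator
#'
#' Convenience wrapper chaining [generate_ancestral_genes()],
#' [evolve_species()], [fragment_focal()], [emit_hit_tables()] (both levels)
#' and [plant_annotations()] (one planted enriched term over a random gene
#' subset, recorded in the truth). Identical configs produce identical
#' output.
#'
#' @param config A [sim_config()].
#' @return List with `focal`, `references`, `proteins` (translated CDS
#'   sequences per species), `hits_nt`, `hits_aa` (per-species `fwd`/`rev`
#'   hit tables), `annotation`, `truth` and `config`.
#' @export
simulate_orthology_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  anc <- generate_ancestral_genes(config)
  sim <- evolve_species(anc, config)
  fr <- fragment_focal(sim$focal, config)
  sim$focal <- fr$transcripts
  sim$truth$fragments <- fr$fragment_map
  hits_nt <- emit_hit_tables(sim, "nucleotide")
  hits_aa <- emit_hit_tables(sim, "protein")

  set.seed(config$seed + 5L)
  focal_ids <- sim$focal$transcript_id
  enriched <- list()
  target <- character(0)
  if (config$enriched_set_size > 0L && config$n_terms >= 0L &&
      config$enriched_set_size <= length(focal_ids)) {
    target <- sort(sample(focal_ids, config$enriched_set_size))
    enriched <- list(T_ENRICHED = list(genes = target,
                                       fold = config$enriched_fold))
  }
  annotation <- plant_annotations(focal_ids, n_terms = config$n_terms,
                                  base_rate = config$base_rate,
                                  enriched = enriched,
                                  seed = config$seed + 6L)
  sim$truth$planted_term <- if (length(enriched)) "T_ENRICHED" else NA_character_
  sim$truth$planted_target <- target

  proteins <- sim_proteins(sim)
  list(focal = sim$focal, references = sim$references, proteins = proteins,
       hits_nt = hits_nt, hits_aa = hits_aa, annotation = annotation,
       truth = sim$truth, config = config)
}

# Translated CDS sequences (terminal stop excluded) for every species;
# fragmented focal transcripts are translated over their in-frame codon
# overlap with the CDS and omitted when no complete codon survives.
sim_proteins <- function(sim) {
  truth <- sim$truth
  out <- list()
  foc_ids <- character(0); foc_aa <- character(0)
  for (i in seq_len(nrow(truth$genes))) {
    fid <- truth$genes$focal_id[[i]]
    win <- fragment_window(truth, fid)
    cw <- codon_overlap(truth, i, win)
    if (is.null(cw)) next
    foc_ids <- c(foc_ids, fid)
    foc_aa <- c(foc_aa,
                translate_codons(sim$focal$sequence[[match(fid, sim$focal$transcript_id)]],
                                 truth$genes$cds_start[[i]] + 3L * (cw[[1L]] - 1L) - win[[1L]] + 1L,
                                 cw[[2L]] - cw[[1L]] + 1L))
  }
  out[[truth$config$focal]] <- data.frame(transcript_id = foc_ids,
                                          sequence = foc_aa,
                                          stringsAsFactors = FALSE)
  for (sp in truth$species) {
    df <- sim$references[[sp]]
    aa <- character(nrow(df))
    for (k in seq_len(nrow(df))) {
      gid <- sub(paste0("^", sp, "_"), "", sub("_p1$", "", df$transcript_id[[k]]))
      i <- match(gid, truth$genes$gene_id)
      aa[[k]] <- translate_codons(df$sequence[[k]], truth$genes$cds_start[[i]],
                                  truth$genes$n_codons[[i]] - 1L)
    }
    out[[sp]] <- data.frame(transcript_id = df$transcript_id, sequence = aa,
                            stringsAsFactors = FALSE)
  }
  out
}
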