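#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (see the annotated example shipped at
#' `system.file("extdata", "example-config.yaml", package =
#' "orthocascade")`) and fills defaults. A configuration names the focal
#' species, the species priority order, the e-value cutoff, the number of
#' conservation partitions, enrichment options, an output directory, a seed,
#' and either a `simulate:` block (knobs of [sim_config()]) or an `inputs:`
#' block pointing at existing FASTA/hit-table/annotation files.
#'
#' @param path Path to a YAML file, or a named list with the same structure.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    yaml::read_yaml(path)
  } else if (is.list(path)) {
    path
  } else {
    stop("config must be a YAML path or a list", call. = FALSE)
  }
  defaults <- list(focal = "shrew",
                   species_priority = c("human", "mouse", "dog", "ferret"),
                   evalue_cutoff = 1e-5, partitions = 10L,
                   min_count = 2L, ease = FALSE,
                   out_dir = "orthocascade_out", seed = 1L,
                   gene_sets = list(), simulate = NULL, inputs = NULL)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg$species_priority <- as.character(unlist(cfg$species_priority))
  if (length(cfg$species_priority) == 0L ||
      anyDuplicated(cfg$species_priority)) {
    stop("config field 'species_priority' must be a non-empty, ",
         "duplicate-free species list", call. = FALSE)
  }
  if (cfg$partitions < 1L) {
    stop("config field 'partitions' must be >= 1", call. = FALSE)
  }
  if (cfg$evalue_cutoff < 0) {
    stop("config field 'evalue_cutoff' must be non-negative", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

as_sim_config <- function(cfg) {
  sim <- cfg$simulate
  if (is.null(sim)) sim <- list()
  args <- list(focal = cfg$focal, seed = cfg$seed)
  if (!is.null(sim$divergence)) {
    args$divergence <- unlist(sim$divergence)
    sim$divergence <- NULL
  }
  known <- setdiff(names(formals(sim_config)), names(args))
  for (nm in intersect(names(sim), known)) args[[nm]] <- sim[[nm]]
  cfg_species <- cfg$species_priority
  if (is.null(args$divergence)) {
    defaults <- eval(formals(sim_config)$divergence)
    missing <- setdiff(cfg_species, names(defaults))
    if (length(missing)) {
      stop("no default divergence for species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    args$divergence <- defaults[cfg_species]
  }
  do.call(sim_config, args)
}

log_output <- function(path, nrows) {
  message(sprintf("[orthocascade] wrote %s (%d row(s))", path, nrows))
}

out_path <- function(cfg, ...) {
  dir <- file.path(cfg$out_dir, ...)
  dir.create(dirname(dir), recursive = TRUE, showWarnings = FALSE)
  dir
}

#' Pipeline stage: simulate a synthetic study
#'
#' Generates the complete synthetic dataset on disk under
#' `<out_dir>`: per-species nucleotide and protein FASTA, outfmt-6 hit
#' tables for both directions and both levels, the planted annotation
#' table, the truth tables and the echoed simulation configuration.
#'
#' @param cfg A [pipeline_config()] (or path/list accepted by it).
#' @return The in-memory simulation (invisibly).
#' @export
cmd_simulate <- function(cfg) {
  cfg <- pipeline_config(cfg)
  sc <- as_sim_config(cfg)
  sim <- simulate_orthology_study(sc)

  fa_dir <- file.path(cfg$out_dir, "fasta")
  hit_dir <- file.path(cfg$out_dir, "hits")
  truth_dir <- file.path(cfg$out_dir, "truth")
  for (d in c(fa_dir, hit_dir, truth_dir)) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  write_fasta(sim$focal, file.path(fa_dir, paste0(cfg$focal, ".fa")))
  log_output(file.path(fa_dir, paste0(cfg$focal, ".fa")), nrow(sim$focal))
  for (sp in sc$species) {
    write_fasta(sim$references[[sp]], file.path(fa_dir, paste0(sp, ".fa")))
  }
  for (sp in names(sim$proteins)) {
    write_fasta(sim$proteins[[sp]],
                file.path(fa_dir, paste0(sp, "_protein.fa")))
  }
  for (sp in sc$species) {
    write_blast_tab(sim$hits_nt[[sp]]$fwd,
                    file.path(hit_dir, sprintf("%s_vs_%s.nt.tsv", cfg$focal, sp)))
    write_blast_tab(sim$hits_nt[[sp]]$rev,
                    file.path(hit_dir, sprintf("%s_vs_%s.nt.tsv", sp, cfg$focal)))
    write_blast_tab(sim$hits_aa[[sp]]$fwd,
                    file.path(hit_dir, sprintf("%s_vs_%s.aa.tsv", cfg$focal, sp)))
    write_blast_tab(sim$hits_aa[[sp]]$rev,
                    file.path(hit_dir, sprintf("%s_vs_%s.aa.tsv", sp, cfg$focal)))
  }
  write_annotation_table(sim$annotation, file.path(cfg$out_dir, "annotation.tsv"))
  write_tsv(sim$truth$genes, file.path(truth_dir, "genes.tsv"))
  ort <- data.frame(focal_id = rownames(sim$truth$orthologs),
                    sim$truth$orthologs, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(ort, file.path(truth_dir, "orthologs.tsv"))
  write_tsv(sim$truth$paralogs, file.path(truth_dir, "paralogs.tsv"))
  write_tsv(sim$truth$fragments, file.path(truth_dir, "fragments.tsv"))
  if (length(sim$truth$planted_target)) {
    writeLines(c("# planted enriched gene subset", sim$truth$planted_target),
               file.path(truth_dir, "planted_target.txt"))
  }
  yaml::write_yaml(unclass(sc), file.path(cfg$out_dir, "sim-config.yaml"))
  invisible(sim)
}

hit_file <- function(cfg, from, to, level) {
  file.path(cfg$out_dir, "hits", sprintf("%s_vs_%s.%s.tsv", from, to,
                                         if (level == "nucleotide") "nt" else "aa"))
}

#' Pipeline stage: reciprocal-best-hit pairs per species
#'
#' Reads the two hit tables per reference species (focal-to-reference and
#' reference-to-focal), reduces each to best hits at the configured e-value
#' cutoff, intersects them into reciprocal pairs, attaches protein identity
#' from the protein-level tables when present, and writes one pair TSV per
#' species under `<out_dir>/pairs/`.
#'
#' @inheritParams cmd_simulate
#' @return Named list of pair data frames (invisibly).
#' @export
cmd_orthology <- function(cfg) {
  cfg <- pipeline_config(cfg)
  dir.create(file.path(cfg$out_dir, "pairs"), recursive = TRUE,
             showWarnings = FALSE)
  pairs <- list()
  for (sp in cfg$species_priority) {
    f_fwd <- hit_file(cfg, cfg$focal, sp, "nucleotide")
    f_rev <- hit_file(cfg, sp, cfg$focal, "nucleotide")
    for (f in c(f_fwd, f_rev)) {
      if (!file.exists(f)) {
        stop("missing input hit table: ", f, call. = FALSE)
      }
    }
    fwd <- best_hits(read_blast_tab(f_fwd), cfg$evalue_cutoff)
    rev <- best_hits(read_blast_tab(f_rev), cfg$evalue_cutoff)
    pr <- reciprocal_best_hits(fwd, rev)
    pr$protein_identity <- NA_real_
    f_aa <- hit_file(cfg, cfg$focal, sp, "protein")
    if (file.exists(f_aa)) {
      aa_best <- best_hits(read_blast_tab(f_aa), cfg$evalue_cutoff)
      i <- match(pr$focal_id, aa_best$query_id)
      same <- !is.na(i) & aa_best$subject_id[i] == pr$reference_id
      pr$protein_identity[same] <- aa_best$pct_identity[i][same]
    }
    path <- file.path(cfg$out_dir, "pairs", paste0(sp, ".tsv"))
    write_tsv(pr, path)
    log_output(path, nrow(pr))
    pairs[[sp]] <- pr
  }
  invisible(pairs)
}

read_pairs <- function(cfg) {
  pairs <- list()
  for (sp in cfg$species_priority) {
    path <- file.path(cfg$out_dir, "pairs", paste0(sp, ".tsv"))
    if (!file.exists(path)) {
      stop("missing pair table: ", path, " (run cmd_orthology first)",
           call. = FALSE)
    }
    pairs[[sp]] <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  pairs
}

#' Pipeline stage: non-redundant cascade assignment
#'
#' Runs [cascade_assign()] over the per-species pair tables in the
#' configured priority order and writes the assignment table plus a
#' per-species count summary.
#'
#' @inheritParams cmd_simulate
#' @return The assignment data frame (invisibly).
#' @export
cmd_cascade <- function(cfg) {
  cfg <- pipeline_config(cfg)
  pairs <- read_pairs(cfg)
  assignments <- cascade_assign(pairs, priority = cfg$species_priority)
  path <- file.path(cfg$out_dir, "cascade_assignments.tsv")
  write_ortholog_map(assignments, path)
  log_output(path, nrow(assignments))
  counts <- data.frame(species = cfg$species_priority,
                       rank = seq_along(cfg$species_priority),
                       n_pairs = vapply(pairs, nrow, integer(1))[cfg$species_priority],
                       n_assigned = vapply(cfg$species_priority, function(sp) {
                         sum(assignments$reference_species == sp)
                       }, integer(1)),
                       stringsAsFactors = FALSE, row.names = NULL)
  counts <- rbind(counts,
                  data.frame(species = "total", rank = NA_integer_,
                             n_pairs = NA_integer_,
                             n_assigned = nrow(assignments),
                             stringsAsFactors = FALSE))
  spath <- file.path(cfg$out_dir, "cascade_counts.tsv")
  write_tsv(counts, spath)
  log_output(spath, nrow(counts))
  invisible(assignments)
}

#' Pipeline stage: shared one-to-one orthologs
#'
#' Runs [shared_orthologs()] over the per-species pair tables and writes the
#' shared-set table (one id and identity column per species).
#'
#' @inheritParams cmd_simulate
#' @return The shared-set data frame (invisibly).
#' @export
cmd_shared <- function(cfg) {
  cfg <- pipeline_config(cfg)
  shared <- shared_orthologs(read_pairs(cfg))
  path <- file.path(cfg$out_dir, "shared_orthologs.tsv")
  write_tsv(shared, path)
  log_output(path, nrow(shared))
  invisible(shared)
}

#' Pipeline stage: length, identity and conservation statistics
#'
#' Writes the focal length summary and histogram, per-species mean
#' nucleotide/protein identities over the shared ortholog set, the pairwise
#' two-proportion z-test report across species, the gene-by-species identity
#' matrix (ordered by the highest-priority species), and the conservation
#' partitions.
#'
#' @inheritParams cmd_simulate
#' @return List with the computed objects (invisibly).
#' @export
cmd_stats <- function(cfg) {
  cfg <- pipeline_config(cfg)
  fa <- file.path(cfg$out_dir, "fasta", paste0(cfg$focal, ".fa"))
  if (!file.exists(fa)) {
    stop("missing focal FASTA: ", fa, call. = FALSE)
  }
  focal <- read_fasta(fa, species = cfg$focal)
  ls <- length_summary(focal)
  write_tsv(data.frame(n = ls$n, min_bp = ls$min_bp, max_bp = ls$max_bp,
                       mean_bp = ls$mean_bp, sd_bp = ls$sd_bp,
                       total_bp = ls$total_bp),
            file.path(cfg$out_dir, "length_summary.tsv"))
  write_tsv(ls$histogram, file.path(cfg$out_dir, "length_histogram.tsv"))

  pairs <- read_pairs(cfg)
  shared <- shared_orthologs(pairs)
  shared_pairs <- lapply(cfg$species_priority, function(sp) {
    pairs[[sp]][pairs[[sp]]$focal_id %in% shared$focal_id, , drop = FALSE]
  })
  names(shared_pairs) <- cfg$species_priority

  means <- do.call(rbind, lapply(cfg$species_priority, function(sp) {
    pr <- shared_pairs[[sp]]
    aa_ok <- !anyNA(pr$protein_identity) && nrow(pr) > 0L
    data.frame(species = sp, n = nrow(pr),
               mean_nt_identity = if (nrow(pr)) mean_identity(pr, "nucleotide") else NA_real_,
               mean_aa_identity = if (aa_ok) mean_identity(pr, "protein") else NA_real_,
               stringsAsFactors = FALSE)
  }))
  write_tsv(means, file.path(cfg$out_dir, "identity_means.tsv"))

  ztab <- list()
  combos <- utils::combn(cfg$species_priority, 2, simplify = FALSE)
  for (level in c("nt", "aa")) {
    col <- paste0("mean_", level, "_identity")
    for (cp in combos) {
      m1 <- means[[col]][means$species == cp[[1L]]]
      m2 <- means[[col]][means$species == cp[[2L]]]
      n1 <- means$n[means$species == cp[[1L]]]
      n2 <- means$n[means$species == cp[[2L]]]
      if (anyNA(c(m1, m2)) || n1 < 1L || n2 < 1L) next
      hi <- if (m1 >= m2) 1L else 2L; lo <- 3L - hi
      zt <- two_proportion_ztest(c(m1, m2)[[hi]] / 100, c(m1, m2)[[lo]] / 100,
                                 c(n1, n2)[[hi]], c(n1, n2)[[lo]])
      ztab[[length(ztab) + 1L]] <-
        data.frame(level = level,
                   species_high = cp[[hi]], species_low = cp[[lo]],
                   p1 = zt$p1, p2 = zt$p2, n1 = zt$n1, n2 = zt$n2,
                   z = zt$z, p_one_tailed = zt$p_one_tailed,
                   p_two_tailed = zt$p_two_tailed,
                   stringsAsFactors = FALSE)
    }
  }
  ztab <- if (length(ztab)) do.call(rbind, ztab) else
    data.frame(level = character(0))
  write_tsv(ztab, file.path(cfg$out_dir, "ztest_report.tsv"))

  order_by <- cfg$species_priority[[1L]]
  im <- identity_matrix(shared$focal_id, shared_pairs, order_by = order_by)
  imdf <- data.frame(gene = rownames(im), im, check.names = FALSE,
                     stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(imdf, file.path(cfg$out_dir, "identity_matrix.tsv"))

  ref_pairs <- shared_pairs[[order_by]]
  rank_id <- ref_pairs$protein_identity
  if (anyNA(rank_id)) rank_id <- ref_pairs$pct_identity
  ord <- order(-rank_id, ref_pairs$focal_id, method = "radix")
  ranked <- data.frame(gene = ref_pairs$focal_id[ord],
                       identity = rank_id[ord], stringsAsFactors = FALSE)
  parts <- partition_by_conservation(ranked, k = cfg$partitions)
  pdf <- do.call(rbind, lapply(parts$partitions, function(p) {
    data.frame(partition = p$index, gene = p$members,
               stringsAsFactors = FALSE)
  }))
  pdf$identity <- ranked$identity[match(pdf$gene, ranked$gene)]
  write_tsv(pdf, file.path(cfg$out_dir, "partitions.tsv"))
  log_output(file.path(cfg$out_dir, "partitions.tsv"), nrow(pdf))

  invisible(list(length_summary = ls, identity_means = means,
                 ztest_report = ztab, identity_matrix = im,
                 partitions = parts))
}

#' Pipeline stage: annotation enrichment
#'
#' Runs [enrich()] for every configured gene-set file and for every
#' conservation partition produced by [cmd_stats()], each against the
#' annotation background, writing one enrichment TSV per set under
#' `<out_dir>/enrichment/`.
#'
#' @inheritParams cmd_simulate
#' @return Named list of enrichment tables (invisibly).
#' @export
cmd_enrich <- function(cfg) {
  cfg <- pipeline_config(cfg)
  ann_path <- file.path(cfg$out_dir, "annotation.tsv")
  if (!is.null(cfg$inputs$annotation)) ann_path <- cfg$inputs$annotation
  if (!file.exists(ann_path)) {
    stop("missing annotation table: ", ann_path, call. = FALSE)
  }
  annotation <- read_annotation_table(ann_path)
  dir.create(file.path(cfg$out_dir, "enrichment"), recursive = TRUE,
             showWarnings = FALSE)
  out <- list()

  for (gs_path in cfg$gene_sets) {
    gs <- read_gene_set(gs_path)
    res <- enrich(gs, annotation, min_count = cfg$min_count, ease = cfg$ease)
    path <- file.path(cfg$out_dir, "enrichment", paste0(gs$name, ".tsv"))
    write_enrichment_table(res, path)
    log_output(path, nrow(res))
    out[[gs$name]] <- res
  }

  part_path <- file.path(cfg$out_dir, "partitions.tsv")
  if (file.exists(part_path)) {
    pdf <- utils::read.delim(part_path, stringsAsFactors = FALSE)
    for (k in sort(unique(pdf$partition))) {
      members <- pdf$gene[pdf$partition == k]
      nm <- sprintf("partition_%02d", k)
      res <- tryCatch(enrich(members, annotation, min_count = cfg$min_count,
                             ease = cfg$ease),
                      error = function(e) NULL)
      if (is.null(res)) next
      path <- file.path(cfg$out_dir, "enrichment", paste0(nm, ".tsv"))
      write_enrichment_table(res, path)
      log_output(path, nrow(res))
      out[[nm]] <- res
    }
  }
  invisible(out)
}

#' Run every pipeline stage in dependency order
#'
#' Equivalent to [cmd_simulate()] (when a `simulate:` block is configured),
#' then [cmd_orthology()], [cmd_cascade()], [cmd_shared()], [cmd_stats()]
#' and [cmd_enrich()], finishing with a `manifest.json` recording the
#' package version, R version, seed, configuration and the MD5 checksum and
#' row count of every written table. Re-running with an unchanged
#' configuration reproduces every output byte for byte.
#'
#' @inheritParams cmd_simulate
#' @return Path of the manifest file (invisibly).
#' @export
cmd_run_all <- function(cfg) {
  cfg <- pipeline_config(cfg)
  if (!is.null(cfg$simulate)) cmd_simulate(cfg)
  cmd_orthology(cfg)
  cmd_cascade(cfg)
  cmd_shared(cfg)
  cmd_stats(cfg)
  cmd_enrich(cfg)

  files <- sort(list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "orthocascade",
    package_version = as.character(utils::packageVersion("orthocascade")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = lapply(files, function(f) {
      list(path = sub(paste0("^", cfg$out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)),
           n_lines = length(readLines(f, warn = FALSE)))
    })
  )
  mpath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  message("[orthocascade] run complete; manifest at ", mpath)
  invisible(mpath)
}
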