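test_that("ancestral genes are valid CDS and fully seed-deterministic", {
  cfg <- tiny_config(n_genes = 50L)
  anc1 <- generate_ancestral_genes(cfg)
  anc2 <- generate_ancestral_genes(cfg)
  expect_identical(anc1$transcripts, anc2$transcripts)

  expect_equal(nrow(generate_ancestral_genes(tiny_config(n_genes = 0L))$transcripts), 0L)

  # codon-scan oracle: start codon, terminal stop, no internal stop in frame
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_len(nrow(anc1$genes))) {
    g <- anc1$genes[i, ]
    cds <- substr(anc1$transcripts$sequence[[i]], g$cds_start,
                  g$cds_start + 3 * g$n_codons - 1)
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    aa <- unname(gc[codons])
    expect_equal(codons[[1]], "ATG")
    expect_equal(aa[[length(aa)]], "*")
    expect_false(any(aa[-length(aa)] == "*"))
    expect_equal(nchar(anc1$transcripts$sequence[[i]]),
                 2 * cfg$utr_bp + 3 * g$n_codons)
  }
})

test_that("zero divergence yields identical copies; full dropout removes a species", {
  cfg <- tiny_config(divergence = c(human = 0, mouse = 0, dog = 0, ferret = 0),
                     dropout_rate = 0, paralog_rate = 0, fragment_rate = 0)
  sim <- evolve_species(generate_ancestral_genes(cfg), cfg)
  for (sp in cfg$species) {
    expect_identical(sim$references[[sp]]$sequence, sim$focal$sequence)
  }
  hits <- emit_hit_tables(sim, "nucleotide", noise = 0)
  expect_true(all(hits$human$fwd$pct_identity == 100))

  cfg2 <- tiny_config(dropout_rate = c(human = 0, mouse = 1, dog = 0, ferret = 0),
                      paralog_rate = 0, fragment_rate = 0)
  sim2 <- evolve_species(generate_ancestral_genes(cfg2), cfg2)
  expect_equal(nrow(sim2$references$mouse), 0L)
  hits2 <- emit_hit_tables(sim2, "nucleotide", noise = 0)
  expect_equal(nrow(hits2$mouse$fwd), 0L)
  pairs <- reciprocal_best_hits(best_hits(hits2$mouse$fwd),
                                best_hits(hits2$mouse$rev))
  expect_equal(nrow(pairs), 0L)
})

test_that("realised nucleotide identity matches the substitution model", {
  cfg <- sim_config(n_genes = 500L, seed = 77L, fragment_rate = 0,
                    dropout_rate = 0, paralog_rate = 0, noise_rate = 0)
  sim <- evolve_species(generate_ancestral_genes(cfg), cfg)
  hits <- emit_hit_tables(sim, "nucleotide", noise = 0)
  hits_aa <- emit_hit_tables(sim, "protein", noise = 0)
  for (sp in cfg$species) {
    d <- cfg$divergence[[sp]]
    ids <- hits[[sp]]$fwd$pct_identity
    expected <- 100 * (1 - d)
    se <- stats::sd(ids) / sqrt(length(ids))
    expect_lt(abs(mean(ids) - expected), 3 * se)
    # synonymous bias: protein identity strictly exceeds nucleotide identity
    aa <- hits_aa[[sp]]$fwd$pct_identity
    expect_gt(mean(aa), mean(ids))
    tt <- stats::t.test(aa, ids, alternative = "greater")
    expect_lt(tt$p.value, 1e-6)
  }
})

test_that("fragmentation respects the floor and preserves substring identity", {
  cfg <- tiny_config(n_genes = 60L, fragment_rate = 0)
  anc <- generate_ancestral_genes(cfg)
  sim <- evolve_species(anc, cfg)
  fr0 <- fragment_focal(sim$focal, cfg)
  expect_identical(fr0$transcripts, sim$focal)   # rate 0: identity transform
  expect_equal(nrow(fr0$fragment_map), 0L)

  cfg1 <- tiny_config(n_genes = 60L, fragment_rate = 1)
  fr1 <- fragment_focal(sim$focal, cfg1)
  expect_equal(nrow(fr1$fragment_map), 60L)
  lens <- nchar(fr1$transcripts$sequence)
  expect_true(all(lens >= cfg1$min_fragment_bp))
  # substring-alignment oracle: each fragment matches its parent exactly
  for (i in seq_len(60)) {
    mp <- fr1$fragment_map[fr1$fragment_map$focal_id ==
                             fr1$transcripts$transcript_id[[i]], ]
    expect_identical(fr1$transcripts$sequence[[i]],
                     substr(sim$focal$sequence[[i]], mp$start, mp$end))
    expect_equal(mp$end - mp$start + 1L, lens[[i]])
  }
})

test_that("emitted hit tables are exact positionwise identities in outfmt 6", {
  cfg <- tiny_config(n_genes = 40L, fragment_rate = 0.4, paralog_rate = 0.3)
  sim <- evolve_species(generate_ancestral_genes(cfg), cfg)
  fr <- fragment_focal(sim$focal, cfg)
  sim$focal <- fr$transcripts
  sim$truth$fragments <- fr$fragment_map
  hits <- emit_hit_tables(sim, "nucleotide", noise = 0)

  focal_seq <- stats::setNames(sim$focal$sequence, sim$focal$transcript_id)
  for (sp in cfg$species) {
    tab <- hits[[sp]]$fwd
    # format contract: parses losslessly through the outfmt-6 reader
    f <- tempfile()
    write_blast_tab(tab, f)
    expect_equal(read_blast_tab(f), tab, tolerance = 1e-12)
    # identity bookkeeping: pct equals an independent Hamming comparison
    ref_seq <- stats::setNames(sim$references[[sp]]$sequence,
                               sim$references[[sp]]$transcript_id)
    for (r in seq_len(nrow(tab))) {
      q <- strsplit(focal_seq[[tab$query_id[[r]]]], "")[[1]]
      s <- strsplit(substr(ref_seq[[tab$subject_id[[r]]]],
                           tab$sstart[[r]], tab$send[[r]]), "")[[1]]
      expect_equal(tab$pct_identity[[r]],
                   round(100 * sum(q == s) / length(q), 2))
    }
    # paralogs are further diverged: the ortholog outranks its paralog
    par <- sim$truth$paralogs[sim$truth$paralogs$species == sp, ]
    for (k in seq_len(nrow(par))) {
      fid <- sim$truth$genes$focal_id[match(par$gene_id[[k]],
                                            sim$truth$genes$gene_id)]
      b_orth <- tab$bitscore[tab$query_id == fid &
                               tab$subject_id == sim$truth$orthologs[fid, sp]]
      b_par <- tab$bitscore[tab$query_id == fid &
                              tab$subject_id == par$paralog_id[[k]]]
      expect_gt(b_orth, b_par)
    }
  }
})

test_that("zero-noise hit counts equal surviving orthologs and RBH recovers truth", {
  cfg <- tiny_config(n_genes = 50L, dropout_rate = 0.2, paralog_rate = 0,
                     fragment_rate = 0)
  sim <- evolve_species(generate_ancestral_genes(cfg), cfg)
  hits <- emit_hit_tables(sim, "nucleotide", noise = 0)
  for (sp in cfg$species) {
    surviving <- sum(!is.na(sim$truth$orthologs[, sp]))
    expect_equal(nrow(hits[[sp]]$fwd), surviving)
    pairs <- reciprocal_best_hits(best_hits(hits[[sp]]$fwd),
                                  best_hits(hits[[sp]]$rev))
    expect_equal(nrow(pairs), surviving)
    i <- !is.na(sim$truth$orthologs[, sp])
    expect_setequal(pairs$reference_id, sim$truth$orthologs[i, sp])
  }
})

test_that("planted annotations carry the configured signal and guard their inputs", {
  genes <- sprintf("g%03d", 1:200)
  expect_error(plant_annotations(genes, enriched =
                                   list(T = list(genes = genes[1:5], fold = 0.5))),
               "fold must be >= 1")
  expect_error(plant_annotations(genes, enriched =
                                   list(T = list(genes = "zz", fold = 2))),
               "belong to the background")
  ann0 <- plant_annotations(genes, n_terms = 0)
  expect_equal(length(ann0$terms), 0L)
  expect_error(suppressMessages(enrich(genes[1:10], ann0)), "no terms")

  # fold 10 over a 50-gene target is recovered as the top-ranked term
  set.seed(19)
  wins <- 0L
  for (r in 1:20) {
    ann <- plant_annotations(genes, n_terms = 20, base_rate = 0.05,
                             enriched = list(HOT = list(genes = genes[1:50],
                                                        fold = 10)),
                             seed = 1900 + r)
    res <- enrich(genes[1:50], ann)
    wins <- wins + (res$term_id[[1L]] == "HOT")
  }
  expect_gte(wins, 19L)
})

test_that("the full study generator is deterministic and internally consistent", {
  cfg <- tiny_config(n_genes = 40L, fragment_rate = 0.2, dropout_rate = 0.1,
                     paralog_rate = 0.1, noise_rate = 0.05,
                     enriched_set_size = 10L, n_terms = 10L)
  s1 <- simulate_orthology_study(cfg)
  s2 <- simulate_orthology_study(cfg)
  expect_identical(s1$focal, s2$focal)
  expect_identical(s1$references, s2$references)
  expect_identical(s1$hits_nt, s2$hits_nt)
  expect_identical(s1$hits_aa, s2$hits_aa)
  expect_identical(s1$annotation, s2$annotation)

  # every emitted focal/reference identifier appears exactly once in truth
  expect_setequal(s1$focal$transcript_id, s1$truth$genes$focal_id)
  for (sp in cfg$species) {
    emitted <- s1$references[[sp]]$transcript_id
    truth_ids <- c(stats::na.omit(s1$truth$orthologs[, sp]),
                   s1$truth$paralogs$paralog_id[s1$truth$paralogs$species == sp])
    expect_setequal(emitted, truth_ids)
    expect_equal(anyDuplicated(emitted), 0L)
  }
  # protein sequences translate the CDS (spot check an unfragmented gene)
  gc <- Biostrings::GENETIC_CODE
  unfrag <- setdiff(s1$truth$genes$focal_id, s1$truth$fragments$focal_id)[1]
  i <- match(unfrag, s1$truth$genes$focal_id)
  cds <- substr(s1$focal$sequence[match(unfrag, s1$focal$transcript_id)],
                s1$truth$genes$cds_start[i],
                s1$truth$genes$cds_start[i] + 3 * (s1$truth$genes$n_codons[i] - 1) - 1)
  aa_oracle <- paste0(gc[substring(cds, seq(1, nchar(cds), 3),
                                   seq(3, nchar(cds), 3))], collapse = "")
  prot <- s1$proteins[[cfg$focal]]
  expect_equal(prot$sequence[match(unfrag, prot$transcript_id)], aa_oracle)
})
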