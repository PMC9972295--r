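test_that("best_hits keeps the dominant-score subject and filters by e-value", {
  hits <- random_hit_table(2L)
  hits$query_id <- "q1"
  hits$subject_id <- c("s1", "s2")
  hits$bitscore <- c(370, 200)
  hits$evalue <- c(1e-50, 1e-40)
  bh <- best_hits(hits)
  expect_equal(bh$subject_id, "s1")

  hits$evalue <- c(1e-3, 1e-40)   # s1 fails the default cutoff
  expect_equal(best_hits(hits)$subject_id, "s2")
  expect_equal(nrow(best_hits(hits, evalue_cutoff = 1e-60)), 0L)
  expect_equal(nrow(best_hits(hits[0, ])), 0L)
})

test_that("best_hits tie-breaking follows bitscore, evalue, identity, subject id", {
  base <- random_hit_table(2L)
  base$query_id <- "q1"
  base$subject_id <- c("s1", "s2")
  base$bitscore <- c(370, 370)
  base$evalue <- c(1e-50, 1e-60)
  expect_equal(best_hits(base)$subject_id, "s2")  # lower e-value wins

  base$evalue <- c(1e-50, 1e-50)
  base$pct_identity <- c(99, 98)
  expect_equal(best_hits(base)$subject_id, "s1")  # higher identity wins

  base$pct_identity <- c(98, 98)
  expect_equal(best_hits(base)$subject_id, "s1")  # lexicographic subject
})

test_that("best_hits equals the exhaustive per-query argmax oracle", {
  set.seed(101)
  for (rep in 1:20) {
    hits <- random_hit_table(200L, n_queries = 20L, n_subjects = 12L)
    mine <- best_hits(hits, evalue_cutoff = 1e-5)
    oracle <- oracle_best_hits(hits, evalue_cutoff = 1e-5)
    mine <- mine[order(mine$query_id), ]
    expect_equal(mine$query_id, oracle$query_id)
    expect_equal(mine$subject_id, oracle$subject_id)
    expect_equal(mine$bitscore, oracle$bitscore)
  }
})

test_that("multiple HSPs per pair are represented by their best HSP", {
  hits <- random_hit_table(3L)
  hits$query_id <- "q1"
  hits$subject_id <- c("s1", "s1", "s2")
  hits$bitscore <- c(100, 340, 300)
  hits$evalue <- c(1e-10, 1e-40, 1e-30)
  hits$pct_identity <- c(80, 95, 90)
  bh <- best_hits(hits)
  expect_equal(bh$subject_id, "s1")
  expect_equal(bh$bitscore, 340)
  expect_equal(bh$pct_identity, 95)
})

test_that("reciprocal_best_hits keeps exactly the mutually-best pairs", {
  fwd <- data.frame(query_id = "q1", subject_id = "s1", bitscore = 370,
                    evalue = 1e-50, pct_identity = 99,
                    stringsAsFactors = FALSE)
  rev <- data.frame(query_id = "s1", subject_id = "q1", bitscore = 360,
                    evalue = 1e-48, pct_identity = 99,
                    stringsAsFactors = FALSE)
  pairs <- reciprocal_best_hits(fwd, rev)
  expect_equal(pairs$focal_id, "q1")
  expect_equal(pairs$reference_id, "s1")

  rev$subject_id <- "q2"   # broken reciprocity
  expect_equal(nrow(reciprocal_best_hits(fwd, rev)), 0L)
})

test_that("RBH equals the set-comprehension oracle and is one-to-one", {
  set.seed(202)
  for (rep in 1:20) {
    qs <- sprintf("q%02d", 1:30)
    ss <- sprintf("s%02d", 1:30)
    fwd <- data.frame(query_id = qs, subject_id = sample(ss, 30, replace = TRUE),
                      bitscore = stats::runif(30, 50, 500),
                      evalue = 10^(-stats::runif(30, 6, 60)),
                      pct_identity = stats::runif(30, 60, 100),
                      stringsAsFactors = FALSE)
    rev <- data.frame(query_id = ss, subject_id = sample(qs, 30, replace = TRUE),
                      bitscore = stats::runif(30, 50, 500),
                      evalue = 10^(-stats::runif(30, 6, 60)),
                      pct_identity = stats::runif(30, 60, 100),
                      stringsAsFactors = FALSE)
    mine <- reciprocal_best_hits(fwd, rev)
    oracle <- oracle_rbh(fwd, rev)
    expect_equal(mine$focal_id, oracle$query_id)
    expect_equal(mine$reference_id, oracle$subject_id)
    expect_equal(anyDuplicated(mine$focal_id), 0L)
    expect_equal(anyDuplicated(mine$reference_id), 0L)
    # symmetry: swapping directions transposes the pair set
    swapped <- reciprocal_best_hits(rev, fwd)
    expect_setequal(paste(swapped$focal_id, swapped$reference_id),
                    paste(mine$reference_id, mine$focal_id))
  }
})

test_that("cascade assigns the first priority species with a pair", {
  pairs <- list(
    human = data.frame(focal_id = "t1", reference_id = "human_t1",
                       bitscore = 300, evalue = 1e-30, pct_identity = 95,
                       stringsAsFactors = FALSE),
    mouse = data.frame(focal_id = character(0), reference_id = character(0),
                       bitscore = numeric(0), evalue = numeric(0),
                       pct_identity = numeric(0), stringsAsFactors = FALSE),
    dog = pairs_dog <- data.frame(focal_id = "t3", reference_id = "dog_t3",
                                  bitscore = 200, evalue = 1e-20,
                                  pct_identity = 88, stringsAsFactors = FALSE),
    ferret = data.frame(focal_id = c("t1", "t3"),
                        reference_id = c("ferret_t1", "ferret_t3"),
                        bitscore = c(280, 250), evalue = c(1e-28, 1e-25),
                        pct_identity = c(93, 90), stringsAsFactors = FALSE))
  asn <- cascade_assign(pairs, priority = c("human", "mouse", "dog", "ferret"))
  expect_equal(asn$reference_species[asn$focal_id == "t1"], "human")
  expect_equal(asn$priority_rank[asn$focal_id == "t1"], 1L)
  expect_equal(asn$reference_species[asn$focal_id == "t3"], "dog")
  expect_false("t2" %in% asn$focal_id)   # unmatched transcript absent
  expect_equal(nrow(asn), 2L)
})

test_that("cascade rejects non-one-to-one inputs and invalid priorities", {
  dup <- list(human = data.frame(focal_id = c("t1", "t1"),
                                 reference_id = c("h1", "h2"),
                                 bitscore = c(1, 2), evalue = c(0, 0),
                                 pct_identity = c(90, 91),
                                 stringsAsFactors = FALSE))
  expect_error(cascade_assign(dup, "human"), "duplicate focal_id 't1'.*human")
  ok <- list(human = dup$human[1, ])
  expect_error(cascade_assign(ok, c("human", "mouse")), "priority")
})

test_that("cascade equals a first-match scan and covers the focal-id union", {
  set.seed(303)
  species <- c("human", "mouse", "dog", "ferret")
  for (rep in 1:15) {
    pool <- sprintf("t%03d", 1:60)
    pairs <- random_pair_sets(species, pool, p_present = 0.45)
    asn <- cascade_assign(pairs, priority = species)
    union_ids <- unique(unlist(lapply(pairs, `[[`, "focal_id")))
    expect_equal(nrow(asn), length(union_ids))
    expect_setequal(asn$focal_id, union_ids)
    # brute-force first-match per transcript
    for (t in union_ids) {
      first <- species[[which(vapply(species, function(sp) {
        t %in% pairs[[sp]]$focal_id
      }, logical(1)))[1L]]]
      expect_equal(asn$reference_species[asn$focal_id == t], first)
    }
    # monotonicity: enriching the lowest-priority species never reassigns
    extra <- pairs
    top_assigned <- asn$focal_id[asn$priority_rank == 1L]
    add <- setdiff(top_assigned, extra$ferret$focal_id)
    if (length(add)) {
      extra$ferret <- rbind(extra$ferret,
                            data.frame(focal_id = add,
                                       reference_id = paste0("ferret_", add),
                                       bitscore = 1, evalue = 1e-30,
                                       pct_identity = 80,
                                       stringsAsFactors = FALSE))
      asn2 <- cascade_assign(extra, priority = species)
      i <- match(top_assigned, asn2$focal_id)
      expect_true(all(asn2$reference_species[i] ==
                        asn$reference_species[match(top_assigned, asn$focal_id)]))
    }
  }
})

test_that("shared_orthologs is exactly the all-species intersection", {
  species <- c("human", "mouse", "dog", "ferret")
  set.seed(404)
  pairs <- random_pair_sets(species, sprintf("t%03d", 1:80), p_present = 0.7)
  shared <- shared_orthologs(pairs)
  oracle_ids <- Reduce(intersect, lapply(pairs, `[[`, "focal_id"))
  expect_setequal(shared$focal_id, oracle_ids)
  expect_lte(nrow(shared), min(vapply(pairs, nrow, integer(1))))
  # every row carries a partner per species
  for (sp in species) {
    expect_false(anyNA(shared[[paste0(sp, "_id")]]))
    expect_equal(shared[[paste0(sp, "_id")]], paste0(sp, "_", shared$focal_id))
  }
  # shared focal ids are a subset of the cascade's focal ids
  asn <- cascade_assign(pairs, priority = species)
  expect_true(all(shared$focal_id %in% asn$focal_id))

  # explicit small cases: present in all vs present in 3 of 4
  pairs4 <- lapply(species, function(sp) {
    data.frame(focal_id = "t1", reference_id = paste0(sp, "_t1"),
               bitscore = 1, evalue = 0, pct_identity = 90,
               stringsAsFactors = FALSE)
  })
  names(pairs4) <- species
  expect_equal(nrow(shared_orthologs(pairs4)), 1L)
  pairs4$ferret <- pairs4$ferret[0, ]
  expect_equal(nrow(shared_orthologs(pairs4)), 0L)
})
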