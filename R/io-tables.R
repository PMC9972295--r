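#' Read a 12-column BLAST tabular hit file (outfmt 6)
#'
#' Parses the standard tab-separated BLAST alignment format: query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value and bit score. Rows are
#' returned in file order; files may contain multiple HSPs per query-subject
#' pair (resolving them is the job of [best_hits()], not the parser).
#'
#' @param path Path to an outfmt-6 file (no header row).
#' @return A data frame with the twelve typed columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_length`, `mismatches`, `gap_opens`,
#'   `qstart`, `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @details A row with a column count other than 12, or a numeric field that
#'   does not parse, is a hard error naming the row number. No silent
#'   coercion is performed.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) {
    stop("hit table not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[[1L]]
    stop("expected 12 tab-separated columns but found ", nf[[bad]],
         " at row ", bad, " of ", path, call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x)) {
      stop("non-numeric ", what, " at row ", which(is.na(x))[[1L]], " of ",
           path, call. = FALSE)
    }
    x
  }
  hits <- data.frame(
    query_id = m[, 1L],
    subject_id = m[, 2L],
    pct_identity = num(3L, "percent identity"),
    aln_length = as.integer(num(4L, "alignment length")),
    mismatches = as.integer(num(5L, "mismatch count")),
    gap_opens = as.integer(num(6L, "gap open count")),
    qstart = as.integer(num(7L, "qstart")),
    qend = as.integer(num(8L, "qend")),
    sstart = as.integer(num(9L, "sstart")),
    send = as.integer(num(10L, "send")),
    evalue = num(11L, "e-value"),
    bitscore = num(12L, "bit score"),
    stringsAsFactors = FALSE
  )
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0, 100] in ", path, call. = FALSE)
  }
  if (any(hits$evalue < 0)) stop("negative e-value in ", path, call. = FALSE)
  if (any(hits$qstart > hits$qend)) {
    stop("qstart > qend in ", path, call. = FALSE)
  }
  hits
}

empty_hit_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write hits in 12-column BLAST tabular format
#'
#' Inverse of [read_blast_tab()]. Numeric columns are written in a fixed
#' canonical form (identity with two decimals, bit score with one, e-value
#' with three significant digits) so that write-read-write round trips are
#' byte identical.
#'
#' @param hits Hit data frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$aln_length, hits$mismatches, hits$gap_opens,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   sprintf("%.3g", hits$evalue), hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Construct an annotation table
#'
#' An annotation table maps term identifiers to gene sets against an explicit
#' background universe. Every annotated gene must belong to the background
#' (genes outside it are a hard error at construction; use the reader's
#' harmonisation if you want them dropped); term gene sets are de-duplicated
#' and must be non-empty.
#'
#' @param terms Named list of character vectors (term id -> gene ids).
#' @param term_names Optional named character vector of human-readable term
#'   names; defaults to the term ids.
#' @param background Character vector of background gene ids; defaults to the
#'   union of all annotated genes.
#' @return An object of class `annotation_table` with elements `terms`,
#'   `term_names` and `background`.
#' @export
annotation_table <- function(terms, term_names = NULL, background = NULL) {
  stopifnot(is.list(terms))
  if (length(terms) > 0L && is.null(names(terms))) {
    stop("terms must be a named list", call. = FALSE)
  }
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(lengths(terms) == 0L)) {
    stop("term gene sets must be non-empty", call. = FALSE)
  }
  annotated <- unique(unlist(terms, use.names = FALSE))
  if (is.null(background)) {
    background <- annotated
  } else {
    background <- unique(as.character(background))
    stray <- setdiff(annotated, background)
    if (length(stray) > 0L) {
      stop("annotated gene(s) outside the background set, e.g. '",
           stray[[1L]], "'", call. = FALSE)
    }
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  } else {
    term_names <- stats::setNames(as.character(term_names)[match(names(terms), names(term_names))],
                                  names(terms))
    term_names[is.na(term_names)] <- names(terms)[is.na(term_names)]
  }
  structure(list(terms = terms, term_names = term_names,
                 background = background),
            class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat("Annotation table:", length(x$terms), "terms,",
      length(x$background), "background genes\n")
  invisible(x)
}

#' Read an annotation table from TSV
#'
#' Accepts the two- or three-column dialect `term <TAB> gene [<TAB> term
#' name]`, one gene per row, without a header. Lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path Path to the annotation TSV.
#' @param background Optional explicit background gene universe. When given,
#'   annotated genes outside it are dropped (harmonisation) and the number of
#'   dropped gene-term rows is reported with a message; when `NULL` the
#'   background is the union of annotated genes.
#' @return An [annotation_table()].
#' @export
read_annotation_table <- function(path, background = NULL) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(annotation_table(stats::setNames(list(), character(0)),
                            background = background))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L | nf > 3L)) {
    bad <- which(nf < 2L | nf > 3L)[[1L]]
    stop("expected 2 or 3 columns at data row ", bad, " of ", path,
         call. = FALSE)
  }
  term <- vapply(fields, `[[`, character(1), 1L)
  gene <- vapply(fields, `[[`, character(1), 2L)
  tname <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else NA_character_,
                  character(1))
  if (!is.null(background)) {
    drop <- !(gene %in% background)
    if (any(drop)) {
      message("read_annotation_table: dropped ", sum(drop),
              " row(s) with genes outside the background")
      term <- term[!drop]; gene <- gene[!drop]; tname <- tname[!drop]
    }
  }
  terms <- split(gene, factor(term, levels = unique(term)))
  nm <- tapply(tname, factor(term, levels = unique(term)),
               function(v) { v <- v[!is.na(v)]; if (length(v)) v[[1L]] else NA_character_ })
  term_names <- stats::setNames(ifelse(is.na(nm), names(terms), nm), names(terms))
  annotation_table(terms, term_names = term_names, background = background)
}

#' Write an annotation table to TSV
#'
#' Inverse of [read_annotation_table()]: emits the three-column dialect
#' `term <TAB> gene <TAB> term name`, terms in stored order, genes in stored
#' order within each term.
#'
#' @param annotation An [annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_table"))
  term <- rep(names(annotation$terms), lengths(annotation$terms))
  gene <- unlist(annotation$terms, use.names = FALSE)
  nm <- annotation$term_names[term]
  writeLines(paste(term, gene, nm, sep = "\t"), path)
  invisible(path)
}

#' Read a gene set from a plain-text list
#'
#' One identifier per line; `#` comment lines and blank lines are ignored;
#' duplicates are collapsed (first occurrence wins).
#'
#' @param path Path to the list file.
#' @param name Set name; defaults to the file name without extension.
#' @return An object of class `gene_set`: a list with elements `name` and
#'   `genes`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop("gene set file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (length(genes) == 0L) {
    stop("gene set file ", path, " contains no identifiers", call. = FALSE)
  }
  gene_set(genes, name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name)
}

#' Construct a gene set
#'
#' @param genes Character vector of gene identifiers (duplicates collapsed).
#' @param name Set name.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, name = "gene_set") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene set must be non-empty", call. = FALSE)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

ortholog_map_columns <- c("focal_id", "species", "reference_id", "rank",
                          "pct_identity")

#' Write a non-redundant ortholog assignment table
#'
#' Writes the output of [cascade_assign()] as a header-bearing TSV with
#' columns `focal_id`, `species`, `reference_id`, `rank` and `pct_identity`.
#' An empty assignment set yields a header-only file.
#'
#' @param assignments Assignment data frame from [cascade_assign()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(assignments, path) {
  stopifnot(is.data.frame(assignments))
  df <- data.frame(focal_id = assignments$focal_id,
                   species = assignments$reference_species,
                   reference_id = assignments$reference_id,
                   rank = assignments$priority_rank,
                   pct_identity = assignments$pct_identity,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a non-redundant ortholog assignment table
#'
#' @param path Path to a TSV written by [write_ortholog_map()].
#' @return Assignment data frame with columns `focal_id`,
#'   `reference_species`, `reference_id`, `priority_rank`, `pct_identity`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(df), ortholog_map_columns)) {
    stop("unexpected ortholog map columns in ", path, call. = FALSE)
  }
  data.frame(focal_id = as.character(df$focal_id),
             reference_species = as.character(df$species),
             reference_id = as.character(df$reference_id),
             priority_rank = as.integer(df$rank),
             pct_identity = as.numeric(df$pct_identity),
             stringsAsFactors = FALSE)
}

#' Write an enrichment result table
#'
#' Emits the classic annotation-enrichment schema: `Term`, `Count`, `%`,
#' `p-value`, `Bonferroni`, `Benjamini`, one row per term sorted as in the
#' input (ascending p). An empty result yields a header-only TSV.
#'
#' @param results Enrichment data frame from [enrich()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  df <- data.frame(Term = if (nrow(results)) results$term_name else character(0),
                   Count = results$count,
                   `%` = results$percent,
                   `p-value` = results$p_value,
                   Bonferroni = results$bonferroni,
                   Benjamini = results$benjamini,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# Deterministic header-bearing TSV writer used for all pipeline outputs.
write_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
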