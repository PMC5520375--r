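#' Forward homology search of one query against a protein database
#'
#' Aligns the query against every database sequence with exact local
#' Smith-Waterman alignment (see [align_pair()]), attaches Karlin-Altschul
#' e-values and bit scores, and returns the hits that pass the e-value
#' threshold, best first. "Best first" means ascending e-value, then
#' descending bit score, then lexicographic subject id, so the ordering is
#' total and stable under permutation of the database.
#'
#' @param query Query sequence (single character string).
#' @param db Named character vector of database sequences (names are
#'   subject ids).
#' @param query_id Id recorded for the query in the output.
#' @param meta Optional data frame with columns `id`, `organism` (and
#'   optionally `genus`, `taxon_group`) used to annotate subjects.
#' @param max_hits Maximum number of hits returned (default 10000).
#' @param evalue_max Retain hits with e-value at or below this (default 1e-5).
#' @param db_residues Effective database size in residues; defaults to the
#'   total residue count of `db`. Fixing it across searches makes e-values
#'   comparable between forward and reverse runs.
#' @param matrix,gap_open,gap_extend Alignment parameters, see [align_pair()].
#' @return Data frame of search hits with columns `query_id`, `subject_id`,
#'   `subject_organism`, `subject_genus`, `subject_taxon_group`, `score`,
#'   `bitscore`, `evalue`, `percent_similarity`, `aln_length`.
#' @export
forward_search <- function(query, db, query_id = "query", meta = NULL,
                           max_hits = 10000, evalue_max = 1e-5,
                           db_residues = NULL, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (length(db) == 0) {
    warning("forward_search: empty database")
    return(empty_hits())
  }
  if (is.null(names(db)) || anyNA(names(db)) || any(!nzchar(names(db)))) {
    stop("forward_search: db must be a named character vector")
  }
  submat <- clock_submat(matrix)
  query <- sanitize_aa(query)
  dbs <- sanitize_aa(db)
  names(dbs) <- names(db)
  if (is.null(db_residues)) db_residues <- sum(nchar(dbs))

  # score-only pass over the whole database, full alignments (for the
  # similarity and length columns) only for hits that pass the filter
  sc <- pairwiseAlignment(AAStringSet(dbs), query, type = "local",
                          substitutionMatrix = submat,
                          gapOpening = gap_open, gapExtension = gap_extend,
                          scoreOnly = TRUE)
  ev <- estimate_evalue(pmax(sc, 0), nchar(query), db_residues)
  keep <- which(sc > 0 & ev <= evalue_max)
  if (!length(keep)) return(empty_hits())
  hits <- data.frame(
    query_id = query_id,
    subject_id = names(dbs)[keep],
    subject_organism = NA_character_,
    subject_genus = NA_character_,
    subject_taxon_group = NA_character_,
    score = sc[keep],
    bitscore = bit_score(sc[keep]),
    evalue = ev[keep],
    percent_similarity = NA_real_,
    aln_length = NA_integer_,
    stringsAsFactors = FALSE
  )
  hits <- hits[order_hits(hits), , drop = FALSE]
  hits <- utils::head(hits, max_hits)
  pa <- pairwiseAlignment(AAStringSet(dbs[hits$subject_id]), query,
                          type = "local", substitutionMatrix = submat,
                          gapOpening = gap_open, gapExtension = gap_extend)
  ap <- as.character(alignedPattern(pa))
  as <- as.character(alignedSubject(pa))
  hits$percent_similarity <- mapply(percent_positives, ap, as,
                                    MoreArgs = list(submat = submat),
                                    USE.NAMES = FALSE)
  hits$aln_length <- nchar(ap)
  hits <- annotate_subjects(hits, meta)
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             subject_organism = character(), subject_genus = character(),
             subject_taxon_group = character(), score = numeric(),
             bitscore = numeric(), evalue = numeric(),
             percent_similarity = numeric(), aln_length = integer(),
             stringsAsFactors = FALSE)
}

order_hits <- function(hits) {
  order(hits$evalue, -hits$bitscore, hits$subject_id)
}

annotate_subjects <- function(hits, meta) {
  if (is.null(meta) || nrow(hits) == 0) return(hits)
  idx <- match(hits$subject_id, meta$id)
  if ("organism" %in% names(meta)) {
    hits$subject_organism <- meta$organism[idx]
  }
  hits$subject_genus <- genus_of(
    hits$subject_organism,
    if ("genus" %in% names(meta)) meta$genus[idx] else NA_character_
  )
  if ("taxon_group" %in% names(meta)) {
    hits$subject_taxon_group <- meta$taxon_group[idx]
  }
  hits
}

#' Genus from an organism name
#'
#' The genus is the explicit metadata value when supplied, otherwise the
#' first whitespace-delimited token of the organism name.
#'
#' @param organism Character vector of organism names.
#' @param genus Optional explicit genus values (NA where absent).
#' @return Character vector of genus names.
#' @export
genus_of <- function(organism, genus = NA_character_) {
  genus <- rep_len(as.character(genus), length(organism))
  fallback <- vapply(strsplit(as.character(organism), "\\s+"),
                     function(x) if (length(x)) x[[1]] else NA_character_,
                     character(1))
  ifelse(is.na(genus) | !nzchar(genus), fallback, genus)
}

#' Reciprocal best-hit filter
#'
#' For each forward hit, searches the subject sequence back against the
#' query genome (with a permissive reverse e-value threshold) and keeps the
#' hit only if the best reverse hit is the original query. Subjects whose
#' sequence cannot be retrieved are skipped with a warning.
#'
#' @param forward_hits Data frame of forward hits (see [forward_search()]).
#' @param db Named character vector holding the subject sequences.
#' @param query_genome Named character vector of the query organism's
#'   proteins (must contain the original queries).
#' @param evalue_max_rev Reverse-search e-value threshold (default 10).
#' @param ... Further alignment parameters passed to [forward_search()].
#' @return Data frame of accepted pairs: the forward-hit columns plus
#'   `reverse_best_id` (always equal to `query_id` for accepted rows).
#' @export
reciprocal_filter <- function(forward_hits, db, query_genome,
                              evalue_max_rev = 10, ...) {
  if (nrow(forward_hits) == 0) {
    out <- empty_hits()
    out$reverse_best_id <- character()
    return(out)
  }
  subjects <- unique(forward_hits$subject_id)
  missing <- setdiff(subjects, names(db))
  if (length(missing)) {
    warning("reciprocal_filter: skipping subjects without sequence: ",
            paste(missing, collapse = ", "))
    subjects <- setdiff(subjects, missing)
  }
  best_rev <- vapply(subjects, function(sid) {
    rev <- forward_search(db[[sid]], query_genome, query_id = sid,
                          evalue_max = evalue_max_rev, max_hits = 1, ...)
    if (nrow(rev) == 0) NA_character_ else rev$subject_id[[1]]
  }, character(1))
  forward_hits$reverse_best_id <- best_rev[forward_hits$subject_id]
  keep <- !is.na(forward_hits$reverse_best_id) &
    forward_hits$reverse_best_id == forward_hits$query_id
  out <- forward_hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best-hit screen of a query set against a proteome collection
#'
#' Runs [forward_search()] for every query, applies [reciprocal_filter()],
#' and attaches subtype labels with [classify_subtype()]. This is the
#' search stage of the comparative screen: queries are the reference clock
#' proteins, the database is the union of all candidate proteomes, and the
#' query genome is the reference organism's protein set.
#'
#' @param queries Named character vector of query protein sequences.
#' @param db Named character vector of database sequences.
#' @param meta Optional subject metadata (see [forward_search()]).
#' @param query_genome Query-organism proteins used for the reverse search;
#'   defaults to `queries`.
#' @param max_hits,evalue_max,evalue_max_rev Search thresholds (defaults
#'   10000, 1e-5 and 10).
#' @param ... Further alignment parameters.
#' @return Data frame of accepted reciprocal best hits with a `subtype`
#'   column.
#' @export
rbh_screen <- function(queries, db, meta = NULL, query_genome = queries,
                       max_hits = 10000, evalue_max = 1e-5,
                       evalue_max_rev = 10, ...) {
  stopifnot(!is.null(names(queries)))
  hits <- lapply(names(queries), function(qid) {
    fwd <- forward_search(queries[[qid]], db, query_id = qid, meta = meta,
                          max_hits = max_hits, evalue_max = evalue_max, ...)
    reciprocal_filter(fwd, db, query_genome,
                      evalue_max_rev = evalue_max_rev, ...)
  })
  rbh <- do.call(rbind, hits)
  rownames(rbh) <- NULL
  classify_subtype(rbh)
}

#' Assign a single subtype to each subject
#'
#' A subject can be a reciprocal best hit to several query subtypes (e.g.
#' both a KaiC1 and a KaiC3 query). Each subject is assigned exactly one
#' subtype: the query with the highest forward bit score; ties are broken by
#' lowest e-value, then by lexicographic query id.
#'
#' @param rbh_pairs Data frame of accepted pairs (see [reciprocal_filter()]).
#' @param label_map Optional named character vector mapping query ids to
#'   subtype labels; by default the query id is the label.
#' @return `rbh_pairs` with a `subtype` column (the subject's assigned
#'   subtype, repeated on every row for that subject).
#' @export
classify_subtype <- function(rbh_pairs, label_map = NULL) {
  if (nrow(rbh_pairs) == 0) {
    rbh_pairs$subtype <- character()
    return(rbh_pairs)
  }
  ord <- order(rbh_pairs$subject_id, -rbh_pairs$bitscore, rbh_pairs$evalue,
               rbh_pairs$query_id)
  best <- rbh_pairs[ord, , drop = FALSE]
  best <- best[!duplicated(best$subject_id), c("subject_id", "query_id")]
  label <- best$query_id
  if (!is.null(label_map)) {
    mapped <- label_map[label]
    label <- ifelse(is.na(mapped), label, mapped)
  }
  names(label) <- best$subject_id
  rbh_pairs$subtype <- unname(label[rbh_pairs$subject_id])
  rbh_pairs
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Imports the standard 12-column tabular format so that hit tables computed
#' by external BLASTP runs can be substituted for the built-in search at
#' scale.
#'
#' @param path Path to a tab-separated file with the columns qseqid sseqid
#'   pident length mismatch gapopen qstart qend sstart send evalue bitscore.
#' @return Data frame with those columns, typed.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12) stop("read_blast_tab: expected 12 columns, got ",
                           ncol(df))
  names(df) <- cols
  df
}

#' Read a proteome FASTA with optional metadata sidecar
#'
#' @param fasta Path to a (multi-)FASTA of protein sequences.
#' @param sidecar Optional path to a tab-separated file with columns
#'   `id`, `organism`, `genus`, `taxon_group`. Without a sidecar the
#'   organism is taken from the FASTA description (text after the first
#'   space), the genus from its first token, and the taxon group is
#'   `"Other"`.
#' @return List with `sequences` (named character vector) and `meta`
#'   (data frame).
#' @export
read_proteome <- function(fasta, sidecar = NULL) {
  ss <- readAAStringSet(fasta)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  seqs <- as.character(ss)
  names(seqs) <- ids
  if (!is.null(sidecar)) {
    meta <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    meta <- meta[match(ids, meta$id), , drop = FALSE]
  } else {
    desc <- sub("^\\S+\\s*", "", full)
    organism <- ifelse(nzchar(desc), desc, NA_character_)
    meta <- data.frame(id = ids, organism = organism,
                       genus = genus_of(organism),
                       taxon_group = "Other", stringsAsFactors = FALSE)
  }
  list(sequences = seqs, meta = meta)
}

#' Write a hits or RBH table as TSV
#'
#' @param hits Data frame of hits.
#' @param path Output path.
#' @param header Optional comment lines (without the leading `#`).
#' @export
write_hits_tsv <- function(hits, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
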