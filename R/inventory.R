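TAXON_GROUPS <- c("Cyanobacteria", "Proteobacteria", "Archaea", "Other")

#' Build per-strain clock-system inventories
#'
#' Aggregates accepted reciprocal best hits into one clock system per
#' strain: the set of factors detected and their copy numbers. Configured
#' label groups are collapsed first (by default the reference KaiB/KaiC
#' queries onto KaiB1/KaiC1). Strains without any KaiC-family homolog are
#' dropped, since KaiC is the core of the oscillator.
#'
#' @param rbh_pairs RBH table with `subtype` assigned
#'   (see [classify_subtype()]).
#' @param merge_map Named character vector collapsing factor labels;
#'   see [default_factor_merge()]. Labels in the map must be known factor
#'   labels or appear in the data.
#' @param keep_factors KaiC-family labels whose presence retains a strain.
#' @return Data frame with one row per strain x detected factor:
#'   `strain`, `genus`, `taxon_group`, `factor`, `copy_count`,
#'   `mean_similarity`.
#' @export
build_inventory <- function(rbh_pairs, merge_map = default_factor_merge(),
                            keep_factors = kaic_family()) {
  known <- union(clock_queries(), unique(rbh_pairs$subtype))
  bad <- setdiff(union(names(merge_map), unname(merge_map)), known)
  if (length(bad)) {
    stop("build_inventory: unknown factor label in merge map: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(rbh_pairs) == 0) {
    return(data.frame(strain = character(), genus = character(),
                      taxon_group = character(), factor = character(),
                      copy_count = integer(), mean_similarity = numeric(),
                      stringsAsFactors = FALSE))
  }
  fac <- merge_factor_labels(rbh_pairs$subtype, merge_map)
  df <- data.frame(strain = rbh_pairs$subject_organism,
                   genus = rbh_pairs$subject_genus,
                   taxon_group = rbh_pairs$subject_taxon_group,
                   factor = fac,
                   percent_similarity = rbh_pairs$percent_similarity,
                   subject_id = rbh_pairs$subject_id,
                   stringsAsFactors = FALSE)
  # one subject protein contributes one copy, whatever the number of
  # query-side RBH partners it had before subtype assignment
  df <- df[!duplicated(df[c("strain", "factor", "subject_id")]), ]
  agg <- aggregate(list(copy_count = df$subject_id),
                   by = df[c("strain", "genus", "taxon_group", "factor")],
                   FUN = function(x) length(unique(x)))
  sim <- aggregate(list(mean_similarity = df$percent_similarity),
                   by = df[c("strain", "factor")], FUN = mean)
  inv <- merge(agg, sim, by = c("strain", "factor"), sort = FALSE)
  inv$copy_count <- as.integer(inv$copy_count)
  retained <- unique(inv$strain[inv$factor %in% keep_factors])
  inv <- inv[inv$strain %in% retained, , drop = FALSE]
  inv <- inv[order(inv$strain, inv$factor),
             c("strain", "genus", "taxon_group", "factor", "copy_count",
               "mean_similarity")]
  rownames(inv) <- NULL
  inv
}

merge_factor_labels <- function(labels, merge_map) {
  mapped <- unname(merge_map[labels])
  unname(ifelse(is.na(mapped), labels, mapped))
}

#' Presence/absence matrix of factors over strains
#'
#' Presence is boolean on copy number >= 1; downstream statistics never
#' weight by copy number.
#'
#' @param inventory Inventory data frame from [build_inventory()].
#' @param factors Ordered factor list defining the columns.
#' @return Integer 0/1 matrix, rows = strains, columns = factors.
#' @export
presence_matrix <- function(inventory, factors = clock_factors()) {
  strains <- sort(unique(inventory$strain))
  m <- matrix(0L, nrow = length(strains), ncol = length(factors),
              dimnames = list(strains, factors))
  keep <- inventory$factor %in% factors
  m[cbind(inventory$strain[keep], inventory$factor[keep])] <- 1L
  m
}

#' Genus-level mean sequence similarity per factor
#'
#' For every genus containing at least one retained strain, the arithmetic
#' mean of the percent similarity of accepted hits is computed per factor
#' across the genus's genomes. Genera are ordered by taxon group
#' (Cyanobacteria, Proteobacteria, Archaea, Other) and, within a group, by
#' descending mean KaiC-family similarity. A genus with no accepted hit for
#' a factor has no row for that factor (missing, not zero).
#'
#' @param rbh_pairs RBH table with subtypes assigned.
#' @param merge_map Factor merge map (see [build_inventory()]).
#' @param keep_factors KaiC-family labels used for the retention filter and
#'   the within-group ordering.
#' @return Data frame `genus`, `taxon_group`, `n_genomes`, `factor`,
#'   `mean_similarity`, with `genus` an ordered factor giving the display
#'   order.
#' @export
genus_mean_similarity <- function(rbh_pairs,
                                  merge_map = default_factor_merge(),
                                  keep_factors = kaic_family()) {
  inv <- build_inventory(rbh_pairs, merge_map, keep_factors)
  if (nrow(inv) == 0) {
    return(data.frame(genus = character(), taxon_group = character(),
                      n_genomes = integer(), factor = character(),
                      mean_similarity = numeric(), stringsAsFactors = FALSE))
  }
  fac <- merge_factor_labels(rbh_pairs$subtype, merge_map)
  hits <- data.frame(genus = rbh_pairs$subject_genus,
                     taxon_group = rbh_pairs$subject_taxon_group,
                     strain = rbh_pairs$subject_organism,
                     factor = fac,
                     percent_similarity = rbh_pairs$percent_similarity,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$strain %in% unique(inv$strain), , drop = FALSE]
  out <- aggregate(list(mean_similarity = hits$percent_similarity),
                   by = hits[c("genus", "taxon_group", "factor")],
                   FUN = mean)
  ngen <- aggregate(list(n_genomes = hits$strain),
                    by = hits["genus"],
                    FUN = function(x) length(unique(x)))
  out <- merge(out, ngen, by = "genus", sort = FALSE)

  kaic_rows <- out[out$factor %in% keep_factors, , drop = FALSE]
  kaic_sim <- aggregate(list(mean_similarity = kaic_rows$mean_similarity),
                        by = kaic_rows["genus"], FUN = mean)
  rank_df <- unique(out[c("genus", "taxon_group")])
  rank_df$group_rank <- match(rank_df$taxon_group, TAXON_GROUPS)
  rank_df$kaic <- kaic_sim$mean_similarity[match(rank_df$genus,
                                                 kaic_sim$genus)]
  rank_df <- rank_df[order(rank_df$group_rank, -rank_df$kaic,
                           rank_df$genus), ]
  out$genus <- factor(out$genus, levels = rank_df$genus, ordered = TRUE)
  out <- out[order(out$genus, out$factor),
             c("genus", "taxon_group", "n_genomes", "factor",
               "mean_similarity")]
  rownames(out) <- NULL
  out
}

#' Condensed copy-number profile
#'
#' Strain-by-factor matrix of homolog copy numbers; counts of 0-5 are
#' reported exactly, larger counts are condensed to the category `">5"`.
#'
#' @param inventory Inventory data frame from [build_inventory()].
#' @param factors Ordered factor list defining the columns.
#' @return Character matrix (values "0".."5" or ">5").
#' @export
copy_number_profile <- function(inventory, factors = clock_factors()) {
  strains <- sort(unique(inventory$strain))
  m <- matrix(0L, nrow = length(strains), ncol = length(factors),
              dimnames = list(strains, factors))
  keep <- inventory$factor %in% factors
  m[cbind(inventory$strain[keep], inventory$factor[keep])] <-
    inventory$copy_count[keep]
  out <- matrix(as.character(m), nrow = nrow(m), dimnames = dimnames(m))
  out[m > 5] <- ">5"
  out
}

#' Protein length records from an RBH table
#'
#' @param rbh_pairs RBH table with subtypes assigned.
#' @param db Named character vector with the subject sequences.
#' @param merge_map Factor merge map.
#' @return Data frame `factor`, `subject_id`, `organism`, `taxon_group`,
#'   `length` (amino acids).
#' @export
length_records <- function(rbh_pairs, db,
                           merge_map = default_factor_merge()) {
  fac <- merge_factor_labels(rbh_pairs$subtype, merge_map)
  rec <- data.frame(factor = fac,
                    subject_id = rbh_pairs$subject_id,
                    organism = rbh_pairs$subject_organism,
                    taxon_group = rbh_pairs$subject_taxon_group,
                    stringsAsFactors = FALSE)
  rec <- rec[!duplicated(rec[c("factor", "subject_id")]), , drop = FALSE]
  rec$length <- nchar(db[rec$subject_id])
  rownames(rec) <- NULL
  rec
}

#' Joint protein-length table and per-factor empirical CDFs
#'
#' For a factor pair (X, Y), emits one row per (X copy, Y copy) combination
#' within each organism having both factors, plus the empirical cumulative
#' distribution of lengths over all records of each factor. Organisms
#' lacking one factor of the pair contribute only to that factor's marginal
#' CDF.
#'
#' @param records Length records (see [length_records()]).
#' @param pair Character vector of two factor labels, `c(factorX, factorY)`.
#' @return List with `joint` (data frame `organism`, `taxon_group`,
#'   `length_x`, `length_y`) and `cdf` (named list of two `ecdf` functions).
#' @export
length_distribution <- function(records, pair) {
  stopifnot(length(pair) == 2, nrow(records) > 0)
  rx <- records[records$factor == pair[[1]], , drop = FALSE]
  ry <- records[records$factor == pair[[2]], , drop = FALSE]
  shared <- intersect(unique(rx$organism), unique(ry$organism))
  joint <- do.call(rbind, lapply(shared, function(org) {
    lx <- rx$length[rx$organism == org]
    ly <- ry$length[ry$organism == org]
    grid <- expand.grid(length_x = lx, length_y = ly)
    grid$organism <- org
    grid$taxon_group <- rx$taxon_group[rx$organism == org][[1]]
    grid
  }))
  if (is.null(joint)) {
    joint <- data.frame(length_x = integer(), length_y = integer(),
                        organism = character(), taxon_group = character())
  }
  cdfs <- list(stats::ecdf(rx$length), stats::ecdf(ry$length))
  names(cdfs) <- pair
  list(joint = joint[c("organism", "taxon_group", "length_x", "length_y")],
       cdf = cdfs)
}
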