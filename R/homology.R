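#' Hit list of a query
#'
#' The set of subjects a query hits (after per-pair collapsing), always
#' including the query itself, which is how the reciprocal-hit intersection
#' treats each list.
#'
#' @param hits Collapsed hit table ([collapse_best_pairs()]).
#' @param id Query sequence ID.
#' @return Character vector of sequence IDs.
#' @export
hit_list <- function(hits, id) {
  union(id, hits$subject_id[hits$query_id == id])
}

rank_subjects <- function(hits, query_id) {
  h <- hits[hits$query_id == query_id & hits$subject_id != query_id, , drop = FALSE]
  h <- h[order(h$e_value, -h$bitscore, h$subject_id), , drop = FALSE]
  h$subject_id
}

#' Build a homolog set by reciprocal-hit intersection
#'
#' For a query, take its top-`top_n` hits (ranked by ascending e-value, ties
#' by descending bitscore then lexicographic subject ID), and intersect the
#' hit lists of the query and of each of those top hits; every list includes
#' its own query. The intersection is the putative homolog set. The query is
#' always a member; a query with no hits yields the singleton set with empty
#' provenance.
#'
#' @param query_id Query sequence ID.
#' @param hits Hit table (already e-value filtered); HSPs are collapsed
#'   internally.
#' @param top_n Number of top hits whose lists are intersected (default 5).
#' @return A list of class `homolog_set` with `query_id`, `members`
#'   (character, sorted), `provenance` (the top-hit IDs used).
#' @export
build_homolog_set <- function(query_id, hits, top_n = 5L) {
  stopifnot(top_n >= 1L)
  hits <- collapse_best_pairs(hits)
  top <- utils::head(rank_subjects(hits, query_id), top_n)
  members <- hit_list(hits, query_id)
  for (id in top) members <- intersect(members, hit_list(hits, id))
  members <- union(query_id, members)
  structure(list(query_id = query_id, members = sort(members),
                 provenance = top),
            class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat("homolog set for", x$query_id, "-", length(x$members), "members,",
      length(x$provenance), "intersected top hits\n")
  invisible(x)
}

member_scores <- function(members, query_id, hits) {
  sc <- rep(-Inf, length(members))
  idx <- match(paste(query_id, members), paste(hits$query_id, hits$subject_id))
  sc[!is.na(idx)] <- hits$bitscore[idx[!is.na(idx)]]
  sc[members == query_id] <- Inf
  sc
}

#' Apply taxonomic sampling filters to a homolog set
#'
#' Enforces the sampling criteria that keep a family's taxon representation
#' balanced: no species represented more than `species_cap` times (likely
#' paralogs), at most `subgroup_cap` distinct prokaryote subgroups, and at
#' most `opisthokont_cap` members each from Fungi and from Metazoa. Within
#' each cap, members are ranked by bitscore to the query (descending, ties by
#' lexicographic ID); the query itself always survives. The operation is
#' idempotent: caps are applied in a fixed order (species, then prokaryote
#' subgroups, then Fungi/Metazoa) and each step only removes members.
#'
#' @param hset A `homolog_set`.
#' @param taxonomy Taxonomy data.frame; every member must resolve.
#' @param hits Collapsed hit table providing query-to-member bitscores.
#' @param species_cap,subgroup_cap,opisthokont_cap Cap values (defaults 5, 5, 15).
#' @return The filtered `homolog_set`.
#' @export
apply_sampling_filters <- function(hset, taxonomy, hits,
                                   species_cap = 5L, subgroup_cap = 5L,
                                   opisthokont_cap = 15L) {
  members <- hset$members
  idx <- match(members, taxonomy$sequence_id)
  if (anyNA(idx))
    stop("homolog-set member(s) absent from taxonomy: ",
         paste(members[is.na(idx)], collapse = ", "))
  hits <- collapse_best_pairs(hits)
  info <- data.frame(id = members,
                     species = taxonomy$species[idx],
                     phylum = taxonomy$phylum[idx],
                     subgroup = taxonomy$subgroup[idx],
                     score = member_scores(members, hset$query_id, hits),
                     stringsAsFactors = FALSE)
  info <- info[order(-info$score, info$id), , drop = FALSE]

  # per-species cap
  keep <- stats::ave(seq_len(nrow(info)), info$species, FUN = seq_along) <= species_cap
  keep[info$id == hset$query_id] <- TRUE
  info <- info[keep, , drop = FALSE]

  # prokaryote subgroup-count cap: keep the subgroups whose best member
  # scores highest (ties by subgroup name)
  pro <- info$phylum == "Prokaryote"
  if (any(pro)) {
    best <- tapply(info$score[pro], info$subgroup[pro], max)
    ord <- order(-best, names(best))
    kept_groups <- names(best)[ord][seq_len(min(subgroup_cap, length(best)))]
    qsub <- info$subgroup[info$id == hset$query_id]
    drop <- pro & !(info$subgroup %in% kept_groups) & info$id != hset$query_id
    info <- info[!drop, , drop = FALSE]
  }

  # Fungi / Metazoa caps
  for (ph in c("Fungi", "Metazoa")) {
    sel <- info$phylum == ph
    if (sum(sel) > opisthokont_cap) {
      rank_in <- cumsum(sel)
      drop <- sel & rank_in > opisthokont_cap & info$id != hset$query_id
      info <- info[!drop, , drop = FALSE]
    }
  }

  hset$members <- sort(info$id)
  hset
}

#' Family-size and alignment eligibility
#'
#' A protein family enters phylogenetic analysis only when it has between
#' `min_members` and `max_members` members and its trimmed alignment retains
#' at least `min_sites` positions.
#'
#' @param set_size Number of members in the (filtered) family.
#' @param alignment Trimmed alignment matrix (or `NULL` with `n_sites`).
#' @param min_members,max_members,min_sites Eligibility bounds (4, 100, 50).
#' @param n_sites Site count, if no alignment object is at hand.
#' @return list(eligible = logical, reason = character).
#' @export
check_family_eligibility <- function(set_size, alignment = NULL,
                                     min_members = 4L, max_members = 100L,
                                     min_sites = 50L, n_sites = NULL) {
  if (is.null(n_sites)) {
    stopifnot(!is.null(alignment))
    n_sites <- ncol(alignment)
  }
  if (set_size < min_members)
    return(list(eligible = FALSE, reason = "too few members"))
  if (set_size > max_members)
    return(list(eligible = FALSE, reason = "too many members"))
  if (n_sites < min_sites)
    return(list(eligible = FALSE, reason = "too few aligned sites"))
  list(eligible = TRUE, reason = "")
}

#' Mask gap-rich alignment columns
#'
#' A documented stand-in for block-based alignment trimming: columns whose
#' gap fraction exceeds `max_gap_fraction` are removed, order preserved.
#' Pre-trimmed alignments can be supplied directly instead.
#'
#' @param alignment Character matrix; gaps are `-` or `.`.
#' @param max_gap_fraction Maximum tolerated gap fraction per column (0.5).
#' @return The masked alignment matrix.
#' @export
mask_columns <- function(alignment, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  if (is.null(dim(alignment)) || nrow(alignment) == 0L || ncol(alignment) == 0L)
    stop("empty alignment")
  gapfrac <- colMeans(alignment == "-" | alignment == ".")
  alignment[, gapfrac <= max_gap_fraction, drop = FALSE]
}

#' Exclusive two-phylum association of a query
#'
#' A query whose significant hits fall only in its own phylum (diatoms) and
#' exactly one other phylum shows an exclusive phyletic association with that
#' partner. The taxonomic-breadth flags record whether the total number of
#' hits drawn from the two phyla reaches x = 2, 10, 20 — associations backed
#' by more hits are less likely to reflect sparse database sampling.
#'
#' @param query_id Query sequence ID (a diatom sequence).
#' @param hits Hit table, already e-value filtered.
#' @param taxonomy Taxonomy data.frame.
#' @return list of class `exclusive_association`: `query_id`,
#'   `partner_phylum` (`NA` if hits span several non-diatom phyla or none),
#'   `n_hits` (non-diatom hit count), and logical `x2`, `x10`, `x20`.
#' @export
exclusive_association <- function(query_id, hits, taxonomy) {
  hits <- collapse_best_pairs(hits)
  subj <- hits$subject_id[hits$query_id == query_id]
  subj <- union(query_id, subj)
  ph <- taxon_phylum(subj, taxonomy)
  n_diatom <- sum(ph == "Diatom")
  other <- unique(ph[ph != "Diatom"])
  n_other <- sum(ph != "Diatom")
  partner <- if (length(other) == 1L) other else NA_character_
  total <- if (!is.na(partner)) n_diatom + n_other else 0L
  structure(list(query_id = query_id, partner_phylum = partner,
                 n_hits = n_other,
                 x2 = !is.na(partner) && total >= 2L,
                 x10 = !is.na(partner) && total >= 10L,
                 x20 = !is.na(partner) && total >= 20L),
            class = "exclusive_association")
}

#' Exclusive-association survey over a query cohort
#'
#' @param query_ids Character vector of diatom queries.
#' @param hits Hit table.
#' @param taxonomy Taxonomy data.frame.
#' @return data.frame, one row per query (a partition: every query gets
#'   exactly one verdict).
#' @export
exclusive_cohort <- function(query_ids, hits, taxonomy) {
  rows <- lapply(query_ids, function(q) {
    a <- exclusive_association(q, hits, taxonomy)
    data.frame(query_id = a$query_id,
               partner_phylum = ifelse(is.na(a$partner_phylum), "none",
                                       a$partner_phylum),
               n_hits = a$n_hits, x2 = a$x2, x10 = a$x10, x20 = a$x20,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Catalog bookkeeping: drop obsolete and redundant protein records
#'
#' Reproduces the input-curation arithmetic of a protein catalog: records
#' flagged obsolete are removed, and records sharing a database accession
#' (redundant entries) are collapsed to their first occurrence.
#'
#' @param catalog data.frame with columns `protein_id`, `species`,
#'   `accession`, `obsolete` (logical).
#' @return The retained catalog rows.
#' @export
filter_protein_catalog <- function(catalog) {
  stopifnot(all(c("protein_id", "species", "accession", "obsolete") %in%
                  names(catalog)))
  kept <- catalog[!catalog$obsolete, , drop = FALSE]
  kept <- kept[!duplicated(kept$accession), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}
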