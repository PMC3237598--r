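#' Controlled phylum vocabulary
#'
#' The closed set of phylum labels used by every screening rule. "Diatom" and
#' "StramenopileOther" are distinct labels but both belong to the
#' "Stramenopiles" rank; "Rhodophyta", "Viridiplantae" and "Glaucophyta"
#' together form the "Plantae" rank. Any taxonomy row with a label outside
#' this vocabulary is rejected at load time, so downstream rules never meet an
#' unknown phylum mid-pipeline.
#'
#' @return Character vector of valid phylum labels.
#' @export
phylum_vocabulary <- function() {
  c("Diatom", "StramenopileOther", "Alveolata", "Rhizaria", "Haptophyta",
    "Cryptophyta", "Rhodophyta", "Viridiplantae", "Glaucophyta", "Fungi",
    "Metazoa", "Amoebozoa", "Excavata", "OtherEukaryote", "Prokaryote")
}

#' Expand a taxonomic rank to its member phyla
#'
#' Screening rules sometimes target a single phylum (the diatom-only phase-1
#' screen) and sometimes a higher rank (all stramenopiles for the topology
#' tests; Plantae for the red/green partner). This helper resolves a rank name
#' to the set of vocabulary phyla it covers.
#'
#' @param rank One of the vocabulary phyla, `"Stramenopiles"` or `"Plantae"`.
#' @return Character vector of phylum labels.
#' @export
expand_rank <- function(rank) {
  stopifnot(is.character(rank), length(rank) == 1L)
  if (rank == "Stramenopiles") return(c("Diatom", "StramenopileOther"))
  if (rank == "Plantae") return(c("Rhodophyta", "Viridiplantae", "Glaucophyta"))
  if (rank %in% phylum_vocabulary()) return(rank)
  stop("unknown rank or phylum: '", rank, "'; valid phyla are: ",
       paste(phylum_vocabulary(), collapse = ", "))
}

validate_taxonomy <- function(tax) {
  required <- c("sequence_id", "species", "phylum", "subgroup")
  missing <- setdiff(required, names(tax))
  if (length(missing))
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  dup <- tax$sequence_id[duplicated(tax$sequence_id)]
  if (length(dup))
    stop("duplicate sequence_id in taxonomy: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(tax$phylum), phylum_vocabulary())
  if (length(bad))
    stop("unknown phylum label(s): ", paste(bad, collapse = ", "),
         "; valid labels are: ", paste(phylum_vocabulary(), collapse = ", "))
  pro <- tax$phylum == "Prokaryote"
  if (any(pro & (is.na(tax$subgroup) | tax$subgroup == "")))
    stop("prokaryote records must carry a nonempty subgroup: ",
         paste(tax$sequence_id[pro & (is.na(tax$subgroup) | tax$subgroup == "")],
               collapse = ", "))
  if (any(!pro & !is.na(tax$subgroup) & tax$subgroup != ""))
    stop("non-prokaryote records must have an empty subgroup: ",
         paste(tax$sequence_id[!pro & !is.na(tax$subgroup) & tax$subgroup != ""],
               collapse = ", "))
  tax$subgroup[is.na(tax$subgroup)] <- ""
  tax[c("sequence_id", "species", "phylum", "subgroup")]
}

#' Read a taxonomy table
#'
#' A taxonomy table maps every sequence ID to its species, phylum (from
#' [phylum_vocabulary()]) and, for prokaryotes, a subgroup such as
#' "Proteobacteria". It is the unit of all phylum-level logic; sequence IDs
#' carry no embedded taxonomy themselves.
#'
#' @param path TSV file with header columns `sequence_id`, `species`,
#'   `phylum`, `subgroup`.
#' @return A data.frame of validated records.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE, na.strings = NULL)
  validate_taxonomy(tax)
}

#' Write a taxonomy table
#'
#' @param tax Taxonomy data.frame as returned by [read_taxonomy()].
#' @param path Output TSV path.
#' @export
write_taxonomy <- function(tax, path) {
  tax <- validate_taxonomy(tax)
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up phylum labels for sequence IDs
#'
#' @param ids Character vector of sequence IDs.
#' @param taxonomy Taxonomy data.frame.
#' @return Character vector of phylum labels, same length as `ids`.
#' @export
taxon_phylum <- function(ids, taxonomy) {
  idx <- match(ids, taxonomy$sequence_id)
  if (anyNA(idx))
    stop("sequence ID(s) absent from taxonomy: ",
         paste(ids[is.na(idx)], collapse = ", "))
  taxonomy$phylum[idx]
}

#' Read a bootstrap-annotated tree
#'
#' Reads a Newick tree in the convention where nonparametric bootstrap
#' supports are stored as integer internal-node labels (0--100), i.e. the
#' usual RAxML/PhyML output dialect. Absent labels become missing support,
#' which never satisfies a support threshold. Other label dialects are
#' rejected rather than guessed at.
#'
#' @param path Newick file containing one tree.
#' @return An `ape::phylo` object whose `node.label` holds the supports
#'   (empty string = missing).
#' @export
read_support_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick in '", path, "': ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in '", path, "': no tree parsed")
  validate_support_tree(tree)
}

validate_support_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$node.label)) {
    tree$node.label <- rep("", tree$Nnode)
  } else {
    lab <- tree$node.label
    lab[is.na(lab)] <- ""
    nonempty <- lab != "" & lab != "Root"
    val <- suppressWarnings(as.numeric(lab[nonempty]))
    if (anyNA(val) || any(val != floor(val)))
      stop("internal node labels must be integer bootstrap supports; offending: ",
           paste(lab[nonempty][is.na(val) | val != floor(val)], collapse = ", "))
    if (any(val < 0 | val > 100))
      stop("bootstrap support outside [0,100]: ",
           paste(val[val < 0 | val > 100], collapse = ", "))
    lab[lab == "Root"] <- ""
    tree$node.label <- lab
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree
}

#' Write a bootstrap-annotated tree
#'
#' @param tree An `ape::phylo` with supports in `node.label`.
#' @param path Output Newick path.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Extract supports as integers
#'
#' @param tree A support tree.
#' @return Integer vector over internal nodes; `NA` = missing support.
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_integer_, tree$Nnode))
  # non-numeric labels (e.g. the "Root" tag added by rooting) read as missing
  suppressWarnings(as.integer(tree$node.label))
}

#' Check that every leaf resolves against a taxonomy table
#'
#' @param tree A support tree.
#' @param taxonomy Taxonomy data.frame.
#' @return The tree, invisibly; errors listing unresolvable leaves otherwise.
#' @export
validate_tree_taxa <- function(tree, taxonomy) {
  missing <- setdiff(tree$tip.label, taxonomy$sequence_id)
  if (length(missing))
    stop("tree leaves absent from taxonomy: ", paste(missing, collapse = ", "))
  invisible(tree)
}

blast_columns <- c("query_id", "subject_id", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "e_value", "bitscore")

#' Read a 12-column BLAST tabular hit table
#'
#' Standard `-outfmt 6` layout (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore). Rows above the
#' e-value inclusion threshold are dropped; the default threshold (1e-10)
#' is the homolog-inclusion cutoff of the screen.
#'
#' @param path TSV path.
#' @param e_max Maximum e-value retained (default `1e-10`).
#' @return data.frame with columns `query_id`, `subject_id`, `e_value`,
#'   `bitscore` (one row per HSP; see [collapse_best_pairs()]).
#' @export
read_hit_table <- function(path, e_max = 1e-10) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns; line(s) ",
         paste(which(nf != 12L), collapse = ", "), " have ",
         paste(unique(nf[nf != 12L]), collapse = "/"))
  m <- do.call(rbind, fields)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     e_value = as.numeric(m[, 11]),
                     bitscore = as.numeric(m[, 12]),
                     stringsAsFactors = FALSE)
  if (any(hits$e_value < 0)) stop("negative e-value in hit table")
  hits[hits$e_value <= e_max, , drop = FALSE]
}

#' Write a hit table in 12-column BLAST tabular layout
#'
#' Alignment-coordinate columns not tracked internally are written as zeros.
#'
#' @param hits data.frame with `query_id`, `subject_id`, `e_value`, `bitscore`.
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  out <- data.frame(hits$query_id, hits$subject_id, 0, 0, 0, 0, 0, 0, 0, 0,
                    format(hits$e_value, digits = 6),
                    format(hits$bitscore, digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse repeated query/subject pairs to their best hit
#'
#' BLAST reports one row per HSP; consumers of the table use the minimum
#' e-value and maximum bitscore per (query, subject) pair.
#'
#' @param hits data.frame from [read_hit_table()].
#' @return One row per pair, best e-value and bitscore.
#' @export
collapse_best_pairs <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  e <- tapply(hits$e_value, key, min)
  b <- tapply(hits$bitscore, key, max)
  ks <- strsplit(names(e), "\r", fixed = TRUE)
  out <- data.frame(query_id = vapply(ks, `[`, "", 1L),
                    subject_id = vapply(ks, `[`, "", 2L),
                    e_value = as.numeric(e), bitscore = as.numeric(b),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' Read a protein alignment from FASTA
#'
#' @param path FASTA file of equal-length aligned sequences; gap character
#'   "-", residues case-insensitive.
#' @return Character matrix, rows named by sequence ID, one column per site.
#' @export
read_alignment <- function(path) {
  aa <- ape::read.FASTA(path, type = "AA")
  lens <- lengths(aa)
  if (length(unique(lens)) != 1L)
    stop("alignment rows differ in length: ", paste(unique(lens), collapse = ", "))
  if (anyDuplicated(names(aa)))
    stop("duplicate sequence IDs in alignment")
  m <- toupper(as.character(as.matrix(aa)))
  rownames(m) <- names(aa)
  m
}

#' Write a protein alignment to FASTA
#'
#' @param alignment Character matrix as returned by [read_alignment()].
#' @param path Output path.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(paste0(">", rownames(alignment)[i]), con)
    writeLines(paste(alignment[i, ], collapse = ""), con)
  }
  invisible(path)
}
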