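#' Round half away from zero
#'
#' The rounding convention used for every printed percentage: 0.05 at the
#' last kept digit rounds up in magnitude (unlike base R's banker's
#' rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places kept (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator, one-decimal
#'
#' @param count,denominator Nonnegative count and positive denominator.
#' @return `round_half_away(100 * count / denominator, 1)`.
#' @export
percentage <- function(count, denominator) {
  if (any(denominator < 1)) stop("denominator must be >= 1")
  round_half_away(100 * count / denominator, 1L)
}

#' Summarise origin calls into category counts and percentages
#'
#' @param calls List of `origin_call` objects (or data.frame with a
#'   `category` column).
#' @param denominator Denominator for percentages, typically the number of
#'   screen-eligible trees.
#' @return list of class `origin_summary`: `n_calls`, `denominator`,
#'   `counts` (named integer), `percentages` (named numeric, one decimal).
#' @export
summarize_origins <- function(calls, denominator) {
  if (denominator < 1) stop("denominator must be >= 1")
  cats <- if (is.data.frame(calls)) calls$category
          else vapply(calls, function(x) x$category, "")
  counts <- table(cats)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(n_calls = length(cats), denominator = denominator,
                 counts = counts,
                 percentages = percentage(counts, denominator)),
            class = "origin_summary")
}

#' @export
print.origin_summary <- function(x, ...) {
  cat("origin calls over", x$denominator, "trees:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %4d (%.1f%%)\n", nm, x$counts[[nm]],
                x$percentages[[nm]]))
  invisible(x)
}

#' Summarise topology-test results into evidence tiers
#'
#' `ml_better` counts trees where the inferred tree fits better than the
#' null (positive log-likelihood difference; exact ties count as `ml_better`
#' but are flagged), `null_better` the rest; `rejected_all_four` counts trees
#' where all four tests reject the null at the 0.05 level, `rejected_some`
#' trees rejected by at least one test but not all four.
#'
#' @param results List of `topo_test` objects.
#' @param p_max Rejection level (default 0.05).
#' @return list of class `topo_summary` with counts, `n_ties`, and
#'   one-decimal `percentages` over the tested count.
#' @export
summarize_topology_tests <- function(results, p_max = 0.05) {
  delta <- vapply(results, function(x) x$delta_logL, 0)
  all4 <- vapply(results, function(x) isTRUE(x$rejected_all_four), TRUE)
  any1 <- vapply(results, function(x) {
    x$p_kh_one_sided <= p_max || x$p_kh_two_sided <= p_max ||
      x$p_sh <= p_max || x$elw_weight_null < p_max
  }, TRUE)
  n <- length(results)
  counts <- c(ml_better = sum(delta >= 0), null_better = sum(delta < 0),
              rejected_all_four = sum(all4),
              rejected_some = sum(any1 & !all4))
  structure(list(n_tested = n, counts = counts, n_ties = sum(delta == 0),
                 percentages = percentage(counts, max(n, 1L))),
            class = "topo_summary")
}

#' @export
print.topo_summary <- function(x, ...) {
  cat("topology tests over", x$n_tested, "trees:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-18s %4d (%.1f%%)\n", nm, x$counts[[nm]],
                x$percentages[[nm]]))
  if (x$n_ties) cat("  (", x$n_ties, "exact ties counted as ml_better )\n")
  invisible(x)
}

#' Cross-tabulate exclusive associations by partner and breadth threshold
#'
#' @param cohort data.frame from [exclusive_cohort()].
#' @return data.frame: one row per partner phylum, counts at x >= 2, 10, 20.
#' @export
x_threshold_distribution <- function(cohort) {
  ex <- cohort[cohort$partner_phylum != "none", , drop = FALSE]
  partners <- sort(unique(ex$partner_phylum))
  out <- data.frame(
    partner_phylum = partners,
    x2 = vapply(partners, function(p) sum(ex$x2[ex$partner_phylum == p]), 0L),
    x10 = vapply(partners, function(p) sum(ex$x10[ex$partner_phylum == p]), 0L),
    x20 = vapply(partners, function(p) sum(ex$x20[ex$partner_phylum == p]), 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the screening pipeline over a directory of trees
#'
#' Reads a taxonomy table and every Newick tree in a directory, applies
#' eligibility filtering, outgroup rooting, the supported-clade scan and
#' origin classification, pools trees into overlap clusters, and writes
#' clade hits, origin calls, cluster membership and a text summary (plus a
#' manifest of thresholds) into a new output directory. Rerunning with the
#' same inputs produces an identical report body.
#'
#' @param trees_dir Directory of `.nwk`/`.tree`/`.newick` files.
#' @param taxonomy_path Taxonomy TSV.
#' @param out_dir Output directory (must not exist; created).
#' @param target_rank,support_min,min_each,max_interrupt,min_phyla,min_taxa,min_overlap
#'   Screen thresholds with their standard defaults.
#' @return list with the origin calls, summary, clusters and output paths.
#' @export
run_pipeline <- function(trees_dir, taxonomy_path, out_dir,
                         target_rank = "Diatom", support_min = 70L,
                         min_each = 2L, max_interrupt = 0.30,
                         min_phyla = 3L, min_taxa = 30L, min_overlap = 3L) {
  if (!dir.exists(trees_dir)) stop("missing tree directory: ", trees_dir)
  if (!file.exists(taxonomy_path)) stop("missing taxonomy: ", taxonomy_path)
  files <- list.files(trees_dir, pattern = "\\.(nwk|tree|newick)$",
                      full.names = TRUE)
  if (!length(files)) stop("no Newick files in ", trees_dir)
  if (dir.exists(out_dir)) stop("output directory already exists: ", out_dir)
  dir.create(out_dir, recursive = TRUE)
  taxonomy <- read_taxonomy(taxonomy_path)

  calls <- list(); hit_rows <- list(); leaf_sets <- list()
  n_eligible <- 0L
  for (f in files) {
    id <- sub("\\.[^.]*$", "", basename(f))
    tree <- read_support_tree(f)
    validate_tree_taxa(tree, taxonomy)
    elig <- tree_eligible(tree, taxonomy, min_phyla, min_taxa)
    if (!elig$eligible) next
    n_eligible <- n_eligible + 1L
    rooted <- root_tree(tree, taxonomy)
    hits <- scan_clades(rooted$tree, taxonomy, target_rank, support_min,
                        min_each, max_interrupt)
    call <- classify_origin(id, hits, rooted$outgroup_used)
    calls[[id]] <- call
    leaf_sets[[id]] <- tree$tip.label
    if (nrow(hits)) hit_rows[[id]] <- cbind(tree_id = id, hits)
  }
  if (!length(calls)) stop("no eligible trees")

  clusters <- cluster_trees(leaf_sets, min_overlap)
  summary <- summarize_origins(calls, n_eligible)
  call_df <- do.call(rbind, lapply(calls, function(x)
    data.frame(tree_id = x$tree_id, category = x$category,
               other_phylum = ifelse(is.na(x$other_phylum), "",
                                     x$other_phylum),
               outgroup_used = x$outgroup_used, n_hits = nrow(x$hits),
               stringsAsFactors = FALSE)))
  hits_df <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(tree_id = character())

  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(origin_calls = wt(call_df, "origin_calls.tsv"),
             clade_hits = wt(hits_df, "clade_hits.tsv"),
             clusters = wt(clusters, "clusters.tsv"))
  manifest <- c(sprintf("n_input\t%d", length(files)),
                sprintf("n_eligible\t%d", n_eligible),
                sprintf("target_rank\t%s", target_rank),
                sprintf("support_min\t%d", support_min),
                sprintf("min_each\t%d", min_each),
                sprintf("max_interrupt\t%g", max_interrupt),
                sprintf("min_phyla\t%d", min_phyla),
                sprintf("min_taxa\t%d", min_taxa),
                sprintf("min_overlap\t%d", min_overlap))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  sink(file.path(out_dir, "summary.txt")); print(summary); sink()

  list(calls = calls, summary = summary, clusters = clusters,
       n_input = length(files), n_eligible = n_eligible, paths = paths)
}
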