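#!/usr/bin/env Rscript
# For every simulated family whose screen found a supported stramenopile +
# red/green clade, builds the constrained null topology (algae moved outside
# the stramenopiles), re-optimises branch lengths under WAG+Gamma, and runs
# the one-sided KH, two-sided KH, SH and ELW tests on RELL replicates.

suppressMessages(library(phylograft))

seed <- 20260921L
in_dir <- "results/synthetic"
out_dir <- "results/topology_tests"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

taxonomy <- read_taxonomy(file.path(in_dir, "taxonomy.tsv"))
tree_files <- list.files(file.path(in_dir, "trees"), pattern = "\\.nwk$",
                         full.names = TRUE)

rows <- list(); results <- list()
for (f in tree_files) {
  id <- sub("\\.nwk$", "", basename(f))
  tree <- read_support_tree(f)
  rooted <- root_tree(tree, taxonomy)
  hits <- scan_clades(rooted$tree, taxonomy, "Stramenopiles")
  alg <- hits[hits$partner_phylum %in% c("Rhodophyta", "Viridiplantae",
                                         "Plantae-both"), , drop = FALSE]
  if (!nrow(alg)) next
  aln <- read_alignment(file.path(in_dir, "alignments",
                                  paste0(id, ".fasta")))
  # each flagged clade is tested separately
  for (k in seq_len(nrow(alg))) {
    anchor <- strsplit(alg$leaves[k], "|", fixed = TRUE)[[1]]
    pair <- tryCatch(make_null_topology(rooted$tree, taxonomy, anchor),
                     error = function(e) NULL)
    if (is.null(pair)) next
    res <- topology_test(aln, pair, wag_model(), n_rell = 1000L,
                         seed = seed + length(results))
    results[[length(results) + 1L]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      tree_id = id, partner = alg$partner_phylum[k],
      delta_logL = res$delta_logL,
      p_kh_one_sided = res$p_kh_one_sided,
      p_kh_two_sided = res$p_kh_two_sided, p_sh = res$p_sh,
      elw_weight_null = res$elw_weight_null,
      rejected_all_four = res$rejected_all_four,
      stringsAsFactors = FALSE)
  }
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out_dir, "topology_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summarize_topology_tests(results))
cat("tested", nrow(tab), "flagged clades;",
    sum(tab$rejected_all_four), "rejected by all four tests\n")
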