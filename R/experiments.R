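# Validation experiments: calibration of the topology tests under a true
# null, their power under a planted transfer, and end-to-end recovery of
# planted histories by the screen. These back both the test suite and the
# numbered analysis drivers.

#' A small fixed transfer scenario for topology-test experiments
#'
#' A nine-leaf family (two prokaryote outgroups, four stramenopiles of which
#' two are diatoms, three green algae) in which the green algal clade is
#' nested inside the stramenopiles on a stalk of length `stalk` — the
#' alternative (transfer) topology — together with the taxonomy and the
#' constrained null derived by [make_null_topology()].
#'
#' @param stalk Length of the green clade's subtending branch (default 0.2).
#' @param edge Backbone edge length (default 0.15).
#' @return list: `pair` (a `topology_pair`), `taxonomy`, `anchor`.
#' @export
transfer_scenario <- function(stalk = 0.2, edge = 0.15) {
  e <- format(edge, digits = 6)
  nwk <- sprintf(
    paste0("((P1:%s,P2:%s):%s,((S1:%s,S2:%s):%s,((G1:%s,(G2:%s,G3:%s):%s):%s,",
           "(S3:%s,S4:%s):%s):%s):%s);"),
    e, e, e, e, e, e, e, e, e, e, format(stalk, digits = 6), e, e, e, e, e)
  ml_tree <- ape::read.tree(text = nwk)
  taxonomy <- data.frame(
    sequence_id = c("P1", "P2", "S1", "S2", "S3", "S4", "G1", "G2", "G3"),
    species = c("P1", "P2", "S1", "S2", "S3", "S4", "G1", "G2", "G3"),
    phylum = c("Prokaryote", "Prokaryote", "Diatom", "Diatom",
               "StramenopileOther", "StramenopileOther",
               "Viridiplantae", "Viridiplantae", "Viridiplantae"),
    subgroup = c("Proteobacteria", "Actinobacteria", rep("", 7)),
    stringsAsFactors = FALSE)
  anchor <- c("S1", "S2", "S3", "S4", "G1", "G2", "G3")
  pair <- make_null_topology(ml_tree, taxonomy, anchor)
  list(pair = pair, taxonomy = taxonomy, anchor = anchor)
}

run_one_test <- function(generating_tree, pair, model, n_sites, n_rell,
                         seed_i) {
  aln <- simulate_alignment(generating_tree, model, n_sites, seed = seed_i)
  topology_test(aln, pair, model, n_rell = n_rell, seed = seed_i,
                bl_rounds = 2L)
}

#' Type-I error of the topology tests under a true null
#'
#' Simulates alignments on the null topology (stramenopiles monophyletic,
#' greens outside) and runs the full comparison machinery against the
#' transfer topology; the empirical rejection rate of each test at the 0.05
#' level estimates its type-I error under the screen's own conditions.
#'
#' @param n_sim Number of simulated datasets (default 100).
#' @param n_sites Sites per alignment (default 300).
#' @param seed Base seed; dataset i uses `seed + i`.
#' @param n_rell RELL replicates per test (default 1000).
#' @param alpha Gamma shape of the generating model (default 0.8).
#' @return list: `results` data.frame (one row per dataset) and `rates`
#'   (named rejection rates).
#' @export
kh_null_calibration <- function(n_sim = 100L, n_sites = 300L, seed = 1L,
                                n_rell = 1000L, alpha = 0.8) {
  sc <- transfer_scenario()
  model <- wag_model(alpha = alpha)
  rows <- lapply(seq_len(n_sim), function(i) {
    res <- run_one_test(sc$pair$null_tree, sc$pair, model, n_sites, n_rell,
                        seed + i)
    data.frame(sim = i, delta_logL = res$delta_logL,
               p_kh_one_sided = res$p_kh_one_sided,
               p_kh_two_sided = res$p_kh_two_sided, p_sh = res$p_sh,
               elw_weight_null = res$elw_weight_null,
               rejected_all_four = res$rejected_all_four)
  })
  results <- do.call(rbind, rows)
  rates <- c(kh_one_sided = mean(results$p_kh_one_sided <= 0.05),
             kh_two_sided = mean(results$p_kh_two_sided <= 0.05),
             sh = mean(results$p_sh <= 0.05),
             elw = mean(results$elw_weight_null < 0.05),
             all_four = mean(results$rejected_all_four))
  list(results = results, rates = rates)
}

#' Power of the topology tests against site count
#'
#' Simulates alignments on the transfer topology (alternative true) and
#' records each test's rejection rate at every requested alignment length;
#' with a graft stalk this long the rejection rate should grow with the
#' number of sites.
#'
#' @param site_counts Alignment lengths (default 100, 300, 1000).
#' @param n_sim Datasets per length (default 25).
#' @param seed Base seed.
#' @param n_rell RELL replicates (default 1000).
#' @param stalk Graft branch length of the scenario (default 0.2).
#' @param alpha Gamma shape (default 0.8).
#' @return data.frame: one row per site count with per-test rejection rates.
#' @export
kh_power_curve <- function(site_counts = c(100L, 300L, 1000L), n_sim = 25L,
                           seed = 1L, n_rell = 1000L, stalk = 0.2,
                           alpha = 0.8) {
  sc <- transfer_scenario(stalk = stalk)
  model <- wag_model(alpha = alpha)
  rows <- lapply(seq_along(site_counts), function(j) {
    n_sites <- site_counts[j]
    res <- lapply(seq_len(n_sim), function(i)
      run_one_test(sc$pair$ml_tree, sc$pair, model, n_sites, n_rell,
                   seed + 1000L * j + i))
    data.frame(
      n_sites = n_sites,
      kh_one_sided = mean(vapply(res, function(x) x$p_kh_one_sided <= 0.05, TRUE)),
      kh_two_sided = mean(vapply(res, function(x) x$p_kh_two_sided <= 0.05, TRUE)),
      sh = mean(vapply(res, function(x) x$p_sh <= 0.05, TRUE)),
      elw = mean(vapply(res, function(x) x$elw_weight_null < 0.05, TRUE)),
      all_four = mean(vapply(res, function(x) x$rejected_all_four, TRUE)))
  })
  do.call(rbind, rows)
}

#' End-to-end recovery of planted gene histories
#'
#' For each history class, simulates gene families (tree, alignment,
#' distance+NJ bootstrap supports), runs the full screen (eligibility,
#' rooting, supported-clade scan, origin classification) and tabulates the
#' calls against the planted truth. The two headline metrics are the
#' per-class recovery accuracy for planted transfers and the false-transfer
#' rate (any red/green category) on vertical families.
#'
#' @param n_per_class Families per class (default 100).
#' @param classes Subset of `"vertical"`, `"green_hgt"`, `"red_hgt"`,
#'   `"red_plus_green_hgt"`.
#' @param n_sites Alignment length (default 500 — strong signal).
#' @param stalk Graft branch length (default 0.2).
#' @param n_bootstrap Bootstrap replicates for supports (default 100).
#' @param seed Base seed.
#' @param support_min,min_each,max_interrupt Screen thresholds (defaults).
#' @return list: `results` data.frame, `confusion` table
#'   (true history x called category), `accuracy` per transfer class,
#'   `false_transfer_rate` on vertical families (NA if absent).
#' @export
origin_recovery <- function(n_per_class = 100L,
                            classes = c("vertical", "green_hgt", "red_hgt"),
                            n_sites = 500L, stalk = 0.2, n_bootstrap = 100L,
                            seed = 1L, support_min = 70L, min_each = 2L,
                            max_interrupt = 0.30) {
  transfer_cats <- c("Green", "Red", "RedPlusGreen", "RedOrGreen")
  hgt_for <- function(class) switch(class,
    vertical = NULL,
    green_hgt = list(donor = "Viridiplantae", size = 4L, stalk = stalk),
    red_hgt = list(donor = "Rhodophyta", size = 4L, stalk = stalk),
    red_plus_green_hgt = list(donor = "both", size = 4L, stalk = stalk),
    stop("unknown class: ", class))
  rows <- list()
  for (ci in seq_along(classes)) {
    class <- classes[ci]
    for (i in seq_len(n_per_class)) {
      seed_i <- seed + 10000L * ci + i
      cfg <- sim_config(hgt = hgt_for(class), n_sites = n_sites,
                        n_bootstrap = n_bootstrap, seed = seed_i)
      sim <- simulate_gene_tree(cfg)
      model <- wag_model(alpha = cfg$alpha, n_gamma = cfg$n_gamma)
      aln <- simulate_alignment(sim$tree, model, cfg$n_sites, seed = seed_i)
      tree <- attach_bootstrap_supports(sim$tree, aln, cfg$n_bootstrap,
                                        seed = seed_i)
      stopifnot(tree_eligible(tree, sim$taxonomy)$eligible)
      rooted <- root_tree(tree, sim$taxonomy)
      hits <- scan_clades(rooted$tree, sim$taxonomy, "Diatom", support_min,
                          min_each, max_interrupt)
      call <- classify_origin(paste0(class, "_", i), hits,
                              rooted$outgroup_used)
      rows[[length(rows) + 1L]] <- data.frame(
        true_history = class, expected = sim$truth$expected_category,
        called = call$category, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  confusion <- table(results$true_history, results$called)
  acc <- vapply(setdiff(classes, "vertical"), function(cl) {
    sel <- results$true_history == cl
    mean(results$called[sel] == results$expected[sel])
  }, 0)
  fpr <- if ("vertical" %in% classes) {
    sel <- results$true_history == "vertical"
    mean(results$called[sel] %in% transfer_cats)
  } else NA_real_
  list(results = results, confusion = confusion, accuracy = acc,
       false_transfer_rate = fpr)
}
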