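#' Build the constrained null topology for a stramenopile/Plantae clade
#'
#' The null hypothesis of vertical descent requires the stramenopiles of a
#' flagged clade to form a group uninterrupted by red/green algae. It is built
#' from the inferred tree by a prune-and-regraft: every Rhodophyta and
#' Viridiplantae leaf inside the anchor clade is pruned (degree-2 nodes
#' suppressed, merged branch lengths summed), their induced subtree is kept
#' intact, and that subtree is re-attached as the single sister group of the
#' now algae-free remainder of the anchor clade. The attachment point splits
#' the clade's subtending branch 50/50, and the regrafted stalk carries the
#' other half. No other branching position changes: every bipartition of the
#' inferred tree not involving the moved leaves is present in the null tree.
#' Supports on unaffected edges are preserved; new edges carry missing
#' support.
#'
#' @param ml_tree The inferred ("best") tree.
#' @param taxonomy Taxonomy data.frame.
#' @param anchor_leaves Character vector: the leaves of the flagged clade
#'   (a clade of `ml_tree` uniting stramenopiles with Plantae).
#' @return list of class `topology_pair`: `ml_tree`, `null_tree`,
#'   `moved_leaves`, `anchor_clade`.
#' @export
make_null_topology <- function(ml_tree, taxonomy, anchor_leaves) {
  validate_tree_taxa(ml_tree, taxonomy)
  stopifnot(all(anchor_leaves %in% ml_tree$tip.label))
  ph <- stats::setNames(taxon_phylum(ml_tree$tip.label, taxonomy),
                        ml_tree$tip.label)
  moved <- anchor_leaves[ph[anchor_leaves] %in% c("Rhodophyta", "Viridiplantae")]
  if (!length(moved)) stop("anchor clade contains no red/green algal leaves")
  remaining <- setdiff(anchor_leaves, moved)
  if (!length(remaining)) stop("pruning the algal leaves would empty the clade")

  donor <- if (length(moved) > 1L) {
    ape::keep.tip(ml_tree, moved)
  } else {
    # single leaf: a one-tip "subtree"
    structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = moved,
                   edge.length = 0.05, Nnode = 1L), class = "phylo")
  }
  reduced <- ape::drop.tip(ml_tree, moved, collapse.singles = TRUE)

  # locate the remaining anchor clade in the reduced tree
  n_tip <- length(reduced$tip.label)
  if (length(remaining) == 1L) {
    where <- match(remaining, reduced$tip.label)
  } else {
    where <- ape::getMRCA(reduced, remaining)
    sets <- clade_leafsets(reduced)
    if (!setequal(sets[[where - n_tip]], remaining))
      stop("remaining anchor leaves do not form a clade after pruning")
  }
  edge_idx <- which(reduced$edge[, 2] == where)
  if (length(edge_idx)) {
    stalk <- reduced$edge.length[edge_idx] / 2
    reduced$edge.length[edge_idx] <- stalk
    donor$root.edge <- stalk
    null_tree <- ape::bind.tree(reduced, donor, where = where,
                                position = stalk)
  } else {
    # the remaining clade is the whole reduced tree: the null is simply the
    # two groups as sisters at the root
    s1 <- sub(";$", "", ape::write.tree(reduced))
    s2 <- if (length(moved) > 1L) sub(";$", "", ape::write.tree(donor))
          else paste0(moved, ":0.05")
    null_tree <- ape::read.tree(text = paste0("(", s1, ":0,", s2, ":0);"))
  }
  null_tree <- validate_support_tree(null_tree)

  structure(list(ml_tree = ml_tree, null_tree = null_tree,
                 moved_leaves = moved, anchor_clade = anchor_leaves),
            class = "topology_pair")
}

#' RELL resampling of site log-likelihoods
#'
#' Resampling estimated log-likelihoods: each replicate draws `n_sites` site
#' indices with replacement and sums the per-site log-likelihoods of every
#' topology over the drawn sites — the bootstrap machinery behind the KH, SH
#' and ELW tests, without re-optimising anything. Fixed seed makes the
#' replicate totals bit-reproducible.
#'
#' @param sitelik Numeric matrix, one row per site, one column per topology.
#' @param n_rep Number of replicates (default 1000).
#' @param seed Integer seed (mandatory).
#' @return `n_rep` x `n_topologies` matrix of replicate total log-likelihoods.
#' @export
rell_resample <- function(sitelik, n_rep = 1000L, seed) {
  sitelik <- as.matrix(sitelik)
  if (n_rep < 1L) stop("n_rep must be >= 1")
  if (ncol(sitelik) < 2L) stop("need at least 2 topologies")
  if (nrow(sitelik) < 1L) stop("need at least 1 site")
  stopifnot(!missing(seed))
  set.seed(seed)
  S <- nrow(sitelik)
  out <- matrix(0, n_rep, ncol(sitelik), dimnames = list(NULL, colnames(sitelik)))
  for (r in seq_len(n_rep)) {
    idx <- sample.int(S, S, replace = TRUE)
    out[r, ] <- colSums(sitelik[idx, , drop = FALSE])
  }
  out
}

#' KH, SH and ELW topology tests on RELL replicates
#'
#' Compares an alternative (inferred) topology with a constrained null
#' topology: the two-sided KH p-value is the fraction of centred replicate
#' log-likelihood differences at least as extreme as the observed difference;
#' the one-sided KH p-value counts only the upper tail (the a-priori
#' direction); the SH test centres each topology's replicates separately and
#' uses the max statistic over the set; the expected likelihood weight of a
#' topology is its replicate-averaged normalised likelihood weight, and the
#' null is outside the 0.95 confidence set when its weight falls below 0.05.
#'
#' @param rell_totals Matrix from [rell_resample()], columns ordered
#'   (alternative, null).
#' @param observed Length-2 vector of observed total log-likelihoods
#'   (alternative, null).
#' @param p_max Rejection level (default 0.05).
#' @return list of class `topo_test`: `delta_logL` (alternative minus null),
#'   `p_kh_one_sided`, `p_kh_two_sided`, `p_sh`, `elw_weight_null`,
#'   `n_rell`, `rejected_all_four`, `zero_variance`.
#' @export
kh_sh_elw <- function(rell_totals, observed, p_max = 0.05) {
  stopifnot(ncol(rell_totals) == 2L, length(observed) == 2L)
  delta_obs <- observed[1] - observed[2]
  rep_delta <- rell_totals[, 1] - rell_totals[, 2]
  centred <- rep_delta - mean(rep_delta)

  zero_var <- FALSE
  if (all(centred == 0) && delta_obs != 0) {
    warning("zero-variance RELL replicates with nonzero observed difference")
    zero_var <- TRUE
    p_two <- 0; p_one <- 0
  } else {
    p_two <- mean(abs(centred) >= abs(delta_obs))
    p_one <- mean(centred >= delta_obs)
  }

  # SH: per-topology centring, max statistic; p for the null topology
  c1 <- rell_totals[, 1] - mean(rell_totals[, 1])
  c2 <- rell_totals[, 2] - mean(rell_totals[, 2])
  obs_stat_null <- max(observed) - observed[2]
  p_sh <- mean((pmax(c1, c2) - c2) >= obs_stat_null)

  shifted <- rell_totals - apply(rell_totals, 1, max)
  w <- exp(shifted)
  w <- w / rowSums(w)
  elw <- colMeans(w)
  elw_null <- elw[2]

  rejected <- !zero_var && p_one <= p_max && p_two <= p_max &&
    p_sh <= p_max && elw_null < p_max
  if (zero_var) rejected <- delta_obs > 0 && elw_null < p_max && p_sh <= p_max

  structure(list(delta_logL = as.numeric(delta_obs),
                 p_kh_one_sided = as.numeric(p_one),
                 p_kh_two_sided = as.numeric(p_two),
                 p_sh = as.numeric(p_sh),
                 elw_weight_null = as.numeric(elw_null),
                 n_rell = nrow(rell_totals),
                 rejected_all_four = rejected,
                 zero_variance = zero_var),
            class = "topo_test")
}

#' @export
print.topo_test <- function(x, ...) {
  cat(sprintf(paste0("topology test: delta lnL = %.3f | one-sided KH p = %.4g",
                     " | two-sided KH p = %.4g | SH p = %.4g | ELW(null) = %.4g",
                     " | reject all four: %s\n"),
              x$delta_logL, x$p_kh_one_sided, x$p_kh_two_sided, x$p_sh,
              x$elw_weight_null, x$rejected_all_four))
  invisible(x)
}

#' Full topology comparison of an alternative vs a null tree
#'
#' Convenience wrapper running the whole comparison for one alignment: the
#' gamma shape is estimated on the alternative topology and reused for the
#' null (so the two site-likelihood vectors differ only by topology and
#' branch lengths), branch lengths are re-optimised on both topologies, and
#' the four tests are computed on RELL replicates.
#'
#' @param alignment Character matrix over the trees' shared leaves.
#' @param pair A `topology_pair` from [make_null_topology()] (or any list
#'   with `ml_tree` and `null_tree`).
#' @param model A [wag_model()] (its alpha is the starting value).
#' @param n_rell RELL replicates (default 1000).
#' @param seed Integer seed (mandatory).
#' @param optimize_shape Estimate alpha on the alternative topology (default
#'   TRUE).
#' @param bl_rounds Branch-length sweeps per topology (default 3).
#' @return A `topo_test` with the fitted trees in attributes `"ml_fit"`,
#'   `"null_fit"` and the site matrix in `"sitelik"`.
#' @export
topology_test <- function(alignment, pair, model = wag_model(), n_rell = 1000L,
                          seed, optimize_shape = TRUE, bl_rounds = 3L) {
  stopifnot(!missing(seed))
  ml_fit <- optimize_branch_lengths(alignment, pair$ml_tree, model,
                                    max_rounds = 1L, tol = 1e-4)
  if (optimize_shape && model$n_gamma > 1L)
    model <- optimize_alpha(alignment, ml_fit, model)
  ml_fit <- optimize_branch_lengths(alignment, ml_fit, model,
                                    max_rounds = bl_rounds, tol = 1e-4)
  null_fit <- optimize_branch_lengths(alignment, pair$null_tree, model,
                                      max_rounds = bl_rounds, tol = 1e-4)
  sitelik <- cbind(ml = site_log_likelihoods(alignment, ml_fit, model),
                   null = site_log_likelihoods(alignment, null_fit, model))
  totals <- colSums(sitelik)
  rell <- rell_resample(sitelik, n_rep = n_rell, seed = seed)
  res <- kh_sh_elw(rell, totals)
  attr(res, "ml_fit") <- ml_fit
  attr(res, "null_fit") <- null_fit
  attr(res, "sitelik") <- sitelik
  attr(res, "alpha_used") <- model$alpha
  res
}
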