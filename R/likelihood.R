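#' Per-site log-likelihoods of an alignment on a fixed tree
#'
#' Felsenstein pruning under the model's discrete-gamma mixture (equal-weight
#' categories, mean-of-bin rates). Gaps and ambiguity codes contribute a
#' partial likelihood of 1 over all states. The tree's branch lengths are
#' taken as given; by reversibility the result does not depend on where the
#' (un)rooted tree is rooted.
#'
#' @param alignment Character matrix; row names must equal the tree's leaves.
#' @param tree `ape::phylo` with branch lengths.
#' @param model A [wag_model()].
#' @return Numeric vector of natural-log site likelihoods (length =
#'   number of columns).
#' @export
site_log_likelihoods <- function(alignment, tree, model) {
  sym <- c(setdiff(rownames(alignment), tree$tip.label),
           setdiff(tree$tip.label, rownames(alignment)))
  if (length(sym))
    stop("alignment/tree leaf mismatch: ", paste(sym, collapse = ", "))
  prep <- likelihood_prep(alignment, tree, model)
  as.numeric(pattern_loglik(prep, prep$lengths))[prep$index]
}

# Shared setup: postorder edges, encoded tips in tree order, eigendecomposition.
# Duplicate site patterns are collapsed with weights; `index` maps original
# sites back to patterns.
likelihood_prep <- function(alignment, tree, model) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  states <- encode_alignment(alignment)
  states <- states[match(tree$tip.label, rownames(states)), , drop = FALSE]
  pat_key <- apply(states, 2, paste, collapse = ",")
  uniq <- !duplicated(pat_key)
  index <- match(pat_key, pat_key[uniq])
  list(edge = matrix(as.integer(tree$edge), ncol = 2),
       n_tip = length(tree$tip.label),
       tip_states = states[, uniq, drop = FALSE],
       weights = as.numeric(tabulate(index, nbins = sum(uniq))),
       index = index,
       lengths = tree$edge.length,
       eig = model_eigen(model),
       rates = discrete_gamma_rates(model$alpha, model$n_gamma),
       tree = tree)
}

pattern_loglik <- function(prep, lengths) {
  pruning_sitelik_cpp(prep$edge, prep$n_tip, prep$tip_states, lengths,
                      prep$eig$values, prep$eig$A, prep$eig$B,
                      prep$eig$pi, prep$rates)
}

total_loglik_at <- function(prep, lengths) {
  sum(prep$weights * pattern_loglik(prep, lengths))
}

#' Write per-site log-likelihoods for one or more topologies
#'
#' One row per site, one column per topology — the layout classic topology-
#' test tools exchange, so third-party implementations can be cross-checked
#' on the same numbers.
#'
#' @param sitelik Numeric vector or matrix (sites x topologies).
#' @param path Output TSV path.
#' @export
write_site_loglik <- function(sitelik, path) {
  m <- as.matrix(sitelik)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("topology", seq_len(ncol(m)))
  out <- data.frame(site = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Optimise branch lengths on a fixed topology
#'
#' Coordinate-wise scalar maximisation of the total log-likelihood. Each
#' sweep computes the rootward and tipward partial likelihoods once and
#' optimises every branch on its local edge profile (bounded golden-section
#' in `[min_len, max_len]`); the exact pruning total then verifies the
#' sweep, and any sweep that fails to improve it falls back to one
#' branch-at-a-time Brent pass against the full likelihood, so the total is
#' non-decreasing across rounds. Sweeps repeat until a round improves the
#' total by less than `tol` or `max_rounds` is reached.
#'
#' @param alignment Character matrix matching the tree's leaves.
#' @param tree Topology; absent branch lengths start at 0.1.
#' @param model A [wag_model()].
#' @param tol Convergence tolerance on the total log-likelihood (1e-6).
#' @param max_rounds Maximum optimisation sweeps (50).
#' @param min_len,max_len Branch-length bounds (1e-8, 10).
#' @return The tree with optimised lengths; total log-likelihood in
#'   attribute `"loglik"`.
#' @export
optimize_branch_lengths <- function(alignment, tree, model, tol = 1e-6,
                                    max_rounds = 50L, min_len = 1e-8,
                                    max_len = 10) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length, min_len), max_len)
  prep <- likelihood_prep(alignment, tree, model)
  lengths <- prep$lengths
  total <- total_loglik_at(prep, lengths)
  if (!is.finite(total)) stop("non-finite initial likelihood")

  exact_pass <- function(lengths, total) {
    # guaranteed-monotone fallback: full-likelihood Brent per branch
    for (i in seq_along(lengths)) {
      f <- function(t) { l <- lengths; l[i] <- t; total_loglik_at(prep, l) }
      lo <- max(min_len, lengths[i] / 10)
      hi <- min(max_len, max(lengths[i] * 10, 0.5))
      opt <- stats::optimize(f, interval = c(lo, hi), maximum = TRUE,
                             tol = 1e-4)
      if (opt$maximum < lo * 1.05 || opt$maximum > hi * 0.98) {
        wide <- stats::optimize(f, interval = c(min_len, max_len),
                                maximum = TRUE, tol = 1e-4)
        if (wide$objective > opt$objective) opt <- wide
      }
      if (!is.finite(opt$objective))
        stop("non-finite likelihood while optimising branch ", i)
      if (opt$objective > total) {
        lengths[i] <- opt$maximum
        total <- opt$objective
      }
    }
    list(lengths = lengths, total = total)
  }

  for (round in seq_len(max_rounds)) {
    prev <- total
    cand <- as.numeric(sweep_branches_cpp(
      prep$edge, prep$n_tip, prep$tip_states, prep$weights, lengths,
      prep$eig$values, prep$eig$A, prep$eig$B, prep$eig$pi, prep$rates,
      min_len, max_len, 1e-4))
    cand_total <- total_loglik_at(prep, cand)
    if (is.finite(cand_total) && cand_total > total) {
      lengths <- cand
      total <- cand_total
    } else {
      res <- exact_pass(lengths, total)
      lengths <- res$lengths
      total <- res$total
    }
    if (total - prev < tol) break
  }
  out <- prep$tree
  out$edge.length <- lengths
  attr(out, "loglik") <- total
  out
}

#' Optimise the gamma shape parameter
#'
#' Golden-section/Brent maximisation of the total log-likelihood over the
#' gamma shape, branch lengths held fixed. With a single rate category the
#' shape is irrelevant and the input is returned unchanged.
#'
#' @param alignment Character matrix matching the tree's leaves.
#' @param tree Tree with branch lengths.
#' @param model A [wag_model()].
#' @param bounds Search interval for alpha (default `c(0.05, 20)`).
#' @return The model with optimised `alpha`.
#' @export
optimize_alpha <- function(alignment, tree, model, bounds = c(0.05, 20)) {
  if (bounds[1] >= bounds[2]) stop("inverted alpha bounds")
  if (model$n_gamma == 1L) return(model)
  opt <- stats::optimize(function(a) {
    m <- model; m$alpha <- a
    sum(site_log_likelihoods(alignment, tree, m))
  }, interval = bounds, maximum = TRUE, tol = 1e-3)
  model$alpha <- opt$maximum
  model
}
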