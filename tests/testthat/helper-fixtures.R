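# Fixture builders and independent oracles shared across the suite.

# random taxonomy over the full vocabulary
random_taxonomy <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- sample(phylum_vocabulary(), n, replace = TRUE)
  data.frame(sequence_id = sprintf("seq%03d", seq_len(n)),
             species = sprintf("sp%02d", sample.int(max(2L, n %/% 2), n,
                                                    replace = TRUE)),
             phylum = ph,
             subgroup = ifelse(ph == "Prokaryote",
                               sample(c("Proteobacteria", "Actinobacteria",
                                        "Firmicutes"), n, replace = TRUE),
                               ""),
             stringsAsFactors = FALSE)
}

# random phylum-labelled support tree + matching taxonomy
random_screen_tree <- function(n_leaves, phyla = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rtree(n_leaves)
  tree$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  tree$node.label <- c("", as.character(sample(0:100, tree$Nnode - 1L,
                                               replace = TRUE)))
  if (is.null(phyla))
    phyla <- sample(phylum_vocabulary(), n_leaves, replace = TRUE)
  tax <- data.frame(sequence_id = tree$tip.label,
                    species = tree$tip.label,
                    phylum = phyla,
                    subgroup = ifelse(phyla == "Prokaryote", "Proteobacteria",
                                      ""),
                    stringsAsFactors = FALSE)
  list(tree = tree, taxonomy = tax)
}

# random hit table over ids, with symmetric self-hits included
random_hit_table <- function(ids, density = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- expand.grid(query_id = ids, subject_id = ids,
                      stringsAsFactors = FALSE)
  keep <- rows$query_id == rows$subject_id |
    stats::runif(nrow(rows)) < density
  rows <- rows[keep, , drop = FALSE]
  rows$bitscore <- round(stats::runif(nrow(rows), 50, 500), 1)
  rows$e_value <- 10^(-rows$bitscore / 10)
  rows
}

# independent brute-force homolog-set oracle: explicit per-row hit lists,
# explicit pairwise intersection loop
oracle_homolog_set <- function(query_id, hits, top_n = 5L) {
  hits <- collapse_best_pairs(hits)
  listof <- function(id) {
    subj <- character(0)
    for (r in seq_len(nrow(hits)))
      if (hits$query_id[r] == id) subj <- c(subj, hits$subject_id[r])
    unique(c(id, subj))
  }
  qrows <- hits[hits$query_id == query_id & hits$subject_id != query_id, ]
  qrows <- qrows[order(qrows$e_value, -qrows$bitscore, qrows$subject_id), ]
  top <- utils::head(qrows$subject_id, top_n)
  members <- listof(query_id)
  for (id in top) {
    other <- listof(id)
    members <- members[vapply(members, function(m) m %in% other, TRUE)]
  }
  sort(unique(c(query_id, members)))
}

# exhaustive clade x partner enumeration oracle for scan_clades (rooted
# trees), using phangorn's descendant machinery for clade extraction
oracle_scan_clades <- function(tree, taxonomy, target_rank = "Diatom",
                               support_min = 70L, min_each = 2L,
                               max_interrupt = 0.30) {
  target <- expand_rank(target_rank)
  phy <- stats::setNames(taxon_phylum(tree$tip.label, taxonomy),
                         tree$tip.label)
  n_tip <- length(tree$tip.label)
  sup <- tree_supports(tree)
  desc <- phangorn::Descendants(tree, n_tip + seq_len(tree$Nnode), "tips")
  rows <- list()
  for (j in seq_along(desc)) {
    if (j == 1L) next  # root node: no subtending edge
    s <- sup[j]
    if (is.na(s) || s < support_min) next
    leaves <- sort(tree$tip.label[desc[[j]]])
    ph <- phy[leaves]
    nt <- sum(ph %in% target)
    if (nt < min_each) next
    n <- length(leaves)
    found <- list()
    for (p in setdiff(unique(ph), target)) {
      np <- sum(ph == p)
      if (np < min_each) next
      ni <- n - nt - np
      if (ni / n > max_interrupt) next
      found[[p]] <- c(np, ni)
    }
    nr <- sum(ph == "Rhodophyta"); ng <- sum(ph == "Viridiplantae")
    if (!("Rhodophyta" %in% target) && nr >= min_each && ng >= min_each) {
      ni <- n - nt - nr - ng
      if (ni / n <= max_interrupt) {
        found[["Rhodophyta"]] <- NULL
        found[["Viridiplantae"]] <- NULL
        found[["Plantae-both"]] <- c(nr + ng, ni)
      }
    }
    for (p in names(found))
      rows[[length(rows) + 1L]] <- data.frame(
        partner_phylum = p, support = s, n_target = nt,
        n_partner = found[[p]][1], n_interrupting = found[[p]][2],
        leaves = paste(leaves, collapse = "|"), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  out <- unique(do.call(rbind, rows))
  sets <- strsplit(out$leaves, "|", fixed = TRUE)
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i != j && out$partner_phylum[i] == out$partner_phylum[j] &&
        length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$partner_phylum, out$leaves), , drop = FALSE]
}

# brute-force per-site likelihood for a 4-taxon rooted binary tree by
# exhaustive enumeration of all 20^3 internal-state assignments per gamma
# category (no pruning involved)
oracle_4taxon_sitelik <- function(tree, alignment, model) {
  stopifnot(length(tree$tip.label) == 4L, tree$Nnode == 3L)
  rates <- discrete_gamma_rates(model$alpha, model$n_gamma)
  pi <- model$freqs
  n_tip <- 4L; root <- 5L
  grid <- as.matrix(expand.grid(1:20, 1:20, 1:20))  # states of nodes 5,6,7
  missing_chars <- c("-", "X", "B", "Z", "U", "?", ".", "*")
  aa <- names(pi)
  S <- ncol(alignment)
  ll <- numeric(S)
  for (k in seq_along(rates)) {
    pmats <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_matrix(model, tree$edge.length[e], rates[k]))
    for (s in seq_len(S)) {
      f <- pi[grid[, root - n_tip]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        P <- pmats[[e]]
        pstate <- grid[, p - n_tip]
        if (ch > n_tip) {
          f <- f * P[cbind(pstate, grid[, ch - n_tip])]
        } else {
          res <- toupper(alignment[tree$tip.label[ch], s])
          if (res %in% missing_chars) f <- f * rowSums(P)[pstate]
          else f <- f * P[cbind(pstate, match(res, aa))]
        }
      }
      ll[s] <- ll[s] + sum(f) / length(rates)
    }
  }
  log(ll)
}

# random homolog set + taxonomy + hits bundle for the sampling filters
filters_fixture <- function(n, seed) {
  set.seed(seed)
  tax <- random_taxonomy(n)
  hits <- data.frame(query_id = tax$sequence_id[1],
                     subject_id = tax$sequence_id,
                     e_value = 10^-runif(n, 10, 60),
                     bitscore = round(runif(n, 50, 400), 1),
                     stringsAsFactors = FALSE)
  hs <- structure(list(query_id = tax$sequence_id[1],
                       members = tax$sequence_id,
                       provenance = character(0)),
                  class = "homolog_set")
  list(tax = tax, hits = hits, hs = hs)
}

# hand-rolled union-find for the clustering oracle
oracle_components <- function(n, edge_pairs) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in edge_pairs) {
    ri <- find(e[1]); rj <- find(e[2])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, 1L)
}

# small transfer-scenario alignment cache used by several test files
scenario_alignment <- function(n_sites = 300L, seed = 7L, on_null = FALSE) {
  sc <- transfer_scenario()
  m <- wag_model(alpha = 0.8)
  tree <- if (on_null) sc$pair$null_tree else sc$pair$ml_tree
  list(scenario = sc, model = m,
       alignment = simulate_alignment(tree, m, n_sites, seed = seed))
}
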