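# Leaf sets below every internal node, by postorder accumulation.
clade_leafsets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets[(n_tip + 1):n_node]
}

#' Screen eligibility of a tree
#'
#' Only trees broad enough to carry phylogenetic signal enter the screen:
#' at least `min_phyla` distinct phyla and at least `min_taxa` leaves.
#'
#' @param tree A support tree.
#' @param taxonomy Taxonomy data.frame.
#' @param min_phyla,min_taxa Eligibility bounds (defaults 3 and 30).
#' @return list(eligible = logical, reason = character).
#' @export
tree_eligible <- function(tree, taxonomy, min_phyla = 3L, min_taxa = 30L) {
  ph <- taxon_phylum(tree$tip.label, taxonomy)
  if (length(tree$tip.label) < min_taxa)
    return(list(eligible = FALSE,
                reason = sprintf("only %d terminal taxa (need >= %d)",
                                 length(tree$tip.label), min_taxa)))
  if (length(unique(ph)) < min_phyla)
    return(list(eligible = FALSE,
                reason = sprintf("only %d distinct phyla (need >= %d)",
                                 length(unique(ph)), min_phyla)))
  list(eligible = TRUE, reason = "")
}

# All bipartitions of an unrooted tree induced by internal-node edges plus
# pendant edges: for each node (tip or internal, root excluded), the leaf
# set below it and the support of the subtending edge.
edge_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- clade_leafsets(tree)
  supports <- tree_supports(tree)
  root <- n_tip + 1L
  nodes <- setdiff(c(seq_len(n_tip), n_tip + seq_len(tree$Nnode)), root)
  lapply(nodes, function(nd) {
    below <- if (nd <= n_tip) tree$tip.label[nd] else sets[[nd - n_tip]]
    list(node = nd, below = below,
         above = setdiff(tree$tip.label, below),
         support = if (nd <= n_tip) NA_integer_ else supports[nd - n_tip])
  })
}

#' Root a tree by outgroup precedence
#'
#' Applies the rooting rule of the screen: root on prokaryotes if any are
#' present, else on Metazoa, else on Fungi; with none of the three, the tree
#' is returned unrooted and its history is treated as unresolved. The root is
#' placed on the edge subtending the largest clade made exclusively of the
#' chosen outgroup phylum (ties: higher support on that edge, then the
#' lexicographically smallest leaf set). Supports stay attached to the edges
#' they came from.
#'
#' @param tree A support tree (unrooted or rooted).
#' @param taxonomy Taxonomy data.frame.
#' @return list(tree = rooted (or original) tree, outgroup_used = one of
#'   "Prokaryote", "Metazoa", "Fungi", "none").
#' @export
root_tree <- function(tree, taxonomy) {
  ph <- taxon_phylum(tree$tip.label, taxonomy)
  outgroup <- NULL
  for (cand in c("Prokaryote", "Metazoa", "Fungi")) {
    if (any(ph == cand)) { outgroup <- cand; break }
  }
  if (is.null(outgroup)) return(list(tree = tree, outgroup_used = "none"))

  phy_of <- stats::setNames(ph, tree$tip.label)
  best <- NULL
  for (bp in edge_bipartitions(tree)) {
    for (side in list(bp$below, bp$above)) {
      if (length(side) == 0L || length(side) == length(tree$tip.label)) next
      if (all(phy_of[side] == outgroup)) {
        cand <- list(leaves = sort(side), size = length(side),
                     support = ifelse(is.na(bp$support), -1L, bp$support))
        if (is.null(best) ||
            cand$size > best$size ||
            (cand$size == best$size && cand$support > best$support) ||
            (cand$size == best$size && cand$support == best$support &&
             paste(cand$leaves, collapse = "|") <
             paste(best$leaves, collapse = "|"))) {
          best <- cand
        }
      }
    }
  }
  rooted <- ape::root(tree, outgroup = best$leaves, resolve.root = TRUE,
                      edgelabel = TRUE)
  list(tree = rooted, outgroup_used = outgroup)
}

clade_counts <- function(leaves, phy_of, target_phyla) {
  ph <- phy_of[leaves]
  list(n_target = sum(ph %in% target_phyla), ph = ph, n = length(leaves))
}

#' Scan a tree for strongly supported two-phylum clades
#'
#' Every internal edge with bootstrap support at or above `support_min` is
#' tested (missing support never qualifies). A clade is a hit for a candidate
#' partner phylum when it holds at least `min_each` leaves of the target rank
#' and of the partner, and leaves of any other lineage (interrupting taxa)
#' make up at most `max_interrupt` of its leaves. When a clade holds at least
#' `min_each` leaves of each of Rhodophyta and Viridiplantae, the two are
#' also tried jointly as the combined "Plantae-both" partner (the mixed-clade
#' signal); a qualifying combined hit supersedes the two
#' single-phylum hits on the same clade. A qualifying clade nested inside
#' another qualifying clade with the same partner is suppressed (only maximal
#' hits are reported). On an unrooted tree both sides of every edge are
#' scanned.
#'
#' @param tree Rooted (or unrooted) support tree.
#' @param taxonomy Taxonomy data.frame.
#' @param target_rank `"Diatom"` (phase-1 screen) or `"Stramenopiles"`
#'   (topology-test screen).
#' @param support_min Bootstrap threshold (default 70).
#' @param min_each Minimum leaves per target phylum in the clade (default 2).
#' @param max_interrupt Maximum interrupting-leaf fraction (default 0.30).
#' @return data.frame of clade hits (possibly 0 rows): `partner_phylum`,
#'   `support`, `n_target`, `n_partner`, `n_interrupting`,
#'   `fraction_interrupting`, `leaves` (pipe-joined leaf IDs).
#' @export
scan_clades <- function(tree, taxonomy, target_rank = "Diatom",
                        support_min = 70L, min_each = 2L,
                        max_interrupt = 0.30) {
  validate_tree_taxa(tree, taxonomy)
  target_phyla <- expand_rank(target_rank)
  phy_of <- stats::setNames(taxon_phylum(tree$tip.label, taxonomy),
                            tree$tip.label)
  rooted <- ape::is.rooted(tree)

  candidates <- list()
  for (bp in edge_bipartitions(tree)) {
    if (is.na(bp$support) || bp$support < support_min) next
    sides <- if (rooted) list(bp$below) else list(bp$below, bp$above)
    for (side in sides) candidates <- c(candidates, list(
      list(leaves = side, support = bp$support)))
  }

  hits <- list()
  for (cl in candidates) {
    ph <- phy_of[cl$leaves]
    n_target <- sum(ph %in% target_phyla)
    if (n_target < min_each) next
    n_total <- length(cl$leaves)
    partner_counts <- table(ph[!(ph %in% target_phyla)])
    clade_hits <- list()
    for (partner in names(partner_counts)) {
      n_partner <- partner_counts[[partner]]
      if (n_partner < min_each) next
      n_int <- n_total - n_target - n_partner
      if (n_int / n_total > max_interrupt) next
      clade_hits[[partner]] <- list(partner = partner, n_partner = n_partner,
                                    n_int = n_int)
    }
    # combined red+green partner: min_each of each sub-phylum
    n_red <- sum(ph == "Rhodophyta"); n_green <- sum(ph == "Viridiplantae")
    if (!("Rhodophyta" %in% target_phyla) && n_red >= min_each &&
        n_green >= min_each) {
      n_int <- n_total - n_target - n_red - n_green
      if (n_int / n_total <= max_interrupt) {
        clade_hits <- clade_hits[!(names(clade_hits) %in%
                                     c("Rhodophyta", "Viridiplantae"))]
        clade_hits[["Plantae-both"]] <- list(partner = "Plantae-both",
                                             n_partner = n_red + n_green,
                                             n_int = n_int)
      }
    }
    for (h in clade_hits) {
      hits <- c(hits, list(data.frame(
        partner_phylum = h$partner, support = cl$support,
        n_target = n_target, n_partner = h$n_partner,
        n_interrupting = h$n_int,
        fraction_interrupting = h$n_int / n_total,
        leaves = paste(sort(cl$leaves), collapse = "|"),
        stringsAsFactors = FALSE)))
    }
  }
  if (!length(hits))
    return(data.frame(partner_phylum = character(), support = integer(),
                      n_target = integer(), n_partner = integer(),
                      n_interrupting = integer(),
                      fraction_interrupting = numeric(),
                      leaves = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- unique(out)

  # keep only maximal hits per partner
  keep <- rep(TRUE, nrow(out))
  leafsets <- strsplit(out$leaves, "|", fixed = TRUE)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i == j || out$partner_phylum[i] != out$partner_phylum[j]) next
      if (length(leafsets[[i]]) < length(leafsets[[j]]) &&
          all(leafsets[[i]] %in% leafsets[[j]])) keep[i] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the origin of a gene tree from its clade hits
#'
#' Codifies the verdicts of the manual sorting phase as a deterministic rule
#' set over the clade hits of [scan_clades()]:
#' no rootable outgroup means `UndeterminedOutgroup` regardless of hits;
#' no hits means `Unresolved`; hits only with Viridiplantae mean `Green`,
#' only Rhodophyta `Red`; two disjoint hits covering red and green mean
#' `RedPlusGreen`; a mixed red/green ("Plantae-both") hit — or overlapping
#' red and green hits — means `RedOrGreen`; hits only with
#' StramenopileOther read as vertical descent (`Stramenopile`); any other
#' single partner phylum is reported as that phylum's category
#' (`Haptophyta`, `Amoebozoa`, or `OtherPhylum` with the phylum recorded);
#' conflicting partner sets beyond these rules stay `Unresolved`.
#'
#' @param tree_id Identifier of the tree.
#' @param hits data.frame from [scan_clades()] on that tree.
#' @param outgroup_used Outgroup reported by [root_tree()].
#' @return list of class `origin_call`: `tree_id`, `category`,
#'   `other_phylum` (for `OtherPhylum`), `outgroup_used`, `hits`.
#' @export
classify_origin <- function(tree_id, hits, outgroup_used) {
  call <- function(category, other = NA_character_)
    structure(list(tree_id = tree_id, category = category,
                   other_phylum = other, outgroup_used = outgroup_used,
                   hits = hits),
              class = "origin_call")
  if (identical(outgroup_used, "none")) return(call("UndeterminedOutgroup"))
  if (nrow(hits) == 0L) return(call("Unresolved"))

  partners <- unique(hits$partner_phylum)
  red_rows <- hits$partner_phylum == "Rhodophyta"
  green_rows <- hits$partner_phylum == "Viridiplantae"
  both_rows <- hits$partner_phylum == "Plantae-both"

  if (any(red_rows) && any(green_rows)) {
    leafsets <- strsplit(hits$leaves, "|", fixed = TRUE)
    disjoint <- FALSE
    for (i in which(red_rows)) for (j in which(green_rows))
      if (!length(intersect(leafsets[[i]], leafsets[[j]]))) disjoint <- TRUE
    return(call(if (disjoint) "RedPlusGreen" else "RedOrGreen"))
  }
  if (any(both_rows)) {
    # a mixed clade alongside a clean single-phylum clade still reads as
    # red-and/or-green evidence
    return(call("RedOrGreen"))
  }
  if (any(red_rows)) return(call("Red"))
  if (any(green_rows)) return(call("Green"))

  if (setequal(partners, "StramenopileOther")) return(call("Stramenopile"))
  if (length(partners) == 1L) {
    if (partners %in% c("Haptophyta", "Amoebozoa")) return(call(partners))
    return(call("OtherPhylum", other = partners))
  }
  call("Unresolved")
}

#' @export
print.origin_call <- function(x, ...) {
  cat("origin call for", x$tree_id, ":", x$category,
      if (!is.na(x$other_phylum)) paste0("(", x$other_phylum, ")") else "",
      "- outgroup", x$outgroup_used, "-", nrow(x$hits), "clade hit(s)\n")
  invisible(x)
}

#' Pool trees into clusters by shared proteins
#'
#' Trees whose leaf sets share at least `min_overlap` sequences are linked;
#' clusters are the connected components of the resulting graph (so a chain
#' of pairwise overlaps pools into one cluster). Trees overlapping nothing
#' form singleton clusters.
#'
#' @param leaf_sets Named list: tree_id -> character vector of leaf IDs.
#' @param min_overlap Minimum shared-leaf count to link two trees (default 3).
#' @return data.frame with `tree_id` and integer `cluster`.
#' @export
cluster_trees <- function(leaf_sets, min_overlap = 3L) {
  ids <- names(leaf_sets)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(ids)
  edges <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      if (length(intersect(leaf_sets[[i]], leaf_sets[[j]])) >= min_overlap)
        edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  data.frame(tree_id = ids, cluster = as.integer(comp),
             stringsAsFactors = FALSE)
}
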