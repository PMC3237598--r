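default_phylum_plan <- function() {
  data.frame(
    phylum = c("Prokaryote", "Metazoa", "Fungi", "Rhodophyta",
               "Viridiplantae", "Haptophyta", "Alveolata",
               "StramenopileOther", "Diatom"),
    n_species = c(5L, 4L, 4L, 4L, 4L, 3L, 4L, 4L, 6L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles everything one synthetic gene family needs: the per-phylum species
#' counts (defaulting to a 38-leaf, 9-phylum family, comfortably above the
#' screen's 3-phylum/30-taxon eligibility floor), an optional HGT event
#' grafting an algal clade into the diatom lineage, branch-length scales, the
#' sequence-evolution settings and a mandatory seed.
#'
#' @param phylum_plan data.frame with `phylum`, `n_species`.
#' @param hgt `NULL` for vertical descent, or a list with `donor`
#'   (`"Viridiplantae"`, `"Rhodophyta"` or `"both"`), `size` (leaves per
#'   grafted clade, default 4) and `stalk` (length of the graft's subtending
#'   branch, default 0.2 substitutions/site).
#' @param branch_scale Backbone edge length in substitutions/site (0.15).
#' @param n_sites Alignment length (300).
#' @param alpha Gamma shape for rate heterogeneity (0.8).
#' @param n_gamma Gamma categories (4).
#' @param n_bootstrap Bootstrap replicates for supports (100).
#' @param seed Integer seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(phylum_plan = default_phylum_plan(), hgt = NULL,
                       branch_scale = 0.15, n_sites = 300L, alpha = 0.8,
                       n_gamma = 4L, n_bootstrap = 100L, seed) {
  stopifnot(!missing(seed))
  stopifnot(all(phylum_plan$phylum %in% phylum_vocabulary()),
            all(phylum_plan$n_species >= 1L),
            !anyDuplicated(phylum_plan$phylum),
            branch_scale > 0, n_sites >= 1L, alpha > 0, n_bootstrap >= 1L)
  if (nrow(phylum_plan) < 3L)
    stop("a screen-eligible tree needs >= 3 phyla in the plan")
  if (!is.null(hgt)) {
    stopifnot(hgt$donor %in% c("Viridiplantae", "Rhodophyta", "both"))
    if (is.null(hgt$size)) hgt$size <- 4L
    if (is.null(hgt$stalk)) hgt$stalk <- 0.2
    stopifnot(hgt$size >= 1L, hgt$stalk > 0)
  }
  structure(list(phylum_plan = phylum_plan, hgt = hgt,
                 branch_scale = branch_scale, n_sites = as.integer(n_sites),
                 alpha = alpha, n_gamma = as.integer(n_gamma),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Newick for a random within-phylum subtree (coalescent topology scaled to
# the requested depth), without the trailing branch to its parent.
subtree_newick <- function(labels, depth) {
  if (length(labels) == 1L) return(labels)
  t <- ape::rcoal(length(labels), tip.label = labels)
  t$edge.length <- t$edge.length / max(ape::node.depth.edgelength(t)) * depth
  sub(";$", "", ape::write.tree(t))
}

prokaryote_subgroups <- c("Proteobacteria", "Actinobacteria", "Firmicutes",
                          "Cyanobacteria", "Bacteroidetes")

#' Simulate a phylum-structured gene tree with optional HGT graft
#'
#' The species backbone is fixed (not sampled) so that "vertical" has an
#' unambiguous meaning: prokaryotes are the outgroup, opisthokonts
#' (Metazoa + Fungi) are sister to the remaining eukaryotes, Rhodophyta and
#' Viridiplantae group as Plantae, and diatoms sit with the other
#' stramenopiles inside the chromalveolate assemblage. Within-phylum subtrees
#' are random coalescent topologies. An HGT event grafts a clade of new
#' donor-phylum leaves inside the diatom clade (splitting it), producing
#' exactly the nested-algae-in-stramenopiles signal the screen targets; with
#' donor `"both"`, a green and a red clade are grafted into the two halves of
#' the diatom clade.
#'
#' @param config A [sim_config()].
#' @return list: `tree` (no supports), `taxonomy`, `truth` (list with
#'   `true_history`, `grafted_leaves`, `expected_category`).
#' @export
simulate_gene_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plan <- config$phylum_plan
  b <- config$branch_scale
  depth <- 0.6 * b
  len <- function(s) paste0(s, ":", format(b, digits = 6))

  leaves <- list()
  subs <- list()
  for (i in seq_len(nrow(plan))) {
    ph <- plan$phylum[i]
    lab <- paste0(ph, "_", seq_len(plan$n_species[i]))
    leaves[[ph]] <- lab
    subs[[ph]] <- subtree_newick(lab, depth)
  }

  grafted <- character(0)
  history <- "vertical"
  expected <- "Stramenopile"
  if (!is.null(config$hgt)) {
    donors <- if (config$hgt$donor == "both")
      c("Viridiplantae", "Rhodophyta") else config$hgt$donor
    dia <- leaves[["Diatom"]]
    if (is.null(dia)) stop("HGT graft needs Diatom in the phylum plan")
    if (length(donors) == 2L && length(dia) < 4L)
      stop("a double graft needs >= 4 diatom species")
    half1 <- dia[seq_len(ceiling(length(dia) / 2))]
    half2 <- setdiff(dia, half1)
    graft_one <- function(donor, recipient_labels, k) {
      glab <- paste0(donor, "_hgt", seq_len(config$hgt$size))
      gsub_nwk <- paste0(subtree_newick(glab, depth), ":",
                         format(config$hgt$stalk, digits = 6))
      rec <- paste0(subtree_newick(recipient_labels, depth), ":",
                    format(b / 2, digits = 6))
      grafted <<- c(grafted, glab)
      paste0("(", gsub_nwk, ",", rec, ")")
    }
    if (length(donors) == 1L) {
      part1 <- len(graft_one(donors, half1, 1))
      part2 <- len(subtree_newick(half2, depth))
      subs[["Diatom"]] <- paste0("(", part1, ",", part2, ")")
      history <- if (donors == "Viridiplantae") "green_hgt" else "red_hgt"
      expected <- if (donors == "Viridiplantae") "Green" else "Red"
    } else {
      part1 <- len(graft_one("Viridiplantae", half1, 1))
      part2 <- len(graft_one("Rhodophyta", half2, 2))
      subs[["Diatom"]] <- paste0("(", part1, ",", part2, ")")
      history <- "red_plus_green_hgt"
      expected <- "RedPlusGreen"
    }
  }

  # fixed backbone: joins collapse silently when a phylum is absent
  join <- function(...) {
    parts <- Filter(Negate(is.null), list(...))
    if (!length(parts)) return(NULL)
    if (length(parts) == 1L) return(parts[[1]])
    paste0("(", paste(vapply(parts, len, ""), collapse = ","), ")")
  }
  g <- function(ph) subs[[ph]]
  sar <- join(join(g("Alveolata"), g("Rhizaria")),
              join(g("StramenopileOther"), g("Diatom")))
  chrom <- join(g("Cryptophyta"), join(g("Haptophyta"), sar))
  plantae <- join(join(g("Rhodophyta"), g("Glaucophyta")), g("Viridiplantae"))
  opist <- join(g("Metazoa"), g("Fungi"))
  euk <- join(opist,
              join(g("Amoebozoa"),
                   join(g("Excavata"),
                        join(g("OtherEukaryote"), join(plantae, chrom)))))
  top <- join(g("Prokaryote"), euk)
  tree <- ape::read.tree(text = paste0(top, ";"))
  tree <- ape::collapse.singles(tree)
  tree$edge.length[is.na(tree$edge.length)] <- b

  phylum_of_label <- function(lab) sub("_.*$", "", lab)
  ph <- phylum_of_label(tree$tip.label)
  taxonomy <- data.frame(
    sequence_id = tree$tip.label,
    species = tree$tip.label,
    phylum = ph,
    subgroup = ifelse(ph == "Prokaryote",
                      prokaryote_subgroups[
                        (seq_along(tree$tip.label) %% length(prokaryote_subgroups)) + 1L],
                      ""),
    stringsAsFactors = FALSE)
  taxonomy <- validate_taxonomy(taxonomy)

  list(tree = tree, taxonomy = taxonomy,
       truth = list(true_history = history, grafted_leaves = grafted,
                    expected_category = expected))
}

#' Simulate a protein alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies and evolved
#' edge by edge with the model's transition matrices; each site carries a
#' discrete-gamma rate category. Deterministic per seed.
#'
#' @param tree Tree with branch lengths.
#' @param model A [wag_model()].
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed.
#' @return Character matrix (leaves x sites).
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  if (n_sites < 1L) stop("need at least one site")
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  rates <- discrete_gamma_rates(model$alpha, model$n_gamma)
  cat_of <- sample.int(length(rates), n_sites, replace = TRUE)
  eig <- model_eigen(model)
  pmat <- function(t, r) {
    p <- eig$A %*% diag(exp(eig$values * t * r)) %*% eig$B
    p[p < 0] <- 0
    p / rowSums(p)
  }
  states <- matrix(0L, n_node, n_sites)
  root <- n_tip + 1L
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = eig$pi)
  for (e in rev(seq_len(nrow(tree$edge)))) {  # preorder traversal
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    for (k in seq_along(rates)) {
      sel <- which(cat_of == k)
      if (!length(sel)) next
      P <- pmat(t, rates[k])
      ps <- states[parent, sel]
      for (s in unique(ps)) {
        at <- sel[ps == s]
        states[child, at] <- sample.int(20L, length(at), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  out <- matrix(AA_LEVELS[states[seq_len(n_tip), , drop = FALSE]],
                nrow = n_tip, dimnames = list(tree$tip.label, NULL))
  out
}

# Poisson-corrected mismatch distance between aligned protein rows.
protein_distance <- function(alignment) {
  st <- encode_alignment(alignment)
  n <- nrow(st); S <- ncol(st)
  ind <- matrix(0L, 21L * S, n)
  for (i in seq_len(n)) ind[(seq_len(S) - 1L) * 21L + st[i, ] + 1L, i] <- 1L
  matches <- crossprod(ind)
  p <- 1 - matches / S
  p <- pmin(p, 0.95)
  d <- -log(1 - p)
  diag(d) <- 0
  rownames(d) <- colnames(d) <- rownames(alignment)
  stats::as.dist(d)
}

#' Attach bootstrap supports from a distance+NJ bootstrap
#'
#' Site-resampled replicates, each summarised by a neighbour-joining tree on
#' Poisson-corrected mismatch distances; the support of each internal edge of
#' the input tree is the percentage of replicate trees containing that
#' bipartition. These are fixture-grade supports — realistic inputs to the
#' screen, not publication-grade ML bootstraps.
#'
#' @param tree The (true) tree to annotate.
#' @param alignment Alignment simulated on the tree.
#' @param n_bootstrap Replicates (default 100).
#' @param seed Integer seed.
#' @return The tree, unrooted, with integer percentage supports in
#'   `node.label`.
#' @export
attach_bootstrap_supports <- function(tree, alignment, n_bootstrap = 100L,
                                      seed) {
  if (n_bootstrap < 1L) stop("need at least one bootstrap replicate")
  set.seed(seed)
  tree <- ape::unroot(tree)  # screen input trees are unrooted
  alignment <- alignment[match(tree$tip.label, rownames(alignment)), ,
                         drop = FALSE]
  counts <- ape::boot.phylo(tree, alignment,
                            FUN = function(x) ape::nj(protein_distance(x)),
                            B = n_bootstrap, quiet = TRUE, rooted = FALSE)
  pct <- as.integer(round(100 * counts / n_bootstrap))
  lab <- as.character(pct)
  lab[is.na(lab)] <- ""
  lab[1] <- ""  # root node carries no edge
  tree$node.label <- lab
  validate_support_tree(tree)
}

#' Simulate a similarity hit table consistent with a tree
#'
#' Bitscores decay exponentially with patristic distance
#' (`bitscore = base * exp(-decay * d) + noise`), e-values are a monotone
#' map of bitscores, and both (q,s) and (s,q) rows are emitted. Self-hits
#' always outrank everything else.
#'
#' @param tree Tree with branch lengths.
#' @param base Bitscore of a zero-distance pair (default 400).
#' @param decay Exponential decay rate per substitution/site (default 1).
#' @param noise_sd Gaussian bitscore noise (default 0 = noise-free).
#' @param seed Integer seed.
#' @return data.frame with `query_id`, `subject_id`, `e_value`, `bitscore`.
#' @export
simulate_hit_table <- function(tree, base = 400, decay = 1, noise_sd = 0,
                               seed) {
  stopifnot(decay > 0)
  set.seed(seed)
  d <- ape::cophenetic.phylo(tree)
  ids <- rownames(d)
  q <- rep(ids, each = length(ids))
  s <- rep(ids, times = length(ids))
  dist <- as.vector(t(d))
  bits <- base * exp(-decay * dist)
  if (noise_sd > 0) bits <- bits + stats::rnorm(length(bits), 0, noise_sd)
  bits[q == s] <- base + 10  # self-hit dominates
  bits <- pmax(bits, 1)
  data.frame(query_id = q, subject_id = s,
             e_value = exp(-0.7 * bits), bitscore = bits,
             stringsAsFactors = FALSE)
}
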