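make_hits <- function(...) {
  # build a hit table from query -> subjects lists; e-values rank by order
  lists <- list(...)
  rows <- list()
  for (q in names(lists)) {
    subj <- lists[[q]]
    for (i in seq_along(subj))
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = q, subject_id = subj[i],
        e_value = 10^-(50 - i), bitscore = 200 - i,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("homolog sets are the intersection of top-hit lists", {
  hits <- make_hits(Q = c("A", "B"), A = c("Q", "A", "B"), B = c("Q", "B", "C"))
  hs <- build_homolog_set("Q", hits)
  expect_setequal(hs$members, c("Q", "B"))  # A drops: absent from B's list

  hits2 <- make_hits(Q = c("A", "B", "C"), A = c("Q", "A", "B", "C"),
                     B = c("Q", "A", "B", "C"), C = c("Q", "A", "B", "C"))
  expect_setequal(build_homolog_set("Q", hits2)$members,
                  c("Q", "A", "B", "C"))

  none <- build_homolog_set("Q", make_hits(Z = c("Y")))
  expect_identical(none$members, "Q")
  expect_length(none$provenance, 0L)
})

test_that("homolog sets equal the brute-force oracle on random tables", {
  for (i in 1:100) {
    ids <- sprintf("p%d", 1:8)
    hits <- random_hit_table(ids, density = 0.5, seed = 1000 + i)
    q <- sample(ids, 1)
    expect_identical(build_homolog_set(q, hits)$members,
                     oracle_homolog_set(q, hits))
  }
})

test_that("adding intersected top hits never grows the member set", {
  for (i in 1:25) {
    ids <- sprintf("p%d", 1:8)
    hits <- random_hit_table(ids, density = 0.6, seed = 2000 + i)
    q <- ids[1]
    prev <- NULL
    for (n in 1:5) {
      cur <- build_homolog_set(q, hits, top_n = n)$members
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("sampling caps are enforced, idempotent, and keep the query", {
  # 7 members of one species -> 5 kept, the top-5 by bitscore
  tax <- data.frame(sequence_id = sprintf("m%d", 1:7),
                    species = "same_sp", phylum = "Metazoa", subgroup = "",
                    stringsAsFactors = FALSE)
  hits <- data.frame(query_id = "m1", subject_id = tax$sequence_id,
                     e_value = 1e-30, bitscore = c(500, 90, 80, 70, 60, 50, 40),
                     stringsAsFactors = FALSE)
  hs <- structure(list(query_id = "m1", members = tax$sequence_id,
                       provenance = character(0)), class = "homolog_set")
  out <- apply_sampling_filters(hs, tax, hits)
  expect_setequal(out$members, c("m1", "m2", "m3", "m4", "m5"))

  # 20 metazoans from 20 species -> 15 kept
  tax2 <- data.frame(sequence_id = sprintf("z%02d", 1:20),
                     species = sprintf("sp%02d", 1:20), phylum = "Metazoa",
                     subgroup = "", stringsAsFactors = FALSE)
  hits2 <- data.frame(query_id = "z01", subject_id = tax2$sequence_id,
                      e_value = 1e-30, bitscore = seq(400, 20, length.out = 20),
                      stringsAsFactors = FALSE)
  hs2 <- structure(list(query_id = "z01", members = tax2$sequence_id,
                        provenance = character(0)), class = "homolog_set")
  expect_length(apply_sampling_filters(hs2, tax2, hits2)$members, 15L)

  for (i in 1:50) {
    fx <- filters_fixture(sample(10:40, 1), seed = 3000 + i)
    out <- apply_sampling_filters(fx$hs, fx$tax, fx$hits)
    info <- fx$tax[match(out$members, fx$tax$sequence_id), ]
    expect_true(all(table(info$species) <= 5))
    expect_true(sum(info$phylum == "Fungi") <= 15)
    expect_true(sum(info$phylum == "Metazoa") <= 15)
    expect_lte(length(unique(info$subgroup[info$phylum == "Prokaryote"])), 5L)
    expect_true(fx$hs$query_id %in% out$members)
    again <- apply_sampling_filters(out, fx$tax, fx$hits)
    expect_identical(again$members, out$members)
  }
})

test_that("the prokaryote subgroup cap keeps the best-scoring subgroups", {
  set.seed(9)
  groups <- sprintf("grp%d", 1:8)
  tax <- data.frame(sequence_id = sprintf("b%02d", 1:16),
                    species = sprintf("bs%02d", 1:16), phylum = "Prokaryote",
                    subgroup = rep(groups, each = 2), stringsAsFactors = FALSE)
  tax <- rbind(data.frame(sequence_id = "q", species = "dsp",
                          phylum = "Diatom", subgroup = "",
                          stringsAsFactors = FALSE), tax)
  score <- round(runif(16, 50, 400), 1)
  hits <- data.frame(query_id = "q", subject_id = tax$sequence_id[-1],
                     e_value = 1e-30, bitscore = score,
                     stringsAsFactors = FALSE)
  hs <- structure(list(query_id = "q", members = tax$sequence_id,
                       provenance = character(0)), class = "homolog_set")
  out <- apply_sampling_filters(hs, tax, hits)
  kept_groups <- unique(tax$subgroup[match(setdiff(out$members, "q"),
                                           tax$sequence_id)])
  best_by_group <- tapply(score, rep(groups, each = 2), max)
  expected <- names(sort(best_by_group, decreasing = TRUE))[1:5]
  expect_setequal(kept_groups, expected)
})

test_that("family eligibility applies the size and site bounds", {
  aln50 <- matrix("A", 4, 50)
  expect_false(check_family_eligibility(3, aln50)$eligible)
  expect_true(check_family_eligibility(4, aln50)$eligible)
  expect_true(check_family_eligibility(100, aln50)$eligible)
  expect_false(check_family_eligibility(101, aln50)$eligible)
  expect_false(check_family_eligibility(10, n_sites = 49)$eligible)
  expect_true(check_family_eligibility(10, n_sites = 50)$eligible)
})

test_that("gap masking drops exactly the gap-rich columns", {
  aln <- matrix(c("A", "A", "A", "A",
                  "-", "-", "-", "-",
                  "R", "-", "R", "R"), nrow = 4)
  out <- mask_columns(aln)
  expect_equal(ncol(out), 2L)  # all-gap column removed at default 0.5

  clean <- matrix("K", 5, 8)
  expect_identical(mask_columns(clean), clean)
  expect_error(mask_columns(matrix(character(0), 0, 0)), "empty")

  for (i in 1:30) {
    set.seed(4000 + i)
    aln <- matrix(sample(c("A", "R", "-"), 120, TRUE, prob = c(.4, .3, .3)),
                  nrow = 6)
    thr <- runif(1)
    got <- ncol(mask_columns(aln, thr))
    want <- sum(vapply(seq_len(ncol(aln)), function(j)
      mean(aln[, j] == "-") <= thr, TRUE))
    expect_equal(got, want)
  }
})

test_that("exclusive associations detect single-partner hit profiles", {
  tax <- data.frame(
    sequence_id = c("d1", "d2", "d3", "h1", "h2", "h3", "h4", "f1"),
    species = sprintf("sp%d", 1:8),
    phylum = c(rep("Diatom", 3), rep("Haptophyta", 4), "Fungi"),
    subgroup = "", stringsAsFactors = FALSE)
  hits <- data.frame(query_id = "d1",
                     subject_id = c("d1", "d2", "d3", "h1", "h2", "h3", "h4"),
                     e_value = 1e-20, bitscore = 100, stringsAsFactors = FALSE)
  a <- exclusive_association("d1", hits, tax)
  expect_identical(a$partner_phylum, "Haptophyta")
  expect_true(a$x2); expect_false(a$x10); expect_false(a$x20)

  hits2 <- rbind(hits, data.frame(query_id = "d1", subject_id = "f1",
                                  e_value = 1e-20, bitscore = 90))
  expect_true(is.na(exclusive_association("d1", hits2, tax)$partner_phylum))
})

test_that("a planted exclusive cohort is recovered exactly and partitions", {
  set.seed(77)
  phyla <- c("Haptophyta", "Alveolata", "Fungi", "Metazoa")
  planted <- sample(c(phyla, "none"), 20, replace = TRUE)
  tax_rows <- list(); hit_rows <- list()
  for (i in 1:20) {
    q <- sprintf("q%02d", i)
    tax_rows[[length(tax_rows) + 1L]] <- data.frame(
      sequence_id = q, species = q, phylum = "Diatom", subgroup = "",
      stringsAsFactors = FALSE)
    partners <- if (planted[i] == "none") sample(phyla, 2) else planted[i]
    for (p in partners) {
      for (j in 1:3) {
        sid <- sprintf("%s_%s%d", q, substr(p, 1, 3), j)
        tax_rows[[length(tax_rows) + 1L]] <- data.frame(
          sequence_id = sid, species = sid, phylum = p, subgroup = "",
          stringsAsFactors = FALSE)
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          query_id = q, subject_id = sid, e_value = 1e-25, bitscore = 120,
          stringsAsFactors = FALSE)
      }
    }
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = q, subject_id = q, e_value = 1e-60, bitscore = 400,
      stringsAsFactors = FALSE)
  }
  tax <- do.call(rbind, tax_rows); hits <- do.call(rbind, hit_rows)
  cohort <- exclusive_cohort(sprintf("q%02d", 1:20), hits, tax)
  expect_equal(nrow(cohort), 20L)  # one verdict per query
  expect_identical(cohort$partner_phylum, planted)
  dist <- x_threshold_distribution(cohort)
  expect_equal(sum(dist$x2), sum(planted != "none"))
})
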