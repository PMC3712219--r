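# A tiny deterministic reference world shared by the assignment tests:
# profiles are built from simulated clean hits, so scores are reproducible.
assign_world <- function(seed = 5, lgt_rate = 0, shape = c(2, 1, 1, 1, 1, 2, 2)) {
  cfg <- sim_config(taxonomy_shape = shape, lgt_rate = lgt_rate, seed = seed)
  simulate_reference_world(cfg = cfg, p = 0.85)
}

test_that("profile-matching assignment follows the y threshold and the LCA vote", {
  w <- assign_world()
  tax <- w$refs$taxonomy
  sp <- species_nodes(tax)
  qid <- paste0(sp[1], "|q1")
  q <- build_profile(w$queries[[qid]], 0.85, qid)

  # its own species' references dominate; with y close to 1 the call is the
  # query's source taxon truncated to genus
  a <- spanner_assign(q, w$refs, y = 0.999)
  expect_identical(a$assigned_taxon, ancestor_at(tax, sp[1], 6))
  expect_identical(a$assigned_depth, 6L)
  expect_true(all(a$support$source_taxon == sp[1]))

  # y = 0 degenerates to the LCA over every reference with positive score
  a0 <- spanner_assign(q, w$refs, y = 0)
  sc <- score_against_references(q, w$refs)
  expect_identical(a0$assigned_taxon,
                   truncate_taxon(tax, lca(tax, sc$source_taxon[sc$score > 0]), 6))

  # a retained set spanning both domains votes for the root
  far <- sp[ancestor_at(tax, sp, 1) != ancestor_at(tax, sp[1], 1)][1]
  two <- list(r1 = data.frame(taxon = sp[1], bitscore = 400, evalue = 1e-40),
              r2 = data.frame(taxon = far, bitscore = 400, evalue = 1e-40))
  refs2 <- build_reference_set(two, c(r1 = sp[1], r2 = far), 0.85, tax)
  qq <- build_profile(data.frame(taxon = c(sp[1], far),
                                 bitscore = c(400, 400),
                                 evalue = c(1e-40, 1e-40)), 0.85, "qq")
  expect_identical(spanner_assign(qq, refs2, y = 0.9)$assigned_taxon, tax$root)

  # empty query profile -> explicit unclassified (root)
  ae <- spanner_assign(empty_profile("nohits"), w$refs, y = 0.95)
  expect_identical(ae$assigned_taxon, tax$root)
  expect_identical(ae$assigned_depth, 0L)
})

test_that("raising y weakly shrinks the retained reference set", {
  w <- assign_world(seed = 9)
  tax <- w$refs$taxonomy
  set.seed(101)
  for (qid in sample(names(w$queries), 4)) {
    q <- build_profile(w$queries[[qid]], 0.85, qid)
    prev <- NULL
    for (y in c(0.2, 0.5, 0.8, 0.95, 1)) {
      ret <- spanner_assign(q, w$refs, y = y)$support$source_id
      if (!is.null(prev)) expect_true(all(ret %in% prev))
      prev <- ret
    }
  }
})

test_that("spanner assignments are ancestors of every retained reference taxon", {
  w <- assign_world(seed = 13)
  tax <- w$refs$taxonomy
  for (qid in names(w$queries)[1:6]) {
    q <- build_profile(w$queries[[qid]], 0.85, qid)
    a <- spanner_assign(q, w$refs, y = 0.8, max_depth = 7L)
    for (t in unique(a$support$source_taxon)) {
      expect_true(a$assigned_taxon %in% lineage(tax, t)$taxon)
    }
  }
})

test_that("LCA baseline assigns the profile-wide lowest common ancestor", {
  tax <- toy8()
  sp <- species_nodes(tax)
  one <- build_profile(data.frame(taxon = sp[1], bitscore = 100,
                                  evalue = 1e-10), 0.85, "q1")
  expect_identical(lca_assign(one, tax)$assigned_taxon,
                   ancestor_at(tax, sp[1], 6))   # truncated to genus

  doms <- ancestor_at(tax, sp, 1)
  cross <- build_profile(data.frame(taxon = c(sp[1], sp[doms != doms[1]][1]),
                                    bitscore = c(100, 95),
                                    evalue = c(1e-10, 1e-9)), 0, "q2")
  a <- lca_assign(cross, tax)
  expect_identical(a$assigned_taxon, tax$root)
  expect_identical(a$assigned_depth, 0L)

  tax3 <- make_toy_taxonomy(c(1, 1, 1, 1, 1, 1, 3))
  sp3 <- species_nodes(tax3)
  cong <- build_profile(data.frame(taxon = sp3, bitscore = c(90, 80, 70),
                                   evalue = c(1e-9, 1e-8, 1e-7)), 0, "q3")
  expect_identical(lca_assign(cong, tax3)$assigned_taxon,
                   ancestor_at(tax3, sp3[1], 6))

  # the LCA depth weakly rises as p rises (fewer matches can only push down)
  set.seed(111)
  for (i in 1:10) {
    hits <- random_hits(tax, 10)
    d <- vapply(c(0, 0.5, 0.9), function(p) {
      lca_assign(build_profile(hits, p, "q"), tax, max_depth = 7L)$assigned_depth
    }, integer(1))
    expect_true(all(diff(d) >= 0))
  }
})

test_that("best-BLAST takes the single top hit, capped at genus", {
  tax <- toy8()
  sp <- species_nodes(tax)
  a <- best_blast_assign(data.frame(taxon = sp[1], bitscore = 100,
                                    evalue = 1e-10), tax, query_id = "q")
  expect_identical(a$assigned_taxon, ancestor_at(tax, sp[1], 6))
  expect_identical(a$assigned_depth, 6L)

  tied <- data.frame(taxon = c(sp[1], sp[3]), bitscore = c(100, 100),
                     evalue = c(1e-12, 1e-10))
  expect_identical(best_blast_assign(tied, tax)$support$source_id, sp[1])
  tied2 <- tied[2:1, ]
  expect_identical(best_blast_assign(tied2, tax)$support$source_id, sp[1])

  expect_identical(best_blast_assign(NULL, tax, query_id = "q")$assigned_depth, 0L)

  # LGT-style contrast: a confidently wrong top hit lands in the wrong domain
  doms <- ancestor_at(tax, sp, 1)
  far <- sp[doms != doms[1]][1]
  lgt <- data.frame(taxon = c(far, sp[1]), bitscore = c(400, 390),
                    evalue = c(1e-40, 1e-39))
  wrong <- best_blast_assign(lgt, tax)
  expect_identical(wrong$assigned_taxon, ancestor_at(tax, far, 6))
  expect_false(ancestor_at(tax, wrong$assigned_taxon, 1) == doms[1])
})

test_that("batch classification equals per-query calls and keeps the schema", {
  w <- assign_world(seed = 17)
  tax <- w$refs$taxonomy
  queries <- w$queries[1:3]

  out_lca <- classify_batch(queries, method = "lca", tax = tax, p = 0.85)
  expect_identical(nrow(out_lca), 3L)
  expect_identical(out_lca$query_id, names(queries))
  expect_identical(out_lca$method, rep("lca", 3))

  out_sp <- classify_batch(queries, method = "spanner", refs = w$refs,
                           p = 0.85, y = 0.95)
  for (i in seq_along(queries)) {
    solo <- spanner_assign(build_profile(queries[[i]], 0.85, names(queries)[i]),
                           w$refs, y = 0.95)
    expect_identical(out_sp$assigned_taxon[i], solo$assigned_taxon)
    expect_identical(out_sp$best_score[i], solo$best_score)
  }

  # y = 1 vs y = 0.5: both runs complete, same schema, same query order
  hi <- classify_batch(queries, method = "spanner", refs = w$refs, y = 1)
  lo <- classify_batch(queries, method = "spanner", refs = w$refs, y = 0.5)
  expect_identical(names(hi), names(lo))
  expect_identical(hi$query_id, lo$query_id)

  expect_error(classify_batch(queries, method = "spanner"), "reference set")
  expect_identical(nrow(classify_batch(list(), method = "lca", tax = tax)), 0L)
})
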