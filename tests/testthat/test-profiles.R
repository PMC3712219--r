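test_that("BLAST tabular parsing groups hits and drops unmapped subjects", {
  row <- function(q, s, e, b) {
    paste(q, s, "90.0", "150", "15", "0", "1", "150", "1", "150", e, b,
          sep = "\t")
  }
  tm <- c(s1 = "tA", s2 = "tB", s3 = "tC")

  f <- write_lines(c(row("q1", "s1", "1e-50", "200"),
                     row("q1", "s2", "1e-40", "150"),
                     row("q1", "s3", "1e-30", "100")),
                   tempfile(fileext = ".tsv"))
  out <- parse_blast_tab(f, tm)
  expect_identical(names(out$hits), "q1")
  expect_identical(nrow(out$hits$q1), 3L)
  expect_identical(out$n_dropped, 0L)
  expect_identical(out$hits$q1$taxon, c("tA", "tB", "tC"))

  f2 <- write_lines(c(row("q1", "s1", "1e-50", "200"),
                      row("q1", "unknown", "1e-40", "150"),
                      row("q1", "s3", "1e-30", "100")),
                    tempfile(fileext = ".tsv"))
  expect_message(out2 <- parse_blast_tab(f2, tm), "dropped 1")
  expect_identical(nrow(out2$hits$q1), 2L)
  expect_identical(out2$n_dropped, 1L)

  f3 <- write_lines(c(row("q1", "s1", "1e-50", "200"),
                      row("q1", "s2", "1e-40", "oops")),
                    tempfile(fileext = ".tsv"))
  expect_error(parse_blast_tab(f3, tm), "line 2.*bitscore")

  f4 <- write_lines(character(), tempfile(fileext = ".tsv"))
  out4 <- parse_blast_tab(f4, tm)
  expect_identical(out4$hits, list())
})

test_that("profile construction thresholds, dedupes and orders deterministically", {
  hits <- data.frame(taxon = c("a", "b", "c"),
                     bitscore = c(100, 90, 80),
                     evalue = c(1e-30, 1e-25, 1e-20))
  pr <- build_profile(hits, p = 0.85)
  expect_identical(pr$matches$taxon, c("a", "b"))  # threshold 85, inclusive

  dup <- data.frame(taxon = c("a", "a"), bitscore = c(100, 95),
                    evalue = c(1e-30, 1e-28))
  expect_identical(build_profile(dup, p = 0)$matches$bitscore, 100)

  ties <- data.frame(taxon = c("a", "b", "c"),
                     bitscore = c(100, 100, 99),
                     evalue = c(1e-30, 1e-30, 1e-29))
  expect_identical(build_profile(ties, p = 1)$matches$taxon, c("a", "b"))

  # equal bitscores break ties by ascending e-value then taxon id
  tie2 <- data.frame(taxon = c("z", "y", "x"),
                     bitscore = c(50, 50, 50),
                     evalue = c(1e-10, 1e-12, 1e-10))
  expect_identical(build_profile(tie2, p = 0)$matches$taxon, c("y", "x", "z"))

  expect_true(is_empty_profile(build_profile(hits[0, ], p = 0.85, "q")))
})

test_that("profile construction is monotone in p", {
  tax <- toy8()
  set.seed(31)
  for (i in 1:20) {
    hits <- random_hits(tax, sample(3:20, 1))
    ps <- sort(runif(3))
    prev <- build_profile(hits, ps[1])$matches$taxon
    for (p in ps[-1]) {
      cur <- build_profile(hits, p)$matches$taxon
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("reference sets keep self-hits and shrink as p rises", {
  tax <- toy8()
  sp <- species_nodes(tax)
  mk <- function(self, other) {
    data.frame(taxon = c(self, other), bitscore = c(400, 350),
               evalue = c(1e-40, 1e-35))
  }
  hits <- list(r1 = mk(sp[1], sp[2]), r2 = mk(sp[2], sp[1]))
  src <- c(r1 = sp[1], r2 = sp[2])
  refs <- build_reference_set(hits, src, p = 0.85, tax = tax)
  expect_length(refs$profiles, 2L)
  expect_identical(refs$profiles$r1$matches$taxon[1], sp[1])  # led by self-hit
  expect_identical(refs$profiles$r2$matches$taxon[1], sp[2])

  solo <- list(r1 = mk(sp[1], sp[2])[1, ])
  refs_solo <- build_reference_set(solo, src, p = 0.85, tax = tax)
  expect_identical(nrow(refs_solo$profiles$r1$matches), 1L)

  # raising p: every profile's match list is a subset of before
  set.seed(41)
  hits_r <- lapply(sp[1:4], function(s) {
    h <- random_hits(tax, 12)
    rbind(data.frame(taxon = s, bitscore = 600, evalue = 1e-60), h)
  })
  names(hits_r) <- paste0(sp[1:4], "|ref1")
  src_r <- structure(sp[1:4], names = names(hits_r))
  lo <- build_reference_set(hits_r, src_r, p = 0.85, tax = tax)
  hi <- build_reference_set(hits_r, src_r, p = 0.95, tax = tax)
  for (id in names(lo$profiles)) {
    expect_true(all(hi$profiles[[id]]$matches$taxon %in%
                      lo$profiles[[id]]$matches$taxon))
  }
})

test_that("novelty masking removes the clade then re-applies the threshold", {
  tax <- toy8()
  sp <- species_nodes(tax)
  s1 <- sp[1]
  s2 <- sp[2]                       # same genus as s1
  s3 <- sp[3]                       # same family, other genus
  stopifnot(ancestor_at(tax, s1, 6) == ancestor_at(tax, s2, 6),
            ancestor_at(tax, s1, 5) == ancestor_at(tax, s3, 5),
            ancestor_at(tax, s1, 6) != ancestor_at(tax, s3, 6))
  pr <- build_profile(data.frame(taxon = c(s1, s2, s3),
                                 bitscore = c(300, 250, 220),
                                 evalue = c(1e-30, 1e-25, 1e-22)),
                      p = 0, source_id = "q")

  m_sp <- mask_novelty(pr, s1, 7L, tax, p = 0)
  expect_setequal(m_sp$matches$taxon, c(s2, s3))

  m_cl <- mask_novelty(pr, s1, 3L, tax, p = 0)
  expect_true(is_empty_profile(m_cl))

  # masked best 200 leaves survivors {150, 120}; p = 0.85 of 150 cuts the 120
  pr2 <- build_profile(data.frame(taxon = c(s1, s3, sp[5]),
                                  bitscore = c(200, 150, 120),
                                  evalue = c(1e-20, 1e-15, 1e-12)),
                       p = 0, source_id = "q2")
  m2 <- mask_novelty(pr2, s1, 7L, tax, p = 0.85)
  expect_identical(m2$matches$bitscore, 150)

  # property: no retained taxon shares the truth's ancestor at the mask depth
  set.seed(51)
  for (i in 1:15) {
    pr3 <- build_profile(random_hits(tax, 15), p = 0, source_id = "q3")
    d <- sample(4:7, 1)
    m3 <- mask_novelty(pr3, s1, d, tax, p = 0.6)
    if (is_empty_profile(m3)) next
    expect_false(any(ancestor_at(tax, m3$matches$taxon, d) ==
                       ancestor_at(tax, s1, d)))
  }
})

test_that("masking a reference set drops same-clade profiles entirely", {
  cfg <- sim_config(taxonomy_shape = c(2, 1, 1, 1, 1, 2, 2), seed = 3)
  w <- simulate_reference_world(cfg = cfg, p = 0)
  tax <- w$refs$taxonomy
  truth <- species_nodes(tax)[1]
  masked <- mask_reference_set(w$refs, truth, 7L, p = 0.85)
  src <- vapply(masked$profiles, function(pr) pr$source_taxon, "")
  expect_false(any(src == truth))
  expect_true(length(masked$profiles) < length(w$refs$profiles))
  # and surviving profiles contain no matches to the held-out species
  for (pr in masked$profiles) {
    expect_false(truth %in% pr$matches$taxon)
  }
})
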