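# Shared fixtures and the independent kernel oracle.

# Naive pyramid match: materializes the full 2D histogram at every level,
# binning each match by walking its parent chain (independent of the
# package's precomputed ancestor matrix and key-hashing implementation).
naive_pmk <- function(a, b, tax, h, evalue_floor = 1e-180) {
  norm <- function(pr) {
    x <- -log10(pmax(pr$matches$evalue, evalue_floor))
    rng <- range(x)
    p <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(1, length(x))
    list(taxon = pr$matches$taxon, pos = p)
  }
  walk_up <- function(taxon, d) {
    t <- taxon
    while (tax$depth[[t]] > d) t <- tax$parent[[t]]
    t
  }
  ga <- norm(a); gb <- norm(b)
  I <- numeric(h)
  for (i in seq_len(h)) {
    d <- h - i
    nb <- 2^(h - i)
    tb <- unique(c(vapply(ga$taxon, walk_up, "", d = d),
                   vapply(gb$taxon, walk_up, "", d = d)))
    A <- matrix(0L, length(tb), nb, dimnames = list(tb, NULL))
    B <- A
    for (k in seq_along(ga$taxon)) {
      e <- min(floor(ga$pos[k] * nb), nb - 1)
      r <- walk_up(ga$taxon[k], d)
      A[r, e + 1] <- A[r, e + 1] + 1L
    }
    for (k in seq_along(gb$taxon)) {
      e <- min(floor(gb$pos[k] * nb), nb - 1)
      r <- walk_up(gb$taxon[k], d)
      B[r, e + 1] <- B[r, e + 1] + 1L
    }
    I[i] <- sum(pmin(A, B))
  }
  list(I = I, score = sum(2^(1 - seq_len(h)) * I))
}

# Random profile over the non-root nodes of a taxonomy (exercises shallow
# lineages as well as species); taxa sampled without replacement so the
# profile size is exact after dedup.
random_profile <- function(tax, n, id = "q", p = 0) {
  pool <- setdiff(tax$id, tax$root)
  taxa <- sample(pool, min(n, length(pool)))
  hits <- data.frame(taxon = taxa,
                     bitscore = stats::runif(length(taxa), 50, 500),
                     evalue = 10^(-stats::runif(length(taxa), 3, 120)))
  build_profile(hits, p = p, source_id = id)
}

# Like random_profile but sampling taxa from a fixed pool (e.g. one domain's
# species only).
random_profile_from <- function(tax, pool, n, id = "q") {
  taxa <- sample(pool, min(n, length(pool)))
  hits <- data.frame(taxon = taxa,
                     bitscore = stats::runif(length(taxa), 50, 500),
                     evalue = 10^(-stats::runif(length(taxa), 3, 120)))
  build_profile(hits, p = 0, source_id = id)
}

# Random hit table (possibly with repeated taxa) for profile-construction
# properties.
random_hits <- function(tax, n) {
  pool <- setdiff(tax$id, tax$root)
  data.frame(taxon = sample(pool, n, replace = TRUE),
             bitscore = stats::runif(n, 50, 500),
             evalue = 10^(-stats::runif(n, 3, 120)))
}

toy8 <- function() make_toy_taxonomy(c(2, 1, 1, 1, 1, 2, 2))

write_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
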