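# Synthetic homology worlds: toy taxonomies, simulated BLAST hit tables whose
# bitscores decay with taxonomic distance from the true source, optional
# lateral-gene-transfer (LGT) confounders, and the small worked-example
# fixture used as the kernel's regression anchor.  Everything is a pure
# function of (configuration, seed), so the rest of the package is testable
# without external databases.

# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build a complete balanced toy taxonomy
#'
#' @param shape Integer vector of 7 branching factors, one per rank from
#'   domain down to species.  The number of species is `prod(shape)`.
#' @return A `"taxonomy"` over the canonical 8 ranks with deterministic ids
#'   (`"r"` for the root, then dot-separated child indices).
#' @export
#' @examples
#' tax <- make_toy_taxonomy(c(2, 1, 1, 1, 1, 2, 2))
#' length(species_nodes(tax))  # 2 * 2 * 2 = 8
make_toy_taxonomy <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 7L) {
    stop("shape must give 7 branching factors (domain ... species)")
  }
  if (any(is.na(shape)) || any(shape < 1L)) {
    stop("branching factors must be integers >= 1")
  }
  ranks <- canonical_ranks()
  id <- "r"; parent <- NA_character_; rank <- ranks[1L]
  level <- "r"
  for (d in seq_len(7L)) {
    kids <- unlist(lapply(level, function(p) paste0(p, ".", seq_len(shape[d]))),
                   use.names = FALSE)
    id <- c(id, kids)
    parent <- c(parent, rep(level, each = shape[d]))
    rank <- c(rank, rep(ranks[d + 1L], length(kids)))
    level <- kids
  }
  new_taxonomy(id, parent, rank)
}

#' Simulator configuration
#'
#' Defines the regime a protein BLAST search produces.  Every reference
#' species registers one hit whose bitscore decays with the taxonomic
#' distance of that species from the query's true source
#' (`depth(deeper node) - depth(their LCA)`):
#' \deqn{bitscore(s \to t) = base \times F(dist) \times e^{w_t - w_s}
#'   \times e^{\epsilon}}
#' where `F` is the decay profile, `w` is a per-species rate factor and
#' `epsilon` is per-hit jitter.  E-values derive monotonically from
#' bitscores (`e = 10^(-bitscore / evalue_k)`) so the two axes order hits
#' consistently, as real BLAST output does.
#'
#' `decay_per_rank` may be a single factor in (0, 1), giving geometric decay
#' `F(d) = decay^d`, or a strictly decreasing vector of 7 fractions for
#' distances 1-7.  The default is a saturating curve — high similarity
#' retained across congeners and confamilials, then a sharp drop — which is
#' how protein sequence similarity behaves (divergence saturates within
#' close clades and falls off steeply toward the twilight zone), and which
#' makes a p = 0.85 profile span roughly the family, as profiles from real
#' searches do.
#'
#' `species_rate_sd` models lineage-specific evolutionary rates: each
#' species draws one factor `w` per simulated world, applied to every hit it
#' receives in every profile (relative to the source's own rate, so a
#' sequence's self-hit is unaffected).  This is what makes match patterns
#' \emph{reproducible} across profiles from the same neighbourhood — the
#' property profile-matching classification exploits.  Per-hit `noise_sd`
#' is kept small: BLAST scores are near-deterministic given the sequences,
#' so most variation between profiles is structured, not white.
#'
#' With probability `lgt_rate` a species is marked as carrying a laterally
#' transferred gene from a fixed donor species in another domain; its queries
#' (and a fraction `lgt_ref_frac` of its reference proteins, which share the
#' same donor) then receive one anomalously strong hit at
#' `lgt_strength * bitscore_base`, inside the default p = 0.85 window.
#'
#' @param taxonomy_shape Branching factors per rank, domain to species (see
#'   [make_toy_taxonomy()]).
#' @param n_refs_per_species Reference proteins per species.
#' @param n_queries_per_species Query sequences per species.
#' @param bitscore_base Bitscore of a same-species (distance 0) hit.
#' @param decay_per_rank Bitscore fraction retained per rank of lineage
#'   distance: a single multiplicative factor in (0, 1), or a strictly
#'   decreasing length-7 vector of fractions for distances 1-7.
#' @param evalue_k Bitscore-to-e-value scale: `e = 10^(-bitscore / evalue_k)`.
#' @param species_rate_sd Log-sd of the per-species rate factor `w`
#'   (0 disables rate variation).
#' @param noise_sd Lognormal sdlog of the per-hit bitscore jitter
#'   (0 disables noise).
#' @param lgt_rate Probability a species carries the LGT confounder.
#' @param lgt_strength Donor-hit bitscore as a fraction of `bitscore_base`.
#' @param lgt_ref_frac Fraction of an affected species' reference proteins
#'   that share the same donor hit (rounded up).
#' @param seed Integer seed; every generated object is a pure function of the
#'   configuration and this seed.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(taxonomy_shape = c(2, 2, 1, 1, 2, 2, 2),
                       n_refs_per_species = 3L,
                       n_queries_per_species = 1L,
                       bitscore_base = 400,
                       decay_per_rank = c(0.96, 0.92, 0.70, 0.55,
                                          0.45, 0.35, 0.25),
                       evalue_k = 10,
                       species_rate_sd = 0.01,
                       noise_sd = 0.005,
                       lgt_rate = 0,
                       lgt_strength = 0.95,
                       lgt_ref_frac = 0.5,
                       seed = 1L) {
  cfg <- list(taxonomy_shape = as.integer(taxonomy_shape),
              n_refs_per_species = as.integer(n_refs_per_species),
              n_queries_per_species = as.integer(n_queries_per_species),
              bitscore_base = bitscore_base,
              decay_per_rank = decay_per_rank,
              evalue_k = evalue_k,
              species_rate_sd = species_rate_sd,
              noise_sd = noise_sd,
              lgt_rate = lgt_rate,
              lgt_strength = lgt_strength,
              lgt_ref_frac = lgt_ref_frac,
              seed = as.integer(seed))
  stopifnot(cfg$n_refs_per_species >= 1L, cfg$n_queries_per_species >= 0L,
            cfg$bitscore_base > 0, cfg$evalue_k > 0, cfg$noise_sd >= 0,
            cfg$species_rate_sd >= 0)
  dk <- cfg$decay_per_rank
  if (!(length(dk) %in% c(1L, 7L))) {
    stop("decay_per_rank must be a single factor or 7 per-distance fractions")
  }
  if (any(dk <= 0) || any(dk >= 1)) {
    stop("decay fractions must lie strictly inside (0, 1)")
  }
  if (length(dk) == 7L && any(diff(dk) >= 0)) {
    stop("a decay curve must be strictly decreasing with distance")
  }
  for (f in c("lgt_rate", "lgt_strength", "lgt_ref_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

# Decay fraction for integer distances 0..7.
decay_fraction <- function(cfg, dist) {
  dk <- cfg$decay_per_rank
  if (length(dk) == 1L) dk^dist else c(1, dk)[dist + 1L]
}

# Lineage distance from one species to every species in the taxonomy, via the
# shared ancestor matrix: the LCA depth of (s, t) is the number of leading
# columns on which their filled ancestor rows agree, minus one.
species_distances <- function(tax, true_species) {
  sp <- species_nodes(tax)
  m <- tax$anc[sp, , drop = FALSE]
  tr <- tax$anc[true_species, ]
  eq <- m == matrix(tr, nrow(m), length(tr), byrow = TRUE)
  lca_depth <- rowSums(eq) - 1L
  dmax <- length(tax$rank_order) - 1L
  structure(dmax - lca_depth, names = sp)
}

sim_hits_impl <- function(true_species, tax, cfg, donor = NULL, rates = NULL) {
  dist <- species_distances(tax, true_species)
  sp <- names(dist)
  noise <- if (cfg$noise_sd > 0) stats::rlnorm(length(sp), 0, cfg$noise_sd) else 1
  rel <- if (is.null(rates)) 1 else exp(rates[sp] - rates[[true_species]])
  bit <- cfg$bitscore_base * decay_fraction(cfg, dist) * rel * noise
  if (!is.null(donor) && !is.na(donor)) {
    dn <- if (cfg$noise_sd > 0) stats::rlnorm(1L, 0, cfg$noise_sd) else 1
    bit[match(donor, sp)] <- cfg$bitscore_base * cfg$lgt_strength * dn
  }
  order_matches(data.frame(taxon = sp, bitscore = unname(bit),
                           evalue = 10^(-unname(bit) / cfg$evalue_k),
                           stringsAsFactors = FALSE))
}

#' Simulate one sequence's homology hit table
#'
#' One hit per reference species; see [sim_config()] for the generating
#' model.  Reproducible: the same `(cfg, seed)` always yields the same table.
#'
#' @param true_species The species the sequence really comes from (a
#'   species-rank node of `tax`).
#' @param tax Taxonomy.
#' @param cfg A [sim_config()].
#' @param donor Optional donor species id for an LGT confounder hit.
#' @param seed Seed for this table (defaults to `cfg$seed`).
#' @return A data.frame of hits (`taxon`, `bitscore`, `evalue`), best first.
#' @export
simulate_hits <- function(true_species, tax, cfg = sim_config(), donor = NULL,
                          seed = cfg$seed) {
  stopifnot(inherits(tax, "taxonomy"), inherits(cfg, "sim_config"))
  true_species <- resolve_taxon(tax, true_species)
  leaf_rank <- tax$rank_order[length(tax$rank_order)]
  if (tax$rank[[true_species]] != leaf_rank) {
    stop("true_species must be a ", leaf_rank, "-rank node")
  }
  with_seed(seed, sim_hits_impl(true_species, tax, cfg, donor))
}

#' Simulate a complete reference world
#'
#' Generates, for every species in the taxonomy, `n_refs_per_species`
#' reference protein hit tables (all-versus-all style, each led by its
#' same-species self-hit) and `n_queries_per_species` query hit tables with
#' known truth.  Species drawn as LGT carriers (probability `lgt_rate`) get a
#' fixed donor from another domain; their queries and the first
#' `ceiling(lgt_ref_frac * n_refs_per_species)` of their reference proteins
#' all carry the \emph{same} donor hit, so confounded queries have reference
#' profiles that reflect the same evolutionary event.
#'
#' @param tax Taxonomy (defaults to a toy built from `cfg$taxonomy_shape`).
#' @param cfg A [sim_config()].
#' @param p Bitscore fraction used to build the reference profiles.
#' @return List with `refs` (a `"reference_set"`), `ref_hits` (raw reference
#'   hit tables), `queries` (named list of query hit tables), `truth`
#'   (data.frame `query_id`, `taxon`), `lgt_species` and `donors` (named by
#'   carrier species).
#' @export
simulate_reference_world <- function(tax = make_toy_taxonomy(cfg$taxonomy_shape),
                                     cfg = sim_config(), p = 0.85) {
  stopifnot(inherits(cfg, "sim_config"))
  force(tax)
  with_seed(cfg$seed, {
    sp <- species_nodes(tax)
    rates <- if (cfg$species_rate_sd > 0) {
      structure(stats::rnorm(length(sp), 0, cfg$species_rate_sd), names = sp)
    } else NULL
    affected <- stats::runif(length(sp)) < cfg$lgt_rate
    donors <- rep(NA_character_, length(sp))
    names(donors) <- sp
    if (any(affected)) {
      dom <- ancestor_at(tax, sp, 1L)
      for (i in which(affected)) {
        cand <- sp[dom != dom[i]]
        if (!length(cand)) {
          stop("LGT simulation needs at least two domains in the taxonomy")
        }
        donors[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      }
    }
    ref_hits <- list()
    query_hits <- list()
    truth_id <- character()
    truth_taxon <- character()
    for (i in seq_along(sp)) {
      s <- sp[i]
      n_confounded <- if (affected[i]) {
        ceiling(cfg$lgt_ref_frac * cfg$n_refs_per_species)
      } else 0L
      for (j in seq_len(cfg$n_refs_per_species)) {
        id <- paste0(s, "|ref", j)
        ref_hits[[id]] <- sim_hits_impl(s, tax, cfg,
                                        donor = if (j <= n_confounded) donors[[i]],
                                        rates = rates)
      }
      for (j in seq_len(cfg$n_queries_per_species)) {
        id <- paste0(s, "|q", j)
        query_hits[[id]] <- sim_hits_impl(s, tax, cfg,
                                          donor = if (affected[i]) donors[[i]],
                                          rates = rates)
        truth_id <- c(truth_id, id)
        truth_taxon <- c(truth_taxon, s)
      }
    }
    source_taxa <- structure(sub("\\|ref\\d+$", "", names(ref_hits)),
                             names = names(ref_hits))
    refs <- build_reference_set(ref_hits, source_taxa, p, tax)
    list(refs = refs,
         ref_hits = ref_hits,
         queries = query_hits,
         truth = data.frame(query_id = truth_id, taxon = truth_taxon,
                            stringsAsFactors = FALSE),
         lgt_species = sp[affected],
         donors = donors[affected],
         rates = rates)
  })
}

#' Worked-example kernel fixture
#'
#' A reduced 4-rank taxonomy (root at "order") and two 3-match profiles
#' ("star" and "circle") arranged so the kernel's per-iteration total
#' intersection counts are exactly (0, 1, 2, 3): no pair of matches shares a
#' species-level 2D bin; exactly one pair co-bins at genus; two pairs at
#' family; and all three in the single root-level bin.  With weights
#' (1, 1/2, 1/4, 1/8) the cumulative similarity is 0.5 after iteration 2,
#' 1.0 after iteration 3 and 1.375 overall.  Serves as the kernel's
#' regression anchor; its score must never drift.
#'
#' @return List with profiles `a` ("star") and `b` ("circle"), `taxonomy`
#'   (4 ranks) and `h = 4`.
#' @export
#' @examples
#' fx <- pmk_example_fixture()
#' res <- pmk_score(fx$a, fx$b, fx$taxonomy, pmk_config(h = fx$h))
#' res$score                        # 1.375
#' res$per_iteration$intersections  # 0 1 2 3
pmk_example_fixture <- function() {
  rank_order <- c("order", "family", "genus", "species")
  id <- c("o1",
          "f1", "f2", "f3",
          "g11", "g12", "g13", "g21", "g31",
          "s111", "s112", "s121", "s131", "s211", "s311")
  parent <- c(NA,
              "o1", "o1", "o1",
              "f1", "f1", "f1", "f2", "f3",
              "g11", "g11", "g12", "g13", "g21", "g31")
  rank <- c("order", rep("family", 3L), rep("genus", 5L), rep("species", 6L))
  tax <- new_taxonomy(id, parent, rank, rank_order = rank_order)
  star <- build_profile(
    data.frame(taxon = c("s111", "s121", "s211"),
               bitscore = c(100, 80, 60),
               evalue = c(1e-10, 1e-6, 1e-2)),
    p = 0, source_id = "star")
  circle <- build_profile(
    data.frame(taxon = c("s112", "s131", "s311"),
               bitscore = c(100, 80, 60),
               evalue = c(1e-10, 1e-6, 1e-2)),
    p = 0, source_id = "circle")
  list(a = star, b = circle, taxonomy = tax, h = 4L)
}
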