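# Rank-flexible taxonomic assignment: the profile-matching classifier plus
# the MEGAN-style LCA and best-BLAST baselines.  A root assignment is the
# explicit "unclassified" representation.

new_assignment <- function(query_id, taxon, tax, method, support = NULL,
                           y_used = NA_real_, p_used = NA_real_,
                           best_score = NA_real_, note = NA_character_) {
  taxon <- resolve_taxon(tax, taxon)
  lin <- lineage(tax, taxon)
  structure(
    list(query_id = query_id,
         assigned_taxon = taxon,
         assigned_depth = unname(tax$depth[[taxon]]),
         assigned_rank = unname(tax$rank[[taxon]]),
         lineage_string = paste(lin$taxon, collapse = ";"),
         method = method,
         support = support,
         y_used = y_used, p_used = p_used,
         best_score = best_score,
         note = note),
    class = "taxon_assignment"
  )
}

root_assignment <- function(query_id, tax, method, note, ...) {
  new_assignment(query_id, tax$root, tax, method, note = note, ...)
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(x$method, " assignment for '", x$query_id, "': ", x$assigned_taxon,
      " (", x$assigned_rank, ", depth ", x$assigned_depth, ")\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  if (!is.null(x$support) && nrow(x$support)) {
    cat("  support: ", nrow(x$support), " reference(s), best score ",
        format(x$best_score), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.taxon_assignment <- function(x, ...) {
  data.frame(query_id = x$query_id,
             method = x$method,
             assigned_taxon = x$assigned_taxon,
             assigned_rank_name = x$assigned_rank,
             assigned_depth = x$assigned_depth,
             lineage = x$lineage_string,
             n_support = if (is.null(x$support)) 0L else nrow(x$support),
             best_score = x$best_score,
             y = x$y_used,
             p = x$p_used,
             stringsAsFactors = FALSE)
}

#' Profile-matching assignment (pyramid-match classifier)
#'
#' Scores the query profile against every reference profile with the pyramid
#' match kernel, retains references whose score is at least `y` times the best
#' score (inclusive boundary, mirroring the `p` threshold), and assigns the
#' lowest common ancestor of the retained references' source taxa, truncated
#' to `max_depth`.
#'
#' An empty query profile, or a best score of zero, yields a root
#' ("unclassified") assignment with an explanatory note.
#'
#' @param q Query `"lca_profile"`.
#' @param refs A non-empty `"reference_set"`.
#' @param y Score fraction in `[0, 1]` (default 0.95).
#' @param cfg A [pmk_config()]; defaults to the reference taxonomy's rank
#'   count.
#' @param max_depth Deepest rank an assignment may take (default 6, genus).
#' @return A `"taxon_assignment"`; its `support` lists the retained
#'   references and their scores.
#' @export
spanner_assign <- function(q, refs, y = 0.95,
                           cfg = pmk_config(length(refs$taxonomy$rank_order)),
                           max_depth = 6L) {
  stopifnot(inherits(refs, "reference_set"))
  if (!length(refs$profiles)) stop("empty reference set")
  if (y < 0 || y > 1) stop("y must lie in [0, 1]")
  tax <- refs$taxonomy
  if (is_empty_profile(q)) {
    return(root_assignment(q$source_id, tax, "spanner",
                           note = "empty query profile",
                           y_used = y, p_used = q$p_used))
  }
  sc <- score_against_references(q, refs, cfg)
  best <- sc$score[1L]
  if (best <= 0) {
    return(root_assignment(q$source_id, tax, "spanner",
                           note = "no informative match (best score 0)",
                           y_used = y, p_used = q$p_used, best_score = 0))
  }
  retained <- sc[sc$score >= y * best, , drop = FALSE]
  assigned <- truncate_taxon(tax, lca(tax, retained$source_taxon), max_depth)
  new_assignment(q$source_id, assigned, tax, "spanner", support = retained,
                 y_used = y, p_used = q$p_used, best_score = best)
}

#' MEGAN-style lowest-common-ancestor assignment
#'
#' Assigns the lowest common ancestor of all taxa in the query's LCA Profile
#' (which was built within the bitscore fraction `p` of the best hit),
#' truncated to `max_depth`.  An empty profile yields a root assignment.
#'
#' @param q Query `"lca_profile"`, built with the desired `p`.
#' @param tax Taxonomy.
#' @param max_depth Deepest rank an assignment may take (default 6, genus).
#' @return A `"taxon_assignment"`.
#' @export
lca_assign <- function(q, tax, max_depth = 6L) {
  stopifnot(inherits(tax, "taxonomy"))
  if (is_empty_profile(q)) {
    return(root_assignment(q$source_id, tax, "lca",
                           note = "empty query profile", p_used = q$p_used))
  }
  assigned <- truncate_taxon(tax, lca(tax, q$matches$taxon), max_depth)
  support <- data.frame(source_id = q$matches$taxon,
                        score = q$matches$bitscore,
                        stringsAsFactors = FALSE)
  new_assignment(q$source_id, assigned, tax, "lca", support = support,
                 p_used = q$p_used, best_score = q$matches$bitscore[1L])
}

#' Best-BLAST assignment
#'
#' Assigns the taxon of the single top-bitscore hit (ties broken by ascending
#' e-value then lexicographic taxon id), truncated to `max_depth`; by default
#' all predictions are interpreted at a minimum rank of genus.  A rank-fixed
#' baseline: confidently wrong when the best hit is a confounded (e.g.
#' laterally transferred) match.
#'
#' @param hits A data.frame of hits with columns `taxon`, `bitscore`,
#'   `evalue`; may be `NULL` or empty, which yields a root assignment.
#' @param tax Taxonomy.
#' @param max_depth Deepest rank an assignment may take (default 6, genus).
#' @param query_id Identifier carried on the assignment.
#' @return A `"taxon_assignment"`.
#' @export
best_blast_assign <- function(hits, tax, max_depth = 6L,
                              query_id = NA_character_) {
  stopifnot(inherits(tax, "taxonomy"))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(root_assignment(query_id, tax, "best-blast", note = "no hits"))
  }
  m <- order_matches(hits[, c("taxon", "bitscore", "evalue"), drop = FALSE])
  top <- m[1L, ]
  assigned <- truncate_taxon(tax, top$taxon, max_depth)
  support <- data.frame(source_id = top$taxon, score = top$bitscore,
                        stringsAsFactors = FALSE)
  new_assignment(query_id, assigned, tax, "best-blast", support = support,
                 best_score = top$bitscore)
}

#' Classify a batch of queries
#'
#' Runs one method over a map of query hit tables and returns one row per
#' query, in input order, using the package's standard assignment schema.
#'
#' @param queries Named list of per-query hit data.frames (columns `taxon`,
#'   `bitscore`, `evalue`), e.g. the `hits` element of [parse_blast_tab()].
#' @param method `"spanner"`, `"lca"` or `"best-blast"`.
#' @param refs A `"reference_set"`; required for `"spanner"`.
#' @param tax Taxonomy; defaults to the reference set's.
#' @param p Bitscore fraction used to build each query's profile (default
#'   0.85).  Ignored by `"best-blast"`, which uses the raw hits.
#' @param y Score fraction for `"spanner"` (default 0.95).
#' @param cfg A [pmk_config()]; defaults to the taxonomy's rank count.
#' @param max_depth Deepest rank an assignment may take (default 6, genus).
#' @return A data.frame with columns `query_id`, `method`, `assigned_taxon`,
#'   `assigned_rank_name`, `assigned_depth`, `lineage`, `n_support`,
#'   `best_score`, `y`, `p`.
#' @export
classify_batch <- function(queries, method = c("spanner", "lca", "best-blast"),
                           refs = NULL, tax = refs$taxonomy, p = 0.85,
                           y = 0.95, cfg = NULL, max_depth = 6L) {
  method <- match.arg(method)
  if (method == "spanner" && is.null(refs)) {
    stop("method 'spanner' requires a reference set")
  }
  if (is.null(tax)) stop("a taxonomy is required (directly or via refs)")
  if (is.null(cfg)) cfg <- pmk_config(length(tax$rank_order))
  if (!length(queries)) {
    return(data.frame(query_id = character(), method = character(),
                      assigned_taxon = character(),
                      assigned_rank_name = character(),
                      assigned_depth = integer(), lineage = character(),
                      n_support = integer(), best_score = numeric(),
                      y = numeric(), p = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(queries), function(id) {
    hits <- queries[[id]]
    a <- switch(method,
      "best-blast" = best_blast_assign(hits, tax, max_depth, id),
      "lca" = lca_assign(build_profile(hits, p, id), tax, max_depth),
      "spanner" = spanner_assign(build_profile(hits, p, id), refs, y, cfg,
                                 max_depth))
    as.data.frame(a)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
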