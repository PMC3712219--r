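# Ordinal evaluation of rank-flexible assignments.
#
# Every rank is an ordinal 0 (root, effectively unclassified) .. 7 (species).
# For a prediction: precision = number of ranks assigned (the assigned
# depth); correct = deepest depth at which the assigned lineage still agrees
# with the truth lineage (their longest common prefix, i.e. the depth of
# their LCA); incorrect = precision - correct.  A sequence assigned at genus
# but accurate only to class is thus partially correct (3 ranks) and
# partially incorrect (3 ranks).  Assignments deeper than a novelty-capped
# target count the excess depths as incorrect rather than being truncated,
# which is what lets a rank-fixed baseline be "too precise".

#' Score one assignment against the known truth
#'
#' @param a A `"taxon_assignment"`.
#' @param truth_taxon The query's true source taxon.
#' @param tax Taxonomy.
#' @return One-row data.frame: `query_id`, `method`, `precision`, `correct`,
#'   `incorrect` (always exactly `precision - correct`).
#' @export
score_assignment <- function(a, truth_taxon, tax) {
  stopifnot(inherits(a, "taxon_assignment"), inherits(tax, "taxonomy"))
  precision <- a$assigned_depth
  common <- lca(tax, c(a$assigned_taxon, truth_taxon))
  correct <- unname(tax$depth[[common]])
  data.frame(query_id = a$query_id, method = a$method,
             precision = precision, correct = correct,
             incorrect = precision - correct,
             stringsAsFactors = FALSE)
}

#' Summarize evaluation records
#'
#' Arithmetic means per method.  The identity
#' `mean_correct = mean_precision - mean_incorrect` holds exactly.
#'
#' @param records A data.frame of [score_assignment()] rows (any number of
#'   methods).
#' @param target_depth Optional target rank depth; adds
#'   `mean_ranks_above_target = target_depth - mean_precision` (e.g. "ranks
#'   above genus" for target 6).
#' @return A data.frame with one row per method: `method`, `n`,
#'   `mean_precision`, `mean_correct`, `mean_incorrect` and optionally
#'   `mean_ranks_above_target`.
#' @export
summarize_eval <- function(records, target_depth = NULL) {
  if (is.null(records) || nrow(records) == 0L) stop("no evaluation records")
  sp <- split(records, records$method)
  out <- do.call(rbind, lapply(names(sp), function(m) {
    r <- sp[[m]]
    data.frame(method = m, n = nrow(r),
               mean_precision = mean(r$precision),
               mean_correct = mean(r$correct),
               mean_incorrect = mean(r$incorrect),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(target_depth)) {
    out$mean_ranks_above_target <- target_depth - out$mean_precision
  }
  rownames(out) <- NULL
  out
}

#' Leave-one-out taxonomic novelty experiment
#'
#' Treats reference profiles as queries with known truth and simulates
#' taxonomic novelty: for each query, all matches to taxa sharing the truth's
#' ancestor at `novelty_depth` are removed from both the query profile and
#' every reference profile, reference profiles whose source shares that
#' ancestor are dropped entirely, and the `p` threshold is applied \emph{after}
#' masking, relative to the best surviving match.  Build `refs` with `p = 0`
#' (full match lists) and pass the working `p` here, so that matches below
#' the unmasked threshold can rejoin once the stronger same-clade matches are
#' gone — that is what removing a clade from the database does to a real
#' search.  Assignments are capped at `novelty_depth - 1` (genus for
#' species-level novelty, and so on) since deeper ranks cannot be correct;
#' deeper assignments would count their excess ranks as incorrect.
#'
#' @param refs A `"reference_set"` whose source lineages all reach
#'   `novelty_depth`; ideally built with `p = 0` (see above).
#' @param novelty_depth Ordinal depth of the simulated novelty (7 = species,
#'   6 = genus, 3 = class); must be at least 1.
#' @param methods Subset of `c("spanner", "lca", "best-blast")`.
#' @param p Bitscore fraction applied after masking (defaults to the
#'   reference set's own).
#' @param y Score fraction for the profile-matching classifier.
#' @param cfg A [pmk_config()]; defaults to the taxonomy's rank count.
#' @param query_ids Which reference profiles to use as queries (default all).
#' @return List with `records` (per query x method, including the truth and
#'   assigned taxon) and `summary` (per method, via [summarize_eval()] with
#'   the capped depth as target).
#' @export
leave_one_out_experiment <- function(refs, novelty_depth,
                                     methods = c("spanner", "lca", "best-blast"),
                                     p = refs$p, y = 0.95, cfg = NULL,
                                     query_ids = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  methods <- match.arg(methods, several.ok = TRUE)
  if (novelty_depth < 1L) stop("novelty rank must be below the root")
  tax <- refs$taxonomy
  if (is.null(cfg)) cfg <- pmk_config(length(tax$rank_order))
  if (is.null(query_ids)) query_ids <- names(refs$profiles)
  max_depth <- novelty_depth - 1L
  rows <- vector("list", length(query_ids) * length(methods))
  k <- 0L
  for (id in query_ids) {
    q0 <- refs$profiles[[id]]
    if (is.null(q0)) stop("unknown reference profile: ", id)
    truth <- q0$source_taxon
    qm <- mask_novelty(q0, truth, novelty_depth, tax, p = p)
    refs_m <- mask_reference_set(refs, truth, novelty_depth, p = p)
    for (m in methods) {
      a <- if (is_empty_profile(qm) ||
               (m == "spanner" && !length(refs_m$profiles))) {
        root_assignment(id, tax, m, note = "nothing informative after masking")
      } else {
        switch(m,
          "spanner" = spanner_assign(qm, refs_m, y, cfg, max_depth),
          "lca" = lca_assign(qm, tax, max_depth),
          "best-blast" = best_blast_assign(qm$matches, tax, max_depth, id))
      }
      rec <- score_assignment(a, truth, tax)
      rec$truth <- truth
      rec$assigned_taxon <- a$assigned_taxon
      k <- k + 1L
      rows[[k]] <- rec
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records,
       summary = summarize_eval(records, target_depth = max_depth))
}
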