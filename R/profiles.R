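# LCA Profiles: p-thresholded, best-hit-per-taxon sets of homology matches.
#
# A profile keeps, per matched taxon, only the best hit (by bitscore), then
# discards matches whose bitscore falls below p * the best bitscore in the
# profile.  Dedup happens before thresholding so a taxon's weaker secondary
# hits never influence the threshold.  The boundary is inclusive: a match at
# exactly p * best is kept.

#' Empty LCA Profile sentinel
#'
#' Represents a sequence with no usable homology matches; classified
#' downstream as unassigned (root).
#'
#' @param source_id Sequence identifier.
#' @param source_taxon Known source taxon, or `NA` for environmental queries.
#' @param p The bitscore fraction that was in effect.
#' @return An `"lca_profile"` with zero matches.
#' @export
empty_profile <- function(source_id = NA_character_,
                          source_taxon = NA_character_, p = NA_real_) {
  structure(
    list(source_id = source_id, source_taxon = source_taxon,
         matches = data.frame(taxon = character(), bitscore = numeric(),
                              evalue = numeric(), stringsAsFactors = FALSE),
         p_used = p),
    class = "lca_profile"
  )
}

#' Is a profile the empty sentinel?
#'
#' @param x An `"lca_profile"`.
#' @return `TRUE` when the profile has no matches.
#' @export
is_empty_profile <- function(x) {
  stopifnot(inherits(x, "lca_profile"))
  nrow(x$matches) == 0L
}

# Deterministic match order: bitscore descending, ties by ascending e-value,
# then lexicographic taxon id.
order_matches <- function(m) {
  m <- m[order(-m$bitscore, m$evalue, m$taxon), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Build an LCA Profile from homology hits
#'
#' Reduces the hits to the best hit per taxon (highest bitscore, ties broken
#' by ascending e-value then taxon id), then discards matches with bitscore
#' below `p` times the best retained bitscore.  The boundary is inclusive:
#' `bitscore >= p * best` is kept.
#'
#' @param hits A data.frame with columns `taxon`, `bitscore`, `evalue` (one
#'   row per hit; extra columns are ignored).
#' @param p Bitscore fraction in `[0, 1]`.
#' @param source_id Sequence identifier carried on the profile.
#' @param source_taxon Known source taxon (references) or `NA` (queries).
#' @return An `"lca_profile"`; the [empty_profile()] sentinel when `hits` has
#'   no rows.
#' @export
#' @examples
#' hits <- data.frame(taxon = c("a", "b", "c"),
#'                    bitscore = c(100, 90, 80),
#'                    evalue = c(1e-30, 1e-25, 1e-20))
#' build_profile(hits, p = 0.85)$matches   # the 80 falls below 85 and is cut
build_profile <- function(hits, p, source_id = NA_character_,
                          source_taxon = NA_character_) {
  stopifnot(is.numeric(p) || is.na(p))
  if (!is.na(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  if (is.null(hits) || nrow(hits) == 0L) {
    return(empty_profile(source_id, source_taxon, p))
  }
  m <- order_matches(hits[, c("taxon", "bitscore", "evalue"), drop = FALSE])
  m <- m[!duplicated(m$taxon), , drop = FALSE]
  m <- m[m$bitscore >= p * m$bitscore[1L], , drop = FALSE]
  rownames(m) <- NULL
  structure(
    list(source_id = source_id, source_taxon = source_taxon,
         matches = m, p_used = p),
    class = "lca_profile"
  )
}

#' @export
print.lca_profile <- function(x, ...) {
  cat("LCA Profile '", x$source_id, "'", sep = "")
  if (!is.na(x$source_taxon)) cat(" (source taxon ", x$source_taxon, ")", sep = "")
  cat(": ", nrow(x$matches), " match(es), p = ", x$p_used, "\n", sep = "")
  if (nrow(x$matches)) print(utils::head(x$matches, 10L))
  invisible(x)
}

# Accept either a named character vector or a two-column data.frame
# (subject_id, taxon_id).
as_taxon_map <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("taxon map data.frame needs 2 columns (subject, taxon)")
    return(structure(as.character(x[[2L]]), names = as.character(x[[1L]])))
  }
  x <- vapply(x, as.character, "")
  if (is.null(names(x)) && length(x)) stop("taxon map vector must be named by subject id")
  x
}

#' Parse a BLAST tabular hit file
#'
#' Reads an outfmt-6-style tab-separated file and groups hits by query.
#' Subject ids are translated to taxon ids through `taxon_map`; hits whose
#' subject is absent from the map are dropped and counted.
#'
#' @param path Path to the tabular file.  Blank lines and lines starting with
#'   `#` are skipped.
#' @param taxon_map Named character vector (or 2-column data.frame) mapping
#'   subject id to taxon id; see [read_taxon_map()].
#' @param columns Named integer vector giving the 1-based positions of the
#'   `qseqid`, `sseqid`, `evalue` and `bitscore` fields.  The default matches
#'   BLAST `-outfmt 6`'s standard 12-column order.
#' @return A list with `hits` (named list of per-query data.frames with
#'   columns `taxon`, `bitscore`, `evalue`, `subject`, queries in file order)
#'   and `n_dropped` (hits dropped for unmapped subjects).  An empty file
#'   yields an empty `hits` list.
#' @export
parse_blast_tab <- function(path, taxon_map,
                            columns = c(qseqid = 1L, sseqid = 2L,
                                        evalue = 11L, bitscore = 12L)) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  stopifnot(all(c("qseqid", "sseqid", "evalue", "bitscore") %in% names(columns)))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  idx <- which(keep)
  if (!length(idx)) return(list(hits = list(), n_dropped = 0L))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  need <- max(columns)
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad)) {
    stop("malformed BLAST line ", idx[bad[1L]], ": expected at least ", need,
         " tab-separated fields, found ", nf[bad[1L]])
  }
  pick <- function(k) vapply(fields, `[[`, "", columns[[k]])
  q <- pick("qseqid")
  s <- pick("sseqid")
  ev <- suppressWarnings(as.numeric(pick("evalue")))
  bs <- suppressWarnings(as.numeric(pick("bitscore")))
  if (anyNA(ev)) {
    stop("malformed BLAST line ", idx[which(is.na(ev))[1L]], ": non-numeric e-value")
  }
  if (anyNA(bs)) {
    stop("malformed BLAST line ", idx[which(is.na(bs))[1L]], ": non-numeric bitscore")
  }
  tm <- as_taxon_map(taxon_map)
  taxon <- unname(tm[s])
  dropped <- is.na(taxon)
  n_dropped <- sum(dropped)
  if (n_dropped) {
    message("parse_blast_tab: dropped ", n_dropped,
            " hit(s) whose subject is absent from the taxon map")
  }
  df <- data.frame(taxon = taxon[!dropped], bitscore = bs[!dropped],
                   evalue = ev[!dropped], subject = s[!dropped],
                   stringsAsFactors = FALSE)
  qk <- q[!dropped]
  hits <- split(df, factor(qk, levels = unique(qk)))
  list(hits = hits, n_dropped = n_dropped)
}

#' Read a subject-to-taxon map
#'
#' Tab-separated, two columns `subject_id<TAB>taxon_id`, no header.
#'
#' @param path Path to the TSV.
#' @return Named character vector, subject id -> taxon id.
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxon map must have 2 tab-separated columns")
  structure(df[[2L]], names = df[[1L]])
}

#' Build reference LCA Profiles from an all-versus-all search
#'
#' One profile per reference sequence.  Self-hits are retained: they define
#' the best bitscore against which the `p` threshold is applied.
#'
#' @param hits Named list of per-sequence hit data.frames (columns `taxon`,
#'   `bitscore`, `evalue`), e.g. the `hits` element of [parse_blast_tab()] run
#'   on an all-versus-all search.
#' @param source_taxa Named character vector (or 2-column data.frame) mapping
#'   each reference sequence id to its source taxon.
#' @param p Bitscore fraction (default 0.85).
#' @param tax Taxonomy used to validate source taxa.
#' @return A `"reference_set"`: list of profiles plus the `p` and taxonomy
#'   used to build them.
#' @export
build_reference_set <- function(hits, source_taxa, p = 0.85, tax) {
  stopifnot(inherits(tax, "taxonomy"))
  source_taxa <- as_taxon_map(source_taxa)
  ids <- names(hits)
  if (is.null(ids)) stop("hits must be a named list keyed by reference sequence id")
  profiles <- vector("list", length(ids))
  names(profiles) <- ids
  skipped <- character()
  for (id in ids) {
    if (!(id %in% names(source_taxa))) {
      stop("reference sequence '", id, "' has no source taxon in the map")
    }
    st <- source_taxa[[id]]
    resolve_taxon(tax, st)  # errors on unresolvable source taxa
    pr <- build_profile(hits[[id]], p, id, st)
    if (is_empty_profile(pr)) {
      skipped <- c(skipped, id)
      profiles[[id]] <- NULL
    } else {
      profiles[[id]] <- pr
    }
  }
  if (length(skipped)) {
    warning("skipped reference sequence(s) with no usable hits: ",
            paste(skipped, collapse = ", "))
    profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  }
  structure(list(profiles = profiles, p = p, taxonomy = tax),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("Reference set: ", length(x$profiles), " LCA Profiles (p = ", x$p,
      ") over a ", length(x$taxonomy$id), "-node taxonomy\n", sep = "")
  invisible(x)
}

#' Mask a profile for a leave-one-out novelty experiment
#'
#' Removes every match whose taxon shares the truth lineage's ancestor at
#' `novelty_depth` (e.g. all same-species matches for species-level novelty),
#' then re-applies the `p` threshold relative to the new best bitscore.
#' Masking precedes thresholding, so matches that fell below the original
#' threshold can never re-enter, but the threshold itself drops with the new
#' best hit.
#'
#' @param profile An `"lca_profile"`.
#' @param truth_taxon The query's true source taxon; its lineage must reach
#'   `novelty_depth`.
#' @param novelty_depth Ordinal rank depth of the simulated novelty
#'   (7 = species, 6 = genus, 3 = class, ...).
#' @param tax Taxonomy.
#' @param p Bitscore fraction re-applied after masking (defaults to the
#'   profile's own).
#' @return An `"lca_profile"`; the empty sentinel when every match is masked.
#' @export
mask_novelty <- function(profile, truth_taxon, novelty_depth, tax,
                         p = profile$p_used) {
  stopifnot(inherits(profile, "lca_profile"))
  if (taxon_depth(tax, truth_taxon) < novelty_depth) {
    stop("truth lineage does not reach the novelty rank (depth ",
         novelty_depth, ")")
  }
  if (is_empty_profile(profile)) {
    return(empty_profile(profile$source_id, profile$source_taxon, p))
  }
  anc_truth <- ancestor_at(tax, truth_taxon, novelty_depth)
  anc_m <- ancestor_at(tax, profile$matches$taxon, novelty_depth)
  kept <- profile$matches[anc_m != anc_truth, , drop = FALSE]
  build_profile(kept, p, profile$source_id, profile$source_taxon)
}

#' Mask a reference set for a leave-one-out novelty experiment
#'
#' Reference profiles originating from a taxon that shares the truth's
#' novelty-rank ancestor are dropped entirely (a genome absent from the
#' database contributes no profiles); the remaining profiles have their
#' matches masked with [mask_novelty()] and re-thresholded at `p`.
#'
#' For a faithful novelty simulation the incoming reference set should hold
#' full match lists (built with `p = 0`), with the working `p` passed here:
#' masking precedes thresholding, so the threshold is taken relative to the
#' best match that survives the mask.
#'
#' @param refs A `"reference_set"`.
#' @param p Bitscore fraction applied after masking (defaults to the
#'   reference set's own).
#' @inheritParams mask_novelty
#' @return A masked `"reference_set"` (possibly with fewer profiles).
#' @export
mask_reference_set <- function(refs, truth_taxon, novelty_depth, p = refs$p) {
  stopifnot(inherits(refs, "reference_set"))
  tax <- refs$taxonomy
  anc_truth <- ancestor_at(tax, truth_taxon, novelty_depth)
  keep <- vapply(refs$profiles, function(pr) {
    ancestor_at(tax, pr$source_taxon, novelty_depth) != anc_truth
  }, logical(1))
  masked <- lapply(refs$profiles[keep], mask_novelty,
                   truth_taxon = truth_taxon, novelty_depth = novelty_depth,
                   tax = tax, p = p)
  masked <- Filter(Negate(is_empty_profile), masked)
  structure(list(profiles = masked, p = p, taxonomy = tax),
            class = "reference_set")
}
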