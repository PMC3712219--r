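# Ranked taxonomy: construction, canonicalization, lineage and LCA queries.
#
# The whole pipeline works on a fixed ordinal rank scale.  Every rank is an
# integer depth, 0 at the root ("cellular organisms", effectively unclassified)
# down to 7 (species).  Non-canonical ranks (strain, subspecies, "no rank"
# intermediates...) are collapsed onto their nearest canonical ancestor at load
# time, so downstream grids and metrics always see at most 8 levels.

CANONICAL_RANKS <- c("cellular organisms", "domain", "phylum", "class",
                     "order", "family", "genus", "species")

#' Canonical taxonomic ranks
#'
#' The fixed eight-rank scale used throughout the package, ordered from the
#' root (depth 0, \code{"cellular organisms"}) to the leaves (depth 7,
#' \code{"species"}).  A taxon's \emph{depth} is its position on this scale.
#'
#' @return Character vector of the 8 rank names, root first.
#' @export
#' @examples
#' canonical_ranks()
canonical_ranks <- function() CANONICAL_RANKS

#' Construct a taxonomy
#'
#' Low-level constructor used by [load_taxonomy()] and [make_toy_taxonomy()].
#' Validates the tree structure: exactly one root (its parent is `NA`), every
#' rank drawn from `rank_order`, and every parent strictly shallower than its
#' child (which also rules out cycles).
#'
#' @param id Character vector of taxon ids (opaque strings; numeric NCBI
#'   taxids and synthetic names are both legal).
#' @param parent Parent taxon id for each node; `NA` for the root.
#' @param rank Rank name for each node, drawn from `rank_order`.
#' @param name Display name for each node (defaults to the id).
#' @param rank_order Rank names from root to leaf.  Defaults to the canonical
#'   8 ranks; shorter hierarchies are allowed for reduced worked examples.
#' @param alias Named character vector mapping collapsed (non-canonical) taxon
#'   ids onto the id of their nearest canonical ancestor.
#' @return An object of class `"taxonomy"`.
#' @seealso [load_taxonomy()], [lineage()], [lca()]
#' @export
new_taxonomy <- function(id, parent, rank, name = id,
                         rank_order = canonical_ranks(),
                         alias = character()) {
  id <- as.character(id)
  parent <- as.character(parent)
  rank <- as.character(rank)
  name <- as.character(name)
  n <- length(id)
  stopifnot(length(parent) == n, length(rank) == n, length(name) == n)
  if (n == 0L) stop("taxonomy must contain at least a root node")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate taxon id(s): ", paste(unique(dup), collapse = ", "))
  depth <- match(rank, rank_order) - 1L
  if (anyNA(depth)) {
    stop("rank(s) outside the declared rank order: ",
         paste(unique(rank[is.na(depth)]), collapse = ", "))
  }
  root <- id[is.na(parent)]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (found ", length(root), ")")
  }
  if (depth[match(root, id)] != 0L) {
    stop("root node must have rank '", rank_order[1L], "'")
  }
  miss <- setdiff(parent[!is.na(parent)], id)
  if (length(miss)) stop("unknown parent id(s): ", paste(miss, collapse = ", "))
  names(parent) <- names(rank) <- names(name) <- names(depth) <- id
  child <- id[!is.na(parent)]
  bad <- child[depth[parent[child]] >= depth[child]]
  if (length(bad)) {
    stop("parent must be strictly shallower than its child; violated at taxon ",
         bad[1L])
  }
  h <- length(rank_order)
  # anc[t, d+1] = deepest node on t's root-to-t path whose depth is <= d.
  # Always defined (the root qualifies at every d); equals t itself for
  # d >= depth(t).  Shared by LCA, truncation and PMK binning.
  anc <- matrix(NA_character_, n, h, dimnames = list(id, rank_order))
  for (t in id[order(depth)]) {
    d <- depth[[t]]
    if (is.na(parent[[t]])) {
      anc[t, ] <- t
    } else {
      anc[t, ] <- c(anc[parent[[t]], seq_len(d)], rep(t, h - d))
    }
  }
  if (length(alias)) {
    if (is.null(names(alias)) || anyNA(names(alias))) stop("alias must be named")
    tgt <- setdiff(alias, id)
    if (length(tgt)) stop("alias target(s) not in taxonomy: ", paste(tgt, collapse = ", "))
  }
  structure(
    list(id = id, parent = parent, rank = rank, name = name, depth = depth,
         rank_order = rank_order, anc = anc, alias = alias, root = root),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy: ", length(x$id), " nodes over ", length(x$rank_order),
      " ranks (", x$rank_order[1L], " ... ", x$rank_order[length(x$rank_order)],
      ")\n", sep = "")
  tab <- table(factor(x$rank, levels = x$rank_order))
  for (r in x$rank_order) cat(sprintf("  %-18s %d\n", r, tab[[r]]))
  if (length(x$alias)) cat("  (+", length(x$alias), "collapsed non-canonical nodes)\n")
  invisible(x)
}

#' Resolve taxon ids, following collapse aliases
#'
#' Maps ids of collapsed non-canonical nodes (e.g. strains) onto their nearest
#' canonical ancestor; canonical ids pass through unchanged.
#'
#' @param tax A [new_taxonomy()] object.
#' @param taxa Character vector of taxon ids.
#' @return Character vector of canonical taxon ids.
#' @export
resolve_taxon <- function(tax, taxa) {
  taxa <- as.character(taxa)
  out <- taxa
  out[!(taxa %in% tax$id)] <- NA_character_
  if (anyNA(out) && length(tax$alias)) {
    i <- is.na(out)
    out[i] <- unname(tax$alias[taxa[i]])
  }
  if (anyNA(out)) {
    stop("unknown taxon id(s): ",
         paste(unique(taxa[is.na(out)]), collapse = ", "))
  }
  out
}

#' Rank depth of taxa
#'
#' @inheritParams resolve_taxon
#' @return Integer vector of ordinal depths (0 = root).
#' @export
taxon_depth <- function(tax, taxa) {
  unname(tax$depth[resolve_taxon(tax, taxa)])
}

#' Ancestor of a taxon at (or above) a given depth
#'
#' Returns, for each taxon, the deepest node on its lineage whose depth is
#' `<= d`.  For a taxon at least `d` deep with a gap-free lineage this is its
#' ancestor at exactly depth `d`; shallower taxa (or lineages with collapsed
#' intermediate ranks) return their deepest available ancestor, which is the
#' binning rule used on the kernel's taxonomy axis.
#'
#' @inheritParams resolve_taxon
#' @param d Target depth, `0 .. length(rank_order) - 1`.
#' @return Character vector of taxon ids.
#' @export
ancestor_at <- function(tax, taxa, d) {
  h <- length(tax$rank_order)
  stopifnot(length(d) == 1L, d >= 0L, d <= h - 1L)
  taxa <- resolve_taxon(tax, taxa)
  unname(tax$anc[taxa, d + 1L])
}

#' Lineage of a taxon
#'
#' Root-to-node ranked path.  Depths are strictly increasing and the first
#' entry is always the root; truncating the lineage at any depth yields the
#' lineage of the corresponding ancestor.
#'
#' @inheritParams resolve_taxon
#' @param taxon A single taxon id.
#' @return A data.frame with columns `depth`, `taxon`, `rank`, `name`.
#' @export
lineage <- function(tax, taxon) {
  stopifnot(length(taxon) == 1L)
  t <- resolve_taxon(tax, taxon)
  chain <- t
  while (!is.na(tax$parent[[t]])) {
    t <- tax$parent[[t]]
    chain <- c(t, chain)
  }
  data.frame(depth = unname(tax$depth[chain]),
             taxon = chain,
             rank = unname(tax$rank[chain]),
             name = unname(tax$name[chain]),
             row.names = NULL)
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on every input taxon's lineage.  Commutative and
#' idempotent; duplicated inputs are ignored.  Two taxa from different domains
#' resolve to the root ("cellular organisms").
#'
#' @inheritParams resolve_taxon
#' @param taxa Non-empty vector of taxon ids.
#' @return A single taxon id.
#' @export
#' @examples
#' tax <- make_toy_taxonomy(c(2, 1, 1, 1, 1, 2, 2))
#' sp <- species_nodes(tax)
#' lca(tax, sp[1])           # identity
#' lca(tax, sp[c(1, 2)])     # congeneric species -> their genus
lca <- function(tax, taxa) {
  if (length(taxa) == 0L) stop("lca() requires at least one taxon")
  taxa <- unique(resolve_taxon(tax, taxa))
  if (length(taxa) == 1L) return(taxa)
  m <- tax$anc[taxa, , drop = FALSE]
  same <- apply(m, 2L, function(col) all(col == col[1L]))
  unname(m[1L, max(which(same))])
}

#' Truncate a taxon to a maximum depth
#'
#' Returns the taxon's ancestor at `max_depth` when the taxon is deeper, the
#' taxon itself otherwise.  Used to cap assignments at genus (depth 6) by
#' default, since species/strain naming in reference databases is unreliable.
#'
#' @inheritParams resolve_taxon
#' @param taxon A single taxon id.
#' @param max_depth Maximum allowed depth (default 6, genus).
#' @return A single taxon id at depth `<= max_depth`.
#' @export
truncate_taxon <- function(tax, taxon, max_depth = 6L) {
  t <- resolve_taxon(tax, taxon)
  if (tax$depth[[t]] > max_depth) unname(tax$anc[t, max_depth + 1L]) else t
}

#' Species-rank nodes of a taxonomy
#'
#' @inheritParams resolve_taxon
#' @return Character vector of ids of nodes at the deepest rank.
#' @export
species_nodes <- function(tax) {
  leaf_rank <- tax$rank_order[length(tax$rank_order)]
  unname(tax$id[tax$rank == leaf_rank])
}

# --- loading -----------------------------------------------------------------

# NCBI dump rank names mapped onto the canonical scale before collapsing.
NCBI_RANK_SYNONYMS <- c(superkingdom = "domain")

# Shared canonicalization: identify the root, validate structure, collapse
# nodes whose rank is not on the canonical scale onto their nearest canonical
# ancestor, and remember the collapsed ids as aliases.
canonicalize_taxa <- function(id, parent, rank, name, rank_order) {
  id <- as.character(id); parent <- as.character(parent)
  rank <- trimws(as.character(rank)); name <- as.character(name)
  if (anyDuplicated(id)) {
    stop("duplicate taxon id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  is_root <- is.na(parent) | parent == "" | parent == id
  if (sum(is_root) != 1L) {
    stop("taxonomy must have exactly one root (parent empty or equal to the ",
         "taxon id); found ", sum(is_root))
  }
  parent[is_root] <- NA_character_
  syn <- NCBI_RANK_SYNONYMS[rank]
  rank[!is.na(syn)] <- syn[!is.na(syn)]
  rank[is_root] <- rank_order[1L]

  pidx <- match(parent, id)
  miss <- !is.na(parent) & is.na(pidx)
  if (any(miss)) {
    stop("unknown parent id(s): ", paste(unique(parent[miss]), collapse = ", "))
  }
  # Cycle check by chasing parent chains; a chain longer than n nodes cannot
  # reach the root without revisiting something.
  n <- length(id)
  for (i in seq_len(n)) {
    j <- i; steps <- 0L
    while (!is.na(parent[j])) {
      j <- pidx[j]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxon ", id[i])
    }
  }

  keep <- rank %in% rank_order
  keep[is_root] <- TRUE
  nearest_kept <- function(i) {
    j <- pidx[i]
    while (!keep[j]) j <- pidx[j]
    j
  }
  alias <- character()
  if (any(!keep)) {
    gone <- which(!keep)
    alias <- structure(id[vapply(gone, nearest_kept, integer(1))],
                       names = id[gone])
  }
  reparent <- which(keep & !is_root)
  parent[reparent] <- id[vapply(reparent, nearest_kept, integer(1))]

  list(id = id[keep], parent = parent[keep], rank = rank[keep],
       name = name[keep], alias = alias)
}

split_dmp_line <- function(line) {
  f <- strsplit(line, "\t|\t", fixed = TRUE)[[1]]
  sub("\t\\|$", "", f)
}

#' Load a taxonomy from disk
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"simple-tsv"`}{One header line, then
#'     `taxon_id<TAB>parent_id<TAB>rank<TAB>name`.  The root is the row whose
#'     parent is empty or equal to its own id.}
#'   \item{`"ncbi-dump"`}{`nodes.dmp` with `"\t|\t"` field separators; display
#'     names are read from `names.dmp` (scientific names only) when present in
#'     the same directory or given via `names_path`.}
#' }
#' In either dialect, nodes whose rank is not one of the 8 canonical ranks
#' (e.g. `"no rank"`, subspecies, strain) are collapsed onto their nearest
#' canonical ancestor; their ids remain usable and resolve to that ancestor.
#' NCBI's `superkingdom` is treated as `domain`.
#'
#' @param path Path to the taxonomy file (`nodes.dmp` for the NCBI dialect).
#' @param dialect `"simple-tsv"` or `"ncbi-dump"`.
#' @param names_path Optional path to `names.dmp` (NCBI dialect only).
#' @return A `"taxonomy"` object (see [new_taxonomy()]).
#' @export
load_taxonomy <- function(path, dialect = c("simple-tsv", "ncbi-dump"),
                          names_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  if (dialect == "simple-tsv") {
    df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) {
      stop("simple-tsv taxonomy needs 4 columns: taxon_id, parent_id, rank, name")
    }
    can <- canonicalize_taxa(df[[1]], df[[2]], df[[3]], df[[4]],
                             canonical_ranks())
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- lapply(lines, split_dmp_line)
    short <- which(lengths(fields) < 3L)
    if (length(short)) stop("malformed nodes.dmp line ", short[1L])
    id <- vapply(fields, `[[`, "", 1L)
    parent <- vapply(fields, `[[`, "", 2L)
    rank <- vapply(fields, `[[`, "", 3L)
    name <- id
    if (is.null(names_path)) {
      cand <- file.path(dirname(path), "names.dmp")
      if (file.exists(cand)) names_path <- cand
    }
    if (!is.null(names_path)) {
      nl <- readLines(names_path)
      nl <- nl[nzchar(trimws(nl))]
      nf <- lapply(nl, split_dmp_line)
      sci <- vapply(nf, function(f) length(f) >= 4L && trimws(f[[4]]) == "scientific name",
                    logical(1))
      nm <- structure(vapply(nf[sci], `[[`, "", 2L),
                      names = vapply(nf[sci], `[[`, "", 1L))
      hit <- id %in% names(nm)
      name[hit] <- unname(nm[id[hit]])
    }
    can <- canonicalize_taxa(id, parent, rank, name, canonical_ranks())
  }
  new_taxonomy(can$id, can$parent, can$rank, can$name,
               rank_order = canonical_ranks(), alias = can$alias)
}
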