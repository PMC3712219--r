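# Plain-text interchange: outfmt-6 hit tables, taxon maps, simple-TSV
# taxonomies, truth tables, and the reference-set TSV + JSON sidecar.

#' Write hit tables as a BLAST outfmt-6 TSV
#'
#' Emits the standard 12-column order (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`).  Subjects come from the
#' `subject` column when present, otherwise a representative protein id is
#' derived from the taxon (`<taxon>|ref1`).  Alignment bookkeeping columns are
#' filled with plausible constants; only the fields the parsers read (ids,
#' e-value, bitscore) carry signal.
#'
#' @param hits Named list of per-query hit data.frames (`taxon`, `bitscore`,
#'   `evalue`, optionally `subject`).
#' @param path Output path.
#' @return Invisibly, the named character vector of subject id -> taxon used.
#' @export
write_blast_tab <- function(hits, path) {
  rows <- lapply(names(hits), function(q) {
    h <- hits[[q]]
    if (nrow(h) == 0L) return(NULL)
    subject <- if ("subject" %in% names(h)) h$subject else paste0(h$taxon, "|ref1")
    data.frame(qseqid = q, sseqid = subject, pident = 90.0, length = 150L,
               mismatch = 15L, gapopen = 0L, qstart = 1L, qend = 150L,
               sstart = 1L, send = 150L,
               evalue = format(h$evalue, scientific = TRUE, digits = 6),
               bitscore = format(round(h$bitscore, 1), nsmall = 1),
               taxon = h$taxon, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    file.create(path)
    return(invisible(character()))
  }
  utils::write.table(df[, 1:12], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- structure(df$taxon, names = df$sseqid)
  invisible(map[!duplicated(names(map))])
}

#' Write a subject-to-taxon map TSV
#'
#' @param map Named character vector, subject id -> taxon id.
#' @param path Output path (`subject_id<TAB>taxon_id`, no header).
#' @export
write_taxon_map <- function(map, path) {
  utils::write.table(data.frame(names(map), unname(map)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a taxonomy in the simple TSV dialect
#'
#' One header line, then `taxon_id<TAB>parent_id<TAB>rank<TAB>name`; the root
#' row points at itself.  Round-trips through
#' `load_taxonomy(dialect = "simple-tsv")`.  Collapsed aliases are not
#' serialized.
#'
#' @param tax A `"taxonomy"`.
#' @param path Output path.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  parent <- unname(tax$parent[tax$id])
  parent[is.na(parent)] <- tax$root
  df <- data.frame(taxon_id = tax$id, parent_id = parent,
                   rank = unname(tax$rank[tax$id]),
                   name = unname(tax$name[tax$id]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Write / read a query truth table
#'
#' Tab-separated `query_id<TAB>taxon`, with header.
#'
#' @param truth Data.frame with columns `query_id`, `taxon`.
#' @param path File path.
#' @return `read_truth_table` returns the data.frame.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth[, c("query_id", "taxon")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
}

# Weak order-sensitive checksum of the taxonomy structure, recorded in the
# reference-set sidecar so a mismatched taxonomy is caught at load time.
tax_checksum <- function(tax) {
  s <- paste(tax$id, tax$parent, tax$rank, sep = "|", collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%d-%.0f", length(v),
          sum(v * (seq_along(v) %% 97 + 1)) %% 1e9)
}

#' Serialize a reference set
#'
#' Writes one TSV row per retained match (`source_id`, `source_taxon`,
#' `subject_taxon`, `bitscore`, `evalue`) plus a JSON sidecar
#' (`<path>.json`) recording `p`, the profile count and a taxonomy checksum.
#'
#' @param refs A `"reference_set"`.
#' @param path Output TSV path.
#' @param sidecar Sidecar path (default `<path>.json`).
#' @export
write_reference_set <- function(refs, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(refs, "reference_set"))
  rows <- lapply(refs$profiles, function(pr) {
    data.frame(source_id = pr$source_id, source_taxon = pr$source_taxon,
               subject_taxon = pr$matches$taxon,
               bitscore = pr$matches$bitscore, evalue = pr$matches$evalue,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  jsonlite::write_json(
    list(p = refs$p, n_profiles = length(refs$profiles),
         taxonomy_checksum = tax_checksum(refs$taxonomy)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized reference set
#'
#' Reconstructs the profiles written by [write_reference_set()]; matches are
#' already deduplicated and thresholded, so they are taken as-is.  A taxonomy
#' checksum mismatch against the sidecar raises a warning.
#'
#' @param path TSV path.
#' @param tax Taxonomy the profiles refer to.
#' @param sidecar Sidecar path (default `<path>.json`).
#' @return A `"reference_set"`.
#' @export
read_reference_set <- function(path, tax, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(tax, "taxonomy"))
  if (!file.exists(sidecar)) stop("reference sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$taxonomy_checksum, tax_checksum(tax))) {
    warning("taxonomy checksum does not match the one recorded when the ",
            "reference set was built")
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(source_id = "character",
                                         source_taxon = "character",
                                         subject_taxon = "character",
                                         bitscore = "numeric",
                                         evalue = "numeric"))
  sp <- split(df, factor(df$source_id, levels = unique(df$source_id)))
  profiles <- lapply(sp, function(d) {
    structure(
      list(source_id = d$source_id[1L], source_taxon = d$source_taxon[1L],
           matches = order_matches(data.frame(taxon = d$subject_taxon,
                                              bitscore = d$bitscore,
                                              evalue = d$evalue,
                                              stringsAsFactors = FALSE)),
           p_used = meta$p),
      class = "lca_profile")
  })
  structure(list(profiles = profiles, p = meta$p, taxonomy = tax),
            class = "reference_set")
}
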