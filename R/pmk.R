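# Modified Pyramid Match Kernel over a taxonomy x normalized-e-value grid.
#
# Matches are embedded as points: the taxonomy axis positions a match by its
# taxon, the other axis by its e-value normalized within the profile.  The
# kernel runs h iterations over successively coarser grids.  At iteration i
# the taxonomy axis groups matches by their ancestor at rank depth h - i
# (i = 1: species-level bins; i = h: one root bin) and the e-value axis is cut
# into 2^(h-i) equal bins (i = h: a single bin spanning the axis).  The total
# intersection count I_i (sum over 2D bins of min(count_a, count_b)) is
# weighted by w_i = 2^(1-i) and the weighted counts are summed.  Unlike the
# original pyramid match kernel, TOTAL counts per level are weighted, not the
# increment over the previous level.

#' Kernel configuration
#'
#' @param h Number of hierarchy levels; must equal the taxonomy's rank count
#'   (8 for the canonical ranks).
#' @param evalue_floor Smallest representable e-value.  BLAST reports `0` for
#'   e-values below its floating range; they are clamped to this floor before
#'   the log transform.
#' @return A `"pmk_config"` object.
#' @export
pmk_config <- function(h = 8L, evalue_floor = 1e-180) {
  h <- as.integer(h)
  stopifnot(length(h) == 1L, h >= 2L,
            is.numeric(evalue_floor), evalue_floor > 0)
  structure(list(h = h, evalue_floor = evalue_floor), class = "pmk_config")
}

#' Place a profile's matches on the normalized e-value axis
#'
#' Each e-value is transformed to `x = -log10(max(e, evalue_floor))`, then
#' min-max rescaled within the profile so the best match (smallest e-value)
#' sits at position 1 and the worst at 0.  Profiles are normalized
#' separately, which makes the kernel compare the \emph{shape} of two match
#' patterns rather than their absolute significance: substitution-rate
#' variation between genes shifts and scales all of a profile's `-log10(e)`
#' values together, and the min-max rescaling cancels exactly such affine
#' effects.  If all e-values coincide (including a single-match profile)
#' every point maps to 1.
#'
#' @param profile A non-empty `"lca_profile"`.
#' @param cfg A [pmk_config()].
#' @return A data.frame with columns `taxon` and `pos` (in `[0, 1]`).
#' @export
#' @examples
#' pr <- build_profile(data.frame(taxon = c("a", "b", "c"),
#'                                bitscore = c(300, 150, 40),
#'                                evalue = c(1e-100, 1e-50, 1e-3)), p = 0)
#' normalize_evalues(pr, pmk_config())$pos   # 1, (50-3)/(100-3), 0
normalize_evalues <- function(profile, cfg = pmk_config()) {
  stopifnot(inherits(profile, "lca_profile"))
  if (is_empty_profile(profile)) stop("cannot normalize an empty profile")
  x <- -log10(pmax(profile$matches$evalue, cfg$evalue_floor))
  rng <- range(x)
  pos <- if (rng[2L] > rng[1L]) (x - rng[1L]) / (rng[2L] - rng[1L]) else rep(1, length(x))
  data.frame(taxon = profile$matches$taxon, pos = pos,
             stringsAsFactors = FALSE)
}

# Per-iteration 2D bin keys for a normalized profile.  Taxonomy bin = deepest
# available ancestor at depth h - i; e-value bin index =
# min(floor(pos * nbins), nbins - 1), i.e. half-open bins closed at the top so
# position 1 lands in the last bin.
pmk_keys <- function(grid, tax, h) {
  taxa <- resolve_taxon(tax, grid$taxon)
  lapply(seq_len(h), function(i) {
    d <- h - i
    nb <- 2^(h - i)
    tb <- unname(tax$anc[taxa, d + 1L])
    eb <- pmin(floor(grid$pos * nb), nb - 1)
    paste(tb, eb, sep = "\r")
  })
}

count_intersections <- function(ka, kb) {
  u <- unique(c(ka, kb))
  ca <- tabulate(match(ka, u), length(u))
  cb <- tabulate(match(kb, u), length(u))
  sum(pmin(ca, cb))
}

#' Pyramid match similarity of two LCA Profiles
#'
#' Scores the similarity of two profiles on the taxonomy x e-value grid (see
#' the package overview and [pmk_config()]).  Symmetric in its profile
#' arguments.  Intersection counts are non-decreasing over iterations, since
#' bins only coarsen; the score is `sum(w_i * I_i)` with `w_i = 2^(1-i)`.
#'
#' @param a,b Non-empty `"lca_profile"` objects whose taxa resolve in `tax`.
#' @param tax Taxonomy; its rank count must equal `cfg$h`.
#' @param cfg A [pmk_config()].
#' @return A `"pmk_result"`: list with `score` and `per_iteration`, a
#'   data.frame of `iteration`, `weight`, `intersections`.
#' @export
#' @examples
#' fx <- pmk_example_fixture()
#' pmk_score(fx$a, fx$b, fx$taxonomy, pmk_config(h = fx$h))
pmk_score <- function(a, b, tax, cfg = pmk_config()) {
  stopifnot(inherits(tax, "taxonomy"))
  if (is_empty_profile(a) || is_empty_profile(b)) {
    stop("pmk_score requires two non-empty profiles")
  }
  h <- cfg$h
  if (h != length(tax$rank_order)) {
    stop("cfg$h (", h, ") must equal the taxonomy's rank count (",
         length(tax$rank_order), ")")
  }
  ka <- pmk_keys(normalize_evalues(a, cfg), tax, h)
  kb <- pmk_keys(normalize_evalues(b, cfg), tax, h)
  I <- vapply(seq_len(h), function(i) count_intersections(ka[[i]], kb[[i]]),
              numeric(1))
  w <- 2^(1 - seq_len(h))
  structure(
    list(score = sum(w * I),
         per_iteration = data.frame(iteration = seq_len(h), weight = w,
                                    intersections = as.integer(I))),
    class = "pmk_result"
  )
}

#' @export
print.pmk_result <- function(x, ...) {
  cat("PMK similarity:", format(x$score), "\n")
  print(x$per_iteration)
  invisible(x)
}

#' Score a query profile against every reference profile
#'
#' @param q A non-empty query `"lca_profile"`.
#' @param refs A non-empty `"reference_set"`.
#' @param cfg A [pmk_config()]; defaults to `h` = the reference taxonomy's
#'   rank count.
#' @return A data.frame of `source_id`, `source_taxon`, `score`, ordered by
#'   score descending then source id ascending (deterministic).
#' @export
score_against_references <- function(q, refs,
                                     cfg = pmk_config(length(refs$taxonomy$rank_order))) {
  stopifnot(inherits(refs, "reference_set"))
  if (!length(refs$profiles)) stop("empty reference set")
  if (is_empty_profile(q)) stop("query profile is empty")
  tax <- refs$taxonomy
  h <- cfg$h
  if (h != length(tax$rank_order)) {
    stop("cfg$h (", h, ") must equal the taxonomy's rank count (",
         length(tax$rank_order), ")")
  }
  kq <- pmk_keys(normalize_evalues(q, cfg), tax, h)
  w <- 2^(1 - seq_len(h))
  sc <- vapply(refs$profiles, function(pr) {
    kr <- pmk_keys(normalize_evalues(pr, cfg), tax, h)
    sum(w * vapply(seq_len(h),
                   function(i) count_intersections(kq[[i]], kr[[i]]),
                   numeric(1)))
  }, numeric(1))
  out <- data.frame(
    source_id = names(refs$profiles),
    source_taxon = vapply(refs$profiles, function(pr) pr$source_taxon, ""),
    score = unname(sc),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$source_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
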