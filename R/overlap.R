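#' Venn-style overlap of candidate gene sets across screens
#'
#' Computes, for every non-empty combination of screens, both the exclusive
#' region (genes in exactly those screens and no other — the numbers printed
#' inside a Venn diagram) and the plain intersection. Gene identity is by
#' exact gene-id string match.
#'
#' @param screens named list of character vectors (candidate gene ids); names
#'   are experiment ids (e.g. `mmc`, `mms`, `phleo`) and must be unique
#' @return list with data.frames `regions` and `intersections`, each with
#'   columns `screens` (``+``-separated combination), `n`, and `genes`
#'   (comma-separated, sorted); rows ordered by combination size then name
#' @export
overlap_screens <- function(screens) {
  if (length(screens) < 2L) stop("need at least two screens")
  ids <- names(screens)
  if (is.null(ids) || any(!nzchar(ids))) stop("screens must be named")
  if (anyDuplicated(ids)) stop("duplicate experiment ids: ",
                               ids[duplicated(ids)][1L])
  screens <- lapply(screens, function(s) unique(as.character(s)))
  combos <- unlist(lapply(seq_along(ids), function(k) {
    utils::combn(ids, k, simplify = FALSE)
  }), recursive = FALSE)

  region_row <- function(members, genes) {
    data.frame(screens = paste(members, collapse = "+"),
               n = length(genes),
               genes = paste(sort(genes), collapse = ","),
               stringsAsFactors = FALSE)
  }
  regions <- lapply(combos, function(members) {
    inside <- Reduce(intersect, screens[members])
    outside <- unlist(screens[setdiff(ids, members)], use.names = FALSE)
    region_row(members, setdiff(inside, outside))
  })
  inters <- lapply(combos, function(members) {
    region_row(members, Reduce(intersect, screens[members]))
  })
  list(regions = do.call(rbind, regions),
       intersections = do.call(rbind, inters))
}

#' Write an overlap report
#'
#' One row per exclusive Venn region followed by one per intersection, with a
#' `kind` column distinguishing them; deterministic ordering.
#'
#' @param overlap result of [overlap_screens()]
#' @param path output TSV path
#' @export
write_overlap_report <- function(overlap, path) {
  reg <- cbind(kind = "exclusive_region", overlap$regions,
               stringsAsFactors = FALSE)
  int <- cbind(kind = "intersection", overlap$intersections,
               stringsAsFactors = FALSE)
  utils::write.table(rbind(reg, int), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
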