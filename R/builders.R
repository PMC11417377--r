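# Universe builders that work directly on coverage: union, intersection,
# genome tiles, the coverage cutoff (CC) universe and its flexible two-cutoff
# variant (CCF), plus the optimal-cutoff rule and post-hoc filtering.

empty_universe <- function(method, params = list(), flexible = FALSE) {
  new_universe(tibble(chrom = character(), start = numeric(),
                      core_start = numeric(), core_end = numeric(),
                      end = numeric()),
               method = method, params = params, flexible = flexible)
}

#' Union universe
#'
#' Merges all region sets in the collection: the universe covers exactly the
#' bases covered by at least one set, as maximal merged intervals.
#'
#' @param collection A collection tibble (`set`, `chrom`, `start`, `end`).
#' @return A fixed `universe`.
#' @export
union_universe <- function(collection) {
  if (nrow(collection) == 0) {
    warn("empty collection: union universe is empty")
    return(empty_universe("union"))
  }
  new_universe(merge_regions(collection[, c("chrom", "start", "end")]),
               method = "union", flexible = FALSE)
}

#' Intersection universe
#'
#' Keeps only bases covered in every region set of the collection.
#'
#' @inheritParams union_universe
#' @return A fixed `universe`.
#' @export
intersection_universe <- function(collection) {
  if (nrow(collection) == 0) {
    warn("empty collection: intersection universe is empty")
    return(empty_universe("intersection"))
  }
  sets <- split(collection, collection$set)
  per_chrom <- function(chrom) {
    irs <- lapply(sets, function(d) {
      to_iranges(merge_regions(d[d$chrom == chrom, c("chrom", "start", "end")]))
    })
    from_iranges(Reduce(IRanges::intersect, irs), chrom)
  }
  out <- bind_rows(lapply(sort(unique(collection$chrom)), per_chrom))
  if (nrow(out) == 0) return(empty_universe("intersection"))
  new_universe(out, method = "intersection", flexible = FALSE)
}

#' Tiling universe
#'
#' Bins every chromosome into consecutive non-overlapping tiles; the final
#' partial tile is kept.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param tile_size Tile width in bases (default 1000).
#' @return A fixed `universe`.
#' @export
tiles_universe <- function(chrom_sizes, tile_size = 1000) {
  stopifnot(tile_size >= 1)
  out <- purrr::map_dfr(names(chrom_sizes), function(chrom) {
    L <- chrom_sizes[[chrom]]
    starts <- seq(0, L - 1, by = tile_size)
    tibble(chrom = chrom, start = starts, end = pmin(starts + tile_size, L))
  })
  new_universe(out, method = "tiles", params = list(tile_size = tile_size),
               flexible = FALSE)
}

#' Optimal coverage cutoff
#'
#' The smallest integer cutoff x satisfying x >= S_c / g, where S_c is the
#' collection's total base coverage and g the genome size, clamped into
#' \[1, n\]. Intuitively: a base should appear in at least as many sets as
#' expected by the collection's mean genome coverage.
#'
#' @param stats A one-row tibble from [coverage_stats()].
#' @param n Number of region sets in the collection.
#' @return Integer cutoff.
#' @export
optimal_cutoff <- function(stats, n) {
  stopifnot(stats$g > 0)
  as.integer(min(max(ceiling(stats$s_c / stats$g), 1), max(n, 1)))
}

# maximal runs with core >= x, as a region table (runs are contiguous per chrom)
threshold_runs <- function(tracks, x) {
  d <- tracks$runs[tracks$runs$core >= x, , drop = FALSE]
  if (nrow(d) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  merge_regions(d[, c("chrom", "start", "end")])
}

#' Coverage cutoff (CC) universe
#'
#' The universe consists of the maximal runs of positions covered by at
#' least `x` sets. `x = 1` reproduces the union universe and `x = n` the
#' intersection universe.
#'
#' @param tracks A `signal_tracks` object.
#' @param x Integer cutoff; defaults to [optimal_cutoff()] on the
#'   collection's coverage statistics.
#' @return A fixed `universe`.
#' @export
cc_universe <- function(tracks, x = NULL) {
  if (is.null(x)) x <- optimal_cutoff(coverage_stats(tracks), tracks$n_sets)
  stopifnot(x >= 1)
  runs <- threshold_runs(tracks, x)
  if (nrow(runs) == 0) {
    warn(sprintf("cutoff x = %d exceeds maximum coverage: empty universe", x))
    return(empty_universe("cc", params = list(x = x)))
  }
  new_universe(runs, method = "cc", params = list(x = x), flexible = FALSE)
}

#' Default CCF cutoffs
#'
#' A Poisson-style one-standard-deviation band around the optimal cutoff:
#' `x* - ceiling(sqrt(x*))` to `x* + ceiling(sqrt(x*))`, clamped into
#' \[1, n\].
#'
#' @param x_opt Optimal cutoff.
#' @param n Number of sets.
#' @return List with `x_lower`, `x_upper`.
#' @export
ccf_default_cutoffs <- function(x_opt, n) {
  hw <- ceiling(sqrt(x_opt))
  list(x_lower = as.integer(max(1, x_opt - hw)),
       x_upper = as.integer(min(max(n, 1), x_opt + hw)))
}

#' Flexible coverage cutoff (CCF) universe
#'
#' Uses two cutoffs: the lower defines the flexible boundary intervals and
#' the upper the region core. Each maximal run with coverage >= `x_lower`
#' containing at least one position with coverage >= `x_upper` becomes one
#' flexible region whose outer span is the lower-cutoff run and whose core
#' spans the first to last position reaching the upper cutoff. Runs that
#' never reach the upper cutoff are dropped (a region without a core is
#' undefined).
#'
#' @inheritParams cc_universe
#' @param x_lower,x_upper Integer cutoffs, `1 <= x_lower <= x_upper`;
#'   default to [ccf_default_cutoffs()] around the optimal cutoff.
#' @return A flexible `universe`.
#' @export
ccf_universe <- function(tracks, x_lower = NULL, x_upper = NULL) {
  if (is.null(x_lower) || is.null(x_upper)) {
    x_opt <- optimal_cutoff(coverage_stats(tracks), tracks$n_sets)
    defaults <- ccf_default_cutoffs(x_opt, tracks$n_sets)
    if (is.null(x_lower)) x_lower <- defaults$x_lower
    if (is.null(x_upper)) x_upper <- defaults$x_upper
  }
  stopifnot(1 <= x_lower, x_lower <= x_upper)
  outer <- threshold_runs(tracks, x_lower)
  cores <- threshold_runs(tracks, x_upper)
  if (nrow(outer) == 0 || nrow(cores) == 0) {
    warn("no run reaches the upper cutoff: empty universe")
    return(empty_universe("ccf", params = list(x_lower = x_lower, x_upper = x_upper),
                          flexible = TRUE))
  }
  out <- purrr::map_dfr(seq_len(nrow(outer)), function(i) {
    k <- cores$chrom == outer$chrom[i] & cores$start >= outer$start[i] &
      cores$end <= outer$end[i]
    if (!any(k)) return(NULL)
    tibble(chrom = outer$chrom[i], start = outer$start[i],
           core_start = min(cores$start[k]), core_end = max(cores$end[k]),
           end = outer$end[i])
  })
  if (is.null(out) || nrow(out) == 0) {
    warn("no run reaches the upper cutoff: empty universe")
    return(empty_universe("ccf", params = list(x_lower = x_lower, x_upper = x_upper),
                          flexible = TRUE))
  }
  new_universe(out, method = "ccf",
               params = list(x_lower = x_lower, x_upper = x_upper),
               flexible = TRUE)
}

#' Filter a universe by region width and likelihood contribution
#'
#' Drops regions narrower than `min_width` (outer span) and, when
#' `min_region_loglik` is given, regions whose log-likelihood contribution
#' relative to an all-background labeling (see [universe_likelihood()]) is
#' below the threshold.
#'
#' @param universe A `universe`.
#' @param min_width Minimum outer width in bases (default 0: keep all).
#' @param min_region_loglik Optional log-likelihood threshold.
#' @param models A `track_models` object; required with `min_region_loglik`.
#' @return The filtered `universe` (order preserved).
#' @export
filter_universe <- function(universe, min_width = 0,
                            min_region_loglik = NULL, models = NULL) {
  keep <- (universe$end - universe$start) >= min_width
  if (!is.null(min_region_loglik)) {
    if (is.null(models)) abort("likelihood filtering requires `models`")
    keep <- keep & region_deltas(universe, models,
                                 flexible = is_flexible(universe)) >= min_region_loglik
  }
  new_universe(universe[keep, , drop = FALSE],
               method = attr(universe, "method"),
               params = c(attr(universe, "params"),
                          list(min_width = min_width,
                               min_region_loglik = min_region_loglik)),
               flexible = is_flexible(universe))
}
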