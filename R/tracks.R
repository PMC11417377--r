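# Plane-sweep computation of the three base-resolution signal tracks of a
# region set collection: at position i,
#   starts(i) : number of sets with a (merged) region starting at i
#   core(i)   : number of sets covering i
#   ends(i)   : number of sets whose region's last covered base is i (end - 1)
# Each set is merged first so one experiment contributes at most 1 anywhere.
# Tracks are stored run-length encoded: contiguous runs of constant
# (starts, core, ends) covering [0, chrom_length).

#' Compute start / coverage / end signal tracks for a collection
#'
#' @param collection A collection tibble (`set`, `chrom`, `start`, `end`),
#'   e.g. from [read_collection()].
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return A `signal_tracks` object: run-length encoded tracks plus
#'   `chrom_sizes`, the number of sets `n_sets` and the total number of
#'   merged regions `n_regions`.
#' @export
compute_tracks <- function(collection, chrom_sizes) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  n_sets <- length(unique(collection$set))
  if (nrow(collection) > 0) {
    bad <- setdiff(unique(collection$chrom), names(chrom_sizes))
    if (length(bad)) {
      abort(sprintf("chromosome(s) not in chrom_sizes: %s",
                    paste(bad, collapse = ", ")))
    }
    if (any(collection$end > chrom_sizes[collection$chrom])) {
      abort("interval end exceeds chromosome length")
    }
  }
  merged <- if (nrow(collection) > 0) {
    collection |>
      group_by(.data$set) |>
      group_modify(~ merge_regions(.x)) |>
      ungroup()
  } else {
    tibble(set = character(), chrom = character(),
           start = numeric(), end = numeric())
  }
  runs <- purrr::map_dfr(names(chrom_sizes), function(chrom) {
    L <- chrom_sizes[[chrom]]
    d <- merged[merged$chrom == chrom, , drop = FALSE]
    chrom_runs(chrom, L, d$start, d$end)
  })
  structure(list(runs = runs, chrom_sizes = chrom_sizes,
                 n_sets = n_sets, n_regions = nrow(merged)),
            class = "signal_tracks")
}

chrom_runs <- function(chrom, L, a, b) {
  if (length(a) == 0) {
    return(tibble(chrom = chrom, start = 0, end = L,
                  starts = 0, core = 0, ends = 0))
  }
  bp <- sort(unique(pmin(pmax(c(0, a, a + 1, b - 1, b, L), 0), L)))
  seg_start <- bp[-length(bp)]
  seg_end <- bp[-1]
  keep <- seg_end > seg_start
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  a_sorted <- sort(a); b_sorted <- sort(b)
  core <- as.numeric(findInterval(seg_start, a_sorted) -
                       findInterval(seg_start, b_sorted))
  s_tab <- table(a)
  e_tab <- table(b - 1)
  sv <- as.numeric(s_tab[as.character(seg_start)])
  ev <- as.numeric(e_tab[as.character(seg_start)])
  sv[is.na(sv) | seg_end - seg_start != 1] <- 0
  ev[is.na(ev) | seg_end - seg_start != 1] <- 0
  # point masses sit on width-1 segments by construction of the breakpoints
  d <- tibble(chrom = chrom, start = seg_start, end = seg_end,
              starts = sv, core = core, ends = ev)
  compact_runs(d)
}

compact_runs <- function(d) {
  if (nrow(d) < 2) return(d)
  same <- with(d, c(FALSE, starts[-1] == starts[-nrow(d)] &
                             core[-1] == core[-nrow(d)] &
                             ends[-1] == ends[-nrow(d)]))
  d$grp <- cumsum(!same)
  d |>
    group_by(.data$grp) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), starts = first(.data$starts),
              core = first(.data$core), ends = first(.data$ends),
              .groups = "drop") |>
    select(-"grp")
}

#' @export
print.signal_tracks <- function(x, ...) {
  cat(sprintf("signal tracks: %d set(s), %d merged region(s), genome %g bp, %d runs\n",
              x$n_sets, x$n_regions, sum(x$chrom_sizes), nrow(x$runs)))
  invisible(x)
}

#' Materialize dense per-base track vectors for one chromosome
#'
#' @param tracks A `signal_tracks` object.
#' @param chrom Chromosome name.
#' @return A list of numeric vectors `starts`, `core`, `ends`, each of
#'   length `chrom_sizes[chrom]` (position i stored at index i + 1).
#' @export
track_vectors <- function(tracks, chrom) {
  if (!chrom %in% names(tracks$chrom_sizes)) {
    abort(sprintf("unknown chromosome: %s", chrom))
  }
  d <- tracks$runs[tracks$runs$chrom == chrom, , drop = FALSE]
  w <- as.integer(d$end - d$start)
  list(starts = rep(d$starts, w), core = rep(d$core, w), ends = rep(d$ends, w))
}

#' Collection coverage statistics
#'
#' `s_c` is the total base coverage of the genome by the collection (sum of
#' the coverage track over all positions, i.e. bases times sets) and `g` the
#' genome size; their ratio is the mean per-base coverage used to derive the
#' optimal coverage cutoff.
#'
#' @param tracks A `signal_tracks` object.
#' @return A one-row tibble: `s_c`, `g`, `mean_coverage`.
#' @export
coverage_stats <- function(tracks) {
  s_c <- sum((tracks$runs$end - tracks$runs$start) * tracks$runs$core)
  g <- sum(tracks$chrom_sizes)
  tibble(s_c = s_c, g = g, mean_coverage = s_c / g)
}

#' Export signal tracks as bedGraph files
#'
#' Writes `starts.bedGraph`, `core.bedGraph` and `ends.bedGraph` (non-zero
#' runs only) into a directory.
#'
#' @param tracks A `signal_tracks` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_bedgraph <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in c("starts", "core", "ends")) {
    # re-compact runs for this single track before writing
    d <- tracks$runs
    brk <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
               d[[tr]][-1] != d[[tr]][-nrow(d)])
    d$grp <- cumsum(brk)
    d <- d |>
      group_by(.data$grp) |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), value = first(.data[[tr]]),
                .groups = "drop")
    d <- d[d$value > 0, , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%g", d$chrom, as.integer(d$start),
                     as.integer(d$end), d$value)
    writeLines(lines, file.path(dir, paste0(tr, ".bedGraph")))
  }
  invisible(dir)
}
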