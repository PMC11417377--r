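#' @useDynLib uniflex, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Coordinates are 0-based half-open throughout (BED convention).
# A flexible consensus region is stored with four coordinates:
#   start      : outer start (start_start)
#   core_start : end of the flexible start interval == start of the core
#   core_end   : end of the core == start of the flexible end interval
#   end        : outer end (end_end), exclusive
# A fixed region is the degenerate case core_start == start, core_end == end
# (empty boundary intervals, core spanning the whole region).

#' Coerce a data frame to a validated region table
#'
#' A region table is a tibble with columns `chrom`, `start`, `end`
#' (0-based, half-open), sorted by `(chrom, start, end)`. Duplicate rows are
#' allowed; they are removed where a normalized (merged) view is required.
#'
#' @param x A data frame with at least columns `chrom`, `start`, `end`.
#' @return A sorted tibble with columns `chrom`, `start`, `end`.
#' @export
as_region_tbl <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort("a region table needs columns `chrom`, `start`, `end`")
  }
  out <- as_tibble(x)[, c("chrom", "start", "end")]
  out$chrom <- as.character(out$chrom)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  if (any(is.na(out$start)) || any(is.na(out$end)) || any(out$chrom == "")) {
    abort("region coordinates must be non-missing and chrom non-empty")
  }
  if (any(out$start >= out$end)) {
    abort("all regions must satisfy start < end")
  }
  if (any(out$start < 0)) abort("negative coordinates are not allowed")
  arrange(out, .data$chrom, .data$start, .data$end)
}

parse_abort <- function(path, line_no, msg) {
  abort(sprintf("%s: line %d: %s", path, line_no, msg),
        class = "uniflex_parse_error")
}

bed_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines, keep = keep)
}

#' Read a BED3+ file as a region table
#'
#' Skips `track`, `browser` and `#` lines; extra columns beyond the first
#' three are ignored. Malformed lines (fewer than 3 fields, non-integer
#' coordinates, or start >= end) raise a parse error naming the line.
#'
#' @param path Path to a BED file.
#' @return A sorted region table (tibble with `chrom`, `start`, `end`).
#' @export
read_bed <- function(path) {
  b <- bed_lines(path)
  idx <- which(b$keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(b$lines[idx], "\t", fixed = TRUE)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    f <- fields[[k]]
    ln <- idx[k]
    if (length(f) < 3) parse_abort(path, ln, "fewer than 3 tab-separated columns")
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      parse_abort(path, ln, "non-integer coordinates")
    }
    if (s >= e) parse_abort(path, ln, sprintf("start >= end (%s >= %s)", f[2], f[3]))
    if (s < 0) parse_abort(path, ln, "negative start coordinate")
    rows[[k]] <- list(chrom = f[1], start = s, end = e)
  }
  out <- bind_rows(rows)
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Read a collection of region sets
#'
#' Reads every BED file into one long tibble with a `set` column naming the
#' source file. This is the standard input for track computation and the
#' universe builders.
#'
#' @param paths Character vector of BED file paths, or a single directory
#'   (all `*.bed` files within, sorted by name).
#' @param names Optional set names; defaults to file base names.
#' @return A tibble with columns `set`, `chrom`, `start`, `end`.
#' @export
read_collection <- function(paths, names = NULL) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.bed$", full.names = TRUE))
  }
  if (length(paths) == 0) abort("no BED files to read")
  if (is.null(names)) names <- sub("\\.bed$", "", basename(paths))
  purrr::map2_dfr(paths, names, function(p, nm) {
    mutate(read_bed(p), set = nm, .before = 1)
  })
}

#' Read a chromosome sizes file
#'
#' @param path Two-column tab-separated file: `chrom<TAB>length`.
#' @return A named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) abort("chromosome lengths must be positive")
  stats::setNames(df$length, df$chrom)
}

# ---- universe container -----------------------------------------------------

new_universe <- function(tbl, method, params = list(), flexible) {
  tbl <- as_tibble(tbl)
  needed <- c("chrom", "start", "core_start", "core_end", "end")
  if (!flexible) {
    tbl$core_start <- tbl$start
    tbl$core_end <- tbl$end
  }
  tbl <- tbl[, needed]
  tbl <- arrange(tbl, .data$chrom, .data$start, .data$end)
  validate_universe(tbl)
  structure(tbl,
            class = c("universe", class(tibble())),
            method = method, params = params, flexible = flexible)
}

validate_universe <- function(tbl) {
  ok <- tbl$start <= tbl$core_start & tbl$core_start <= tbl$core_end &
    tbl$core_end <= tbl$end & tbl$start < tbl$end
  if (!all(ok)) {
    abort("universe regions must satisfy start <= core_start <= core_end <= end and start < end")
  }
  by_chrom <- split(tbl, tbl$chrom)
  for (d in by_chrom) {
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort("universe regions must be non-overlapping on their outer spans")
    }
  }
  invisible(tbl)
}

#' Construct a universe from a data frame
#'
#' @param x A data frame with `chrom`, `start`, `end` and, for a flexible
#'   universe, `core_start`, `core_end` (0-based, half-open; the flexible
#'   start interval is `[start, core_start)`, the core `[core_start,
#'   core_end)`, the flexible end interval `[core_end, end)`).
#' @param flexible Logical; if `NULL`, inferred from the presence of core
#'   columns.
#' @param method Provenance label stored on the object.
#' @param params Named list of builder parameters, stored as an attribute.
#' @return A `universe` tibble.
#' @export
as_universe <- function(x, flexible = NULL, method = "external", params = list()) {
  x <- as_tibble(x)
  if (is.null(flexible)) {
    flexible <- all(c("core_start", "core_end") %in% names(x))
  }
  if (!flexible) x <- as_region_tbl(x)
  new_universe(x, method = method, params = params, flexible = flexible)
}

#' @export
is_flexible <- function(universe) isTRUE(attr(universe, "flexible"))

#' @export
print.universe <- function(x, ...) {
  cat(sprintf("# A %s universe: %d regions, method = %s\n",
              if (is_flexible(x)) "flexible" else "fixed",
              nrow(x), attr(x, "method") %||% "?"))
  NextMethod()
}

#' @importFrom rlang %||%
#' @method glance universe
#' @export
glance.universe <- function(x, ...) {
  tibble(method = attr(x, "method") %||% NA_character_,
         flexible = is_flexible(x),
         n_regions = nrow(x),
         mean_width = if (nrow(x)) mean(x$end - x$start) else NA_real_,
         bases_covered = sum(x$end - x$start))
}

# ---- flexible BED8 dialect --------------------------------------------------

#' Read a universe from BED
#'
#' BED3 files are read as fixed universes. Files with 8+ columns are read in
#' the flexible dialect: columns 2,3 hold the outer span and thickStart /
#' thickEnd (columns 7,8) hold the core boundaries (end of the flexible start
#' interval and start of the flexible end interval).
#'
#' @param path Path to a BED3 or BED8+ file.
#' @return A `universe` tibble.
#' @export
read_universe <- function(path) {
  b <- bed_lines(path)
  idx <- which(b$keep)
  if (length(idx) == 0) {
    return(new_universe(tibble(chrom = character(), start = numeric(),
                               core_start = numeric(), core_end = numeric(),
                               end = numeric()),
                        method = "external", flexible = FALSE))
  }
  ncol1 <- length(strsplit(b$lines[idx[1]], "\t", fixed = TRUE)[[1]])
  if (ncol1 >= 8) read_flexible_bed(path) else {
    new_universe(read_bed(path), method = "external", flexible = FALSE)
  }
}

#' @rdname read_universe
#' @export
read_flexible_bed <- function(path) {
  b <- bed_lines(path)
  idx <- which(b$keep)
  rows <- vector("list", length(idx))
  fields <- strsplit(b$lines[idx], "\t", fixed = TRUE)
  for (k in seq_along(idx)) {
    f <- fields[[k]]
    ln <- idx[k]
    if (length(f) < 8) parse_abort(path, ln, "flexible BED needs >= 8 columns")
    v <- suppressWarnings(as.numeric(f[c(2, 3, 7, 8)]))
    if (any(is.na(v)) || any(v != floor(v))) {
      parse_abort(path, ln, "non-integer coordinates")
    }
    ss <- v[1]; ee <- v[2]; se <- v[3]; es <- v[4]
    if (!(ss <= se && se <= es && es <= ee)) {
      parse_abort(path, ln,
                  "thickStart/thickEnd must satisfy chromStart <= thickStart <= thickEnd <= chromEnd")
    }
    if (ss >= ee) parse_abort(path, ln, "empty outer span")
    rows[[k]] <- list(chrom = f[1], start = ss, core_start = se,
                      core_end = es, end = ee)
  }
  new_universe(bind_rows(rows), method = "external", flexible = TRUE)
}

#' Write a universe to BED
#'
#' Fixed universes are written as BED3. Flexible universes are written as
#' BED8 with `name = "."`, `score = 0`, `strand = "."` and the core
#' boundaries in thickStart/thickEnd; `read_universe()` round-trips all four
#' coordinates exactly.
#'
#' @param universe A `universe` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_universe <- function(universe, path) {
  if (is_flexible(universe)) write_flexible_bed(universe, path) else {
    lines <- sprintf("%s\t%d\t%d", universe$chrom,
                     as.integer(universe$start), as.integer(universe$end))
    writeLines(lines, path)
    invisible(path)
  }
}

#' @rdname write_universe
#' @export
write_flexible_bed <- function(universe, path) {
  lines <- sprintf("%s\t%d\t%d\t.\t0\t.\t%d\t%d",
                   universe$chrom,
                   as.integer(universe$start), as.integer(universe$end),
                   as.integer(universe$core_start), as.integer(universe$core_end))
  writeLines(lines, path)
  invisible(path)
}

# ---- interval arithmetic (IRanges-backed) -----------------------------------

# region tbl (0-based half-open) -> IRanges (1-based closed)
to_iranges <- function(d) IRanges::IRanges(start = d$start + 1, end = d$end)

from_iranges <- function(ir, chrom) {
  tibble(chrom = chrom,
         start = as.numeric(IRanges::start(ir)) - 1,
         end = as.numeric(IRanges::end(ir)))
}

#' Merge overlapping and abutting regions
#'
#' @param regions A region table.
#' @return A region table in which overlapping or touching intervals are
#'   collapsed into maximal runs.
#' @export
merge_regions <- function(regions) {
  regions <- as_region_tbl(regions)
  if (nrow(regions) == 0) return(regions)
  out <- lapply(split(regions, regions$chrom), function(d) {
    from_iranges(IRanges::reduce(to_iranges(d)), d$chrom[1])
  })
  arrange(bind_rows(out), .data$chrom, .data$start, .data$end)
}

# ---- tokenization -----------------------------------------------------------

#' Tokenize a region set against a universe
#'
#' Maps each query interval to every universe region whose outer span
#' overlaps it by at least one base. Queries overlapping nothing are kept
#' with `universe_id = NA` and counted as untokenized.
#'
#' @param query A region table.
#' @param universe A `universe` tibble (sorted, non-overlapping outer spans).
#' @param quiet Suppress the untokenized-count message.
#' @return A tibble with one row per (query, universe region) overlap:
#'   `query_id` (row index into the sorted query), `universe_id` (row index
#'   into the universe, `NA` when untokenized), plus the query coordinates.
#' @export
tokenize_regions <- function(query, universe, quiet = FALSE) {
  query <- as_region_tbl(query)
  query$query_id <- seq_len(nrow(query))
  out <- lapply(split(query, query$chrom), function(d) {
    u <- universe[universe$chrom == d$chrom[1], , drop = FALSE]
    if (nrow(u) == 0) {
      return(tibble(query_id = d$query_id, universe_id = NA_integer_))
    }
    hits <- IRanges::findOverlaps(to_iranges(d), to_iranges(u))
    uid <- match(
      paste(u$chrom, u$start, u$end)[S4Vectors::subjectHits(hits)],
      paste(universe$chrom, universe$start, universe$end))
    res <- tibble(query_id = d$query_id[S4Vectors::queryHits(hits)],
                  universe_id = uid)
    missed <- setdiff(d$query_id, res$query_id)
    if (length(missed)) {
      res <- bind_rows(res, tibble(query_id = missed,
                                   universe_id = NA_integer_))
    }
    res
  })
  res <- arrange(bind_rows(out), .data$query_id, .data$universe_id)
  res <- left_join(res, query, by = "query_id")
  n_untok <- sum(is.na(res$universe_id))
  if (!quiet && n_untok > 0) {
    message(sprintf("%d query region(s) untokenized (no universe overlap)", n_untok))
  }
  res[, c("query_id", "universe_id", "chrom", "start", "end")]
}
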