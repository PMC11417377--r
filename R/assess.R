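# Universe fit metrics: base-level overlap (precision / recall / F10),
# region boundary distance (RBD), and universe likelihood, each with a
# flexible-aware variant, plus collection-level aggregation.

#' Base-level confusion counts of a universe against one query set
#'
#' Treats the universe as a prediction of the query's base coverage:
#' TP = bases covered by both, FP = universe-only bases, FN = query-only
#' bases. For a flexible universe the full outer span counts as covered.
#' F10 is the F-beta score with beta = 10, weighting recall 10x over
#' precision; it is 0 when TP = 0, and recall against an empty query is 1
#' (vacuous).
#'
#' @param universe A `universe`.
#' @param query A region table (merged internally).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f10`.
#' @export
confusion <- function(universe, query) {
  q <- merge_regions(as_region_tbl(query))
  tp <- 0; fp <- 0; fn <- 0
  for (ch in union(unique(universe$chrom), unique(q$chrom))) {
    ui <- to_iranges(universe[universe$chrom == ch, , drop = FALSE])
    qi <- to_iranges(q[q$chrom == ch, , drop = FALSE])
    both <- sum(IRanges::width(IRanges::intersect(ui, qi)))
    tp <- tp + both
    fp <- fp + sum(IRanges::width(ui)) - both
    fn <- fn + sum(IRanges::width(qi)) - both
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  f10 <- fbeta(precision, recall, beta = 10)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f10 = f10)
}

fbeta <- function(p, r, beta = 10) {
  if (beta^2 * p + r <= 0) return(0)
  (1 + beta^2) * p * r / (beta^2 * p + r)
}

#' Collection-level F10 score
#'
#' @param universe A `universe`.
#' @param collection A collection tibble.
#' @return A list with `score` (mean F10 over sets) and `per_set` (tibble of
#'   per-set confusion counts and scores).
#' @export
f10_collection <- function(universe, collection) {
  if (nrow(collection) == 0) abort("empty collection")
  per_set <- collection |>
    group_by(set = .data$set) |>
    group_modify(~ confusion(universe, .x)) |>
    ungroup()
  list(score = mean(per_set$f10), per_set = per_set)
}

# ---- boundary distances -----------------------------------------------------

# distance from each point to the nearest of a set of disjoint sorted closed
# intervals [lo, hi] (0 if inside); NA when no interval exists
dist_points_to_intervals <- function(p, lo, hi) {
  if (length(lo) == 0) return(rep(NA_real_, length(p)))
  i <- findInterval(p, lo)
  d_here <- ifelse(i >= 1, pmax(p - hi[pmax(i, 1)], 0), Inf)
  d_next <- ifelse(i < length(lo), lo[pmin(i + 1, length(lo))] - p, Inf)
  pmin(d_here, d_next)
}

# distance from each closed interval [lo, hi] to the nearest of a set of
# sorted points (0 if any point falls inside)
dist_intervals_to_points <- function(lo, hi, p) {
  if (length(p) == 0) return(rep(NA_real_, length(lo)))
  p <- sort(p)
  j <- findInterval(hi, p)
  inside <- j >= 1 & p[pmax(j, 1)] >= lo
  d_below <- ifelse(j >= 1, lo - p[pmax(j, 1)], Inf)
  d_above <- ifelse(j < length(p), p[pmin(j + 1, length(p))] - hi, Inf)
  ifelse(inside, 0, pmin(d_below, d_above))
}

# universe boundary intervals by type; for a fixed universe both edges of
# each interval coincide with the point boundary
boundary_intervals <- function(universe, flexible) {
  list(start = tibble(chrom = universe$chrom, lo = universe$start,
                      hi = if (flexible) universe$core_start else universe$start),
       end = tibble(chrom = universe$chrom,
                    lo = if (flexible) universe$core_end else universe$end,
                    hi = universe$end))
}

#' Region boundary distances between a query set and a universe
#'
#' For every region boundary in the (merged) query, computes the distance to
#' the nearest universe boundary of the same type (starts match starts, ends
#' match ends), and vice versa from universe boundaries to query boundaries.
#' For a flexible universe the distance is 0 whenever the query boundary
#' falls inside the corresponding flexible boundary interval, and otherwise
#' the distance to the interval's nearest edge. Per-direction summaries are
#' medians; the combined RBD score is the weighted harmonic mean of the
#' closenesses 1/(1 + d) with weights `weights[1]` (query to universe) and
#' `weights[2]` (universe to query), so RBD = 1 exactly when both median
#' distances are 0. When one side has no boundary on a chromosome, the
#' distance for the other side's boundaries there is the maximal coordinate
#' observed on that chromosome.
#'
#' @param query A region table.
#' @param universe A non-empty `universe`.
#' @param flexible Use the flexible containment rule (defaults to the
#'   universe's flavor).
#' @param weights Harmonic-mean weights, query-to-universe first
#'   (default `c(10, 1)`).
#' @return A one-row tibble: `d_qu`, `d_uq`, `rbd`.
#' @export
boundary_distances <- function(query, universe,
                               flexible = is_flexible(universe),
                               weights = c(10, 1)) {
  if (nrow(universe) == 0) abort("universe is empty: boundary distances undefined")
  q <- merge_regions(as_region_tbl(query))
  if (nrow(q) == 0) abort("query is empty: boundary distances undefined")
  ub <- boundary_intervals(universe, flexible)
  d_qu <- c(); d_uq <- c()
  for (ch in union(unique(q$chrom), unique(universe$chrom))) {
    qd <- q[q$chrom == ch, , drop = FALSE]
    span <- max(c(qd$end, universe$end[universe$chrom == ch], 1))
    for (type in c("start", "end")) {
      u_int <- ub[[type]][ub[[type]]$chrom == ch, , drop = FALSE]
      q_pts <- if (type == "start") qd$start else qd$end
      dq <- dist_points_to_intervals(q_pts, u_int$lo, u_int$hi)
      du <- dist_intervals_to_points(u_int$lo, u_int$hi, q_pts)
      d_qu <- c(d_qu, ifelse(is.na(dq), span, dq))
      d_uq <- c(d_uq, ifelse(is.na(du), span, du))
    }
  }
  d_qu <- stats::median(d_qu)
  d_uq <- stats::median(d_uq)
  tibble(d_qu = d_qu, d_uq = d_uq,
         rbd = sum(weights) / (weights[1] * (1 + d_qu) + weights[2] * (1 + d_uq)))
}

#' Collection-level RBD score
#'
#' @inheritParams f10_collection
#' @inheritParams boundary_distances
#' @return A list with `score` (mean RBD over sets) and `per_set`.
#' @export
rbd_collection <- function(universe, collection,
                           flexible = is_flexible(universe),
                           weights = c(10, 1)) {
  if (nrow(collection) == 0) abort("empty collection")
  per_set <- collection |>
    group_by(set = .data$set) |>
    group_modify(~ boundary_distances(.x, universe, flexible, weights)) |>
    ungroup()
  list(score = mean(per_set$rbd), per_set = per_set)
}

# ---- universe likelihood ----------------------------------------------------

# per-region log-likelihood gain over an all-background labeling.
# Fixed regions label first base S, interior C, last base E (width-1: S
# only; width-2: S then E). Flexible regions treat the whole outer span as
# core-covered and aggregate the boundary-track probability over each
# boundary interval: log(min(1 - eps, sum p)) in place of the single-base
# term.
region_deltas <- function(universe, models, flexible = is_flexible(universe),
                          eps = 1e-12) {
  if (nrow(universe) == 0) return(numeric(0))
  out <- numeric(nrow(universe))
  for (ch in unique(universe$chrom)) {
    idx <- which(universe$chrom == ch)
    u <- universe[idx, , drop = FALSE]
    p <- model_probs(models, ch)
    logit_s <- log(p$starts) - log1p(-p$starts)
    logit_c <- log(p$core) - log1p(-p$core)
    logit_e <- log(p$ends) - log1p(-p$ends)
    cum_c <- c(0, cumsum(logit_c))
    cum_ps <- c(0, cumsum(p$starts))
    cum_pe <- c(0, cumsum(p$ends))
    cum_l1s <- c(0, cumsum(log1p(-p$starts)))
    cum_l1e <- c(0, cumsum(log1p(-p$ends)))
    for (r in seq_along(idx)) {
      ss <- u$start[r]; ee <- u$end[r]
      core_term <- cum_c[ee + 1] - cum_c[ss + 1]
      if (!flexible) {
        w <- ee - ss
        out[idx[r]] <- core_term + logit_s[ss + 1] +
          if (w >= 2) logit_e[ee] else 0
      } else {
        se <- u$core_start[r]; es <- u$core_end[r]
        ps_lo <- ss; ps_hi <- if (se > ss) se else ss + 1
        pe_lo <- if (ee > es) es else ee - 1; pe_hi <- ee
        sum_ps <- cum_ps[ps_hi + 1] - cum_ps[ps_lo + 1]
        sum_pe <- cum_pe[pe_hi + 1] - cum_pe[pe_lo + 1]
        start_term <- log(min(1 - eps, sum_ps)) -
          (cum_l1s[ps_hi + 1] - cum_l1s[ps_lo + 1])
        end_term <- log(min(1 - eps, sum_pe)) -
          (cum_l1e[pe_hi + 1] - cum_l1e[pe_lo + 1])
        out[idx[r]] <- core_term + start_term + end_term
      }
    }
  }
  out
}

#' Universe likelihood score
#'
#' Log-likelihood of the universe under the positional track models: every
#' position is labeled background except universe regions, scored with the
#' same label model as the maximum-likelihood path builder. `delta` is the
#' log-likelihood normalized by subtracting the likelihood of an empty
#' universe (all background), so the empty universe scores exactly 0; a
#' positive `delta` means the universe is more likely than no regions at
#' all. The flexible variant aggregates each boundary-track probability over
#' the corresponding flexible interval (capped at 1 - eps) so that wider
#' boundary intervals can only help, and scores the whole outer span on the
#' coverage track.
#'
#' @param universe A `universe`.
#' @param models A [track_models()] object.
#' @param flexible Use the flexible boundary rule (defaults to the
#'   universe's flavor).
#' @param eps Cap on the aggregated boundary probability.
#' @return A one-row tibble: `loglik`, `delta`.
#' @export
universe_likelihood <- function(universe, models,
                                flexible = is_flexible(universe),
                                eps = 1e-12) {
  runs <- models$tracks$runs
  a <- models$alpha; n <- models$n
  pr <- function(t) (t + a) / (n + 2 * a)
  background <- sum((runs$end - runs$start) *
                      (log1p(-pr(runs$starts)) + log1p(-pr(runs$core)) +
                         log1p(-pr(runs$ends))))
  delta <- sum(region_deltas(universe, models, flexible, eps))
  tibble(loglik = background + delta, delta = delta)
}

# ---- orchestration ----------------------------------------------------------

#' Assess the fit of a universe to a collection
#'
#' Computes any subset of the three fit metrics: per-set base-level overlap
#' (precision / recall / F10), per-set region boundary distance (RBD), and
#' the collection-level likelihood delta. F10 and RBD are averaged over sets
#' for the collection score; the likelihood is computed once for the whole
#' collection.
#'
#' @param universe A `universe`.
#' @param collection A collection tibble (`set`, `chrom`, `start`, `end`).
#' @param chrom_sizes Named chromosome lengths; required for the likelihood
#'   metric unless `models` is supplied.
#' @param metrics Subset of `c("f10", "rbd", "likelihood")`.
#' @param flexible Use flexible-aware variants (defaults to the universe's
#'   flavor).
#' @param alpha Pseudocount for the track models (likelihood metric).
#' @param rbd_weights RBD harmonic-mean weights.
#' @param models Optional precomputed [track_models()].
#' @return A `universe_fit` object; see [tidy.universe_fit()] and
#'   [glance.universe_fit()].
#' @export
assess_universe <- function(universe, collection, chrom_sizes = NULL,
                            metrics = c("f10", "rbd", "likelihood"),
                            flexible = is_flexible(universe), alpha = 1,
                            rbd_weights = c(10, 1), models = NULL) {
  metrics <- match.arg(metrics, c("f10", "rbd", "likelihood"), several.ok = TRUE)
  if (nrow(collection) == 0) abort("empty collection")
  per_set <- tibble(set = sort(unique(collection$set)))
  summary <- tibble(method = attr(universe, "method") %||% NA_character_,
                    flexible = flexible, n_regions = nrow(universe))
  if ("f10" %in% metrics) {
    f <- f10_collection(universe, collection)
    per_set <- left_join(per_set, f$per_set, by = "set")
    summary$mean_f10 <- f$score
  }
  if ("rbd" %in% metrics) {
    r <- rbd_collection(universe, collection, flexible, rbd_weights)
    per_set <- left_join(per_set, r$per_set, by = "set")
    summary$mean_rbd <- r$score
  }
  if ("likelihood" %in% metrics) {
    if (is.null(models)) {
      if (is.null(chrom_sizes)) {
        abort("likelihood metric needs `chrom_sizes` (or precomputed `models`)")
      }
      models <- track_models(compute_tracks(collection, chrom_sizes), alpha)
    }
    lk <- universe_likelihood(universe, models, flexible)
    summary$loglik <- lk$loglik
    summary$lik_delta <- lk$delta
  }
  structure(list(per_set = per_set, summary = summary, metrics = metrics,
                 flexible = flexible),
            class = "universe_fit")
}

#' @export
print.universe_fit <- function(x, ...) {
  cat("universe fit assessment\n")
  print(x$summary)
  invisible(x)
}

#' Per-set assessment table
#' @param x A `universe_fit` object.
#' @param ... Unused.
#' @method tidy universe_fit
#' @export
tidy.universe_fit <- function(x, ...) x$per_set

#' One-row collection-level summary
#' @param x A `universe_fit` object.
#' @param ... Unused.
#' @method glance universe_fit
#' @export
glance.universe_fit <- function(x, ...) x$summary

#' Write an assessment report as JSON and TSV
#'
#' @param fit A `universe_fit` object.
#' @param dir Output directory (created if needed); writes `report.json`
#'   (nested per-set and aggregate) and `report.tsv` (flat per-set table).
#' @return The directory, invisibly.
#' @export
write_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  round6 <- function(d) mutate(d, across(where(is.numeric), ~ round(.x, 6)))
  jsonlite::write_json(
    list(summary = round6(fit$summary), per_set = round6(fit$per_set)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(round6(fit$per_set), file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
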