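# Independent oracles used across the suite: per-base brute-force track and
# confusion counting, exhaustive enumeration of valid label paths, and a
# small random-collection generator. These deliberately avoid the package's
# plane-sweep / DP code paths.

# merge sorted intervals of one set, touching intervals collapse
oracle_merge <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- c(); me <- c()
  for (i in seq_along(starts)) {
    if (length(ms) && starts[i] <= me[length(me)]) {
      me[length(me)] <- max(me[length(me)], ends[i])
    } else {
      ms <- c(ms, starts[i]); me <- c(me, ends[i])
    }
  }
  list(start = ms, end = me)
}

# dense per-base tracks by explicit counting (position i at index i + 1)
oracle_tracks <- function(collection, chrom_sizes) {
  out <- list()
  for (chrom in names(chrom_sizes)) {
    L <- chrom_sizes[[chrom]]
    s <- integer(L); cv <- integer(L); e <- integer(L)
    for (nm in unique(collection$set)) {
      d <- collection[collection$set == nm & collection$chrom == chrom, ]
      if (nrow(d) == 0) next
      m <- oracle_merge(d$start, d$end)
      for (k in seq_along(m$start)) {
        a <- m$start[k]; b <- m$end[k]
        s[a + 1] <- s[a + 1] + 1L
        e[b] <- e[b] + 1L
        cv[(a + 1):b] <- cv[(a + 1):b] + 1L
      }
    }
    out[[chrom]] <- list(starts = s, core = cv, ends = e)
  }
  out
}

# per-base confusion counts over an explicit genome
oracle_confusion <- function(universe, query, chrom_sizes) {
  tp <- fp <- fn <- 0
  for (chrom in names(chrom_sizes)) {
    L <- chrom_sizes[[chrom]]
    inu <- logical(L); inq <- logical(L)
    u <- universe[universe$chrom == chrom, ]
    for (k in seq_len(nrow(u))) inu[(u$start[k] + 1):u$end[k]] <- TRUE
    q <- query[query$chrom == chrom, ]
    for (k in seq_len(nrow(q))) inq[(q$start[k] + 1):q$end[k]] <- TRUE
    tp <- tp + sum(inu & inq)
    fp <- fp + sum(inu & !inq)
    fn <- fn + sum(!inu & inq)
  }
  list(tp = tp, fp = fp, fn = fn)
}

# exhaustive max score over all valid 4-state label paths (vectorized growth)
oracle_path_max <- function(logemit, logtrans, loginit, logfinal) {
  L <- nrow(logemit)
  scores <- loginit + logemit[1, ]
  last <- 1:4
  keep <- is.finite(scores)
  scores <- scores[keep]; last <- last[keep]
  if (L > 1) {
    for (i in 2:L) {
      n <- length(scores)
      prev <- rep(seq_len(n), each = 4)
      nxt <- rep(1:4, times = n)
      sc <- scores[prev] + logtrans[cbind(last[prev], nxt)] + logemit[i, nxt]
      ok <- is.finite(sc)
      scores <- sc[ok]; last <- nxt[ok]
    }
  }
  max(scores + logfinal[last])
}

# documented label scoring matrix, built directly from track counts
oracle_sigma <- function(v, n, alpha) {
  p <- lapply(v, function(t) (t + alpha) / (n + 2 * alpha))
  cbind(B = log(1 - p$starts) + log(1 - p$core) + log(1 - p$ends),
        S = log(p$starts) + log(p$core) + log(1 - p$ends),
        C = log(1 - p$starts) + log(p$core) + log(1 - p$ends),
        E = log(1 - p$starts) + log(p$core) + log(p$ends))
}

lh_mask_log <- function() {
  m <- matrix(-Inf, 4, 4)
  m[1, c(1, 2)] <- 0; m[2, c(2, 3, 4)] <- 0; m[3, c(3, 4)] <- 0
  m[4, c(4, 1, 2)] <- 0
  m
}

# small random collection on a single chromosome
random_collection <- function(n_sets, L, max_regions = 5, min_w = 1, max_w = NULL) {
  if (is.null(max_w)) max_w <- max(2, L %/% 3)
  purrr::map_dfr(seq_len(n_sets), function(s) {
    k <- sample.int(max_regions, 1)
    w <- sample(seq(min_w, max_w), k, replace = TRUE)
    st <- vapply(w, function(wi) sample.int(L - wi + 1, 1) - 1, numeric(1))
    tibble::tibble(set = paste0("s", s), chrom = "chr1", start = st, end = st + w)
  })
}
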