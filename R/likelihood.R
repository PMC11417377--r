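# Positional likelihood models over the three signal tracks, the label
# scoring matrix, and the maximum-likelihood path universe.
#
# For track t in {starts, core, ends} with count t(i) out of n sets, the
# probability that position i is "on" for that track is the smoothed
# frequency p_t(i) = (t(i) + alpha) / (n + 2 alpha), strictly inside (0,1)
# for alpha > 0. A label l in {B, S, C, E} asserts a subset of tracks on:
#   B: none;  S: {starts, core};  C: {core};  E: {ends, core}
# (a start/end position is itself covered under the end-at-last-base track
# convention). The label score is the Bernoulli log-likelihood
#   sigma(i, l) = sum_t [ ON(l,t) log p_t(i) + (1 - ON(l,t)) log(1 - p_t(i)) ].

STATES <- c("B", "S", "C", "E")

# ON-set indicator, states x tracks (starts, core, ends)
ON_SETS <- matrix(c(0, 0, 0,
                    1, 1, 0,
                    0, 1, 0,
                    0, 1, 1),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(STATES, c("starts", "core", "ends")))

# allowed label transitions: B->{B,S}, S->{S,C,E}, C->{C,E}, E->{E,B,S}
TRANSITION_MASK <- matrix(c(1, 1, 0, 0,
                            0, 1, 1, 1,
                            0, 0, 1, 1,
                            1, 1, 0, 1),
                          nrow = 4, byrow = TRUE,
                          dimnames = list(STATES, STATES))

#' Positional track probability models
#'
#' @param tracks A `signal_tracks` object.
#' @param alpha Smoothing pseudocount (> 0), default 1.
#' @return A `track_models` object.
#' @export
track_models <- function(tracks, alpha = 1) {
  stopifnot(alpha > 0, tracks$n_sets >= 1)
  structure(list(tracks = tracks, alpha = alpha, n = tracks$n_sets),
            class = "track_models")
}

#' @export
print.track_models <- function(x, ...) {
  cat(sprintf("track models: n = %d sets, alpha = %g, background p = %.4f\n",
              x$n, x$alpha, x$alpha / (x$n + 2 * x$alpha)))
  invisible(x)
}

# dense per-position probabilities for one chromosome
model_probs <- function(models, chrom) {
  v <- track_vectors(models$tracks, chrom)
  lapply(v, function(t) (t + models$alpha) / (models$n + 2 * models$alpha))
}

# L x 4 label scoring matrix for one chromosome
scoring_matrix <- function(models, chrom) {
  p <- model_probs(models, chrom)
  L <- length(p$core)
  sig <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, STATES))
  for (k in seq_len(4)) {
    acc <- numeric(L)
    for (t in c("starts", "core", "ends")) {
      acc <- acc + if (ON_SETS[k, t] == 1) log(p[[t]]) else log1p(-p[[t]])
    }
    sig[, k] <- acc
  }
  sig
}

# convert a decoded state path (1=B,2=S,3=C,4=E over positions 0..L-1) into
# flexible regions; the transition mask guarantees S+ C* E+ structure.
path_to_flex <- function(path, chrom) {
  r <- rle(path)
  ends_at <- cumsum(r$lengths)
  starts_at <- ends_at - r$lengths  # 0-based genomic start of each run
  out <- list()
  i <- 1
  while (i <= length(r$values)) {
    if (r$values[i] == 2L) {
      ss <- starts_at[i]; se <- ends_at[i]
      j <- i + 1
      if (j <= length(r$values) && r$values[j] == 3L) j <- j + 1
      # grammar guarantees an E run here
      es <- starts_at[j]; ee <- ends_at[j]
      out[[length(out) + 1]] <- tibble(chrom = chrom, start = ss,
                                       core_start = se, core_end = es,
                                       end = ee)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  bind_rows(out)
}

lh_transitions <- function() {
  lt <- log(TRANSITION_MASK)  # 0 where allowed, -Inf otherwise
  lt
}

#' Maximum-likelihood path universe
#'
#' Labels every genome position background (B), region start (S), core (C)
#' or end (E) so that the summed label score is maximal over all labelings
#' consistent with the region grammar (regions are S+ C* E+ blocks separated
#' or abutting, background elsewhere; chromosomes are independent and a path
#' must begin in B or S and end in B or E). The optimal path is found by
#' dynamic programming; equal-score ties prefer B, then S, C, E. Each
#' decoded block becomes one flexible region whose boundary intervals are
#' the S and E runs.
#'
#' @param tracks A `signal_tracks` object (n >= 1 sets).
#' @param alpha Smoothing pseudocount for the track models (> 0).
#' @return A flexible `universe`; the total path log-likelihood is stored in
#'   the `params` attribute as `loglik`.
#' @export
lh_universe <- function(tracks, alpha = 1) {
  models <- track_models(tracks, alpha)
  lt <- lh_transitions()
  loginit <- c(0, 0, -Inf, -Inf)   # B or S
  logfinal <- c(0, -Inf, -Inf, 0)  # B or E
  total <- 0
  out <- purrr::map_dfr(names(tracks$chrom_sizes), function(chrom) {
    sig <- scoring_matrix(models, chrom)
    v <- viterbi4(sig, lt, loginit, logfinal)
    total <<- total + v$score
    path_to_flex(v$path, chrom)
  })
  if (nrow(out) == 0) {
    return(empty_universe("lh", params = list(alpha = alpha, loglik = total),
                          flexible = TRUE))
  }
  new_universe(out, method = "lh",
               params = list(alpha = alpha, loglik = total), flexible = TRUE)
}
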