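# Hidden Markov model universe: a tunable alternative to the
# maximum-likelihood path. Hidden states are the parts of a flexible region
# (background B, start S, core C, end E); the observations at each position
# are the three track counts, emitted as independent Binomial(n, theta)
# draws per track given the state.

#' HMM parameters
#'
#' Defaults: self-transition 0.9 for B and C and 0.5 for S and E, with the
#' remaining mass split evenly over the allowed moves (B to S; S to C or E;
#' C to E; E to B or S); emission success probabilities 0.5 for the tracks a
#' state asserts (starts and core for S, core for C, core and ends for E)
#' and 0.02 otherwise. Only structurally allowed transitions may be
#' non-zero, and every allowed transition must be positive.
#'
#' @param transitions Optional 4x4 row-stochastic matrix over states
#'   B, S, C, E.
#' @param emissions Optional 4x3 matrix of Binomial success probabilities
#'   (rows B, S, C, E; columns starts, core, ends), all in (0, 1).
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(transitions = NULL, emissions = NULL) {
  if (is.null(transitions)) {
    transitions <- matrix(c(0.90, 0.10, 0.00, 0.00,
                            0.00, 0.50, 0.25, 0.25,
                            0.00, 0.00, 0.90, 0.10,
                            0.25, 0.25, 0.00, 0.50),
                          nrow = 4, byrow = TRUE,
                          dimnames = list(STATES, STATES))
  }
  if (is.null(emissions)) {
    emissions <- matrix(c(0.02, 0.02, 0.02,
                          0.50, 0.50, 0.02,
                          0.02, 0.50, 0.02,
                          0.02, 0.50, 0.50),
                        nrow = 4, byrow = TRUE,
                        dimnames = list(STATES, c("starts", "core", "ends")))
  }
  transitions <- matrix(as.numeric(transitions), 4, 4,
                        dimnames = list(STATES, STATES))
  emissions <- matrix(as.numeric(emissions), 4, 3,
                      dimnames = list(STATES, c("starts", "core", "ends")))
  if (any(abs(rowSums(transitions) - 1) > 1e-8)) {
    abort("each transition row must sum to 1")
  }
  if (any(transitions[TRANSITION_MASK == 0] != 0)) {
    abort("structurally forbidden transitions must have probability 0")
  }
  if (any(transitions[TRANSITION_MASK == 1] <= 0)) {
    abort("all structurally required transitions must have positive probability")
  }
  if (any(emissions <= 0 | emissions >= 1)) {
    abort("emission probabilities must lie strictly in (0, 1)")
  }
  structure(list(transitions = transitions, emissions = emissions),
            class = "hmm_params")
}

hmm_logemit <- function(v, n, emissions) {
  L <- length(v$core)
  le <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, STATES))
  for (k in seq_len(4)) {
    le[, k] <- stats::dbinom(v$starts, n, emissions[k, "starts"], log = TRUE) +
      stats::dbinom(v$core, n, emissions[k, "core"], log = TRUE) +
      stats::dbinom(v$ends, n, emissions[k, "ends"], log = TRUE)
  }
  le
}

hmm_decode_chrom <- function(tracks, chrom, params) {
  v <- track_vectors(tracks, chrom)
  le <- hmm_logemit(v, tracks$n_sets, params$emissions)
  pi0 <- params$transitions["B", c("B", "S")]
  loginit <- c(log(pi0 / sum(pi0)), -Inf, -Inf)  # start in B or S
  logfinal <- c(0, -Inf, -Inf, 0)                # end in B or E
  viterbi4(le, log(params$transitions), loginit, logfinal)
}

#' Hidden Markov model universe
#'
#' Viterbi-decodes the 4-state HMM over the three signal tracks and converts
#' the decoded S+ C* E+ blocks into flexible regions exactly as
#' [lh_universe()] does. Chromosomes are decoded independently; a path must
#' begin in B or S (with probability proportional to the B transition row)
#' and end in B or E. With `refine = TRUE`, emission probabilities are
#' re-estimated by hard (Viterbi) EM: decode, set each theta to the mean
#' observed track fraction within the decoded state, repeat until the path
#' is stable or `max_iter` is reached.
#'
#' @param tracks A `signal_tracks` object.
#' @param params An [hmm_params()] object.
#' @param refine Re-estimate emissions by Viterbi EM (default `FALSE`).
#' @param max_iter Maximum refinement iterations.
#' @return A flexible `universe`; the Viterbi log-probability is stored in
#'   `params` as `loglik`.
#' @export
hmm_universe <- function(tracks, params = hmm_params(), refine = FALSE,
                         max_iter = 10) {
  stopifnot(inherits(params, "hmm_params"), tracks$n_sets >= 1)
  chroms <- names(tracks$chrom_sizes)
  decode_all <- function(p) lapply(chroms, function(ch) hmm_decode_chrom(tracks, ch, p))
  dec <- decode_all(params)
  if (refine) {
    for (it in seq_len(max_iter)) {
      counts <- matrix(0, 4, 3); denom <- numeric(4)
      for (i in seq_along(chroms)) {
        v <- track_vectors(tracks, chroms[i])
        path <- dec[[i]]$path
        for (k in seq_len(4)) {
          sel <- path == k
          counts[k, ] <- counts[k, ] +
            c(sum(v$starts[sel]), sum(v$core[sel]), sum(v$ends[sel]))
          denom[k] <- denom[k] + sum(sel)
        }
      }
      theta <- (counts + 0.5) / (tracks$n_sets * pmax(denom, 1) + 1)
      theta <- pmin(pmax(theta, 1e-4), 1 - 1e-4)
      dimnames(theta) <- dimnames(params$emissions)
      new_params <- hmm_params(params$transitions, theta)
      new_dec <- decode_all(new_params)
      same <- all(purrr::map2_lgl(dec, new_dec,
                                  ~ identical(.x$path, .y$path)))
      params <- new_params
      dec <- new_dec
      if (same) break
    }
  }
  total <- sum(purrr::map_dbl(dec, "score"))
  out <- purrr::map_dfr(seq_along(chroms),
                        function(i) path_to_flex(dec[[i]]$path, chroms[i]))
  p <- list(transitions = params$transitions, emissions = params$emissions,
            refined = refine, loglik = total)
  if (nrow(out) == 0) return(empty_universe("hmm", params = p, flexible = TRUE))
  new_universe(out, method = "hmm", params = p, flexible = TRUE)
}
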