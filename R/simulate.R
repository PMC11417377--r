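# Seeded generator of synthetic region set collections that emulate the
# statistical structure of ATAC/ChIP peak collections: a shared set of true
# loci observed in each set with per-boundary jitter, per-set locus dropout,
# and spurious background regions.

#' Simulate a collection of region sets around shared true loci
#'
#' Places `k` non-overlapping true loci on the genome (gaps of at least
#' `8 * jitter_sd` bases so jittered observations cannot merge across
#' loci), then builds `n_sets` region sets: each locus is observed with
#' probability `1 - dropout_p`, with both boundaries independently shifted
#' by rounded Gaussian jitter (truncated so start < end stays inside the
#' chromosome), plus `Poisson(noise_rate)` spurious regions per set placed
#' uniformly with widths from the locus width distribution. The ground
#' truth is returned as a flexible universe whose boundary intervals span
#' two jitter standard deviations on each side of the true boundaries.
#'
#' @param n_sets Number of region sets (default 10).
#' @param k Number of true loci (default 50).
#' @param genome Named numeric vector of chromosome lengths
#'   (default `c(chr1 = 1e5)`).
#' @param locus_width_mean,locus_width_sd Locus width distribution in bases.
#' @param jitter_sd Per-boundary Gaussian jitter standard deviation (bases).
#' @param dropout_p Probability a locus is absent from a set.
#' @param noise_rate Expected spurious regions per set.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A list: `collection` (tibble `set`, `chrom`, `start`, `end`),
#'   `truth` (flexible `universe` around the true loci), and `loci`
#'   (the true fixed loci as a region table).
#' @export
simulate_collection <- function(n_sets = 10, k = 50, genome = c(chr1 = 1e5),
                                locus_width_mean = 300, locus_width_sd = 50,
                                jitter_sd = 5, dropout_p = 0.2,
                                noise_rate = 2, seed = NULL) {
  stopifnot(n_sets >= 1, k >= 1, all(genome > 0),
            dropout_p >= 0, dropout_p <= 1, noise_rate >= 0, jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  gap <- max(1, 8 * jitter_sd)
  # allocate loci to chromosomes proportionally to length
  k_per <- diff(round(k * cumsum(c(0, genome)) / sum(genome)))
  names(k_per) <- names(genome)
  loci <- purrr::map_dfr(names(genome), function(chrom) {
    ki <- k_per[[chrom]]
    if (ki == 0) return(NULL)
    L <- genome[[chrom]]
    w <- pmax(1, round(stats::rnorm(ki, locus_width_mean, locus_width_sd)))
    slack <- L - sum(w) - (ki + 1) * gap
    if (slack < 0) {
      abort(sprintf("cannot place %d loci on %s (%g bp): use a larger genome",
                    ki, chrom, L))
    }
    extra <- diff(c(0, sort(stats::runif(ki)))) * slack
    starts <- gap + cumsum(extra) + cumsum(c(0, (w + gap)[-ki]))
    tibble(chrom = chrom, start = floor(starts), end = floor(starts) + w)
  })
  loci <- arrange(loci, .data$chrom, .data$start)
  j2 <- 2 * jitter_sd
  truth <- new_universe(
    tibble(chrom = loci$chrom,
           start = pmax(0, loci$start - j2),
           core_start = loci$start + j2,
           core_end = loci$end - j2,
           end = unname(pmin(genome[loci$chrom], loci$end + j2))),
    method = "truth",
    params = list(k = k, jitter_sd = jitter_sd), flexible = TRUE)
  sets <- purrr::map_dfr(seq_len(n_sets), function(s) {
    keep <- stats::runif(nrow(loci)) >= dropout_p
    obs <- loci[keep, , drop = FALSE]
    if (nrow(obs) > 0 && jitter_sd > 0) {
      L <- genome[obs$chrom]
      s2 <- obs$start + round(stats::rnorm(nrow(obs), 0, jitter_sd))
      e2 <- obs$end + round(stats::rnorm(nrow(obs), 0, jitter_sd))
      s2 <- pmin(pmax(s2, 0), L - 1)
      e2 <- pmin(pmax(e2, s2 + 1), L)
      obs$start <- s2; obs$end <- e2
    }
    noise <- purrr::map_dfr(names(genome), function(chrom) {
      nn <- stats::rpois(1, noise_rate * genome[[chrom]] / sum(genome))
      if (nn == 0) return(NULL)
      w <- pmax(1, round(stats::rnorm(nn, locus_width_mean, locus_width_sd)))
      w <- pmin(w, genome[[chrom]])
      st <- floor(stats::runif(nn, 0, genome[[chrom]] - w))
      tibble(chrom = chrom, start = st, end = st + w)
    })
    mutate(bind_rows(obs, noise), set = sprintf("set%02d", s), .before = 1)
  })
  collection <- arrange(sets, .data$set, .data$chrom, .data$start, .data$end)
  list(collection = collection, truth = truth, loci = loci)
}

#' Write a simulated collection to disk
#'
#' Writes one BED3 file per set plus the ground truth as a flexible BED8
#' (`truth.bed8`) and the genome as `genome.chrom.sizes`.
#'
#' @param sim Result of [simulate_collection()].
#' @param dir Output directory (created if needed).
#' @param genome Named chromosome lengths to write alongside.
#' @return The directory, invisibly.
#' @export
write_collection <- function(sim, dir, genome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in unique(sim$collection$set)) {
    d <- sim$collection[sim$collection$set == s, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d", d$chrom, as.integer(d$start),
                       as.integer(d$end)),
               file.path(dir, paste0(s, ".bed")))
  }
  write_flexible_bed(sim$truth, file.path(dir, "truth.bed8"))
  if (!is.null(genome)) {
    writeLines(sprintf("%s\t%d", names(genome), as.integer(genome)),
               file.path(dir, "genome.chrom.sizes"))
  }
  invisible(dir)
}
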