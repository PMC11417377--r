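coll_from_cov <- function(...) {
  # build a collection of single-interval sets; arguments are c(start, end)
  sets <- list(...)
  purrr::imap_dfr(sets, function(iv, i)
    tibble::tibble(set = paste0("s", i), chrom = "chr1",
                   start = iv[1], end = iv[2]))
}

test_that("union and intersection universes match base-level definitions", {
  coll <- coll_from_cov(c(0, 10), c(5, 15))
  u <- union_universe(coll)
  expect_equal(u$start, 0); expect_equal(u$end, 15)
  i <- intersection_universe(coll)
  expect_equal(i$start, 5); expect_equal(i$end, 10)

  # one set: union is the merged set itself
  one <- tibble::tibble(set = "a", chrom = "chr1", start = c(0, 5), end = c(6, 9))
  expect_equal(union_universe(one)$end, 9)

  # disjoint chroms: union concatenates, intersection is empty
  coll2 <- dplyr::bind_rows(
    tibble::tibble(set = "a", chrom = "chr1", start = 0, end = 5),
    tibble::tibble(set = "b", chrom = "chr2", start = 0, end = 5))
  expect_equal(nrow(union_universe(coll2)), 2)
  expect_equal(nrow(intersection_universe(coll2)), 0)

  empty <- tibble::tibble(set = character(), chrom = character(),
                          start = numeric(), end = numeric())
  expect_warning(ue <- union_universe(empty), "empty")
  expect_equal(nrow(ue), 0)
})

test_that("tiles universe bins chromosomes, keeping the final partial tile", {
  u <- tiles_universe(c(chr1 = 2500), tile_size = 1000)
  expect_equal(u$start, c(0, 1000, 2000))
  expect_equal(u$end, c(1000, 2000, 2500))
  expect_equal(nrow(tiles_universe(c(chr1 = 1000), 1000)), 1)
  expect_equal(nrow(tiles_universe(c(chr1 = 37), 1)), 37)
})

test_that("optimal cutoff is the smallest admissible integer, clamped to [1, n]", {
  expect_equal(optimal_cutoff(tibble::tibble(s_c = 10, g = 10), 5), 1L)
  expect_equal(optimal_cutoff(tibble::tibble(s_c = 55, g = 10), 8), 6L)
  expect_equal(optimal_cutoff(tibble::tibble(s_c = 0, g = 100), 4), 1L)
  expect_equal(optimal_cutoff(tibble::tibble(s_c = 900, g = 10), 7), 7L)
})

test_that("cc universe keeps maximal runs at or above the cutoff", {
  # coverage profile [0,1,2,2,1,0]
  coll <- coll_from_cov(c(1, 5), c(2, 4))
  tr <- compute_tracks(coll, c(chr1 = 6))
  u <- cc_universe(tr, 2)
  expect_equal(u$start, 2); expect_equal(u$end, 4)
  expect_warning(ue <- cc_universe(tr, 5), "empty")
  expect_equal(nrow(ue), 0)
})

test_that("cc at x = 1 is the union and at x = n the intersection", {
  set.seed(201)
  for (rep in 1:15) {
    L <- sample(30:150, 1)
    n <- sample(2:4, 1)
    coll <- random_collection(n, L)
    tr <- compute_tracks(coll, c(chr1 = L))
    u1 <- cc_universe(tr, 1)
    uu <- union_universe(coll)
    expect_equal(u1$start, uu$start)
    expect_equal(u1$end, uu$end)
    un <- suppressWarnings(cc_universe(tr, n))
    ui <- intersection_universe(coll)
    expect_equal(un$start, ui$start)
    expect_equal(un$end, ui$end)
    # anti-monotone in x: covered bases shrink as the cutoff grows
    covered <- function(u) sum(u$end - u$start)
    covs <- vapply(1:n, function(x)
      covered(suppressWarnings(cc_universe(tr, x))), numeric(1))
    expect_true(all(diff(covs) <= 0))
  }
})

test_that("ccf builds flexible regions from the two-cutoff profile", {
  # coverage profile [0,1,2,3,3,2,1,0]
  coll <- coll_from_cov(c(1, 7), c(2, 6), c(3, 5))
  tr <- compute_tracks(coll, c(chr1 = 8))
  u <- ccf_universe(tr, 2, 3)
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 2)
  expect_equal(u$core_start, 3)
  expect_equal(u$core_end, 5)
  expect_equal(u$end, 6)

  # collapse: lower = upper gives degenerate flexible regions = cc spans
  u2 <- ccf_universe(tr, 2, 2)
  cc2 <- cc_universe(tr, 2)
  expect_equal(u2$start, cc2$start)
  expect_equal(u2$end, cc2$end)
  expect_equal(u2$core_start, u2$start)
  expect_equal(u2$core_end, u2$end)

  # runs never reaching the upper cutoff are dropped
  coll3 <- coll_from_cov(c(0, 4), c(1, 3))  # coverage [1,2,2,1]
  tr3 <- compute_tracks(coll3, c(chr1 = 4))
  expect_warning(u3 <- ccf_universe(tr3, 2, 3), "empty")
  expect_equal(nrow(u3), 0)
})

test_that("ccf outer spans and cores cross-check against cc runs", {
  set.seed(202)
  for (rep in 1:15) {
    L <- sample(40:150, 1)
    n <- sample(3:5, 1)
    coll <- random_collection(n, L)
    tr <- compute_tracks(coll, c(chr1 = L))
    lo <- sample.int(n, 1); hi <- if (lo == n) n else sample(lo:n, 1)
    u <- suppressWarnings(ccf_universe(tr, lo, hi))
    lo_runs <- suppressWarnings(cc_universe(tr, lo))
    hi_runs <- suppressWarnings(cc_universe(tr, hi))
    if (nrow(u) == 0) next
    # every outer span is a lower-cutoff run containing an upper run
    expect_true(all(paste(u$chrom, u$start, u$end) %in%
                      paste(lo_runs$chrom, lo_runs$start, lo_runs$end)))
    # cores start/end on upper-cutoff run boundaries
    expect_true(all(u$core_start %in% hi_runs$start))
    expect_true(all(u$core_end %in% hi_runs$end))
    # lower runs reaching the upper cutoff are exactly the outer spans
    reached <- vapply(seq_len(nrow(lo_runs)), function(i)
      any(hi_runs$start >= lo_runs$start[i] & hi_runs$end <= lo_runs$end[i]),
      logical(1))
    expect_equal(sum(reached), nrow(u))
  }
})

test_that("default ccf cutoffs bracket the optimal cutoff", {
  d <- ccf_default_cutoffs(4, 10)
  expect_equal(d$x_lower, 2L)
  expect_equal(d$x_upper, 6L)
  d2 <- ccf_default_cutoffs(1, 3)
  expect_equal(d2$x_lower, 1L)
  expect_equal(d2$x_upper, 2L)
})

test_that("filter_universe drops short and low-likelihood regions", {
  u <- as_universe(tibble::tibble(chrom = "chr1", start = c(0, 20),
                                  end = c(5, 70)))
  f <- filter_universe(u, min_width = 10)
  expect_equal(nrow(f), 1)
  expect_equal(f$start, 20)
  expect_equal(nrow(filter_universe(u, min_width = 0)), 2)

  # a region over all-zero tracks scores below background and is dropped
  empty <- tibble::tibble(set = "a", chrom = "chr1", start = 90, end = 95)
  tr <- compute_tracks(empty, c(chr1 = 100))
  models <- track_models(tr, alpha = 1)
  u2 <- as_universe(tibble::tibble(chrom = "chr1", start = 5, end = 8))
  f2 <- filter_universe(u2, min_region_loglik = 0, models = models)
  expect_equal(nrow(f2), 0)
  expect_error(filter_universe(u2, min_region_loglik = 0), "models")
})

test_that("all builders emit non-overlapping sorted universes", {
  set.seed(203)
  for (rep in 1:5) {
    L <- 300
    coll <- random_collection(4, L, max_regions = 6)
    tr <- compute_tracks(coll, c(chr1 = L))
    us <- list(union_universe(coll), intersection_universe(coll),
               tiles_universe(c(chr1 = L), 50),
               suppressWarnings(cc_universe(tr)),
               suppressWarnings(ccf_universe(tr)),
               lh_universe(tr), hmm_universe(tr))
    for (u in us) {
      if (nrow(u) < 2) next
      expect_true(all(u$start[-1] >= u$end[-nrow(u)]))
      expect_true(all(u$start <= u$core_start & u$core_start <= u$core_end &
                        u$core_end <= u$end))
    }
  }
})
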