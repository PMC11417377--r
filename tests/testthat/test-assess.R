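fixed_u <- function(start, end) {
  as_universe(tibble::tibble(chrom = "chr1", start = start, end = end))
}

test_that("confusion counts and F10 match hand-derived values", {
  cf <- confusion(fixed_u(0, 10), tibble::tibble(chrom = "chr1", start = 0, end = 5))
  expect_equal(cf$tp, 5); expect_equal(cf$fp, 5); expect_equal(cf$fn, 0)
  expect_equal(cf$precision, 0.5); expect_equal(cf$recall, 1)
  expect_equal(cf$f10, 50.5 / 51, tolerance = 1e-12)

  # universe identical to the query: perfect scores
  q <- tibble::tibble(chrom = "chr1", start = c(0, 20), end = c(10, 30))
  cf2 <- confusion(as_universe(q), q)
  expect_equal(cf2$precision, 1); expect_equal(cf2$recall, 1)
  expect_equal(cf2$f10, 1)
})

test_that("confusion equals a per-base oracle on random instances", {
  set.seed(501)
  for (rep in 1:25) {
    L <- sample(50:500, 1)
    u <- union_universe(random_collection(2, L))
    q <- random_collection(1, L, max_regions = 5)[, c("chrom", "start", "end")]
    cf <- confusion(u, q)
    o <- oracle_confusion(u, merge_regions(q), c(chr1 = L))
    expect_equal(cf$tp, o$tp)
    expect_equal(cf$fp, o$fp)
    expect_equal(cf$fn, o$fn)
  }
})

test_that("union universe has perfect recall against its own members", {
  set.seed(502)
  for (rep in 1:5) {
    coll <- random_collection(4, 300, max_regions = 6)
    u <- union_universe(coll)
    f <- f10_collection(u, coll)
    expect_true(all(f$per_set$recall == 1))
    expect_true(all(f$per_set$fn == 0))
  }
})

test_that("f10_collection averages per-set scores", {
  u <- fixed_u(0, 10)
  coll <- dplyr::bind_rows(
    tibble::tibble(set = "a", chrom = "chr1", start = 0, end = 10),
    tibble::tibble(set = "b", chrom = "chr1", start = 0, end = 5))
  f <- f10_collection(u, coll)
  expect_equal(f$score, mean(f$per_set$f10))
  expect_equal(f$per_set$f10[f$per_set$set == "a"], 1)
  empty <- coll[0, ]
  expect_error(f10_collection(u, empty), "empty")
})

test_that("precision rises (FP never grows) as the cc cutoff increases", {
  set.seed(503)
  coll <- random_collection(4, 200, max_regions = 5)
  tr <- compute_tracks(coll, c(chr1 = 200))
  q <- coll[coll$set == "s1", c("chrom", "start", "end")]
  fps <- vapply(1:4, function(x) {
    u <- suppressWarnings(cc_universe(tr, x))
    if (nrow(u) == 0) 0 else confusion(u, q)$fp
  }, numeric(1))
  expect_true(all(diff(fps) <= 0))
})

test_that("boundary distances match hand-derived values and the flexible rule", {
  u <- fixed_u(0, 10)
  bd <- boundary_distances(tibble::tibble(chrom = "chr1", start = 2, end = 10), u)
  expect_equal(bd$d_qu, 1)  # median of (start: 2, end: 0)

  # identity: perfect score
  q <- tibble::tibble(chrom = "chr1", start = c(0, 30), end = c(10, 40))
  bd2 <- boundary_distances(q, as_universe(q))
  expect_equal(bd2$d_qu, 0); expect_equal(bd2$d_uq, 0); expect_equal(bd2$rbd, 1)

  # flexible containment: boundary inside the interval scores zero
  uf <- as_universe(tibble::tibble(chrom = "chr1", start = 0, core_start = 3,
                                   core_end = 8, end = 10), flexible = TRUE)
  bd3 <- boundary_distances(tibble::tibble(chrom = "chr1", start = 2, end = 9), uf)
  expect_equal(bd3$d_qu, 0)
  expect_equal(bd3$rbd, 1)

  expect_error(boundary_distances(q, fixed_u(numeric(0), numeric(0))), "universe")
})

test_that("rbd is translation invariant and flexible scoring never hurts", {
  set.seed(504)
  for (rep in 1:10) {
    L <- 500
    coll <- random_collection(3, L, max_regions = 5)
    tr <- compute_tracks(coll, c(chr1 = L))
    u <- suppressWarnings(ccf_universe(tr, 1, 2))
    if (nrow(u) == 0) next
    q <- coll[coll$set == "s1", c("chrom", "start", "end")]
    bd <- boundary_distances(q, u, flexible = TRUE)
    # translation by a constant
    shift <- 1000
    u2 <- as_universe(dplyr::mutate(tibble::as_tibble(u),
                                    start = start + shift,
                                    core_start = core_start + shift,
                                    core_end = core_end + shift,
                                    end = end + shift), flexible = TRUE)
    q2 <- dplyr::mutate(q, start = start + shift, end = end + shift)
    bd2 <- boundary_distances(q2, u2, flexible = TRUE)
    expect_equal(bd$rbd, bd2$rbd)
    # flexible >= fixed for the same universe
    bdf <- boundary_distances(q, u, flexible = FALSE)
    expect_true(bd$rbd >= bdf$rbd)
  }
})

test_that("likelihood delta is zero for the empty universe and signed sensibly", {
  coll <- dplyr::bind_rows(
    tibble::tibble(set = "a", chrom = "chr1", start = 1, end = 3),
    tibble::tibble(set = "b", chrom = "chr1", start = 1, end = 3))
  tr <- compute_tracks(coll, c(chr1 = 10))
  models <- track_models(tr, alpha = 1)

  empty <- fixed_u(numeric(0), numeric(0))
  expect_identical(universe_likelihood(empty, models)$delta, 0)

  # a region matching the signal scores above background
  good <- fixed_u(1, 3)
  expect_gt(universe_likelihood(good, models)$delta, 0)

  # a region over silent positions scores below background
  bad <- fixed_u(5, 8)
  expect_lt(universe_likelihood(bad, models)$delta, 0)
})

test_that("flexible likelihood dominates fixed and grows with wider boundaries", {
  sim <- simulate_collection(n_sets = 8, k = 10, genome = c(chr1 = 2e4),
                             jitter_sd = 3, dropout_p = 0, noise_rate = 0,
                             seed = 9)
  tr <- compute_tracks(sim$collection, c(chr1 = 2e4))
  models <- track_models(tr, alpha = 1)
  u <- lh_universe(tr)
  lk_flex <- universe_likelihood(u, models, flexible = TRUE)$delta
  lk_fixed <- universe_likelihood(u, models, flexible = FALSE)$delta
  expect_gte(lk_flex, lk_fixed)

  # widening a start boundary interval (outer span fixed) never decreases delta
  base <- tibble::as_tibble(u)
  deltas <- vapply(0:3, function(w) {
    b <- base
    b$core_start <- pmin(b$core_start + w, b$core_end)
    universe_likelihood(as_universe(b, flexible = TRUE), models,
                        flexible = TRUE)$delta
  }, numeric(1))
  expect_true(all(diff(deltas) >= -1e-9))
})

test_that("assess_universe orchestrates metrics and is deterministic", {
  sim <- simulate_collection(n_sets = 4, k = 5, genome = c(chr1 = 5e3),
                             jitter_sd = 0, dropout_p = 0, noise_rate = 0,
                             seed = 3)
  sizes <- c(chr1 = 5e3)
  u <- union_universe(sim$collection)
  fit_f <- assess_universe(u, sim$collection, sizes, metrics = "f10")
  expect_true("mean_f10" %in% names(glance(fit_f)))
  expect_false("mean_rbd" %in% names(glance(fit_f)))

  # self-collection: every set equals the universe
  fit <- assess_universe(u, sim$collection, sizes)
  expect_equal(glance(fit)$mean_f10, 1)
  expect_equal(glance(fit)$mean_rbd, 1)
  expect_gte(glance(fit)$lik_delta, 0)

  fit2 <- assess_universe(u, sim$collection, sizes)
  expect_identical(glance(fit), glance(fit2))
  expect_identical(tidy(fit), tidy(fit2))
  expect_equal(nrow(tidy(fit)), 4)
})

test_that("reports serialize to JSON and TSV", {
  sim <- simulate_collection(n_sets = 3, k = 4, genome = c(chr1 = 5e3),
                             jitter_sd = 1, dropout_p = 0, noise_rate = 0,
                             seed = 5)
  fit <- assess_universe(union_universe(sim$collection), sim$collection,
                         c(chr1 = 5e3))
  d <- withr::local_tempdir()
  write_report(fit, d)
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_true(all(c("summary", "per_set") %in% names(js)))
  tsv <- read.delim(file.path(d, "report.tsv"))
  expect_equal(nrow(tsv), 3)
  expect_true(all(c("f10", "rbd") %in% names(tsv)))
})
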