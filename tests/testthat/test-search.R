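test_that("a one-point grid at a minimum returns that minimum with occurrence 1", {
  pes <- test_pes()
  bk <- toy_backend(pes)
  well <- bk$optimize(c(0, 0))$par
  # a single-point grid whose one start is already at the well
  bk0 <- list(optimize = function(point) bk$optimize(well))
  grid1 <- enumerate_grid(simple_torsions(1, step = 180, period = 180))
  res <- run_search(grid1, bk0)
  expect_equal(nrow(res$conformers), 1L)
  expect_equal(res$conformers$occurrences, 1L)
  expect_equal(res$conformers$energy, bk$optimize(well)$value)
})

test_that("the 60-degree sweep finds every dense-scan well and nothing else", {
  pes <- test_pes()
  scan <- toy_minima_scan(pes, resolution_deg = 2)
  res <- run_search(enumerate_grid(simple_torsions(2)), toy_backend(pes))
  expect_equal(nrow(res$conformers), nrow(scan))
  # each search conformer coincides with exactly one scanned well
  for (r in seq_len(nrow(res$conformers))) {
    d <- vapply(seq_len(nrow(scan)), function(k) {
      protaff:::torus_distance(res$conformers$angles[[r]],
                               as.numeric(scan[k, 1:2]))
    }, numeric(1))
    expect_equal(sum(d < 2.5), 1L)
    expect_lt(min(abs(res$conformers$energy[r] - scan$energy)), 1e-6)
  }
  # occurrences conservation
  expect_equal(sum(res$conformers$occurrences),
               sum(res$records$converged))
  # broom accessors
  expect_equal(nrow(tidy(res)), nrow(res$conformers))
  expect_equal(glance(res)$n_starts, 36L)
})

test_that("finer grids never lose minima (resolution monotonicity)", {
  pes <- test_pes()
  e60 <- sort(run_search(enumerate_grid(simple_torsions(2, step = 60)),
                         toy_backend(pes))$conformers$energy)
  e30 <- sort(run_search(enumerate_grid(simple_torsions(2, step = 30)),
                         toy_backend(pes))$conformers$energy)
  escan <- sort(toy_minima_scan(pes, resolution_deg = 2)$energy)
  in_set <- function(x, set, tol = 1e-6) {
    all(vapply(x, function(v) any(abs(set - v) < tol), logical(1)))
  }
  expect_true(in_set(e60, e30))
  expect_true(in_set(e30, escan))
})

test_that("a failing backend start is recorded, not fatal", {
  pes <- test_pes()
  bk <- toy_backend(pes)
  flaky <- list(optimize = function(point) {
    if (point[1] == 0 && point[2] == 0) stop("boom")
    bk$optimize(point)
  })
  res <- run_search(enumerate_grid(simple_torsions(2)), flaky)
  expect_equal(nrow(res$records), 36L)
  expect_false(all(res$records$converged))
  expect_true(is.na(res$records$conformer[[1]]))
})

test_that("deduplication honours both thresholds jointly", {
  pair <- tibble::tibble(id = c("a", "b"),
                         energy = c(0, 0.005), A = c(1.0, 1.0 + 1e-4))
  expect_equal(nrow(deduplicate(pair)), 1L)
  pair2 <- tibble::tibble(id = c("a", "b"),
                          energy = c(0, 0.02), A = c(1.0, 1.0))
  expect_equal(nrow(deduplicate(pair2)), 2L)
  # differing only in A is still different
  pair3 <- tibble::tibble(id = c("a", "b"),
                          energy = c(0, 0.001), A = c(1.0, 1.001))
  expect_equal(nrow(deduplicate(pair3)), 2L)
})

test_that("deduplication matches an all-pairs union-find oracle and is idempotent", {
  set.seed(11)
  entries <- tibble::tibble(
    id = seq_len(100),
    energy = round(stats::runif(100, 0, 0.2), 3),
    A = 1 + sample(0:40, 100, replace = TRUE) * 1e-4
  )
  got <- deduplicate(entries)
  # oracle: threshold graph + connected components via igraph
  rel <- entries$energy - min(entries$energy)
  edges <- which(outer(rel, rel, function(a, b) abs(a - b) < 0.01) &
                   outer(entries$A, entries$A,
                         function(a, b) abs(a - b) <= 3e-4) &
                   upper.tri(diag(100)), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = seq_len(100)))
  comp <- igraph::components(g)$membership
  expect_equal(nrow(got), max(comp))
  # representatives are the per-component energy minima
  oracle_reps <- sort(vapply(seq_len(max(comp)), function(k) {
    min(entries$energy[comp == k])
  }, numeric(1)))
  expect_equal(sort(got$energy), oracle_reps)
  # idempotence
  again <- deduplicate(got)
  expect_equal(nrow(again), nrow(got))
  expect_equal(sort(again$energy), sort(got$energy))
})

test_that("filter_minima keeps real minima and refuses unevaluated entries", {
  entries <- tibble::tibble(id = 1:3, n_imaginary = c(0L, 1L, 0L))
  expect_equal(filter_minima(entries)$id, c(1L, 3L))
  entries$n_imaginary[2] <- NA_integer_
  expect_error(filter_minima(entries), "unevaluated")
  expect_error(filter_minima(tibble::tibble(id = 1)), "n_imaginary")
})
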