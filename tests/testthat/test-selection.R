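test_that("neighborhood_radius matches a sort-based brute force and handles edge cases", {
  same <- matrix(1, 5, 2)
  expect_equal(neighborhood_radius(same, 1:5, 2), 0)

  two <- rbind(c(0, 0), c(2, 0))
  expect_equal(neighborhood_radius(two, 1:2, 1), 2)

  set.seed(10)
  x <- matrix(rnorm(60), 30, 2)
  D <- as.matrix(dist(x))
  for (u in c(1, 5, 12)) {
    brute <- mean(vapply(1:30, function(m) sort(D[m, -m])[u], numeric(1)))
    expect_equal(neighborhood_radius(x, 1:30, u), brute)
  }
  expect_error(neighborhood_radius(x, 1:30, 0), "between 1 and")
  expect_error(neighborhood_radius(x, 1:30, 30), "between 1 and")
})

test_that("a constructed fixture assigns edge, internal, and boundary samples per the rules", {
  # class A on the x-axis at -2, -1, 0, 1, 2 (centroid 0, median distance 1);
  # class B flanks the extremes at +/-2.5, within reach of the u=1 radius.
  x <- rbind(c(-2, 0), c(-1, 0), c(0, 0), c(1, 0), c(2, 0),
             c(-2.5, 0), c(2.5, 0))
  data <- labeled_dataset(x, c(rep("A", 5), rep("B", 2)))
  sp <- select_edge_internal(data, class_index = 1, u = 1)
  expect_setequal(sp$edge, c(1L, 5L))       # far + foreign neighbours
  expect_setequal(sp$internal, 3L)          # near + pure neighbourhood
  # samples at exactly the median distance (rows 2 and 4) are unassigned
  expect_false(any(c(2L, 4L) %in% c(sp$edge, sp$internal)))
  expect_equal(sp$median_dist, 1)
})

test_that("the split defaults to the largest class and validates u", {
  d <- make_blobs(2, c(20, 10), dim = 2, separation = 2, noise_sd = 1,
                  seed = 2)
  sp <- select_edge_internal(d, u = 3)
  expect_equal(sp$class_index, 1L)
  expect_true(all(d$labels[c(sp$edge, sp$internal)] == sp$class_label))
  expect_error(select_edge_internal(d, u = 0), "0 < u < N_i")
  expect_error(select_edge_internal(d, u = 20), "0 < u < N_i")
})

test_that("split matches the rule-by-rule oracle and stays disjoint on random data", {
  for (seed in 1:25) {
    d <- make_rings(n_per_class = c(15, 15), radii = c(1, 2), dim = 2,
                    noise_sd = 0.25, seed = seed)
    sp <- tryCatch(select_edge_internal(d, u = 6),
                   error = function(e) NULL)
    o <- oracle_split(d, class_index = 1, u = 6)
    if (is.null(sp)) {
      # the constructor refuses degenerate splits; oracle must agree
      expect_true(length(o$edge) == 0L || length(o$internal) == 0L)
      next
    }
    expect_setequal(sp$edge, o$edge)
    expect_setequal(sp$internal, o$internal)
    expect_length(intersect(sp$edge, sp$internal), 0)
  }
})

test_that("a noiseless spherical shell still yields a non-degenerate split", {
  shell <- make_rings(n_per_class = c(40, 20), radii = c(1, 1.35), dim = 3,
                      noise_sd = 0, seed = 11)
  sp <- select_edge_internal(shell, u = 8)
  ni <- sum(shell$labels == sp$class_label)
  expect_lt(length(sp$edge), ni)      # not everything is an edge sample
  expect_gt(length(sp$edge), 0)
  expect_gt(length(sp$internal), 0)
})

test_that("objective reproduces the hand-evaluated value and flags degeneracy", {
  f <- kda_objective(0.9, c(0.1, 0.1, 0.3))
  expect_equal(f, (0.9 - 0.3) / sd(c(0.1, 0.1, 0.3)))
  expect_equal(f, 5.196152, tolerance = 1e-6)

  expect_warning(f0 <- kda_objective(c(0.5, 0.5), c(0.5, 0.5)), "zero spread")
  expect_true(is.na(f0))
  expect_error(kda_objective(numeric(0), c(0.1, 0.2)), "edge")
  expect_error(kda_objective(0.5, 0.1), "at least 2")
})

test_that("objective is scale-invariant and monotone in the edge maximum", {
  set.seed(5)
  re_ed <- runif(6, 0.4, 0.9)
  re_in <- runif(8, 0.0, 0.3)
  f <- kda_objective(re_ed, re_in)
  for (lam in c(0.2, 3)) {
    expect_equal(kda_objective(lam * re_ed, lam * re_in), f, tolerance = 1e-12)
  }
  bigger <- c(re_ed, max(re_ed) + 0.05)
  expect_gt(kda_objective(bigger, re_in), f)
})

test_that("select_scale returns the argmax with diagnostics, deterministically", {
  d <- demo_rings(1)
  one <- select_scale(d, candidates = 0.7, d = 1, u = 8)
  expect_equal(one$best, 0.7)

  sel <- select_scale(d, d = 1, u = 8)
  expect_true(sel$best %in% sel$candidates)
  expect_equal(nrow(sel$diagnostics), 8L)
  expect_equal(sel$diagnostics$objective,
               (sel$diagnostics$max_re_edge - sel$diagnostics$max_re_internal) /
                 sel$diagnostics$sd_re_internal)

  rev_sel <- select_scale(d, candidates = rev(sel$candidates), d = 1, u = 8)
  expect_equal(rev_sel$best, sel$best)
})

test_that("select_scale costs |S| KDA fits and no classifier calls; grid adds jackknife passes", {
  d <- demo_rings(2)
  counters_reset()
  select_scale(d, d = 1, u = 8)
  c1 <- counters_get()
  expect_equal(c1$kda_fits, 8L)
  expect_equal(c1$knn_calls, 0L)

  counters_reset()
  grid_search(d, d = 1, k = 5)
  c2 <- counters_get()
  expect_equal(c2$kda_fits, 8L)
  expect_equal(c2$knn_calls, 8L * nrow(d$x))  # a leave-one-out pass per candidate
})

test_that("grid_search accuracy table matches standalone per-candidate runs", {
  d <- demo_rings(3)
  cand <- c(0.2, 1, 3)
  gr <- grid_search(d, candidates = cand, d = 1, k = 5)
  for (i in seq_along(cand)) {
    jk <- jackknife(d, s = cand[i], d = 1, k = 5, mode = "fast")
    expect_equal(gr$diagnostics$accuracy[i], eval_metrics(jk$counts)$Q)
  }
  expect_equal(gr$best, min(cand[gr$diagnostics$accuracy ==
                                   max(gr$diagnostics$accuracy)]))
})

test_that("perfectly separated blobs tie every candidate and the smallest scale wins", {
  d <- make_blobs(2, 10, dim = 2, separation = 50, noise_sd = 0.5, seed = 4)
  gr <- grid_search(d, candidates = c(1, 2, 3), d = 1, k = 3)
  expect_true(all(gr$diagnostics$accuracy == 1))
  expect_equal(gr$best, 1)
})

test_that("proposed selection agrees with the grid-search optimum on two-ring data", {
  agree <- 0L
  for (seed in 1:5) {
    d <- demo_rings(seed)
    sel <- select_scale(d, d = 1, u = 8)
    gr <- grid_search(d, d = 1, k = 5)
    acc_at_sel <- gr$diagnostics$accuracy[match(sel$best, gr$candidates)]
    if (acc_at_sel == max(gr$diagnostics$accuracy)) agree <- agree + 1L
  }
  expect_gte(agree, 4L)
})

test_that("downstream accuracy of the selected scale is invariant to u in 6..10", {
  d <- demo_rings(1)
  accs <- vapply(6:10, function(u) {
    sel <- select_scale(d, d = 1, u = u)
    jk <- jackknife(d, s = sel$best, d = 1, k = 5, mode = "fast")
    eval_metrics(jk$counts)$Q
  }, numeric(1))
  expect_equal(length(unique(accs)), 1L)
})
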