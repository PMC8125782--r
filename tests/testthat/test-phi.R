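test_that("phi matches hand values and errors on degenerate counts", {
  expect_equal(phiCoefficient(100, 50, 50, 25), 0) # exact independence
  expect_equal(phiCoefficient(100, 50, 50, 50), 1) # identical indicators
  expect_equal(phiCoefficient(100, 60, 40, 30), 0.25)
  expect_error(phiCoefficient(100, 0, 50, 0), "zero-variance")
  expect_error(phiCoefficient(100, 100, 50, 50), "zero-variance")
  expect_error(phiCoefficient(100, 60, 40, 50), "Frechet")
  expect_error(phiCoefficient(100, 60, 60, 10), "Frechet") # below Pi+Pj-n
})

test_that("phi equals the Pearson correlation of explicit indicator vectors, exhaustively to n = 30", {
  for (n in 2:30) {
    for (Pi in 1:(n - 1)) {
      x <- c(rep(1, Pi), rep(0, n - Pi))
      for (Pj in 1:(n - 1)) {
        lo <- max(0L, Pi + Pj - n)
        hi <- min(Pi, Pj)
        cij <- lo:hi
        got <- phiCoefficient(n, Pi, Pj, cij)
        want <- vapply(cij, function(C) {
          # y overlaps x in exactly C of the first Pi positions
          y <- c(rep(1, C), rep(0, Pi - C), rep(1, Pj - C),
                 rep(0, n - Pi - (Pj - C)))
          stats::cor(x, y)
        }, numeric(1))
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("edgePhi carries audit columns and drops undefined edges with a warning", {
  d <- dpn_from_sets(list(c("A", "B"), c("A", "B"), c("A", "C")), level = 1L)
  # A is prescribed to every patient: phi(A,.) undefined
  expect_warning(ep <- edgePhi(d), "undefined")
  expect_equal(nrow(ep), 0L)

  d2 <- dpn_from_sets(list(c("A", "B"), c("A", "B"), "C", "D"), level = 1L)
  ep2 <- edgePhi(d2)
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$phi, 1) # identical indicators over the 4 patients
  expect_equal(ep2[, c("Pi", "Pj", "Cij")], data.frame(Pi = 2L, Pj = 2L, Cij = 2L),
               ignore_attr = TRUE)
})

test_that("thresholding keeps edges with phi >= phi*, nodes always retained", {
  d <- dpn_from_sets(list(c("A", "B"), c("A", "B"), c("C", "D"), "A", "C"),
                     level = 1L)
  all_edges <- thresholdNetwork(d, -1)
  expect_equal(nEdges(all_edges), nEdges(d))
  none <- thresholdNetwork(d, 1 + 1e-9)
  expect_equal(nEdges(none), 0L)
  expect_equal(nNodes(none), nNodes(d))

  # a mid threshold separates the strong pair from the weak one
  ep <- edgePhi(d)
  mid <- mean(range(ep$phi))
  kept <- thresholdNetwork(d, mid)
  expect_equal(nEdges(kept), sum(ep$phi >= mid))
})

test_that("retention curves are step functions of the edge phi values", {
  # all edges share phi = 0.25: fractions jump from 1 to 0 across it
  d <- dpn_from_sets(list(c("A", "B"), "A", "B", c("C", "D"), "C", "D"),
                     level = 1L)
  ep <- edgePhi(d)
  expect_equal(length(unique(ep$phi)), 1L)
  cv <- retentionCurve(d, grid = c(0.1, 0.5))
  expect_equal(cv@node_frac, c(1, 0))
  expect_equal(cv@edge_frac, c(1, 0))

  expect_error(retentionCurve(d, grid = numeric(0)), "empty")
  expect_error(retentionCurve(d, grid = c(0.5, 0.1)), "increasing")
})

test_that("retention fractions equal per-point re-thresholding on a simulated DPN", {
  set.seed(73)
  sim <- generateRecords(simConfig(n_patients = 400))
  d <- buildDPN(buildIncidence(sim$records, 3))
  grid <- phiGrid(25)
  cv <- retentionCurve(d, grid)
  ep <- suppressWarnings(edgePhi(d))
  n_edges0 <- nrow(ep)
  connected0 <- length(unique(c(ep$i, ep$j)))
  for (g in seq_along(grid)) {
    thr <- thresholdNetwork(d, grid[g])
    met <- nodeMetrics(thr, "unweighted")
    expect_equal(cv@edge_frac[g], nEdges(thr) / n_edges0)
    expect_equal(cv@node_frac[g], sum(met$ki > 0) / connected0)
  }
  expect_true(all(diff(cv@node_frac) <= 0))
  expect_true(all(diff(cv@edge_frac) <= 0))
})

test_that("logistic fit recovers noiseless parameters and flags degeneracy", {
  xs <- seq(-5, 0, length.out = 50)
  true <- list(A = 1, x0 = -1.5, s = 0.3)
  y <- true$A / (1 + exp((xs - true$x0) / true$s))
  fit <- fitLogistic(xs, y)
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-6)
  expect_equal(fit$x0, true$x0, tolerance = 1e-4)
  expect_equal(fit$s, true$s, tolerance = 1e-4)

  expect_error(fitLogistic(xs, rep(1, 50)), "degenerate")
  expect_error(fitLogistic(xs[1:3], y[1:3]), "4 distinct")
  expect_error(fitLogistic(xs, y + 2), "\\[0, 1\\]")
})

test_that("logistic midpoint is recovered within 3 SE under noise", {
  xs <- seq(-5, 0, length.out = 50)
  truth <- 1 / (1 + exp((xs + 1.5) / 0.3))
  x0s <- vapply(1:10, function(seed) {
    set.seed(seed)
    y <- pmin(pmax(truth + stats::rnorm(50, 0, 0.01), 0), 1)
    fitLogistic(xs, y)$x0
  }, numeric(1))
  se <- stats::sd(x0s) / sqrt(10)
  expect_lt(abs(mean(x0s) - (-1.5)), 3 * max(se, 1e-3))
})

test_that("phi-max of two analytic logistics sits at the closed-form stationary point", {
  # equal widths: the gap is symmetric about the midpoint of the two x0s
  node_fit <- list(A = 1, x0 = -1, s = 0.3, rss = 0, converged = TRUE)
  edge_fit <- list(A = 1, x0 = -2, s = 0.3, rss = 0, converged = TRUE)
  pm <- phiMax(node_fit, edge_fit)
  expect_gt(pm, 1e-2)
  expect_lt(pm, 1e-1)
  expect_equal(pm, 10^(-1.5), tolerance = 1e-4)

  # identical fits: gap identically zero -> NA
  expect_message(pm0 <- phiMax(node_fit, node_fit), "undefined")
  expect_true(is.na(pm0))

  bad <- node_fit; bad$converged <- FALSE
  expect_error(phiMax(bad, edge_fit), "converged")
})

test_that("phi-max is invariant to grid spacing within refinement tolerance", {
  set.seed(79)
  sim <- generateRecords(simConfig(n_patients = 800))
  d <- buildDPN(buildIncidence(sim$records, 3))
  cv_log <- fitRetention(retentionCurve(d, phiGrid(50)))
  lin_grid <- sort(unique(c(seq(1e-5, 1, length.out = 400), phiGrid(50))))
  cv_lin <- fitRetention(retentionCurve(d, lin_grid))
  expect_equal(log10(phiMaxOf(cv_log)), log10(phiMaxOf(cv_lin)), tolerance = 0.1)
})

test_that("thresholding at phi-max isolates the planted modules", {
  set.seed(83)
  sim <- generateRecords(simConfig(n_patients = 1500))
  d <- buildDPN(buildIncidence(sim$records, 5))
  cv <- fitRetention(retentionCurve(d))
  pm <- phiMaxOf(cv)
  expect_false(is.na(pm))
  ep <- suppressWarnings(edgePhi(d))
  key <- paste(ep$i, ep$j)
  within <- unlist(lapply(sim$modules, function(m) {
    pr <- t(combn(sort(m), 2)); paste(pr[, 1], pr[, 2])
  }))
  between <- character(0)
  for (a in 1:2) for (b in (a + 1):3) {
    between <- c(between, as.vector(outer(sim$modules[[a]], sim$modules[[b]],
                                          function(x, y) paste(pmin(x, y), pmax(x, y)))))
  }
  w <- ep$phi[key %in% within]
  btw <- ep$phi[key %in% between]
  expect_gt(mean(w >= pm), 0.9)
  expect_lt(mean(btw >= pm), 0.1)
})
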