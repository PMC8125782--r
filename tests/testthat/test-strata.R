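test_that("stratification produces disjoint sex-by-age groups covering the cohort", {
  rec <- data.frame(
    patient_id = c("P1", "P2"), sex = c("F", "M"),
    birth_year = c(1949L, 1949L), date = as.Date("2019-01-01"),
    atc5 = "J01CR02", stringsAsFactors = FALSE
  )
  st <- stratifyRecords(rec)
  expect_setequal(names(st), c("F_65+", "M_65+"))
  expect_equal(vapply(st, nrow, integer(1))[["F_65+"]], 1L)

  set.seed(87)
  sim <- generateRecords(simConfig(n_patients = 500))
  st2 <- stratifyRecords(sim$records)
  expect_lte(length(st2), 6L) # at most six sex-by-age groups
  expect_equal(sum(vapply(st2, nrow, integer(1))), nrow(sim$records))
  pats <- lapply(st2, function(s) unique(s$patient_id))
  expect_equal(sum(lengths(pats)), length(unique(sim$records$patient_id)))
})

test_that("binary layers have the right support, zero rows and phi gating", {
  d <- dpn_from_sets(list(c("A", "B"), "C"), level = 1L)
  uni <- c("A", "B", "C", "D")
  A <- binaryLayer(d, uni)
  expect_equal(sum(A), 2L) # one undirected edge = two 1-entries
  expect_equal(A["A", "B"], 1L)
  expect_true(all(A["D", ] == 0L)) # absent code: all-zero row
  expect_true(all(diag(A) == 0L))
  expect_identical(A, t(A))

  expect_true(all(binaryLayer(d, uni, phi_star = 1 + 1e-9) == 0L))
  expect_error(binaryLayer(d, c("A", "B")), "universe")
})

test_that("cross-layer distances: identity, hamming identity, and the naive oracle", {
  d <- dpn_from_sets(list(c("A", "B"), c("B", "C")), level = 1L)
  uni <- c("A", "B", "C")
  L <- binaryLayer(d, uni)
  D_self <- layerDistance(L, L)
  expect_equal(diag(D_self), stats::setNames(rep(0, 3), uni))
  expect_equal(D_self, t(D_self))

  # rows differing in exactly 4 positions are at distance 2
  A <- matrix(0L, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  B <- A
  A["a", c("b", "c")] <- 1L; A[c("b", "c"), "a"] <- 1L
  B["a", c("d", "e")] <- 1L; B[c("d", "e"), "a"] <- 1L
  expect_equal(layerDistance(A, B)["a", "a"], 2)

  set.seed(89)
  for (rep in 1:5) {
    n <- 20L
    X <- matrix(rbinom(n * n, 1, 0.3), n, n)
    X <- (X | t(X)) * 1L; diag(X) <- 0L
    Y <- matrix(rbinom(n * n, 1, 0.3), n, n)
    Y <- (Y | t(Y)) * 1L; diag(Y) <- 0L
    dimnames(X) <- dimnames(Y) <- list(sprintf("c%02d", 1:n), sprintf("c%02d", 1:n))
    D <- layerDistance(X, Y)
    for (i in sample.int(n, 4)) for (j in sample.int(n, 4)) {
      expect_equal(D[i, j], sqrt(sum((X[i, ] - Y[j, ])^2)))
      expect_equal(D[i, j]^2, sum(X[i, ] != Y[j, ])) # Hamming identity
    }
  }
  expect_error(layerDistance(A, B[1:3, 1:3]), "universe")
})

test_that("ward.D2 linkage matches hand cases and the naive Lance-Williams oracle", {
  # two points at distance 5 merge at height 5
  D2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- wardD2(D2)
  expect_equal(t2$height, 5)

  # collinear points 0, 1, 10: nearest pair merges first
  pts <- c(0, 1, 10)
  D3 <- as.matrix(stats::dist(pts))
  dimnames(D3) <- list(c("p0", "p1", "p10"), c("p0", "p1", "p10"))
  t3 <- wardD2(D3)
  expect_equal(sort(t3$merge[1, ]), c(-2, -1)) # {0, 1} first

  expect_error(wardD2(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  set.seed(97)
  for (rep in 1:50) {
    P <- matrix(stats::rnorm(12 * 3), 12, 3)
    D <- as.matrix(stats::dist(P))
    dimnames(D) <- list(sprintf("x%02d", 1:12), sprintf("x%02d", 1:12))
    tree <- wardD2(D)
    cop_pkg <- as.matrix(stats::cophenetic(tree))
    cop_oracle <- oracle_ward_d2_cophenetic(D)
    dimnames(cop_oracle) <- dimnames(D)
    expect_equal(cop_pkg[rownames(D), colnames(D)], cop_oracle,
                 tolerance = 1e-9)
    expect_true(all(diff(tree$height) >= -1e-12)) # no inversions
  }
})

test_that("cutClusters spans k = 1..n and recovers planted blobs", {
  set.seed(101)
  blob <- rbind(matrix(stats::rnorm(10 * 2, 0, 0.1), ncol = 2),
                matrix(stats::rnorm(10 * 2, 10, 0.1), ncol = 2))
  D <- as.matrix(stats::dist(blob))
  dimnames(D) <- list(sprintf("b%02d", 1:20), sprintf("b%02d", 1:20))
  tree <- wardD2(D)
  expect_length(unique(cutClusters(tree, 1L)), 1L)
  expect_length(unique(cutClusters(tree, 20L)), 20L)
  two <- cutClusters(tree, 2L)
  expect_length(unique(two[1:10]), 1L)
  expect_length(unique(two[11:20]), 1L)
  expect_true(two[1] != two[20])
  expect_error(cutClusters(tree, 0L), "k must be")
  expect_error(cutClusters(tree, 21L), "k must be")

  auto <- chooseK(D)
  expect_equal(auto$k, 2L)
  expect_gt(auto$silhouette, 0.9)
})

test_that("compareLayers runs end to end and symmetrises cross matrices", {
  set.seed(103)
  sim <- generateRecords(simConfig(n_patients = 600))
  st <- stratifyRecords(sim$records)
  eldest <- grep("65", names(st), value = TRUE)
  dF <- buildDPN(buildIncidence(st[[grep("^F", eldest, value = TRUE)]], 1))
  dM <- buildDPN(buildIncidence(st[[grep("^M", eldest, value = TRUE)]], 1))
  ld <- compareLayers(dF, dM)
  expect_s4_class(ld, "LayerDistance")
  expect_equal(dim(ld@D), c(length(ld@labels), length(ld@labels)))
  expect_true(all(ld@D >= 0))
  expect_true(all(abs(round(ld@D^2) - ld@D^2) < 1e-8)) # squared = integer
  expect_equal(sort(unique(ld@clusters)), seq_len(ld@k))
  expect_error(compareLayers(dF, buildDPN(buildIncidence(sim$records, 2))),
               "level")
})

test_that("same-parameter strata are closer than disjointly-moduled strata", {
  set.seed(105)
  shared_catalog <- generateCatalog(60)
  gen_layer <- function(seed, modules) {
    set.seed(seed)
    cfg <- simConfig(n_patients = 400, catalog_size = 60, modules = modules)
    sim <- generateRecords(cfg, catalog = shared_catalog)
    buildDPN(buildIncidence(sim$records, 5))
  }
  same_mods <- list(list(size = 4L, rate = 0.2, boost = 0.9))
  dA <- gen_layer(107, same_mods)
  dB <- gen_layer(109, same_mods)
  dC <- gen_layer(113, list(list(size = 12L, rate = 0.5, boost = 0.95)))
  uniAB <- sort(union(names(nodeWeights(dA)), names(nodeWeights(dB))))
  uniAC <- sort(union(names(nodeWeights(dA)), names(nodeWeights(dC))))
  d_same <- layerDistance(binaryLayer(dA, uniAB), binaryLayer(dB, uniAB))
  d_diff <- layerDistance(binaryLayer(dA, uniAC), binaryLayer(dC, uniAC))
  expect_lt(stats::median(diag(d_same)), stats::median(diag(d_diff)))
})
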