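# Distance matrices, spectral structure detection, cluster-size penalty,
# raw scoring and the universal score transform.

test_that("pairwise distances sum per-site contributions", {
  prof <- direct_profile(c(1.0, 0.5))
  expect_equal(pairwise_profile_distance(c(1, 1), c(1, 1), prof), 0)
  # one differing het site
  p1 <- direct_profile(1.2)
  expect_equal(pairwise_profile_distance(1, 0, p1), 1.2)
  # opposite-hom (4 * 1.0) plus het-vs-homref (0.5) = 4.5
  expect_equal(pairwise_profile_distance(c(0, 0), c(2, 1), prof), 4.5)
  expect_error(pairwise_profile_distance(c(0), c(2, 1), prof), "site")
})

test_that("the distance matrix equals the brute-force oracle entrywise", {
  set.seed(21)
  d <- runif(6, 0.1, 3)
  prof <- direct_profile(d)
  G <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                     prob = c(.5, .25, .2, .05)), nrow = 10)
  rownames(G) <- paste0("i", 1:10)
  dm <- build_distance_matrix(G, prof)
  expect_true(isSymmetric(dm$D))
  expect_equal(unname(diag(dm$D)), rep(0, 10))
  for (i in 1:10) for (j in 1:10)
    expect_equal(dm$D[i, j], brute_distance(G[i, ], G[j, ], d),
                 tolerance = 1e-10)
  # an empty profile yields an all-zero, flagged matrix
  dm0 <- build_distance_matrix(G[, 0, drop = FALSE], direct_profile(numeric(0)))
  expect_true(dm0$degenerate)
  expect_true(all(dm0$D == 0))
})

test_that("the Gaussian kernel uses the median bandwidth and is monotone", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  sim <- gaussian_similarity(D)
  expect_equal(sim$sigma, 2)              # median of (1, 2, 3)
  expect_equal(diag(sim$S), rep(1, 3))
  # strictly decreasing in distance for fixed sigma
  expect_true(sim$S[1, 2] > sim$S[1, 3])
  expect_true(sim$S[1, 3] > sim$S[2, 3])
  expect_equal(sim$S[1, 2], exp(-1 / 8))
  # all-zero distances give a degenerate kernel
  expect_true(gaussian_similarity(matrix(0, 4, 4))$degenerate)
})

test_that("eigengap detection finds planted blocks and ignores noise", {
  bc <- block_cohort()
  sim <- gaussian_similarity(build_distance_matrix(bc$G, bc$profile))
  det <- detect_structure(sim)
  expect_true(det$has_structure)
  expect_equal(det$k, 2L)
  # two individuals can never form detectable structure
  expect_false(detect_structure(gaussian_similarity(
    matrix(c(0, 5, 5, 0), 2)))$has_structure)
})

test_that("unstructured cohorts are declared structure-free", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    nsite <- 50; n <- 80
    d <- runif(nsite, 0.1, 1)
    G <- matrix(rbinom(n * nsite, 2, rep(runif(nsite, 0.1, 0.4), each = n)), n)
    det <- detect_structure(gaussian_similarity(
      build_distance_matrix(G, direct_profile(d))))
    hits <- hits + det$has_structure
  }
  expect_lte(hits, 10)   # no structure in >= 90% of null cohorts
})

test_that("relative eigengaps separate structured from null landscapes", {
  # the winning gap relative to the eigenvalue beneath it is orders of
  # magnitude smaller on unstructured cohorts than on genotype blocks,
  # which is what makes the 0.1 floor of detect_structure uncritical
  rel_gap <- function(sim) {
    ev <- genofirst:::laplacian_eigen(sim$S)$values
    lam <- ev[1:10]
    gaps <- diff(lam)
    k <- which.max(gaps[-1]) + 1L
    gaps[k] / lam[k]
  }
  null_rel <- vapply(1:20, function(s) {
    set.seed(s)
    G <- matrix(rbinom(80 * 50, 2, rep(runif(50, 0.1, 0.4), each = 80)), 80)
    rel_gap(gaussian_similarity(
      build_distance_matrix(G, direct_profile(runif(50, 0.1, 1)))))
  }, numeric(1))
  bc <- block_cohort()
  block_rel <- rel_gap(gaussian_similarity(
    build_distance_matrix(bc$G, bc$profile)))
  expect_lt(max(null_rel), 0.05)
  expect_gt(block_rel, 0.3)
})

test_that("spectral clustering recovers blocks and respects relabeling", {
  bc <- block_cohort()
  sim <- gaussian_similarity(build_distance_matrix(bc$G, bc$profile))
  asg <- embed_and_cluster(sim, 2)
  lab <- asg$labels
  expect_equal(length(unique(lab[1:16])), 1L)
  expect_equal(length(unique(lab[17:24])), 1L)
  expect_false(lab[1] == lab[17])
  # permuting individuals permutes labels consistently
  perm <- sample(nrow(bc$G))
  simp <- gaussian_similarity(build_distance_matrix(bc$G[perm, ], bc$profile))
  labp <- embed_and_cluster(simp, 2)$labels
  expect_equal(outer(labp, labp, "=="),
               outer(lab[perm], lab[perm], "=="),
               ignore_attr = TRUE)
})

test_that("k equal to n with distinct points gives singletons", {
  G <- diag(2, 4)
  rownames(G) <- paste0("i", 1:4)
  sim <- gaussian_similarity(build_distance_matrix(G, direct_profile(rep(1, 4))))
  asg <- embed_and_cluster(sim, 4)
  expect_equal(sort(as.integer(table(asg$labels))), rep(1L, 4))
})

test_that("the cluster-size penalty has forced endpoints and hand value", {
  expect_equal(size_penalty(100, 100), 0)
  expect_equal(size_penalty(100, 0), 1)
  # hand evaluation at half the cohort: (e^4.5 - 1) / (e^9 - 1)
  expect_equal(size_penalty(100, 50), 0.010987, tolerance = 1e-4)
  # strictly decreasing and continuous in cluster size
  mu <- size_penalty(1000, 0:1000)
  expect_true(all(diff(mu) < 0))
  expect_error(size_penalty(10, 11), "size_cluster")
})

test_that("without structure the raw score is the mean background distance", {
  set.seed(5)
  G <- matrix(rbinom(8 * 5, 2, 0.3), 8)
  rownames(G) <- paste0("i", 1:8)
  prof <- direct_profile(runif(5, 0.5, 2))
  dm <- build_distance_matrix(G, prof)
  sc <- raw_outlier_scores(dm, NULL, background = paste0("i", 1:6))
  for (i in 1:8) {
    others <- setdiff(1:6, i)
    expect_equal(sc$raw[i], mean(dm$D[i, others]))
  }
  expect_equal(sc$global, rep(0, 8))
  expect_equal(sc$combinatorial, rep(0, 8))
  expect_error(raw_outlier_scores(dm, NULL, background = integer(0)),
               "background")
})

test_that("adding a duplicate background genome follows the mean update", {
  set.seed(6)
  G <- matrix(rbinom(6 * 4, 2, 0.3), 6)
  rownames(G) <- paste0("i", 1:6)
  prof <- direct_profile(runif(4, 0.5, 2))
  dm1 <- build_distance_matrix(G, prof)
  s1 <- raw_outlier_scores(dm1, NULL, background = paste0("i", 1:6))
  G2 <- rbind(G, dup = G[3, ])
  dm2 <- build_distance_matrix(G2, prof)
  s2 <- raw_outlier_scores(dm2, NULL, background = rownames(G2))
  for (i in 1:6) {
    others <- setdiff(1:6, i)
    predicted <- (sum(dm1$D[i, others]) + dm1$D[i, 3]) / (length(others) + 1)
    expect_equal(s2$raw[i], predicted, tolerance = 1e-12)
  }
})

test_that("a whole-cohort cluster contributes no global distance", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  dimnames(D) <- list(paste0("i", 1:5), paste0("i", 1:5))
  dm <- structure(list(D = D, individuals = paste0("i", 1:5),
                       degenerate = FALSE), class = "distance_matrix")
  asg <- structure(list(has_structure = TRUE, k = 1L,
                        labels = setNames(rep(1L, 5), paste0("i", 1:5))),
                   class = "cluster_assignment")
  sc <- raw_outlier_scores(dm, asg, background = paste0("i", 1:5))
  expect_equal(sc$global, rep(0, 5))
  expect_equal(sc$mu, rep(0, 5))
  expect_equal(sc$raw, sc$local)
})

test_that("a far outlier inside a clustered term outscores its mean distance", {
  bc <- block_cohort(with_far = TRUE)
  sset <- score_term(bc$profile, bc$G)
  far <- "i25"
  sc <- sset$scores
  i <- match(far, sc$individual)
  expect_true(sset$has_structure)
  u <- mean(sset$dm$D[i, -i])
  expect_gt(sc$raw[i], u)
  expect_gt(sc$combinatorial[i], 0)
  expect_equal(sc$individual[which.max(sc$transformed)], far)
})

test_that("the rank-factor identity holds to 1e-12", {
  phi <- 150; N <- 40
  r <- 0:(N - 1)
  expect_equal(exp(-(1 + r / N) * phi) / exp(-phi), exp(-phi * r / N),
               tolerance = 1e-12)
})

test_that("transformed scores match the independent evaluation of the formula", {
  s <- c(10, 5, 2, 1, 0.5)
  tr <- transform_scores(s, phi = 150)
  expect_equal(tr$transformed, brute_transform(s, 150), tolerance = 1e-10)
  # the top score has rank 0 hence rank factor exactly 1
  expect_equal(tr$rank[1], 0)
  expect_true(all(tr$transformed >= 0 & tr$transformed <= 1))
  # ordering of transformed scores follows ordering of raw scores
  expect_equal(order(-tr$transformed), order(-s))
})

test_that("transformed scores stay in [0, 1] on random inputs and ties", {
  set.seed(9)
  for (rep in 1:20) {
    s <- rexp(sample(3:30, 1))
    s[sample(length(s), 1)] <- s[1]   # force a tie
    tr <- transform_scores(s)
    expect_true(all(tr$transformed >= 0 & tr$transformed <= 1))
    expect_true(all(diff(tr$transformed[order(-s)]) <= 1e-12))
  }
  # tied raw scores share a mean rank and an identical transform
  tr2 <- transform_scores(c(4, 4, 1))
  expect_equal(tr2$rank[1:2], c(0.5, 0.5))
  expect_equal(tr2$transformed[1], tr2$transformed[2])
})

test_that("degenerate score vectors are flagged, not errors", {
  z <- transform_scores(c(0, 0, 0))
  expect_true(attr(z, "degenerate"))
  expect_equal(z$transformed, rep(0, 3))
  # all-equal nonzero scores: min-max factor defined as 0
  e <- transform_scores(c(2, 2, 2))
  expect_equal(e$transformed, rep(0, 3))
  expect_error(transform_scores(5), "at least 2")
})

test_that("scoring is deterministic and a batch of one matches itself", {
  bc <- block_cohort()
  s1 <- score_term(bc$profile, bc$G)
  s2 <- score_term(bc$profile, bc$G)
  expect_identical(s1$scores, s2$scores)
  # restricting the batch to one appended individual reproduces its score:
  # the background plus that single individual is the same matrix either way
  bg <- paste0("i", 1:23)
  joint <- score_term(bc$profile, bc$G, background = bg)
  alone <- score_term(bc$profile, bc$G[c(bg, "i24"), ], background = bg)
  expect_equal(joint$scores$raw[joint$scores$individual == "i24"],
               alone$scores$raw[alone$scores$individual == "i24"])
})
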