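# Ablation-based explanation of outlier calls: variant roles, outlier
# types, frequency classes and the combinatorial contribution.

# A small cohort where one subject carries chosen dosages over a direct
# profile; seeds are fixed per test so the term has no hidden structure
# and the scoring path is fully checkable by hand.
role_world <- function(d, subject_dosage, n_bg = 9, seed = 31) {
  set.seed(seed)
  prof <- direct_profile(d)
  G <- matrix(rbinom(n_bg * length(d), 2, 0.05), n_bg)
  G <- rbind(G, subject_dosage)
  dimnames(G) <- list(c(paste0("b", seq_len(n_bg)), "subj"),
                      prof$sites$variant_id)
  list(profile = prof, G = G, background = paste0("b", seq_len(n_bg)))
}

test_that("ablating nothing reproduces the original score exactly", {
  w <- role_world(c(3, 1, 0.5), c(2, 1, 0))
  sset <- score_term(w$profile, w$G, background = w$background)
  orig <- sset$scores$transformed[sset$scores$individual == "subj"]
  expect_identical(
    ablate_and_rescore("subj", w$profile, w$G, character(0), w$background),
    orig)
})

test_that("ablating the only non-reference site matches a reference genome", {
  w <- role_world(c(3, 1, 0.5), c(2, 0, 0))
  # a genome with no alternate alleles, scored in the subject's place
  G_ref <- w$G
  G_ref["subj", ] <- 0
  ref_score <- score_term(w$profile, G_ref, background = w$background)
  ref <- ref_score$scores$transformed[ref_score$scores$individual == "subj"]
  expect_equal(
    ablate_and_rescore("subj", w$profile, w$G, "s1", w$background),
    ref, tolerance = 1e-12)
  # single-site fixture: the ablated score equals a from-scratch rerun
  w1 <- role_world(4, 2)
  G1 <- w1$G; G1["subj", 1] <- 0
  rerun <- score_term(w1$profile, G1, background = w1$background)
  expect_equal(
    ablate_and_rescore("subj", w1$profile, w1$G, "s1", w1$background),
    rerun$scores$transformed[rerun$scores$individual == "subj"])
  expect_error(ablate_and_rescore("subj", w1$profile, w1$G, "zz"),
               "not in profile")
})

test_that("variant roles match an independent brute-force implementation", {
  # <= 6 sites, 10 individuals, no hidden structure: the oracle recomputes
  # every single-site ablation score literally (loops, no shared code)
  d <- c(5, 2.5, 0.8, 0.3, 4, 1.2)
  w <- role_world(d, c(2, 1, 1, 0, 1, 0), seed = 38)
  params <- score_params(threshold = 0.45)
  sset <- score_term(w$profile, w$G, background = w$background, params = params)
  expect_false(sset$has_structure)
  roles <- classify_variant_roles("subj", w$profile, w$G,
                                  background = w$background, params = params)
  oracle_score <- function(G) {
    n <- nrow(G)
    D <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n)
      D[i, j] <- brute_distance(G[i, ], G[j, ], d)
    raw <- sapply(1:n, function(i) mean(D[i, setdiff(1:9, i)]))
    brute_transform(raw)[n]
  }
  orig <- oracle_score(w$G)
  expect_gte(orig, params$threshold)
  for (v in seq_along(d)) {
    Gv <- w$G
    Gv["subj", v] <- 0
    abl <- oracle_score(Gv)
    expected_role <-
      if (w$G["subj", v] == 0) "none"
      else if (abl < params$threshold) "required"
      else if (orig - abl > 1e-9) "contributing"
      else "none"
    expect_equal(roles$role[v], expected_role, label = paste("site", v))
    if (w$G["subj", v] > 0)
      expect_equal(roles$ablated_score[v], abl, tolerance = 1e-10)
  }
})

test_that("role assignment does not depend on site order", {
  d <- c(5, 2.5, 0.8, 0.3)
  w <- role_world(d, c(2, 1, 1, 0), seed = 47)
  params <- score_params(threshold = 0.45)
  roles <- classify_variant_roles("subj", w$profile, w$G,
                                  background = w$background, params = params)
  # a fixture rich enough to exercise required and contributing at once
  expect_setequal(unique(roles$role), c("required", "contributing", "none"))
  perm <- c(3, 1, 4, 2)
  prof2 <- w$profile
  prof2$sites <- prof2$sites[perm, ]
  roles2 <- classify_variant_roles("subj", prof2, w$G,
                                   background = w$background, params = params)
  expect_equal(roles2$role, roles$role[perm])
})

test_that("outlier types follow the required/contributing pattern", {
  # one dominant variant, nothing else carried: 1-a
  w <- role_world(c(6, 1, 0.4), c(2, 0, 0), seed = 3)
  params <- score_params(threshold = 0.3)
  sset <- score_term(w$profile, w$G, background = w$background, params = params)
  call <- classify_call(sset, "subj", w$profile, w$G,
                        background = w$background)
  expect_equal(sum(call$roles$role == "required"), 1L)
  expect_equal(call$type, "1-a")
  # one dominant plus a minor contributor: 1-b
  w2 <- role_world(c(6, 1, 0.4), c(2, 1, 0), seed = 12)
  ss2 <- score_term(w2$profile, w2$G, background = w2$background, params = params)
  call2 <- classify_call(ss2, "subj", w2$profile, w2$G,
                         background = w2$background)
  expect_equal(call2$type, "1-b")
  # three variants each necessary: 2-b (any single ablation kills the call)
  w3 <- role_world(c(2, 2, 2), c(1, 1, 1), seed = 47)
  params3 <- score_params(threshold = 0.28)
  ss3 <- score_term(w3$profile, w3$G, background = w3$background,
                    params = params3)
  s3 <- ss3$scores$transformed[ss3$scores$individual == "subj"]
  expect_gte(s3, params3$threshold)
  call3 <- classify_call(ss3, "subj", w3$profile, w3$G,
                         background = w3$background, params = params3)
  expect_equal(unname(sum(call3$roles$role == "required")), 3L)
  expect_equal(call3$type, "2-b")
})

test_that("redundant variants are contributing, and dominance gives 2-a", {
  # two variants each sufficient alone: neither required, both contribute
  w <- role_world(c(4, 4, 0.2), c(2, 2, 0), seed = 12)
  params <- score_params(threshold = 0.05)
  roles <- classify_variant_roles("subj", w$profile, w$G,
                                  background = w$background, params = params)
  expect_equal(roles$role[1:2], c("contributing", "contributing"))
  # no single required variant, one hugely dominant in drop: type 2-a
  w2 <- role_world(c(8, 2, 0.2), c(2, 2, 0), seed = 12)
  ss2 <- score_term(w2$profile, w2$G, background = w2$background, params = params)
  call2 <- classify_call(ss2, "subj", w2$profile, w2$G,
                         background = w2$background, params = params)
  expect_equal(sum(call2$roles$role == "required"), 0L)
  expect_equal(call2$type, "2-a")
})

test_that("frequency classes follow the zygosity-dependent MAF bands", {
  expect_equal(frequency_class(0.004, "het"), "rare")
  expect_equal(frequency_class(0.004, "hom_alt"), "rare")
  expect_equal(frequency_class(0.008, "het"), "low_frequency")
  expect_equal(frequency_class(0.008, "hom_alt"), "rare")
  expect_equal(frequency_class(0.03, "hom_alt"), "low_frequency")
  expect_equal(frequency_class(0.03, "het"), "common")
  expect_equal(frequency_class(0.10, "het"), "common")
  expect_equal(frequency_class(0.10, "hom_alt"), "common")
  # dosage form and vectorisation
  expect_equal(frequency_class(c(0.004, 0.03), c(1, 2)),
               c("rare", "low_frequency"))
  expect_error(frequency_class(0.7, "het"), "maf")
})

test_that("combinatorial contribution is zero without structure, positive with", {
  # a lone extreme subject over a flat background: the kernel is
  # degenerate (all background pairs identical), forcing the
  # no-structure path, where the contribution is zero by definition
  prof <- direct_profile(c(3, 1))
  G <- rbind(matrix(0L, 9, 2), c(2L, 1L))
  rownames(G) <- c(paste0("b", 1:9), "subj")
  sset <- score_term(prof, G, background = paste0("b", 1:9))
  expect_false(sset$has_structure)
  expect_equal(combinatorial_contribution(sset, "subj"), 0)
  # co-occurrence fixture: a small subgroup shares site 1; the subject
  # alone carries site 2 inside the subgroup, while site 2 is common
  # outside it ("rare only within its cluster")
  set.seed(61)
  n <- 100
  G2 <- matrix(0L, n, 3, dimnames = list(paste0("i", 1:n), NULL))
  grp <- 1:3
  G2[grp, 1] <- 2L
  G2[-grp, 2] <- rbinom(n - 3, 2, 0.4)
  G2[1, 2] <- 1L
  G2[, 3] <- rbinom(n, 2, 0.02)
  prof2 <- direct_profile(c(8, 12, 0.5))
  sset2 <- score_term(prof2, G2)
  expect_true(sset2$has_structure)
  expect_gt(combinatorial_contribution(sset2, "i1"), 0)
  expect_error(combinatorial_contribution(sset2, "nope"), "unknown")
})

test_that("planted outlier types are recovered at their planted proportions", {
  # ten small cohorts, each planting one single-variant outlier; the
  # classifier should label the planted call as single-variant type
  # (1-a or 1-b) in line with a 100% planted proportion, within
  # binomial error at n = 10 (>= 8 successes)
  hits <- 0; calls <- 0
  for (s in 1:10) {
    cf <- sim_config(seed = s, n_background = 120, n_subjects = 5,
                     n_terms = 40, n_domains = 12, domain_length = 40,
                     plants = list(list(type = "single_rare")))
    w <- generate_world(cf)
    r <- w$truth[[1]]
    prof <- build_term_profile(r$term, w$map, w$hits, w$variants, w$hmms)
    sset <- score_term(prof, w$genotypes, background = w$background)
    sc <- sset$scores
    if (sc$transformed[sc$individual == r$subject] < sset$params$threshold)
      next
    calls <- calls + 1
    cl <- classify_call(sset, r$subject, prof, w$genotypes,
                        background = w$background)
    if (cl$type %in% c("1-a", "1-b") &&
        r$variant_ids %in% cl$roles$variant_id[cl$roles$role == "required"])
      hits <- hits + 1
  }
  expect_gte(calls, 8)
  expect_gte(hits, 8)
})
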