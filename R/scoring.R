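#' Scoring parameters
#'
#' @param gamma penalty strength for large clusters (default 9; at this
#'   value a cluster holding over half the cohort loses more than 99% of
#'   its between-cluster distance).
#' @param phi rank-contribution strength of the score transform (default
#'   150, giving roughly the top 2% of ranks a material contribution).
#' @param threshold outlier-call threshold on the transformed score
#'   (default 0.022).
#' @param max_k largest cluster count considered by structure detection.
#' @param rho eigengap dominance factor (see [detect_structure()]).
#' @param seed RNG seed for K-means.
#' @param nstart K-means restarts.
#' @param sigma optional fixed Gaussian-kernel bandwidth (default: median
#'   heuristic).
#' @return List of class `score_params`.
#' @export
score_params <- function(gamma = 9, phi = 150, threshold = 0.022,
                         max_k = 10, rho = 3, seed = 1, nstart = 10,
                         sigma = NULL) {
  stopifnot(gamma > 0, phi > 0, threshold > 0, threshold < 1, max_k >= 2)
  structure(list(gamma = gamma, phi = phi, threshold = threshold,
                 max_k = max_k, rho = rho, seed = seed, nstart = nstart,
                 sigma = sigma),
            class = "score_params")
}

#' Cluster-size penalty on the between-cluster distance
#'
#' `mu = (exp(gamma * (size_cohort - size_cluster) / size_cohort) - 1) /
#' (exp(gamma) - 1)`.  Strictly decreasing in the cluster size, with the
#' endpoints forced: a cluster containing the whole cohort gets `mu = 0`
#' (its between-cluster distance is discounted entirely) and a vanishing
#' cluster gets `mu = 1`.  At the default `gamma = 9` a cluster holding
#' more than half the cohort is penalised by over 99%.
#'
#' @param size_cohort total number of individuals (positive).
#' @param size_cluster cluster size, in `[0, size_cohort]`; vectorised.
#' @param gamma penalty strength (> 0).
#' @return `mu` in `[0, 1]`.
#' @examples
#' size_penalty(100, 50)        # ~0.011: >99% penalty at half the cohort
#' @export
size_penalty <- function(size_cohort, size_cluster, gamma = 9) {
  stopifnot(gamma > 0, size_cohort > 0)
  if (any(size_cluster < 0 | size_cluster > size_cohort))
    stop_input("size_cluster must lie in [0, size_cohort]")
  expm1(((size_cohort - size_cluster) / size_cohort) * gamma) / expm1(gamma)
}

# Mean distance from each individual to the background members
# (excluding self).  This is the no-structure raw outlier score.
mean_background_distance <- function(D, bg_idx) {
  if (!length(bg_idx)) stop_input("background of size 0")
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    others <- setdiff(bg_idx, i)
    if (!length(others)) return(0)
    mean(D[i, others])
  }, numeric(1))
}

#' Raw outlier scores for every individual of a term
#'
#' Without hidden structure an individual's raw score is its mean genetic
#' distance to the background members.  With structure the score is the
#' sum of a local distance (mean distance to the other members of the
#' individual's cluster) and a global distance (mean distance between the
#' individual's cluster and the rest of the cohort) down-weighted by the
#' cluster-size penalty `mu`.  Both components are measured on the
#' original genetic-distance matrix so that clustered and unclustered
#' scores share a scale; the positive part of their difference is the
#' combinatorial contribution — extra score that exists only because
#' clustering made some variants conditionally rare.
#'
#' @param dm a [build_distance_matrix()] result.
#' @param assignment a `cluster_assignment`, or `NULL` for no structure.
#' @param background identifiers (or indices) of background individuals.
#' @param params a [score_params()].
#' @return Data frame: individual, raw, local, global, combinatorial,
#'   cluster, cluster_size, mu.
#' @export
raw_outlier_scores <- function(dm, assignment, background, params = score_params()) {
  D <- dm$D
  ids <- dm$individuals
  n <- length(ids)
  bg_idx <- if (is.character(background)) match(background, ids) else as.integer(background)
  if (anyNA(bg_idx) || !length(bg_idx)) stop_input("invalid background set")
  u <- mean_background_distance(D, bg_idx)
  if (is.null(assignment) || !isTRUE(assignment$has_structure)) {
    return(data.frame(individual = ids, raw = u, local = u, global = 0,
                      combinatorial = 0, cluster = NA_integer_,
                      cluster_size = NA_integer_, mu = NA_real_,
                      stringsAsFactors = FALSE))
  }
  labels <- assignment$labels
  local <- global <- mu <- numeric(n)
  csize <- integer(n)
  for (c in sort(unique(labels))) {
    members <- which(labels == c)
    outside <- which(labels != c)
    g <- if (length(outside)) mean(D[members, outside, drop = FALSE]) else 0
    m <- size_penalty(n, length(members), params$gamma)
    for (i in members) {
      others <- setdiff(members, i)
      local[i] <- if (length(others)) mean(D[i, others]) else 0
      global[i] <- g
      mu[i] <- m
      csize[i] <- length(members)
    }
  }
  raw <- local + mu * global
  data.frame(individual = ids, raw = raw, local = local, global = global,
             combinatorial = pmax(0, raw - u), cluster = as.integer(labels),
             cluster_size = csize, mu = mu, stringsAsFactors = FALSE)
}

#' Transform raw scores to the universal per-term scale
#'
#' Phenotype terms have wildly different raw-score distributions, so raw
#' scores are mapped to a comparable scale: the cube root of the product
#' of a rank factor `exp(-phi * rank / N)` (rank 0 for the top raw score;
#' ties share the mean of their rank range), the individual's share of the
#' term's total score, and a min-max factor.  Each factor lies in
#' `[0, 1]`, so transformed scores do too, and every factor is monotone in
#' the raw score, so the ordering is preserved.  All-equal scores give a
#' zero min-max factor (nobody is an outlier); an all-zero score vector is
#' flagged degenerate.
#'
#' @param s numeric vector of raw scores (length >= 2, non-negative).
#' @param phi rank-contribution strength.
#' @return Data frame: raw, rank (0-based), transformed; attribute
#'   `degenerate` when the total score is zero.
#' @export
transform_scores <- function(s, phi = 150) {
  if (length(s) < 2L) stop_input("need at least 2 scores")
  if (any(!is.finite(s)) || any(s < 0)) stop_input("raw scores must be finite and >= 0")
  N <- length(s)
  r <- rank(-s, ties.method = "average") - 1
  total <- sum(s)
  rng <- max(s) - min(s)
  if (total == 0) {
    out <- data.frame(raw = s, rank = r, transformed = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  # exp(-(1 + r/N) * phi) / exp(-phi) simplifies exactly to exp(-phi * r / N)
  rank_factor <- exp(-phi * r / N)
  share <- s / total
  minmax <- if (rng == 0) rep(0, N) else (s - min(s)) / rng
  out <- data.frame(raw = s, rank = r,
                    transformed = (rank_factor * share * minmax)^(1 / 3))
  attr(out, "degenerate") <- FALSE
  out
}

#' Score every individual of a cohort for one ontology term
#'
#' Runs the full per-term engine: distance matrix over the profile sites,
#' Gaussian-kernel similarity, eigengap structure detection, spectral
#' clustering when structure exists, raw local/global scoring with the
#' cluster-size penalty, and the universal score transform.  Individuals
#' of interest are scored jointly with (and effectively become part of)
#' the background, so batch composition can influence results; a batch of
#' one reproduces the single-individual run exactly.
#'
#' @param profile a [build_term_profile()] result.
#' @param genotypes dosage matrix, individuals x catalogue variants
#'   (column names are variant ids; extra columns are ignored).
#' @param background character vector of background identifiers; defaults
#'   to all individuals (self-background mode, as used for patient cohorts
#'   scored against themselves).
#' @param params a [score_params()].
#' @return Object of class `outlier_score_set`: `term_id`, `scores` data
#'   frame (individual, raw, local, global, combinatorial, rank,
#'   transformed, cluster, cluster_size), `has_structure`, `k`, `sigma`,
#'   `degenerate`, `n`, `missing_sites` (count of missing genotype calls
#'   imputed as hom_ref), `params`.
#' @export
score_term <- function(profile, genotypes, background = NULL,
                       params = score_params()) {
  G <- profile_genotypes(as.matrix(genotypes), profile)
  ids <- rownames(G) %||% paste0("ind", seq_len(nrow(G)))
  rownames(G) <- ids
  background <- background %||% ids
  dm <- build_distance_matrix(G, profile)
  sim <- NULL
  assignment <- NULL
  degenerate <- dm$degenerate
  if (!degenerate) {
    sim <- gaussian_similarity(dm, sigma = params$sigma)
    degenerate_kernel <- sim$degenerate
    if (!degenerate_kernel) {
      det <- detect_structure(sim, max_k = params$max_k, rho = params$rho)
      if (det$has_structure)
        assignment <- embed_and_cluster(sim, det$k, max_k = params$max_k,
                                        seed = params$seed,
                                        nstart = params$nstart)
    }
  }
  rawdf <- raw_outlier_scores(dm, assignment, background, params)
  tr <- transform_scores(rawdf$raw, phi = params$phi)
  scores <- cbind(rawdf[, c("individual", "raw", "local", "global",
                            "combinatorial")],
                  rank = tr$rank, transformed = tr$transformed,
                  rawdf[, c("cluster", "cluster_size", "mu")])
  structure(list(term_id = profile$term_id, scores = scores,
                 has_structure = !is.null(assignment),
                 k = if (is.null(assignment)) NA_integer_ else assignment$k,
                 sigma = if (is.null(sim)) NA_real_ else sim$sigma,
                 degenerate = degenerate || isTRUE(attr(tr, "degenerate")),
                 n = length(ids),
                 missing_sites = sum(is.na(G)),
                 params = params, background = background,
                 assignment = assignment, dm = dm),
            class = "outlier_score_set")
}

#' @export
print.outlier_score_set <- function(x, ...) {
  cat("<outlier_score_set>", x$term_id, "-", x$n, "individuals;",
      if (x$has_structure) paste("structure k =", x$k) else "no structure",
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' Above-threshold outlier calls from a score set
#'
#' @param sset an [score_term()] result.
#' @param threshold transformed-score threshold; default from the score
#'   set's parameters.
#' @return The rows of `sset$scores` at or above threshold, with term_id.
#' @export
outlier_calls <- function(sset, threshold = NULL) {
  threshold <- threshold %||% sset$params$threshold
  hit <- sset$scores$transformed >= threshold
  out <- sset$scores[hit, , drop = FALSE]
  if (nrow(out)) out <- cbind(term_id = sset$term_id, out)
  rownames(out) <- NULL
  out
}
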