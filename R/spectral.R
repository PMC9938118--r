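#' Gaussian-kernel similarity from a distance matrix
#'
#' `S = exp(-D^2 / (2 sigma^2))` elementwise.  The bandwidth follows the
#' median heuristic: `sigma` is the median off-diagonal distance.  When
#' every off-diagonal distance is zero the kernel is undefined and the
#' term is flagged degenerate, which downstream forces the no-structure
#' scoring path.
#'
#' @param dm a [build_distance_matrix()] result (or a plain symmetric
#'   matrix).
#' @param sigma optional fixed bandwidth overriding the median heuristic.
#' @return List: `S` (similarity matrix, unit diagonal), `sigma`,
#'   `degenerate`.
#' @export
gaussian_similarity <- function(dm, sigma = NULL) {
  D <- if (inherits(dm, "distance_matrix")) dm$D else as.matrix(dm)
  off <- D[upper.tri(D)]
  if (is.null(sigma)) sigma <- median(off)
  if (!length(off) || sigma == 0)
    return(list(S = diag(nrow(D)), sigma = 0, degenerate = TRUE))
  S <- exp(-D^2 / (2 * sigma^2))
  diag(S) <- 1
  dimnames(S) <- dimnames(D)
  list(S = S, sigma = sigma, degenerate = FALSE)
}

# Eigendecomposition of the symmetric normalised graph Laplacian
# L = I - Dg^{-1/2} S Dg^{-1/2}; eigenvalues returned ascending.
laplacian_eigen <- function(S) {
  deg <- rowSums(S)
  if (any(deg <= 0)) stop_input("similarity graph has an isolated vertex")
  isd <- 1 / sqrt(deg)
  L <- diag(nrow(S)) - (isd * S) * rep(isd, each = nrow(S))
  L <- (L + t(L)) / 2
  e <- eigen(L, symmetric = TRUE)
  if (any(!is.finite(e$values))) stop("non-finite Laplacian spectrum")
  list(values = rev(e$values), vectors = e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE])
}

#' Detect hidden structure in a term's genetic landscape
#'
#' Computes the spectrum of the symmetric normalised graph Laplacian of
#' the similarity matrix and looks for the biggest gap between consecutive
#' eigenvalues among the first `max_k`.  A cohort with `k` well-separated
#' groups has `k` near-zero eigenvalues followed by a jump, so the gap
#' position estimates the number of clusters.  Structure is declared only
#' when the winning gap (at position `k >= 2`) dominates: it must exceed
#' `rho` times the mean of the remaining gaps.  A gap at position 1 means
#' one connected component, i.e. no structure.
#'
#' @param sim result of [gaussian_similarity()] (or a similarity matrix).
#' @param max_k largest number of clusters considered (default 10).
#' @param rho dominance factor for the winning eigengap (default 3).
#' @param min_rel_gap floor on the winning gap relative to the eigenvalue
#'   level beneath it (default 0.1).  Unstructured cohorts have smoothly
#'   decaying spectra whose biggest gap is a tiny fraction of the
#'   eigenvalue below it (relative gaps around 0.01 in simulation), while
#'   even weakly separated genotype groups produce relative gaps above
#'   0.3, so any floor between those regimes behaves identically.
#' @return List: `has_structure`, `k` (NA when none), `eigenvalues`,
#'   `gaps`.
#' @export
detect_structure <- function(sim, max_k = 10, rho = 3, min_rel_gap = 0.1) {
  if (is.list(sim) && isTRUE(sim$degenerate))
    return(list(has_structure = FALSE, k = NA_integer_,
                eigenvalues = numeric(0), gaps = numeric(0)))
  S <- if (is.list(sim)) sim$S else sim
  n <- nrow(S)
  if (n < 4L)
    return(list(has_structure = FALSE, k = NA_integer_,
                eigenvalues = numeric(0), gaps = numeric(0)))
  ev <- laplacian_eigen(S)$values
  mk <- min(max_k, n)
  lam <- ev[seq_len(mk)]
  gaps <- diff(lam)                       # gaps[i] = lam[i+1] - lam[i]
  # only gaps among eigenvalues 2..max_k compete: the first gap separates
  # the trivial eigenvalue and implies k = 1, i.e. no structure
  cand <- seq_along(gaps)[-1]
  k <- cand[which.max(gaps[cand])]
  dominant <- length(cand) > 1L && gaps[k] > 0 &&
    gaps[k] > rho * mean(gaps[setdiff(cand, k)]) &&
    gaps[k] >= min_rel_gap * lam[k]
  list(has_structure = isTRUE(dominant),
       k = if (isTRUE(dominant)) as.integer(k) else NA_integer_,
       eigenvalues = ev, gaps = gaps)
}

#' Spectral embedding and K-means clustering
#'
#' Embeds individuals in the space of the leading Laplacian eigenvectors
#' and partitions them with K-means.  The embedding dimension `m` is
#' chosen by the elbow of the sorted eigenvalue curve (largest second
#' difference), never below `k`; embedding rows are unit-normalised, the
#' standard stabilisation for the normalised Laplacian.  K-means runs with
#' a fixed seed and `nstart` restarts; an empty-cluster failure triggers
#' one deterministic re-seed at `seed + 1`.
#'
#' @param sim result of [gaussian_similarity()] (or a similarity matrix).
#' @param k number of clusters (from [detect_structure()]).
#' @param max_k window for the elbow rule.
#' @param seed RNG seed for K-means.
#' @param nstart K-means restarts.
#' @return List of class `cluster_assignment`: `has_structure = TRUE`,
#'   `k`, `labels` (integer vector, names = individuals), `embedding`,
#'   `eigenvalues`, `m`.
#' @export
embed_and_cluster <- function(sim, k, max_k = 10, seed = 1, nstart = 10) {
  S <- if (is.list(sim)) sim$S else sim
  n <- nrow(S)
  stopifnot(k >= 2, k <= n)
  e <- laplacian_eigen(S)
  mk <- min(max_k, n)
  m <- if (mk >= 3L) {
    d2 <- diff(e$values[seq_len(mk)], differences = 2)  # at positions 2..mk-1
    # rounded so that numerically tied elbows resolve to the same m
    # regardless of the order individuals arrived in
    which.max(signif(d2, 8)) + 1L
  } else 2L
  m <- max(m, k)
  emb <- e$vectors[, seq_len(m), drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  emb <- emb / nrm
  rownames(emb) <- rownames(S)
  uniq <- unique(round(emb, 12))
  if (nrow(uniq) <= k) {
    # as many distinct embedded points as clusters: each its own cluster
    labels <- match(apply(round(emb, 12), 1, paste, collapse = ","),
                    apply(uniq, 1, paste, collapse = ","))
    k <- nrow(uniq)
  } else {
    # Lloyd handles the duplicate-heavy rows a spectral embedding of
    # discrete genotypes produces; Hartigan-Wong warns and stalls there.
    # An empty-cluster event triggers one deterministic re-seed; if it
    # persists, the empty clusters are simply dropped.
    try_km <- function(sd, strict = TRUE) with_seed(sd, tryCatch(
      withCallingHandlers(
        kmeans(emb, centers = k, nstart = nstart, iter.max = 200,
               algorithm = "Lloyd"),
        warning = function(w) {
          if (strict && grepl("empty cluster", conditionMessage(w)))
            stop("empty cluster")
          invokeRestart("muffleWarning")
        }),
      error = function(e2) NULL))
    km <- try_km(seed)
    if (is.null(km)) km <- try_km(seed + 1)
    if (is.null(km)) km <- try_km(seed + 1, strict = FALSE)
    labels <- match(km$cluster, sort(unique(km$cluster)))
    k <- length(unique(labels))
  }
  names(labels) <- rownames(S)
  structure(list(has_structure = TRUE, k = as.integer(k),
                 labels = as.integer(labels) |> setNames(rownames(S)),
                 embedding = emb, eigenvalues = e$values, m = m),
            class = "cluster_assignment")
}
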