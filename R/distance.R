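#' Per-site genetic distance between two genotypes
#'
#' Genotypes are alternate-allele dosages: 0 (`hom_ref`), 1 (`het`),
#' 2 (`hom_alt`); `NA` marks a missing call and is treated as `hom_ref`
#' (conservative: missingness never inflates an outlier score; callers
#' flag such sites).  Equal zygosities contribute nothing; genotypes that
#' differ contribute the site's functional distance, increased fourfold
#' when the two individuals are homozygous and opposite.  With dosages the
#' zygosity weight is exactly the squared dosage difference (1 for any
#' het/hom pair, 4 for opposite homozygotes).
#'
#' @param a,b dosage vectors (0/1/2/NA), recycled to common length.
#' @param d non-negative functional distance(s) of the site(s).
#' @return Non-negative numeric vector of per-site distances.
#' @examples
#' site_distance(0, 2, 1.386)  # opposite homozygotes: 4 * 1.386
#' site_distance(0, 1, 1.386)  # baseline differing pair
#' @export
site_distance <- function(a, b, d) {
  if (any(d < 0, na.rm = TRUE)) stop_input("functional distance must be >= 0")
  a <- dosage(a)
  b <- dosage(b)
  a[is.na(a)] <- 0L
  b[is.na(b)] <- 0L
  (a - b)^2 * d
}

# Normalise genotype input to integer dosage 0/1/2/NA.  Accepts integers
# or the zygosity labels hom_ref/het/hom_alt/missing.
dosage <- function(g) {
  if (is.character(g) || is.factor(g)) {
    g <- as.character(g)
    m <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)
    if (any(!g %in% names(m))) stop_input("unknown zygosity label")
    unname(m[g])
  } else {
    g <- as.integer(g)
    if (any(!g %in% c(0L, 1L, 2L) & !is.na(g)))
      stop_input("dosages must be 0, 1, 2 or NA")
    g
  }
}

#' Total genetic distance between two individuals over a term profile
#'
#' Sums [site_distance()] over every site of the profile for which the two
#' genotype vectors differ.
#'
#' @param ga,gb dosage vectors aligned to `profile$sites` (same order).
#' @param profile a [build_term_profile()] result.
#' @return Non-negative scalar.
#' @export
pairwise_profile_distance <- function(ga, gb, profile) {
  d <- profile$sites$distance
  if (length(ga) != length(d) || length(gb) != length(d))
    stop_input("genotype vectors must have one entry per profile site")
  sum(site_distance(ga, gb, d))
}

#' All-against-all distance matrix for one term
#'
#' Computes the symmetric matrix of summed per-site distances for every
#' pair of individuals.  Because the zygosity weight equals the squared
#' dosage difference, the matrix is a squared Euclidean distance on
#' dosages scaled by the square root of each site's functional distance,
#' which is what makes the all-against-all computation cheap.
#'
#' @param genotypes numeric matrix, individuals in rows (rownames are the
#'   identifiers), profile sites in columns, entries 0/1/2/NA.
#' @param profile a [build_term_profile()] result; `ncol(genotypes)` must
#'   equal the number of profile sites.
#' @return A list of class `distance_matrix`: `D` (symmetric, zero
#'   diagonal), `individuals`, and `degenerate` (`TRUE` when the profile is
#'   empty or no site varies, in which case `D` is all zero).
#' @export
build_distance_matrix <- function(genotypes, profile) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (n < 2L) stop_input("need at least 2 individuals")
  ids <- rownames(genotypes) %||% paste0("ind", seq_len(n))
  nsite <- nrow(profile$sites)
  if (ncol(genotypes) != nsite)
    stop_input("genotype matrix has ", ncol(genotypes),
               " columns but the profile has ", nsite, " sites")
  if (nsite == 0L) {
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    return(structure(list(D = D, individuals = ids, degenerate = TRUE),
                     class = "distance_matrix"))
  }
  G <- genotypes
  G[is.na(G)] <- 0
  W <- G %*% diag(sqrt(profile$sites$distance), nsite)
  D <- as.matrix(stats::dist(W))^2
  dimnames(D) <- list(ids, ids)
  structure(list(D = D, individuals = ids,
                 degenerate = all(D == 0)),
            class = "distance_matrix")
}
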