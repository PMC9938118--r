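# Hand-built fixtures shared across the suite.  Everything is generated in
# code; no binary files.

AA <- genofirst:::AA_ALPHABET

# A 3-state HMM with hand-chosen emission probabilities at state 1:
# P(A) = 0.4, P(V) = 0.1, everything else uniform on the remainder.
toy_hmm <- function() {
  em <- matrix(1 / 20, nrow = 3, ncol = 20, dimnames = list(NULL, AA))
  em[1, "A"] <- 0.4
  em[1, "V"] <- 0.1
  rest <- setdiff(AA, c("A", "V"))
  em[1, rest] <- (1 - 0.5) / length(rest)
  profile_hmm("TOY", em)
}

# A random (seeded) HMM for property-style checks.
random_hmm <- function(n_states = 10, seed = 7, id = "RND") {
  set.seed(seed)
  em <- matrix(rgamma(n_states * 20, 0.5), nrow = n_states)
  profile_hmm(id, em / rowSums(em))
}

# Minimal variant catalogue over one protein with two domains.
toy_catalogue <- function() {
  variant_catalogue(data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    ref = "A", alt = "G",
    protein_id = "PROT1",
    residue_index = c(5L, 12L, 30L, 60L),
    ref_aa = c("A", "A", "L", "K"),
    alt_aa = c("V", "G", "P", "E"),
    maf = c(0.001, 0.01, 0.2, 0.05),
    stringsAsFactors = FALSE))
}

# A tiny ontology: root with two children, one grandchild.
#   ROOT -> MID1 -> LEAF ; ROOT -> MID2
toy_ontology <- function() {
  ontology(data.frame(term_id = c("X:1", "X:2", "X:3", "X:4"),
                      name = c("root", "mid1", "mid2", "leaf"),
                      stringsAsFactors = FALSE),
           list("X:1" = character(0), "X:2" = "X:1", "X:3" = "X:1",
                "X:4" = "X:2"))
}

# Build a term profile directly from site distances, bypassing the HMM
# machinery, for engine-level tests.
direct_profile <- function(d, term_id = "X:test",
                           maf = rep(0.01, length(d))) {
  sites <- data.frame(
    variant_id = sprintf("s%d", seq_along(d)),
    protein_id = rep("P", length(d)), residue_index = seq_along(d),
    ref_aa = rep("A", length(d)), alt_aa = rep("V", length(d)),
    maf = maf, hmm_id = rep("H", length(d)),
    state = seq_along(d), distance = d, stringsAsFactors = FALSE)
  structure(list(term_id = term_id, empty = length(d) == 0L, sites = sites),
            class = "term_profile")
}

# Independent brute-force distance between two dosage vectors: literal
# per-site zygosity rules, no vectorisation tricks.
brute_distance <- function(ga, gb, d) {
  tot <- 0
  for (i in seq_along(d)) {
    a <- ga[i]; b <- gb[i]
    if (is.na(a)) a <- 0
    if (is.na(b)) b <- 0
    if (a == b) next
    w <- if ((a == 0 && b == 2) || (a == 2 && b == 0)) 4 else 1
    tot <- tot + w * d[i]
  }
  tot
}

# Independent step-by-step evaluation of the universal score transform.
brute_transform <- function(s, phi = 150) {
  N <- length(s)
  r <- rank(-s, ties.method = "average") - 1
  out <- numeric(N)
  for (p in seq_len(N)) {
    f_rank <- exp(-(1 + r[p] / N) * phi) / exp(-phi)
    f_share <- s[p] / sum(s)
    f_mm <- (s[p] - min(s)) / (max(s) - min(s))
    out[p] <- (f_rank * f_share * f_mm)^(1 / 3)
  }
  out
}

# A small two-block cohort with an optional far outlier appended.  The
# blocks are deliberately unbalanced (16 vs 8): with equal blocks the
# majority of pairs lies between the blocks, so the median kernel
# bandwidth lands on the between-block distance and blurs the structure.
block_cohort <- function(n1 = 16, n2 = 8, with_far = FALSE, seed = 11) {
  set.seed(seed)
  d <- c(30, 30, rep(0.3, 6))
  G <- rbind(
    cbind(2, 0, matrix(rbinom(n1 * 6, 2, 0.15), n1)),
    cbind(0, 2, matrix(rbinom(n2 * 6, 2, 0.15), n2)))
  if (with_far) G <- rbind(G, rep(2, 8))
  rownames(G) <- paste0("i", seq_len(nrow(G)))
  list(G = G, profile = direct_profile(d))
}
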