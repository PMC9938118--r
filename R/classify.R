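#' Re-score an individual with some of its variants ablated
#'
#' Ablation sets the individual's genotype at the excluded profile sites
#' to homozygous reference and reruns the full per-term engine.  The site
#' itself stays in the profile, so the background geometry is unchanged
#' for the rest of the cohort.  Excluding nothing reproduces the original
#' score exactly; excluding every site scores the individual as a
#' reference-only genome.  Deterministic given the scoring seed.
#'
#' @param individual identifier (a row name of `genotypes`).
#' @param profile a [build_term_profile()] result.
#' @param genotypes cohort dosage matrix (individuals x variants).
#' @param exclude character vector of profile variant ids to ablate.
#' @param background background identifiers (default: all).
#' @param params a [score_params()].
#' @return The individual's transformed score after ablation.
#' @export
ablate_and_rescore <- function(individual, profile, genotypes,
                               exclude = character(0), background = NULL,
                               params = score_params()) {
  genotypes <- profile_genotypes(as.matrix(genotypes), profile)
  if (!individual %in% rownames(genotypes))
    stop_input("unknown individual: ", individual)
  bad <- setdiff(exclude, profile$sites$variant_id)
  if (length(bad))
    stop_input("excluded variants not in profile: ",
               paste(bad, collapse = ", "))
  if (length(exclude)) genotypes[individual, exclude] <- 0
  sset <- score_term(profile, genotypes, background = background,
                     params = params)
  sset$scores$transformed[match(individual, sset$scores$individual)]
}

#' Classify the role of each variant behind an outlier call
#'
#' Each profile variant carried by the individual is ablated on its own
#' and the term re-scored.  A variant is `required` when its ablation
#' alone drops the transformed score below the call threshold,
#' `contributing` when it is not required but its ablation still strictly
#' decreases the score (beyond a numeric tolerance), and `none`
#' otherwise.  Variants the individual does not carry are `none` by
#' construction (their ablation is a no-op).
#'
#' @inheritParams ablate_and_rescore
#' @param threshold call threshold on the transformed score (default from
#'   `params`).
#' @param tol minimum decrease that counts as contributing.
#' @return Data frame: variant_id, dosage, role, ablated_score, drop
#'   (original minus ablated score); attribute `score` holds the original
#'   transformed score.
#' @export
classify_variant_roles <- function(individual, profile, genotypes,
                                   background = NULL,
                                   params = score_params(),
                                   threshold = NULL, tol = 1e-9) {
  threshold <- threshold %||% params$threshold
  genotypes <- profile_genotypes(as.matrix(genotypes), profile)
  orig <- ablate_and_rescore(individual, profile, genotypes,
                             character(0), background, params)
  if (orig < threshold)
    stop_input("individual ", individual, " is not above threshold (",
               signif(orig, 4), " < ", threshold, ")")
  vids <- profile$sites$variant_id
  dos <- as.integer(genotypes[individual, vids])
  dos[is.na(dos)] <- 0L
  ablated <- rep(orig, length(vids))
  carried <- which(dos > 0L)
  for (i in carried)
    ablated[i] <- ablate_and_rescore(individual, profile, genotypes,
                                     vids[i], background, params)
  drop <- orig - ablated
  role <- rep("none", length(vids))
  role[ablated < threshold] <- "required"
  role[role != "required" & drop > tol] <- "contributing"
  role[dos == 0L] <- "none"
  out <- data.frame(variant_id = vids, dosage = dos, role = role,
                    ablated_score = ablated, drop = drop,
                    stringsAsFactors = FALSE)
  attr(out, "score") <- orig
  out
}

#' Classify an outlier call into the four genetic types
#'
#' Types: `1-a` — a single variant is required and nothing else
#' contributes; `1-b` — a single required variant plus contributing
#' variant(s); `2-a` — no single variant is required on its own (or
#' several are) but one variant's solo effect dominates, its ablation drop
#' exceeding the summed drops of all the others; `2-b` — the call rests on
#' multiple variants jointly, none dominant.
#'
#' @param roles result of [classify_variant_roles()].
#' @return One of `"1-a"`, `"1-b"`, `"2-a"`, `"2-b"`.
#' @export
classify_outlier_type <- function(roles) {
  eff <- roles[roles$role != "none", , drop = FALSE]
  if (!nrow(eff))
    stop("inconsistent call: no variant has any effect on the score")
  n_req <- sum(eff$role == "required")
  n_con <- sum(eff$role == "contributing")
  if (n_req == 1L) return(if (n_con == 0L) "1-a" else "1-b")
  drops <- sort(eff$drop, decreasing = TRUE)
  if (length(drops) > 1L && drops[1] > sum(drops[-1])) "2-a" else "2-b"
}

#' Minor-allele-frequency class of a carried variant
#'
#' Frequency bands depend on zygosity: rare means MAF < 0.5% for a
#' heterozygous genotype or MAF < 1% for a homozygous one; low-frequency
#' means MAF < 1% heterozygous or MAF < 5% homozygous; anything above both
#' bands is common.
#'
#' @param maf minor allele frequency in `[0, 0.5]`; vectorised.
#' @param zygosity `"het"`/`"hom_alt"` (or dosage 1/2); vectorised.
#' @return Character vector: `"rare"`, `"low_frequency"` or `"common"`.
#' @export
frequency_class <- function(maf, zygosity) {
  if (any(maf < 0 | maf > 0.5)) stop_input("maf must lie in [0, 0.5]")
  z <- if (is.numeric(zygosity)) ifelse(zygosity >= 2, "hom", "het")
       else ifelse(zygosity %in% c("hom_alt", "hom_ref", "hom"), "hom", "het")
  n <- max(length(maf), length(z))
  maf <- rep_len(maf, n); z <- rep_len(z, n)
  rare <- ifelse(z == "het", maf < 0.005, maf < 0.01)
  low <- ifelse(z == "het", maf < 0.01, maf < 0.05)
  ifelse(rare, "rare", ifelse(low, "low_frequency", "common"))
}

#' Combinatorial contribution of an individual's score
#'
#' The positive part of the clustered raw score minus the unclustered
#' mean-distance score: extra score the individual only has because
#' clustering made some of its variants conditionally rare.  Zero for
#' terms without hidden structure.
#'
#' @param sset an [score_term()] result.
#' @param individual identifier.
#' @return Non-negative scalar.
#' @export
combinatorial_contribution <- function(sset, individual) {
  i <- match(individual, sset$scores$individual)
  if (is.na(i)) stop_input("unknown individual: ", individual)
  sset$scores$combinatorial[i]
}

#' Fully classify one above-threshold outlier call
#'
#' Combines variant roles, outlier type, per-variant frequency classes and
#' the combinatorial contribution into one call record.
#'
#' @inheritParams classify_variant_roles
#' @param sset the [score_term()] result the call came from.
#' @return Object of class `outlier_call`: individual, term_id, score,
#'   type, roles (data frame with maf, zygosity and frequency class per
#'   carried variant), combinatorial contribution and its share of the
#'   raw score.
#' @export
classify_call <- function(sset, individual, profile, genotypes,
                          background = NULL, params = NULL,
                          threshold = NULL) {
  params <- params %||% sset$params
  threshold <- threshold %||% params$threshold
  roles <- classify_variant_roles(individual, profile, genotypes,
                                  background = background, params = params,
                                  threshold = threshold)
  type <- classify_outlier_type(roles)
  sites <- profile$sites
  roles$maf <- sites$maf[match(roles$variant_id, sites$variant_id)]
  roles$zygosity <- c("hom_ref", "het", "hom_alt")[roles$dosage + 1L]
  roles$frequency_class <- NA_character_
  carried <- roles$dosage > 0L
  roles$frequency_class[carried] <-
    frequency_class(roles$maf[carried], roles$zygosity[carried])
  comb <- combinatorial_contribution(sset, individual)
  i <- match(individual, sset$scores$individual)
  raw <- sset$scores$raw[i]
  structure(list(individual = individual, term_id = sset$term_id,
                 score = attr(roles, "score"), type = type, roles = roles,
                 combinatorial = comb,
                 combinatorial_share = if (raw > 0) comb / raw else 0),
            class = "outlier_call")
}

#' @export
print.outlier_call <- function(x, ...) {
  cat("<outlier_call>", x$individual, "@", x$term_id,
      sprintf("score %.4f type %s; %d required, %d contributing\n",
              x$score, x$type, sum(x$roles$role == "required"),
              sum(x$roles$role == "contributing")))
  invisible(x)
}
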