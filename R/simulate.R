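#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the design the framework is built for: a large
#' diverse background cohort plus a handful of individuals of interest,
#' exome-style missense variation inside protein domains, domain-to-term
#' maps over a toy ontology DAG, and planted outliers whose genetic
#' architecture is known.  Genotypes follow Hardy-Weinberg equilibrium at
#' each site's minor allele frequency, with no linkage disequilibrium
#' except where a combinatorial plant explicitly induces co-occurrence.
#'
#' @param seed RNG seed; the whole world is a deterministic function of
#'   the config.
#' @param n_background background cohort size (default 500).
#' @param n_subjects individuals of interest (default 20).
#' @param n_terms ontology terms (default 200).
#' @param n_domains protein domains / HMMs (default 50).
#' @param domain_length match states per HMM (default 80).
#' @param variants_per_domain catalogue variants per domain (default 8).
#' @param dirichlet concentration of the symmetric Dirichlet emissions
#'   (default 0.3; small values give skewed columns, so some
#'   substitutions are strongly intolerant).
#' @param maf_weights mixture weights of the rare / low-frequency / common
#'   MAF classes (uniform draws on (0.0005, 0.005), (0.005, 0.05) and
#'   (0.05, 0.4) respectively).
#' @param plants list of planted outliers, each
#'   `list(type = "single_rare" | "multi_variant" | "combinatorial",
#'   subject =, term =)` with `NULL` entries auto-assigned; default one
#'   plant of each type.
#' @param combinatorial_group_frac fraction of the cohort forming the
#'   genotype-defined subgroup of a combinatorial plant (default 0.1).
#' @param base_yes_rate probability that a decoy / unplanted question is
#'   answered yes (default 0.008, the baseline rate of self-identifying a
#'   random phenotype).
#' @param planted_yes_rate probability that a planted true prediction is
#'   answered yes (default 0.8).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_background = 500, n_subjects = 20,
                       n_terms = 200, n_domains = 50, domain_length = 80,
                       variants_per_domain = 8, dirichlet = 0.3,
                       maf_weights = c(rare = 0.3, low = 0.3, common = 0.4),
                       plants = list(list(type = "single_rare"),
                                     list(type = "multi_variant"),
                                     list(type = "combinatorial")),
                       combinatorial_group_frac = 0.02,
                       base_yes_rate = 0.008, planted_yes_rate = 0.8) {
  stopifnot(n_background > 0, n_subjects > 0, n_terms > 0, n_domains > 0,
            domain_length > 1, variants_per_domain > 0,
            base_yes_rate >= 0, base_yes_rate <= 1,
            planted_yes_rate >= 0, planted_yes_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a complete synthetic world
#'
#' Produces every input the pipeline consumes — HMM emission tables,
#' domain hits, a domain-to-term map, an ontology DAG, a missense variant
#' catalogue, cohort genotypes — plus truth records for the planted
#' outliers.  Plant types: `single_rare` gives one subject a homozygous
#' genotype at a site with MAF at most 0.5% and top-decile functional
#' distance; `multi_variant` gives one subject heterozygous genotypes at
#' three rare moderate-distance sites of one term; `combinatorial` builds
#' a genotype-defined subgroup sharing a marginally common variant and
#' gives the subject, inside that subgroup, an allele that is common
#' outside the subgroup but absent within it — rare conditional on the
#' subgroup, common marginally.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_world`: `config`, `hmms`, `hits`, `map`,
#'   `onto`, `variants`, `genotypes` (dosage matrix with individual row
#'   names), `background`, `subjects`, `truth` (list of planted records).
#' @export
generate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cf) {
  dom_ids <- sprintf("HMM%04d", seq_len(cf$n_domains))
  hmms <- lapply(dom_ids, function(id) {
    em <- matrix(rgamma(cf$domain_length * 20, shape = cf$dirichlet),
                 nrow = cf$domain_length)
    profile_hmm(id, em / rowSums(em))
  })
  names(hmms) <- dom_ids

  term_ids <- sprintf("T:%06d", seq_len(cf$n_terms))
  parents <- c(list(character(0)),
               lapply(2:cf$n_terms, function(i)
                 term_ids[sample.int(i - 1L, 1L)]))
  onto <- ontology(data.frame(term_id = term_ids,
                              name = paste("synthetic term", seq_len(cf$n_terms)),
                              stringsAsFactors = FALSE),
                   setNames(parents, term_ids))

  # link each non-root term to 1-3 domains; every domain linked somewhere
  n_linked <- sample(1:3, cf$n_terms - 1L, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
  map <- do.call(rbind, lapply(seq_along(n_linked), function(i)
    data.frame(hmm_id = sample(dom_ids, n_linked[i]),
               term_id = term_ids[i + 1L], stringsAsFactors = FALSE)))
  unlinked <- setdiff(dom_ids, map$hmm_id)
  if (length(unlinked))
    map <- rbind(map, data.frame(
      hmm_id = unlinked,
      term_id = sample(term_ids[-1], length(unlinked), replace = TRUE),
      stringsAsFactors = FALSE))
  map <- unique(map)
  map <- domain_term_map(map[order(map$term_id, map$hmm_id), ])

  hits <- lapply(dom_ids, function(id)
    domain_hit(paste0("P_", id), id, 1L, cf$domain_length,
               paste0(cf$domain_length, "M"), score = 100))

  nv <- cf$n_domains * cf$variants_per_domain
  w <- cf$maf_weights / sum(cf$maf_weights)
  cls <- sample(names(w), nv, replace = TRUE, prob = w)
  maf <- ifelse(cls == "rare", runif(nv, 0.0005, 0.005),
         ifelse(cls == "low", runif(nv, 0.005, 0.05),
                runif(nv, 0.05, 0.4)))
  residues <- unlist(lapply(seq_len(cf$n_domains), function(d)
    sort(sample.int(cf$domain_length, cf$variants_per_domain))))
  vdom <- rep(dom_ids, each = cf$variants_per_domain)
  # purifying selection: the commoner the allele, the more tolerated the
  # substitution must be, so alternate residues of common variants are
  # drawn in proportion to their emission probability while rare variants
  # may hit any residue
  ref_aa <- alt_aa <- character(nv)
  for (i in seq_len(nv)) {
    em <- hmms[[vdom[i]]]$emissions[residues[i], ]
    ref_aa[i] <- names(which.max(em))
    others <- setdiff(AA_ALPHABET, ref_aa[i])
    wgt <- switch(cls[i],
                  common = em[others],
                  low    = sqrt(em[others]),
                  rare   = rep(1, 19))
    alt_aa[i] <- sample(others, 1, prob = wgt)
  }
  nts <- c("A", "C", "G", "T")
  ref_nt <- sample(nts, nv, replace = TRUE)
  alt_nt <- vapply(ref_nt, function(r) sample(setdiff(nts, r), 1), "")
  variants <- variant_catalogue(data.frame(
    variant_id = sprintf("rs%06d", seq_len(nv)),
    chrom = as.character(rep_len(1:22, nv)),
    pos = seq_len(nv) * 1000L,
    ref = ref_nt, alt = unname(alt_nt),
    protein_id = paste0("P_", vdom),
    residue_index = residues,
    ref_aa = ref_aa, alt_aa = alt_aa, maf = maf,
    stringsAsFactors = FALSE))

  bg_ids <- sprintf("BG%04d", seq_len(cf$n_background))
  sub_ids <- sprintf("SUB%03d", seq_len(cf$n_subjects))
  ids <- c(bg_ids, sub_ids)
  n <- length(ids)
  G <- matrix(rbinom(n * nv, 2L, rep(maf, each = n)), nrow = n,
              dimnames = list(ids, variants$variant_id))

  truth <- plant_outliers(cf, hmms, map, variants, G, bg_ids, sub_ids)
  structure(list(config = cf, hmms = hmms, hits = hits, map = map,
                 onto = onto, variants = truth$variants,
                 genotypes = truth$G, background = bg_ids,
                 subjects = sub_ids, truth = truth$records),
            class = "sim_world")
}

# Install the planted outliers, mutating the catalogue and genotype matrix.
plant_outliers <- function(cf, hmms, map, variants, G, bg_ids, sub_ids) {
  records <- list()
  n <- nrow(G)
  # candidate terms: exactly one linked domain, so the plant dominates
  link_counts <- table(map$term_id)
  cand_terms <- names(link_counts)[link_counts == 1L]
  used_terms <- character(0)
  used_subjects <- character(0)
  used_domains <- character(0)
  term_domain <- setNames(map$hmm_id[match(cand_terms, map$term_id)],
                          cand_terms)
  for (pi in seq_along(cf$plants)) {
    pl <- cf$plants[[pi]]
    subject <- pl$subject %||% setdiff(sub_ids, used_subjects)[1]
    free <- cand_terms[!cand_terms %in% used_terms &
                       !term_domain[cand_terms] %in% used_domains]
    term <- pl$term %||% free[1]
    if (is.na(subject) || is.na(term))
      stop("infeasible plant: no free subject or single-domain term left")
    used_terms <- c(used_terms, term)
    used_subjects <- c(used_subjects, subject)
    dom <- map$hmm_id[map$term_id == term][1]
    used_domains <- c(used_domains, dom)
    dom_vars <- which(variants$protein_id == paste0("P_", dom))
    if (pl$type == "single_rare") {
      # plant at the domain's most intolerant site (widest emission
      # log-odds), so the planted genotype is the profile's most extreme
      span <- vapply(dom_vars, function(v) {
        em <- hmms[[dom]]$emissions[variants$residue_index[v], ]
        log(max(em)) - log(min(em))
      }, numeric(1))
      v <- dom_vars[which.max(span)]
      variants$maf[v] <- 0.001
      em <- hmms[[dom]]$emissions[variants$residue_index[v], ]
      variants$ref_aa[v] <- names(which.max(em))
      variants$alt_aa[v] <- names(which.min(em))
      G[, v] <- rbinom(n, 2L, variants$maf[v])
      G[subject, v] <- 2L
      records[[pi]] <- list(type = "single_rare", subject = subject,
                            term = term,
                            variant_ids = variants$variant_id[v])
    } else if (pl$type == "multi_variant") {
      if (length(dom_vars) < 3L) stop("infeasible plant: <3 domain variants")
      vs <- dom_vars[1:3]
      variants$maf[vs] <- 0.003
      for (v in vs) G[, v] <- rbinom(n, 2L, variants$maf[v])
      G[subject, vs] <- 1L
      records[[pi]] <- list(type = "multi_variant", subject = subject,
                            term = term,
                            variant_ids = variants$variant_id[vs])
    } else if (pl$type == "combinatorial") {
      if (length(dom_vars) < 2L) stop("infeasible plant: <2 domain variants")
      grp_size <- max(3L, round(cf$combinatorial_group_frac * n))
      if (grp_size + 1L >= n)
        stop("infeasible plant: combinatorial subgroup covers the cohort")
      grp <- c(subject, sample(bg_ids, grp_size - 1L))
      # the conditionally-rare variant must carry a high per-site distance,
      # so it sits at the domain site with the widest emission log-odds
      span <- vapply(dom_vars, function(v) {
        em <- hmms[[dom]]$emissions[variants$residue_index[v], ]
        log(max(em)) - log(min(em))
      }, numeric(1))
      vb <- dom_vars[which.max(span)]   # common outside the subgroup, absent within
      va <- setdiff(dom_vars, vb)[1]    # subgroup-defining, marginally common
      for (v in c(va, vb)) {     # strong substitutions at both sites
        em <- hmms[[dom]]$emissions[variants$residue_index[v], ]
        variants$ref_aa[v] <- names(which.max(em))
        variants$alt_aa[v] <- names(which.min(em))
      }
      # the co-occurrence subgroup must be the dominant structure of this
      # term's landscape: the remaining profile sites are redrawn from the
      # rare band so no other common split competes with it
      rest <- setdiff(dom_vars, c(va, vb))
      if (length(rest)) {
        variants$maf[rest] <- runif(length(rest), 0.0005, 0.005)
        for (v in rest) G[, v] <- rbinom(n, 2L, variants$maf[v])
      }
      G[, va] <- 0L
      G[grp, va] <- 2L
      variants$maf[va] <- min(0.5, grp_size / n)
      outside <- setdiff(rownames(G), grp)
      G[, vb] <- 0L
      G[outside, vb] <- rbinom(length(outside), 2L, 0.3)
      # heterozygous inside the subgroup: rare conditional on the subgroup
      # genotype, common marginally, and close enough to the subgroup that
      # clustering keeps the subject inside it
      G[subject, vb] <- 1L
      variants$maf[vb] <- min(0.5, sum(G[, vb]) / (2 * n))
      records[[pi]] <- list(type = "combinatorial", subject = subject,
                            term = term,
                            variant_ids = variants$variant_id[c(va, vb)],
                            group = grp)
    } else stop("unknown plant type: ", pl$type)
  }
  list(variants = variants, G = G, records = records)
}

#' Generate phenotype answers for a set of questions
#'
#' Decoy and unplanted questions are answered yes at the configured base
#' rate (the chance of self-identifying a random phenotype); questions
#' matching a planted (subject, term) truth record are answered yes at
#' the planted rate.
#'
#' @param world a [generate_world()] result.
#' @param questions data frame with `individual_id`, `term_id`,
#'   `is_decoy`, `score` (e.g. stacked [build_questionnaire()] outputs).
#' @param seed RNG seed (default: derived from the world's seed).
#' @return An [answer_table()].
#' @export
generate_answers <- function(world, questions, seed = NULL) {
  cf <- world$config
  seed <- seed %||% (cf$seed + 1000L)
  planted <- vapply(world$truth, function(r)
    paste(r$subject, r$term, sep = "\r"), "")
  key <- paste(questions$individual_id, questions$term_id, sep = "\r")
  p_yes <- ifelse(key %in% planted, cf$planted_yes_rate, cf$base_yes_rate)
  ans <- with_seed(seed, runif(nrow(questions)) < p_yes)
  answer_table(data.frame(individual_id = questions$individual_id,
                          term_id = questions$term_id,
                          answer = ans,
                          is_decoy = questions$is_decoy,
                          score = questions$score,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Emits the same formats the readers consume: VCF for the cohort
#' genotypes, TSV for emissions / domain hits / domain-term map / variant
#' catalogue, OBO for the ontology and JSON for the truth records.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    hmms = file.path(dir, "emissions.tsv"),
    hits = file.path(dir, "domain_hits.tsv"),
    map = file.path(dir, "domain_term_map.tsv"),
    obo = file.path(dir, "ontology.obo"),
    variants = file.path(dir, "variants.tsv"),
    vcf = file.path(dir, "cohort.vcf"),
    truth = file.path(dir, "truth.json"))
  write_hmm_emissions(world$hmms, paths$hmms)
  write_domain_hits(world$hits, paths$hits)
  write.table(world$map, paths$map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_obo(world$onto, paths$obo)
  write.table(world$variants, paths$variants, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_vcf(world$genotypes, world$variants, paths$vcf)
  jsonlite::write_json(world$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
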