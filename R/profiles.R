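#' Read a domain-to-ontology-term map
#'
#' Flat (hmm_id, term_id) pairs of the kind produced by domain-centric
#' function annotation.  Duplicate pairs are an input error.  Term links
#' are deliberately not propagated along the ontology at profile-build
#' time: each term is processed independently.
#'
#' @param path TSV with columns `hmm_id`, `term_id`.
#' @return Data frame of class `domain_term_map`.
#' @export
read_domain_term_map <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  domain_term_map(tab)
}

#' @rdname read_domain_term_map
#' @param df data frame with columns `hmm_id`, `term_id`.
#' @export
domain_term_map <- function(df) {
  if (!all(c("hmm_id", "term_id") %in% names(df)))
    stop_input("domain-term map needs columns hmm_id, term_id")
  if (anyDuplicated(df[, c("hmm_id", "term_id")]))
    stop_input("duplicate (hmm_id, term_id) pairs in map")
  rownames(df) <- NULL
  class(df) <- unique(c("domain_term_map", class(df)))
  df
}

#' Build the variant profile of one ontology term
#'
#' Collects every catalogue variant that falls, via the domain hits, on a
#' match state of an HMM linked to the term, and attaches the functional
#' distance of its substitution at that state.  Residues aligned to
#' insertion columns, or outside every linked hit, are excluded.  When
#' several linked hits cover a residue, [map_variant_to_state()] resolves
#' the conflict by hit score.
#'
#' @param term_id the ontology term.
#' @param map a [domain_term_map()].
#' @param hits list of [domain_hit()] objects.
#' @param variants a [variant_catalogue()] data frame.
#' @param hmms named list of [profile_hmm()] objects (names are hmm ids).
#' @return A list of class `term_profile`: `term_id`, `empty` flag, and
#'   `sites` (data frame with variant_id, protein_id, residue_index,
#'   ref_aa, alt_aa, maf, hmm_id, state, distance).  A term with no linked
#'   domains yields an empty, flagged profile rather than an error.
#' @export
build_term_profile <- function(term_id, map, hits, variants, hmms) {
  linked <- sort(unique(map$hmm_id[map$term_id == term_id]))
  empty_sites <- data.frame(
    variant_id = character(0), protein_id = character(0),
    residue_index = integer(0), ref_aa = character(0),
    alt_aa = character(0), maf = numeric(0), hmm_id = character(0),
    state = integer(0), distance = numeric(0), stringsAsFactors = FALSE)
  if (!length(linked))
    return(structure(list(term_id = term_id, empty = TRUE,
                          sites = empty_sites), class = "term_profile"))
  missing_hmm <- setdiff(linked, names(hmms))
  if (length(missing_hmm))
    stop_input("HMMs linked to ", term_id, " not supplied: ",
               paste(missing_hmm, collapse = ", "))
  linked_hits <- Filter(function(h) h$hmm_id %in% linked, hits)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    m <- map_variant_to_state(v, linked_hits)
    if (is.null(m)) return(NULL)
    d <- score_substitution(hmms[[m$hmm_id]], m$state, v$ref_aa, v$alt_aa)
    data.frame(variant_id = v$variant_id, protein_id = v$protein_id,
               residue_index = v$residue_index, ref_aa = v$ref_aa,
               alt_aa = v$alt_aa, maf = v$maf, hmm_id = m$hmm_id,
               state = m$state, distance = d, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, c(list(empty_sites), rows))
  sites <- sites[order(sites$variant_id), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(term_id = term_id, empty = nrow(sites) == 0L,
                 sites = sites), class = "term_profile")
}

#' @export
print.term_profile <- function(x, ...) {
  cat("<term_profile>", x$term_id, "with", nrow(x$sites), "sites",
      if (x$empty) "(empty)" else "", "\n")
  invisible(x)
}

#' Serialise / restore a term profile as JSON
#'
#' Used for caching profiles between runs; `read_term_profile_json()`
#' round-trips the result of `write_term_profile_json()` exactly (full
#' double precision).
#'
#' @param profile a [build_term_profile()] result.
#' @param path file path.
#' @return `path` invisibly, or the restored `term_profile`.
#' @export
write_term_profile_json <- function(profile, path) {
  jsonlite::write_json(list(term_id = profile$term_id, empty = profile$empty,
                            sites = profile$sites),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_term_profile_json
#' @export
read_term_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- as.data.frame(x$sites, stringsAsFactors = FALSE)
  if (nrow(sites)) {
    sites$residue_index <- as.integer(sites$residue_index)
    sites$state <- as.integer(sites$state)
  }
  structure(list(term_id = x$term_id, empty = isTRUE(x$empty),
                 sites = sites), class = "term_profile")
}

#' Genotype dosages of a cohort at the sites of one profile
#'
#' Convenience selector: extracts and orders the columns of a cohort
#' dosage matrix to match `profile$sites$variant_id`.
#'
#' @param genotypes matrix individuals x catalogue variants, with variant
#'   ids as column names.
#' @param profile a `term_profile`.
#' @return Matrix individuals x profile sites.
#' @export
profile_genotypes <- function(genotypes, profile) {
  if (is.null(colnames(genotypes))) {
    # unnamed matrices are taken as already aligned to the profile sites
    if (ncol(genotypes) != nrow(profile$sites))
      stop_input("unnamed genotype matrix must have one column per profile site")
    colnames(genotypes) <- profile$sites$variant_id
    return(genotypes)
  }
  miss <- setdiff(profile$sites$variant_id, colnames(genotypes))
  if (length(miss))
    stop_input("genotype matrix lacks profile variants: ",
               paste(head(miss, 5), collapse = ", "))
  genotypes[, profile$sites$variant_id, drop = FALSE]
}
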