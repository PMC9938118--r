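#' Create a domain hit
#'
#' A domain hit places one profile HMM on a stretch of protein sequence and
#' records which residues align to which match states.  The alignment is
#' given as a CIGAR-like column string over the residues
#' `protein_start..protein_end`: `M` consumes one residue and one match
#' state, `I` consumes one residue only (insertion relative to the model,
#' no comparable emission), `D` consumes one match state only (deletion).
#'
#' @param protein_id,hmm_id identifiers.
#' @param protein_start,protein_end 1-based inclusive residue coordinates.
#' @param alignment CIGAR-like string, e.g. `"12M3I20M"`.
#' @param score hit score (bit score or similar), used to resolve residues
#'   covered by several hits: the highest-scoring hit wins, ties broken by
#'   lexicographic `hmm_id`.
#' @param first_state match state aligned by the first `M` column.
#' @return An object of class `domain_hit` with a `residue_to_state` map.
#' @export
domain_hit <- function(protein_id, hmm_id, protein_start, protein_end,
                       alignment, score = 0, first_state = 1L) {
  stopifnot(protein_start >= 1L, protein_end >= protein_start)
  ops <- parse_cigar(alignment)
  res <- as.integer(protein_start)
  state <- as.integer(first_state)
  map_res <- integer(0)
  map_state <- integer(0)
  for (k in seq_len(nrow(ops))) {
    n <- ops$len[k]
    if (ops$op[k] == "M") {
      map_res <- c(map_res, seq.int(res, length.out = n))
      map_state <- c(map_state, seq.int(state, length.out = n))
      res <- res + n
      state <- state + n
    } else if (ops$op[k] == "I") {
      res <- res + n
    } else {                      # D
      state <- state + n
    }
  }
  if (res - 1L != protein_end)
    stop_input("alignment consumes residues up to ", res - 1L,
               " but protein_end is ", protein_end)
  structure(list(protein_id = protein_id, hmm_id = hmm_id,
                 protein_start = as.integer(protein_start),
                 protein_end = as.integer(protein_end),
                 score = as.numeric(score),
                 alignment = alignment,
                 residue_to_state = setNames(map_state, map_res)),
            class = "domain_hit")
}

parse_cigar <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!grepl("^([0-9]+[MID])+$", s))
    stop_input("malformed alignment string: ", s)
  len <- as.integer(regmatches(s, gregexpr("[0-9]+", s))[[1]])
  op <- regmatches(s, gregexpr("[MID]", s))[[1]]
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Read domain hits from a TSV file
#'
#' Columns: `protein_id`, `hmm_id`, `protein_start`, `protein_end`,
#' `score`, `alignment` (CIGAR-like column string, see [domain_hit()]).
#'
#' @param path file path.
#' @return List of `domain_hit` objects.
#' @export
read_domain_hits <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "hmm_id", "protein_start", "protein_end",
            "score", "alignment")
  if (!all(need %in% names(tab)))
    stop_input("domain-hit TSV must have columns: ",
               paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    domain_hit(tab$protein_id[i], tab$hmm_id[i], tab$protein_start[i],
               tab$protein_end[i], tab$alignment[i], tab$score[i]))
}

#' Write domain hits to TSV
#' @param hits list of [domain_hit()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  tab <- do.call(rbind, lapply(hits, function(h) {
    data.frame(protein_id = h$protein_id, hmm_id = h$hmm_id,
               protein_start = h$protein_start, protein_end = h$protein_end,
               score = h$score, alignment = h$alignment,
               stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a missense-variant catalogue
#'
#' The catalogue is a data frame with one row per missense variant:
#' `variant_id`, `chrom`, `pos`, `ref`, `alt` (genomic, bookkeeping only),
#' `protein_id`, `residue_index` (1-based), `ref_aa`, `alt_aa`, `maf`
#' (minor allele frequency in `[0, 0.5]`).
#'
#' @param df data frame of variants.
#' @return The validated data frame (invisibly classed `variant_catalogue`).
#' @export
variant_catalogue <- function(df) {
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "protein_id",
            "residue_index", "ref_aa", "alt_aa", "maf")
  if (!all(need %in% names(df)))
    stop_input("variant catalogue must have columns: ",
               paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$variant_id))
    stop_input("duplicate variant_id in catalogue")
  if (any(df$ref_aa == df$alt_aa))
    stop_input("ref_aa must differ from alt_aa")
  if (any(df$maf < 0 | df$maf > 0.5))
    stop_input("maf must lie in [0, 0.5]")
  aa_index(df$ref_aa); aa_index(df$alt_aa)  # validates codes
  class(df) <- unique(c("variant_catalogue", class(df)))
  df
}

#' Map a missense variant to a profile-HMM match state
#'
#' Finds the domain hit covering the variant's residue and returns the
#' aligned match state.  Residues outside every hit, or aligned to an
#' insertion column, carry no functional distance and yield `NULL`.  When
#' several hits cover the residue the highest-scoring hit wins; ties are
#' broken by lexicographic `hmm_id` for determinism.
#'
#' @param variant one row of a [variant_catalogue()] (or any list with
#'   `protein_id` and `residue_index`).
#' @param hits list of [domain_hit()] objects.
#' @return `list(hmm_id =, state =)` or `NULL` when the residue is not
#'   aligned to any match state.
#' @export
map_variant_to_state <- function(variant, hits) {
  res <- as.integer(variant$residue_index)
  cand <- Filter(function(h) {
    h$protein_id == variant$protein_id &&
      !is.na(h$residue_to_state[as.character(res)])
  }, hits)
  if (!length(cand)) return(NULL)
  scores <- vapply(cand, `[[`, numeric(1), "score")
  ids <- vapply(cand, `[[`, character(1), "hmm_id")
  best <- order(-scores, ids)[1]
  list(hmm_id = ids[best],
       state = unname(cand[[best]]$residue_to_state[as.character(res)]))
}
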