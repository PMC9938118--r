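#' Construct a profile HMM from match-state emission probabilities
#'
#' A profile HMM here is reduced to what the functional-distance model
#' needs: one emission probability vector over the 20 standard amino acids
#' per match state.  Emissions are pseudocounted on construction (floored at
#' `floor` and renormalised) so every log-odds is finite.
#'
#' @param id character scalar, model identifier.
#' @param emissions numeric matrix, one row per match state, 20 columns in
#'   fixed alphabetical amino-acid order (A, C, D, ..., Y).  Rows must be
#'   probability vectors (non-negative, summing to 1 within `1e-6` before
#'   pseudocounting).
#' @param floor minimum emission probability after pseudocounting.
#' @return An object of class `profile_hmm` with elements `id`,
#'   `n_match_states` and `emissions` (rows renormalised to sum to 1).
#' @examples
#' em <- matrix(1 / 20, nrow = 3, ncol = 20)
#' hmm <- profile_hmm("toy", em)
#' hmm$n_match_states
#' @export
profile_hmm <- function(id, emissions, floor = 1e-6) {
  stopifnot(is.character(id), length(id) == 1L)
  emissions <- as.matrix(emissions)
  if (ncol(emissions) != 20L)
    stop_input("emission table must have 20 amino-acid columns, got ",
               ncol(emissions))
  if (any(!is.finite(emissions)) || any(emissions < 0))
    stop_input("emission probabilities must be finite and non-negative")
  rs <- rowSums(emissions)
  if (any(abs(rs - 1) > 1e-6))
    stop_input("emission rows must sum to 1 (max deviation ",
               signif(max(abs(rs - 1)), 3), ")")
  emissions <- t(apply(emissions, 1, pseudocount_floor, floor = floor))
  colnames(emissions) <- AA_ALPHABET
  rownames(emissions) <- NULL
  structure(list(id = id,
                 n_match_states = nrow(emissions),
                 emissions = emissions),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("<profile_hmm>", x$id, "with", x$n_match_states, "match states\n")
  invisible(x)
}

# Floor small probabilities at exactly `floor` and renormalise the
# remaining mass, so the operation is idempotent and written tables
# round-trip exactly.
pseudocount_floor <- function(p, floor) {
  if (abs(sum(p) - 1) > 1e-9) p <- p / sum(p)
  for (it in 1:3) {
    low <- p < floor
    if (!any(low)) break
    p[low] <- floor
    p[!low] <- p[!low] * (1 - sum(low) * floor) / sum(p[!low])
  }
  p
}

aa_index <- function(aa) {
  i <- match(toupper(aa), AA_ALPHABET)
  if (anyNA(i))
    stop_input("unknown amino-acid code: ",
               paste(unique(aa[is.na(i)]), collapse = ", "))
  i
}

#' Functional distance of a missense substitution
#'
#' The deleteriousness of replacing `ref_aa` by `alt_aa` at a match state is
#' the magnitude of the natural-log odds between the state's emission
#' probabilities of the two residues, `|ln P(ref) - ln P(alt)|`.  It is zero
#' iff the two amino acids are emitted with equal probability, symmetric in
#' its amino-acid arguments, and invariant to a common rescaling of the two
#' probabilities.
#'
#' @param hmm a [profile_hmm()].
#' @param state match-state index (1-based); vectorised.
#' @param ref_aa,alt_aa single-letter amino-acid codes; vectorised.
#' @return Non-negative numeric vector of functional distances.
#' @examples
#' em <- matrix(1 / 20, 2, 20)
#' em[1, 1] <- 0.4; em[1, 18] <- 0.1           # A and V at state 1
#' em <- em / rowSums(em)
#' hmm <- profile_hmm("toy", em)
#' score_substitution(hmm, 1, "A", "V")         # |ln(0.4/0.1)| = ln 4
#' @export
score_substitution <- function(hmm, state, ref_aa, alt_aa) {
  stopifnot(inherits(hmm, "profile_hmm"))
  state <- as.integer(state)
  if (any(is.na(state)) || any(state < 1L) || any(state > hmm$n_match_states))
    stop_input("match-state index out of range [1, ", hmm$n_match_states, "]")
  i <- aa_index(ref_aa)
  j <- aa_index(alt_aa)
  abs(log(hmm$emissions[cbind(state, i)]) -
      log(hmm$emissions[cbind(state, j)]))
}

#' Read profile-HMM emission tables from a TSV file
#'
#' Expected columns: `hmm_id`, `state_index` (1-based, contiguous per
#' model), then 20 probability columns in fixed alphabetical amino-acid
#' order.  A header line is optional; it is detected by a non-numeric third
#' field.
#'
#' @param path file path.
#' @param floor pseudocount floor passed to [profile_hmm()].
#' @return Named list of `profile_hmm` objects.
#' @export
read_hmm_emissions <- function(path, floor = 1e-6) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][3])))
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) != 22L)
    stop_input("emission TSV must have 22 columns (hmm_id, state_index, 20 AAs)")
  names(tab) <- c("hmm_id", "state_index", AA_ALPHABET)
  out <- lapply(split(tab, tab$hmm_id), function(d) {
    d <- d[order(d$state_index), ]
    if (!identical(d$state_index, seq_len(nrow(d))))
      stop_input("state indices for ", d$hmm_id[1], " are not contiguous from 1")
    profile_hmm(d$hmm_id[1], as.matrix(d[, AA_ALPHABET]), floor = floor)
  })
  out[order(names(out))]
}

#' Write profile HMMs to the emission TSV format
#'
#' @param hmms named list of [profile_hmm()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hmm_emissions <- function(hmms, path) {
  rows <- lapply(hmms, function(h) {
    data.frame(hmm_id = h$id, state_index = seq_len(h$n_match_states),
               h$emissions, check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a HMMER3 .hmm file to profile HMMs
#'
#' Reads the match-emission lines of a HMMER3 text model (scores are
#' negative natural logs of probabilities, `*` meaning probability zero)
#' and converts them to emission probability vectors.  HMMER3 stores
#' emissions in the same fixed alphabetical amino-acid order used here.
#'
#' @param path path to a HMMER3 `.hmm` text file.
#' @param floor pseudocount floor passed to [profile_hmm()].
#' @return Named list of `profile_hmm` objects (one per model in the file).
#' @export
read_hmmer_hmm <- function(path, floor = 1e-6) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^HMMER3", lines[i])) {
      name <- NA_character_
      j <- i + 1L
      while (j <= length(lines) && !grepl("^HMM\\s", lines[j])) {
        if (grepl("^NAME\\s", lines[j]))
          name <- sub("^NAME\\s+", "", lines[j])
        j <- j + 1L
      }
      j <- j + 2L  # skip the two HMM header lines (symbols, transitions)
      em <- list()
      while (j <= length(lines) && !grepl("^//", lines[j])) {
        fields <- strsplit(trimws(lines[j]), "\\s+")[[1]]
        # match-emission lines start with the 1-based node number
        if (length(fields) >= 21L && grepl("^[0-9]+$", fields[1])) {
          sc <- fields[2:21]
          p <- ifelse(sc == "*", 0, exp(-as.numeric(sc)))
          em[[length(em) + 1L]] <- p / sum(p)
          j <- j + 3L  # skip insert-emission and transition lines
        } else j <- j + 1L
      }
      if (length(em))
        out[[name]] <- profile_hmm(name, do.call(rbind, em), floor = floor)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}
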