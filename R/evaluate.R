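#' Validate a phenotype answer table
#'
#' One record per (individual, term) question: `individual_id`, `term_id`,
#' `answer` (logical yes/no), `is_decoy` (whether the question came from
#' the decoy genome's top terms rather than the participant's own), and
#' the transformed outlier `score` behind the question.
#'
#' @param df data frame.
#' @return Validated data frame of class `answer_table`.
#' @export
answer_table <- function(df) {
  need <- c("individual_id", "term_id", "answer", "is_decoy", "score")
  if (!all(need %in% names(df)))
    stop_input("answer table needs columns: ", paste(need, collapse = ", "))
  if (is.character(df$answer)) df$answer <- tolower(df$answer) == "yes"
  df$answer <- as.logical(df$answer)
  df$is_decoy <- as.logical(df$is_decoy)
  if (anyDuplicated(df[, c("individual_id", "term_id")]))
    stop_input("one record per (individual, term) required")
  class(df) <- unique(c("answer_table", class(df)))
  df
}

#' Read / write answer tables as CSV
#' @param path file path.
#' @return An `answer_table`, or `path` invisibly.
#' @export
read_answers <- function(path) {
  answer_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_answers
#' @param answers an [answer_table()].
#' @export
write_answers <- function(answers, path) {
  utils::write.csv(answers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a personalised questionnaire with decoy questions
#'
#' The participant's `n_top` highest-scoring terms are mixed, in seeded
#' random order, with the `n_top` top-scoring terms of a decoy genome
#' drawn uniformly from the background pool.  Decoys guard against gaming
#' and measure the baseline rate of self-identifying a random phenotype.
#' When the participant and the decoy share a top term, the question is
#' asked once, attributed to the participant, and the decoy side takes its
#' next-ranked term, so the questionnaire always holds `2 * n_top`
#' distinct questions.
#'
#' @param participant data frame with `term_id` and `score` for the
#'   participant (all scoreable terms).
#' @param pool named list of such data frames, one per background genome.
#' @param n_top questions per side (default 25).
#' @param seed RNG seed (decoy draw and question shuffle).
#' @return Data frame: `term_id`, `is_decoy`, `score` (score of the side
#'   the question is attributed to), in presentation order; the chosen
#'   decoy id is in attribute `decoy_id`.
#' @export
build_questionnaire <- function(participant, pool, n_top = 25, seed = 1) {
  stopifnot(length(pool) >= 1)
  with_seed(seed, {
    decoy_id <- sample(names(pool) %||% seq_along(pool), 1)
    decoy <- pool[[decoy_id]]
    part_sorted <- participant[order(-participant$score,
                                     participant$term_id), ]
    decoy_sorted <- decoy[order(-decoy$score, decoy$term_id), ]
    if (nrow(part_sorted) < n_top)
      stop_input("participant has fewer than ", n_top, " scoreable terms")
    part_terms <- part_sorted$term_id[seq_len(n_top)]
    decoy_terms <- setdiff(decoy_sorted$term_id, part_terms)
    if (length(decoy_terms) < n_top)
      stop_input("decoy has fewer than ", n_top,
                 " scoreable terms outside the participant's top list")
    decoy_terms <- decoy_terms[seq_len(n_top)]
    q <- rbind(
      data.frame(term_id = part_terms, is_decoy = FALSE,
                 score = part_sorted$score[seq_len(n_top)],
                 stringsAsFactors = FALSE),
      data.frame(term_id = decoy_terms, is_decoy = TRUE,
                 score = decoy_sorted$score[match(decoy_terms,
                                                  decoy_sorted$term_id)],
                 stringsAsFactors = FALSE))
    q <- q[sample.int(nrow(q)), ]
    rownames(q) <- NULL
    attr(q, "decoy_id") <- decoy_id
    q
  })
}

#' Question quality control
#'
#' Questions are designed to identify outliers; a high positive-response
#' rate signals a question capturing a common phenotype instead.  A term
#' is retained when its rate of positive answers is strictly above zero
#' and strictly below `max_rate`, and at least `min_answers` answers were
#' recorded for it.
#'
#' @param answers an [answer_table()].
#' @param max_rate exclusive upper bound on the positive rate
#'   (default 0.05).
#' @param min_answers minimum answers per term (default 20).
#' @return Character vector of retained term ids.
#' @export
qc_questions <- function(answers, max_rate = 0.05, min_answers = 20) {
  n <- tapply(answers$answer, answers$term_id, length)
  pos <- tapply(answers$answer, answers$term_id, sum)
  rate <- pos / n
  names(n)[n >= min_answers & pos > 0 & rate < max_rate]
}

perm_result <- function(observed, permuted) {
  n_perm <- length(permuted)
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  s <- sd(permuted)
  z <- if (is.finite(s) && s > 0) (observed - mean(permuted)) / s else NA_real_
  # the z-based right-tailed p is an alternative reading of the same test
  structure(list(observed = observed, permuted = permuted, p_value = p,
                 z_score = z,
                 p_value_z = if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE),
                 n_perm = n_perm),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed %.5g, p = %.4g (z = %.3g, %d permutations)\n",
              x$observed, x$p_value, x$z_score, x$n_perm))
  invisible(x)
}

#' Global permutation test of scores against answers
#'
#' Tests whether outlier scores are on average higher for questions that
#' received a positive answer.  The statistic is the mean score over
#' yes-answers; the null re-allocates scores uniformly across all answer
#' records.  The p-value uses the add-one convention
#' `(1 + b) / (1 + n_perm)`.
#'
#' @param answers an [answer_table()].
#' @param n_perm number of permutations (default 2000).
#' @param seed RNG seed.
#' @return A `permutation_result`.
#' @export
global_score_permutation <- function(answers, n_perm = 2000, seed = 1) {
  k <- sum(answers$answer)
  if (k < 1) stop_input("no positive answers; statistic undefined")
  s <- answers$score
  observed <- mean(s[answers$answer])
  permuted <- with_seed(seed,
    vapply(seq_len(n_perm), function(b) mean(sample(s, k)), numeric(1)))
  perm_result(observed, permuted)
}

#' Confirmation rate above a score threshold, with permutation test
#'
#' The rate of positive answers among questions whose score is at or
#' above the threshold, compared with the decoy positive rate and with a
#' null obtained by re-allocating scores across records (which makes the
#' above-threshold set a uniform random subset of the same size).
#'
#' @param answers an [answer_table()].
#' @param threshold score threshold in (0, 1) (default 0.022).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List: `rate`, `decoy_rate`, `n_above`, `test` (a
#'   `permutation_result` on the rate).
#' @export
threshold_rate_test <- function(answers, threshold = 0.022, n_perm = 2000,
                                seed = 1) {
  stopifnot(threshold > 0, threshold < 1)
  above <- answers$score >= threshold
  if (!any(above)) stop_input("no question scores at or above ", threshold)
  rate <- mean(answers$answer[above])
  decoy_rate <- if (any(answers$is_decoy)) mean(answers$answer[answers$is_decoy])
                else NA_real_
  m <- sum(above)
  permuted <- with_seed(seed,
    vapply(seq_len(n_perm), function(b) mean(sample(answers$answer, m)),
           numeric(1)))
  list(rate = rate, decoy_rate = decoy_rate, n_above = m,
       test = perm_result(rate, permuted))
}

#' Per-phenotype permutation test and expected-by-chance excess curve
#'
#' For each term the statistic is the sum of scores over its positive
#' answers, and its p-value comes from permuting scores within the term.
#' Terms are then ranked by p-value.  To judge how many of the top `x`
#' terms exceed chance, scores are re-permuted (within term), every term
#' p-value recomputed, and the number of terms reaching the observed
#' rank-`x` p-value recorded; repeating gives the mean and standard
#' deviation of the count expected by chance, and
#' `excess(x) = x - expected(x)` with a permutation-SD band.  A term with
#' no positive answers has `p = 1` by convention.
#'
#' @param answers an [answer_table()]; normally restricted to terms
#'   retained by [qc_questions()].
#' @param n_perm permutations per term (default 2000).
#' @param seed RNG seed.
#' @return Object of class `phenotype_ranking`: `terms` (term_id, n,
#'   n_pos, observed, p_value, z_score, rank), `expected`, `expected_sd`,
#'   `excess` (all indexed by rank).
#' @export
per_phenotype_permutation <- function(answers, n_perm = 2000, seed = 1) {
  term_ids <- sort(unique(answers$term_id))
  if (length(term_ids) < 2) stop_input("need at least 2 terms")
  per_term <- with_seed(seed, lapply(term_ids, function(t) {
    d <- answers[answers$term_id == t, ]
    k <- sum(d$answer)
    obs <- sum(d$score[d$answer])
    if (k == 0)
      return(list(n = nrow(d), n_pos = 0L, observed = 0, p = 1,
                  z = NA_real_, null_p = rep(1, n_perm)))
    perm <- vapply(seq_len(n_perm), function(b) sum(sample(d$score, k)),
                   numeric(1))
    p <- (1 + sum(perm >= obs)) / (1 + n_perm)
    s <- sd(perm)
    z <- if (is.finite(s) && s > 0) (obs - mean(perm)) / s else NA_real_
    # p-value each permuted replicate would have received as "observed"
    # (self-inclusive rank), used for the expected-by-chance curve
    null_p <- (rank(-perm, ties.method = "max")) / n_perm
    list(n = nrow(d), n_pos = k, observed = obs, p = p, z = z,
         null_p = null_p)
  }))
  terms <- data.frame(
    term_id = term_ids,
    n = vapply(per_term, `[[`, numeric(1), "n"),
    n_pos = vapply(per_term, `[[`, numeric(1), "n_pos"),
    observed = vapply(per_term, `[[`, numeric(1), "observed"),
    p_value = vapply(per_term, `[[`, numeric(1), "p"),
    z_score = vapply(per_term, `[[`, numeric(1), "z"),
    stringsAsFactors = FALSE)
  ord <- order(terms$p_value, terms$term_id)
  terms <- terms[ord, ]
  terms$rank <- seq_len(nrow(terms))
  rownames(terms) <- NULL
  null_p <- do.call(cbind, lapply(per_term[ord], `[[`, "null_p"))
  p_sorted <- terms$p_value
  counts <- t(apply(null_p, 1, function(row)
    findInterval(p_sorted, sort(row))))
  if (nrow(terms) == 1L) counts <- t(counts)
  expected <- colMeans(counts)
  expected_sd <- apply(counts, 2, sd)
  structure(list(terms = terms, expected = expected,
                 expected_sd = expected_sd,
                 excess = seq_len(nrow(terms)) - expected,
                 n_perm = n_perm),
            class = "phenotype_ranking")
}

#' @export
print.phenotype_ranking <- function(x, ...) {
  cat("<phenotype_ranking>", nrow(x$terms), "terms; top excess",
      sprintf("%.2f", max(x$excess)), "\n")
  invisible(x)
}

#' Confirm outlier calls against clinical annotations
#'
#' A call is confirmed when one of the individual's annotated terms is a
#' [close_match()] of the predicted term.  Individuals without annotations
#' are never confirmed — the necessary assumption for a fair automatic
#' evaluation is that an absent annotation means the phenotype is absent.
#'
#' @param calls data frame with columns `individual` and `term_id` (e.g.
#'   rows of [outlier_calls()]).
#' @param annotations named list: per individual, the character vector of
#'   annotated term ids.
#' @param onto,counts,total,delta_ic passed to [close_match()].
#' @return `calls` with a logical `confirmed` column.
#' @export
confirm_against_annotations <- function(calls, annotations, onto, counts,
                                        total, delta_ic = 1.0) {
  confirmed <- vapply(seq_len(nrow(calls)), function(i) {
    ann <- annotations[[calls$individual[i]]]
    if (is.null(ann) || !length(ann)) return(FALSE)
    any(vapply(ann, function(a)
      close_match(calls$term_id[i], a, onto, counts, total, delta_ic),
      logical(1)))
  }, logical(1))
  calls$confirmed <- confirmed
  calls
}
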