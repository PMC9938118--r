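#' Read an ontology from OBO format
#'
#' Minimal OBO reader covering the fields the framework consumes: `id`,
#' `name` and `is_a` of each `[Term]` stanza.  Obsolete terms are dropped.
#' The parent graph must be acyclic.
#'
#' @param path path to an `.obo` file.
#' @return An object of class `ontology`: data frame `terms` (term_id,
#'   name) and list `parents` (character vector of parent ids per term).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  ids <- character(0); nms <- character(0); parents <- list()
  cur <- NULL; cur_name <- NA_character_; cur_par <- character(0)
  obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      ids <<- c(ids, cur); nms <<- c(nms, cur_name)
      parents[[cur]] <<- cur_par
    }
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      flush(); in_term <- TRUE
      cur <- NULL; cur_name <- NA_character_; cur_par <- character(0)
      obsolete <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE; cur <- NULL
    } else if (in_term) {
      if (grepl("^id: ", ln)) cur <- sub("^id: ", "", ln)
      else if (grepl("^name: ", ln)) cur_name <- sub("^name: ", "", ln)
      else if (grepl("^is_a: ", ln))
        cur_par <- c(cur_par, sub("\\s*(!.*)?$", "", sub("^is_a: ", "", ln)))
      else if (grepl("^is_obsolete: true", ln)) obsolete <- TRUE
    }
  }
  flush()
  ontology(data.frame(term_id = ids, name = nms, stringsAsFactors = FALSE),
           parents)
}

#' Construct an ontology object from terms and parent links
#'
#' @param terms data frame with columns `term_id`, `name`.
#' @param parents named list mapping each term_id to a character vector of
#'   parent term_ids (empty for roots).  The graph must be a DAG.
#' @return Object of class `ontology`.
#' @export
ontology <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("term_id", "name") %in% names(terms)))
  parents <- parents[terms$term_id]
  names(parents) <- terms$term_id
  parents <- lapply(parents, function(p) {
    p <- p %||% character(0)
    p[p %in% terms$term_id]
  })
  obj <- structure(list(terms = terms, parents = parents),
                   class = "ontology")
  # cycle check via iterative DFS colouring
  colour <- setNames(rep(0L, nrow(terms)), terms$term_id)  # 0 new 1 open 2 done
  for (start in terms$term_id) {
    if (colour[start] != 0L) next
    stack <- list(c(start, "enter"))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      node <- top[1]
      if (top[2] == "exit") { colour[node] <- 2L; next }
      if (colour[node] == 2L) next
      if (colour[node] == 1L) stop_input("cycle in ontology at ", node)
      colour[node] <- 1L
      stack[[length(stack) + 1L]] <- c(node, "exit")
      for (p in obj$parents[[node]]) {
        if (colour[p] == 1L) stop_input("cycle in ontology at ", p)
        if (colour[p] == 0L) stack[[length(stack) + 1L]] <- c(p, "enter")
      }
    }
  }
  obj
}

#' @export
print.ontology <- function(x, ...) {
  cat("<ontology>", nrow(x$terms), "terms,",
      sum(lengths(x$parents)), "is_a links\n")
  invisible(x)
}

#' Ancestors of a term (including the term itself)
#'
#' @param onto an [ontology()].
#' @param term_id a term identifier.
#' @return Character vector of `term_id` and all its ancestors.
#' @export
term_ancestors <- function(onto, term_id) {
  if (!term_id %in% onto$terms$term_id)
    stop_input("unknown term: ", term_id)
  seen <- character(0)
  frontier <- term_id
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(onto$parents[frontier])), seen)
  }
  seen
}

#' Write an ontology to OBO format
#' @param onto an [ontology()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(onto$terms))) {
    id <- onto$terms$term_id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", onto$terms$name[i]),
                 if (length(onto$parents[[id]]))
                   paste0("is_a: ", onto$parents[[id]])), con)
  }
  invisible(path)
}

#' Cumulative annotation counts over an ontology
#'
#' Given per-individual annotation term sets, counts for every term the
#' number of individuals annotated at that term or any of its descendants
#' (equivalently: annotations are propagated to all ancestors before
#' counting distinct individuals).  This cumulative count is the
#' information-content metric used for term matching, and is monotone:
#' a parent's count is at least each child's.
#'
#' @param onto an [ontology()].
#' @param annotations named list: for each individual, the character vector
#'   of term_ids annotated to them.
#' @return Named integer vector of counts, one per ontology term.
#' @export
annotation_counts <- function(onto, annotations) {
  counts <- setNames(integer(nrow(onto$terms)), onto$terms$term_id)
  for (terms in annotations) {
    terms <- intersect(unique(terms), names(counts))
    up <- unique(unlist(lapply(terms, term_ancestors, onto = onto)))
    counts[up] <- counts[up] + 1L
  }
  counts
}

#' Information content of a term from cumulative annotation counts
#'
#' `-ln(count(term) / total)`.  Terms annotating every individual (roots)
#' have zero information; rarely annotated terms have high information.
#' A zero count means the term carries no annotation evidence and cannot
#' be used for matching; this signals an error.
#'
#' @param term_id term identifier (vectorised).
#' @param counts named counts from [annotation_counts()].
#' @param total positive integer, number of annotated individuals.
#' @return Non-negative numeric vector of information contents (nats).
#' @export
information_content <- function(term_id, counts, total) {
  stopifnot(total >= 1)
  cnt <- counts[term_id]
  if (anyNA(cnt)) stop_input("unknown term: ",
                             paste(term_id[is.na(cnt)], collapse = ", "))
  if (any(cnt < 1))
    stop_input("zero annotation count; term unusable for matching: ",
               paste(term_id[cnt < 1], collapse = ", "))
  unname(-log(cnt / total))
}

#' Do two ontology terms match closely?
#'
#' Two terms are a close match when they are identical, or when one is an
#' ancestor of the other and their information contents (cumulative
#' annotation counts through the graph) differ by at most `delta_ic` nats.
#' Graph distance alone is a poor proxy for biological similarity, which is
#' why the information-content band is applied along ancestor/descendant
#' paths only.
#'
#' @param a,b term identifiers.
#' @param onto an [ontology()].
#' @param counts named counts from [annotation_counts()].
#' @param total number of annotated individuals.
#' @param delta_ic maximum information-content difference (nats);
#'   default 1.0.
#' @return Logical scalar; symmetric in `a` and `b`.
#' @export
close_match <- function(a, b, onto, counts, total, delta_ic = 1.0) {
  if (!a %in% onto$terms$term_id) stop_input("unknown term: ", a)
  if (!b %in% onto$terms$term_id) stop_input("unknown term: ", b)
  if (a == b) return(TRUE)
  related <- b %in% term_ancestors(onto, a) || a %in% term_ancestors(onto, b)
  if (!related) return(FALSE)
  abs(information_content(a, counts, total) -
      information_content(b, counts, total)) <= delta_ic
}
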