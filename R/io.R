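#' Write cohort genotypes as a VCF file
#'
#' Biallelic SNVs only, GT field, 1-based positions; one sample column per
#' individual.  Missing dosages become `./.`.
#'
#' @param genotypes dosage matrix, individuals x variants (row and column
#'   names required; columns are catalogue variant ids).
#' @param variants the [variant_catalogue()] supplying chrom/pos/ref/alt.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  stopifnot(!is.null(rownames(genotypes)), !is.null(colnames(genotypes)))
  v <- variants[match(colnames(genotypes), variants$variant_id), ]
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=genofirst",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  ord <- order(suppressWarnings(as.integer(v$chrom)), v$chrom, v$pos)
  for (j in ord) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j],
                       v$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write one individual's genotypes in DTC array style
#'
#' Tab-separated `rsid`, `chromosome`, `position`, `genotype` with the
#' genotype as a letter pair (e.g. `AG`), `--` for missing — the common
#' dialect of consumer-array raw downloads.
#'
#' @param dosages named dosage vector (names are catalogue variant ids).
#' @param variants the [variant_catalogue()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dtc_tsv <- function(dosages, variants, path) {
  v <- variants[match(names(dosages), variants$variant_id), ]
  gt <- character(length(dosages))
  for (i in seq_along(dosages)) {
    d <- dosages[i]
    gt[i] <- if (is.na(d)) "--"
             else paste0(rep(c(v$ref[i], v$alt[i]), c(2 - d, d)), collapse = "")
  }
  tab <- data.frame(rsid = v$variant_id, chromosome = v$chrom,
                    position = v$pos, genotype = gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rsid\tchromosome\tposition\tgenotype", con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read genotypes and normalise them against a variant catalogue
#'
#' Supports VCF (biallelic SNV records, GT field) and the DTC
#' letter-pair dialect.  Records absent from the catalogue are dropped
#' with a logged count; multi-allelic records are skipped with a warning.
#' The result always has one column per catalogue variant, `NA` where a
#' site was not covered by the file... sites never observed are missing,
#' not reference.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dtc_tsv"`.
#' @param variants the [variant_catalogue()] to normalise against.
#' @param individual_id sample name for `dtc_tsv` input (one individual
#'   per file).
#' @return Dosage matrix, individuals x catalogue variants.
#' @export
read_genotypes <- function(path, format = c("vcf", "dtc_tsv"), variants,
                           individual_id = "sample") {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path, variants)
  else read_genotypes_dtc(path, variants, individual_id)
}

read_genotypes_vcf <- function(path, variants) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) |
    nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) > 1L
  if (any(multi))
    warning(sum(multi), " multi-allelic or non-SNV record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  key_file <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"])
  key_cat <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  hit <- match(key_file, key_cat)
  hit[multi] <- NA
  dropped <- sum(is.na(hit) & !multi)
  if (dropped) message(dropped, " record(s) not in the variant catalogue; dropped")
  n_sample <- ncol(gt)
  out <- matrix(NA_integer_, nrow = n_sample, ncol = nrow(variants),
                dimnames = list(colnames(gt), variants$variant_id))
  keep <- which(!is.na(hit))
  for (r in keep) {
    g <- gt[r, ]
    d <- vapply(strsplit(g, "[/|]"), function(a) {
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a)) NA_integer_ else sum(a)
    }, integer(1))
    out[, hit[r]] <- d
  }
  out
}

read_genotypes_dtc <- function(path, variants, individual_id) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop_input("malformed DTC record at line ", bad[1])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- c("rsid", "chromosome", "position", "genotype")
  out <- matrix(NA_integer_, nrow = 1, ncol = nrow(variants),
                dimnames = list(individual_id, variants$variant_id))
  hit <- match(tab$rsid, variants$variant_id)
  # fall back to coordinate matching for records without a known rsid
  coord <- paste(tab$chromosome, tab$position)
  hit2 <- match(coord, paste(variants$chrom, variants$pos))
  hit[is.na(hit)] <- hit2[is.na(hit)]
  dropped <- sum(is.na(hit))
  if (dropped) message(dropped, " record(s) not in the variant catalogue; dropped")
  for (i in which(!is.na(hit))) {
    j <- hit[i]
    g <- toupper(tab$genotype[i])
    if (g %in% c("--", "..", "")) next
    alleles <- strsplit(g, "")[[1]]
    if (length(alleles) != 2L) next
    ok <- alleles %in% c(variants$ref[j], variants$alt[j])
    if (!all(ok)) next
    out[1, j] <- sum(alleles == variants$alt[j])
  }
  out
}

#' Read a variant catalogue from TSV
#'
#' @param path TSV with the [variant_catalogue()] columns.
#' @return A validated `variant_catalogue` data frame.
#' @export
read_variant_catalogue <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
  variant_catalogue(tab)
}

#' Read a world directory written by [write_world()]
#'
#' Loads every pipeline input (emission tables, domain hits, domain-term
#' map, ontology, variant catalogue, cohort VCF, and truth records when
#' present) back into the in-memory form [run_pipeline()] consumes.
#' Individuals whose identifiers start with `"SUB"` are taken as the
#' subjects, the rest as the background, matching the generator's naming.
#'
#' @param dir directory containing `emissions.tsv`, `domain_hits.tsv`,
#'   `domain_term_map.tsv`, `ontology.obo`, `variants.tsv`, `cohort.vcf`
#'   and optionally `truth.json`.
#' @return A list shaped like a [generate_world()] result.
#' @export
read_world <- function(dir) {
  variants <- read_variant_catalogue(file.path(dir, "variants.tsv"))
  genotypes <- read_genotypes(file.path(dir, "cohort.vcf"), "vcf", variants)
  ids <- rownames(genotypes)
  truth_path <- file.path(dir, "truth.json")
  structure(list(
    hmms = read_hmm_emissions(file.path(dir, "emissions.tsv")),
    hits = read_domain_hits(file.path(dir, "domain_hits.tsv")),
    map = read_domain_term_map(file.path(dir, "domain_term_map.tsv")),
    onto = read_obo(file.path(dir, "ontology.obo")),
    variants = variants,
    genotypes = genotypes,
    background = ids[!startsWith(ids, "SUB")],
    subjects = ids[startsWith(ids, "SUB")],
    truth = if (file.exists(truth_path)) jsonlite::read_json(truth_path)
            else NULL),
    class = "sim_world")
}

#' Run configuration for the end-to-end pipeline
#'
#' @param background_mode `"external"` (individuals of interest scored
#'   against a designated background cohort) or `"self"` (the cohort is
#'   its own background, as when scoring a patient cohort jointly).
#' @param params a [score_params()].
#' @param n_perm permutations for the evaluation stage.
#' @param seed top-level seed.
#' @param n_top questions per questionnaire side.
#' @param term_filter optional character vector restricting the terms
#'   processed (e.g. one branch of the ontology).
#' @param out_dir optional output directory for TSV/JSON results.
#' @return List of class `run_config`.
#' @export
run_config <- function(background_mode = c("external", "self"),
                       params = score_params(), n_perm = 2000, seed = 1,
                       n_top = 25, term_filter = NULL, out_dir = NULL) {
  background_mode <- match.arg(background_mode)
  structure(list(background_mode = background_mode, params = params,
                 n_perm = n_perm, seed = seed, n_top = n_top,
                 term_filter = term_filter, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat keys mirroring [run_config()] and [score_params()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp_args <- intersect(names(y), names(formals(score_params)))
  params <- do.call(score_params, y[sp_args])
  rc_args <- intersect(names(y), setdiff(names(formals(run_config)), "params"))
  do.call(run_config, c(y[rc_args], list(params = params)))
}

#' Run the full genetics-first pipeline on a world
#'
#' Orchestrates, per ontology term: profile construction, distance
#' matrix, structure detection, outlier scoring, above-threshold call
#' classification; logs counts at every stage.  Fully reproducible given
#' the configuration seeds; inputs are never mutated.
#'
#' @param world a [generate_world()] result, or any list with the same
#'   elements (`hmms`, `hits`, `map`, `onto`, `variants`, `genotypes`,
#'   `background`, `subjects`).
#' @param config a [run_config()].
#' @param verbose log one line per term (default TRUE).
#' @return List of class `pipeline_result`: `scores` (long data frame over
#'   all terms), `calls` (above-threshold rows), `classified` (list of
#'   [classify_call()] objects), `term_log`, `config`.
#' @export
run_pipeline <- function(world, config = run_config(), verbose = TRUE) {
  params <- config$params
  terms <- config$term_filter %||% sort(unique(world$map$term_id))
  background <- switch(config$background_mode,
                       external = world$background,
                       self = rownames(world$genotypes))
  say <- function(...) if (verbose) message(...)
  if (!length(terms)) {
    say("pipeline: empty term filter, nothing to do")
    return(structure(list(scores = NULL, calls = NULL, classified = list(),
                          term_log = NULL, config = config),
                     class = "pipeline_result"))
  }
  scores <- list(); calls <- list(); classified <- list(); logrows <- list()
  profiles <- list()
  for (t in terms) {
    prof <- build_term_profile(t, world$map, world$hits, world$variants,
                               world$hmms)
    if (prof$empty) {
      say("term ", t, ": empty profile, skipped")
      logrows[[t]] <- data.frame(term_id = t, n_sites = 0L,
                                 has_structure = FALSE, k = NA_integer_,
                                 n_calls = 0L)
      next
    }
    profiles[[t]] <- prof
    sset <- score_term(prof, world$genotypes, background = background,
                       params = params)
    cl <- outlier_calls(sset)
    say("term ", t, ": ", nrow(prof$sites), " sites; ",
        if (sset$has_structure) paste0("structure k=", sset$k) else "no structure",
        "; ", nrow(cl), " call(s)")
    scores[[t]] <- cbind(term_id = t, sset$scores)
    if (nrow(cl)) {
      calls[[t]] <- cl
      for (i in seq_len(nrow(cl))) {
        id <- cl$individual[i]
        classified[[paste(t, id)]] <-
          classify_call(sset, id, prof, world$genotypes,
                        background = background, params = params)
      }
    }
    logrows[[t]] <- data.frame(term_id = t, n_sites = nrow(prof$sites),
                               has_structure = sset$has_structure,
                               k = sset$k, n_calls = nrow(cl))
  }
  out <- structure(list(scores = do.call(rbind, c(scores, list(make.row.names = FALSE))),
                        calls = if (length(calls))
                          do.call(rbind, c(calls, list(make.row.names = FALSE)))
                        else NULL,
                        classified = classified,
                        term_log = do.call(rbind, c(logrows, list(make.row.names = FALSE))),
                        profiles = profiles,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(out, config$out_dir)
  out
}

#' Write pipeline outputs as TSV plus a JSON summary
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(scores = file.path(dir, "scores.tsv"),
                calls = file.path(dir, "calls.tsv"),
                log = file.path(dir, "term_log.tsv"),
                summary = file.path(dir, "summary.json"))
  if (!is.null(result$scores))
    write.table(result$scores, paths$scores, sep = "\t", quote = FALSE,
                row.names = FALSE)
  calltab <- pipeline_call_table(result)
  if (!is.null(calltab))
    write.table(calltab, paths$calls, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(result$term_log))
    write.table(result$term_log, paths$log, sep = "\t", quote = FALSE,
                row.names = FALSE)
  jsonlite::write_json(
    list(n_terms = if (is.null(result$term_log)) 0L else nrow(result$term_log),
         n_calls = length(result$classified),
         config = result$config[c("background_mode", "n_perm", "seed")]),
    paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Flat table of classified calls (one row per call).
pipeline_call_table <- function(result) {
  if (!length(result$classified)) return(NULL)
  do.call(rbind, lapply(result$classified, function(cc) {
    data.frame(individual = cc$individual, term_id = cc$term_id,
               score = cc$score, type = cc$type,
               n_required = sum(cc$roles$role == "required"),
               n_contributing = sum(cc$roles$role == "contributing"),
               required_variants = paste(
                 cc$roles$variant_id[cc$roles$role == "required"],
                 collapse = ","),
               combinatorial = cc$combinatorial,
               stringsAsFactors = FALSE)
  }))
}
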