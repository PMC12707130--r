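# Survey orchestration: iterate structures or representative-set entries,
# classify every amine, aggregate the per-base class distribution and the
# ranked acceptor-pair tables, and report pseudotorsion-region summaries.

#' Run the amine survey over a set of structures
#'
#' For each input (a structure data frame, or a file path read via
#' [read_structure()]), strips hydrogens, protonates the amines of the
#' donor chains, classifies every amine, and optionally computes the
#' per-amine descriptor block. Per-entry failures are recorded in the
#' manifest and skipped, never silently dropped.
#'
#' @param inputs list of structure data frames and/or file paths.
#' @param target_chains donor chains (NULL = all chains, or a list parallel
#'   to `inputs`).
#' @param criteria from [hbond_criteria()].
#' @param options from [chem_options()].
#' @param descriptors also compute SASA/density/torsion descriptors.
#' @return An object of class `dualamine_survey`: `records` (per amine),
#'   `summary` (per-base class counts and percentages), `excluded`,
#'   `manifest` (per-entry status), `observations`.
#' @export
run_survey <- function(inputs, target_chains = NULL,
                       criteria = hbond_criteria(),
                       options = chem_options(),
                       descriptors = FALSE) {
  if (inherits(inputs, "dualamine_structure") || is.character(inputs)) {
    inputs <- if (is.character(inputs)) as.list(inputs) else list(inputs)
  }
  records <- list(); excluded <- list(); manifest <- list(); obs <- list()
  for (i in seq_along(inputs)) {
    chains <- if (is.list(target_chains)) target_chains[[i]] else target_chains
    res <- tryCatch({
      s <- inputs[[i]]
      if (is.character(s)) s <- read_structure(s)
      sv <- survey_structure(s, chains, criteria, options)
      rec <- if (descriptors) amine_descriptors(s, sv) else sv$records
      list(rec = rec, exc = sv$excluded, obs = sv$observations,
           id = attr(s, "entry_id"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      manifest[[i]] <- data.frame(input = i, entry_id = NA_character_,
                                  status = "error",
                                  detail = conditionMessage(res),
                                  stringsAsFactors = FALSE)
      next
    }
    manifest[[i]] <- data.frame(input = i, entry_id = res$id, status = "ok",
                                detail = "", stringsAsFactors = FALSE)
    if (!is.null(res$rec)) records[[length(records) + 1]] <- res$rec
    if (nrow(res$exc) > 0) excluded[[length(excluded) + 1]] <- res$exc
    if (!is.null(res$obs)) obs[[length(obs) + 1]] <- res$obs
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  out <- list(records = records,
              summary = summarize_survey(records),
              excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
              manifest = do.call(rbind, manifest),
              observations = if (length(obs)) do.call(rbind, obs) else NULL,
              criteria = criteria)
  class(out) <- "dualamine_survey"
  out
}

summarize_survey <- function(records) {
  bases <- c("A", "C", "G")
  klasses <- c("non", "single", "dual")
  counts <- matrix(0L, 3, 3, dimnames = list(klasses, bases))
  if (!is.null(records) && nrow(records) > 0) {
    tab <- table(factor(records$klass, klasses), factor(records$base, bases))
    counts[] <- as.integer(tab)
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts * 0
  list(counts = counts, percent = pct, total = total,
       per_base_totals = colSums(counts))
}

#' @export
print.dualamine_survey <- function(x, ...) {
  cat("Amine donation survey:", x$summary$total, "amines\n")
  if (x$summary$total > 0) {
    print(round(x$summary$percent, 1))
  }
  if (!is.null(x$excluded) && nrow(x$excluded) > 0) {
    cat("excluded residues:", nrow(x$excluded), "\n")
  }
  invisible(x)
}

#' Ranked acceptor pairs of dual-donating amines
#'
#' Counts dual-donor acceptor pairs by canonical-ordered label pair and the
#' fraction of instances where both acceptors belong to one residue.
#'
#' @param records per-amine records (from [run_survey()] or
#'   [survey_structure()]).
#' @param base restrict to one nucleobase (NULL = all).
#' @param top_k number of pairs to return (all when fewer exist).
#' @return Data frame: `acc1`, `acc2`, `count`, `same_residue_fraction`.
#' @export
rank_acceptor_pairs <- function(records, base = NULL, top_k = 10) {
  empty <- data.frame(acc1 = character(), acc2 = character(),
                      count = integer(), same_residue_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(records) || nrow(records) == 0) return(empty)
  d <- records[records$klass == "dual", , drop = FALSE]
  if (!is.null(base)) d <- d[d$base == base, , drop = FALSE]
  if (nrow(d) == 0) return(empty)
  key <- paste(d$acc1, d$acc2, sep = " / ")
  agg <- lapply(split(seq_len(nrow(d)), key), function(ii) {
    data.frame(acc1 = d$acc1[ii[1]], acc2 = d$acc2[ii[1]],
               count = length(ii),
               same_residue_fraction = mean(d$same_residue[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$count, out$acc1, out$acc2), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Acceptor pairs within a pseudotorsion region
#'
#' Restricts dual-donor records to a pseudotorsion box and tabulates their
#' acceptor pairs, plus the count of 5'-adjacent Location-1/Location-2
#' residue pairs (a Location-1 residue immediately 5' of a Location-2
#' residue on the same chain).
#'
#' @param records per-amine records carrying `eta`/`theta` columns.
#' @param box one element of [region_boxes()] (or its name).
#' @param top_k pairs to return.
#' @return List: `pairs` (ranked table), `n_in_region`, `excluded_undefined`
#'   (count of records without defined pseudotorsions), `adjacency`
#'   (Location-1 -> Location-2 5'-linkage count over all records).
#' @export
region_report <- function(records, box = "location1", top_k = 10) {
  if (is.character(box)) box <- region_boxes()[[box]]
  if (is.null(records) || nrow(records) == 0 || !("eta" %in% names(records))) {
    return(list(pairs = rank_acceptor_pairs(NULL), n_in_region = 0L,
                excluded_undefined = 0L, adjacency = 0L))
  }
  undef <- is.na(records$eta) | is.na(records$theta)
  inside <- in_region(records$eta, records$theta, box)
  sel <- records[!undef & inside & records$klass == "dual", , drop = FALSE]
  boxes <- region_boxes()
  l1 <- in_region(records$eta, records$theta, boxes$location1) &
    records$klass == "dual" & !undef
  l2 <- in_region(records$eta, records$theta, boxes$location2) &
    records$klass == "dual" & !undef
  adj <- 0L
  if (any(l1) && any(l2)) {
    k1 <- paste(records$entry_id[l1], records$chain[l1], records$resno[l1] + 1)
    k2 <- paste(records$entry_id[l2], records$chain[l2], records$resno[l2])
    adj <- sum(k1 %in% k2)
  }
  list(pairs = rank_acceptor_pairs(sel, top_k = top_k),
       n_in_region = nrow(sel),
       excluded_undefined = sum(undef),
       adjacency = adj)
}
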