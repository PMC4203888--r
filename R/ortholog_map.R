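# Ortholog map construction: reciprocal best hits between two
# transcript sets, probe-set -> transcript assignment under the 24/25
# per-probe and 9/11 per-probe-set quorum rules, and collapse of the
# combined match graph into cross-species metagene units.

# Best hit per query: lowest e-value, then highest bitscore, then
# lexicographically smallest subject id. Duplicate (query, subject)
# rows collapse to their best-scoring row first, so the winner is
# always unique when any hit survives the e-value filter.
best_hit_per_query <- function(hits, evalue_max = Inf) {
  if (nrow(hits) == 0L) return(character(0))
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(character(0))
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$qseqid)
  stats::setNames(hits$sseqid[first], hits$qseqid[first])
}

#' Reciprocal best hits between two species
#'
#' Given blastn hit tables in both directions, returns the ordered
#' pairs (a, b) such that b is a's unique best hit and a is b's unique
#' best hit, after discarding hits with e-value above `evalue_max`.
#' Ranking is by lowest e-value, ties broken by highest bitscore, then
#' lexicographic subject id.
#'
#' @param hits_ab,hits_ba Hit tables (data.frames as returned by
#'   [read_blast_tab()]) for the A-vs-B and B-vs-A searches.
#' @param evalue_max E-value threshold; hits above it are ignored
#'   (default 1e-5).
#' @return data.frame with columns `id_A`, `id_B`, sorted by `id_A`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-5) {
  stopifnot(evalue_max > 0)
  validate_blast_hits(hits_ab, "hits_ab")
  validate_blast_hits(hits_ba, "hits_ba")
  best_ab <- best_hit_per_query(hits_ab, evalue_max)
  best_ba <- best_hit_per_query(hits_ba, evalue_max)
  if (length(best_ab) == 0L || length(best_ba) == 0L)
    return(data.frame(id_A = character(0), id_B = character(0)))
  a <- names(best_ab)
  b <- unname(best_ab)
  mutual <- !is.na(best_ba[b]) & best_ba[b] == a
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(id_A = a[mutual], id_B = b[mutual])
  out[order(out$id_A), , drop = FALSE]
}

#' Map probe sets to transcripts under per-probe and quorum thresholds
#'
#' A probe's call is its top blast hit, and the call counts only when
#' the hit covers at least `min_probe_match` matched bases
#' (alignment length minus mismatches; 24 of the nominal 25-mer by
#' default). A probe set maps to transcript T when at least
#' `min_probes_agree` of its probes call T (9 of the nominal 11 by
#' default; for other probe-set sizes the quorum generalizes to
#' `ceiling(0.818 * n_probes)`).
#'
#' @param probe_hits Hit table of probe-vs-transcript blast results.
#' @param probesets data.frame with columns `probeset_id`, `probe_id`
#'   (long-format membership table).
#' @param min_probe_match Minimum matched bases for a probe call
#'   (default 24).
#' @param min_probes_agree Quorum of agreeing probes; `NULL` (default)
#'   uses `ceiling(0.818 * n_probes)` per probe set, which is 9 for the
#'   standard 11-probe set.
#' @return Named character vector: `probeset_id` -> `transcript_id`.
#'   Probe sets failing the quorum are absent.
#' @export
map_probeset_to_transcript <- function(probe_hits, probesets,
                                       min_probe_match = 24L,
                                       min_probes_agree = NULL) {
  stopifnot(all(c("probeset_id", "probe_id") %in% names(probesets)))
  validate_blast_hits(probe_hits, "probe_hits")
  known <- unique(probesets$probe_id)
  if (nrow(probe_hits) > 0L) {
    orphan <- setdiff(unique(probe_hits$qseqid), known)
    if (length(orphan)) {
      warning(length(orphan),
              " probe hit query id(s) not in any probe set; ignored")
      probe_hits <- probe_hits[!(probe_hits$qseqid %in% orphan), ,
                               drop = FALSE]
    }
  }
  if (nrow(probe_hits) == 0L) return(stats::setNames(character(0), character(0)))
  # top hit per probe first, then the matched-bases constraint
  best <- best_hit_per_query(probe_hits)
  key <- paste(probe_hits$qseqid, probe_hits$sseqid)
  bestkey <- paste(names(best), unname(best))
  rows <- probe_hits[match(bestkey, key), , drop = FALSE]
  matched <- rows$length - rows$mismatch
  calls <- stats::setNames(unname(best)[matched >= min_probe_match],
                           names(best)[matched >= min_probe_match])
  if (length(calls) == 0L) return(stats::setNames(character(0), character(0)))
  ps_of <- stats::setNames(probesets$probeset_id, probesets$probe_id)
  tab <- table(probeset = ps_of[names(calls)], transcript = calls)
  n_probes <- table(probesets$probeset_id)
  out <- stats::setNames(character(0), character(0))
  for (ps in rownames(tab)) {
    quorum <- if (is.null(min_probes_agree))
      ceiling(0.818 * as.integer(n_probes[[ps]])) else min_probes_agree
    counts <- tab[ps, ]
    top <- which(counts >= quorum)
    if (length(top) == 1L)
      out[ps] <- colnames(tab)[top]
  }
  out[order(names(out))]
}

#' Collapse ortholog pairs and probe-set links into metagenes
#'
#' Combines cross-species reciprocal-best-hit transcript pairs with
#' within-species probe-set-to-transcript links into one undirected
#' graph, emits unique 1:1 matches directly, and resolves the
#' remaining many-to-many relationships as connected components. Each
#' retained unit (a "metagene") has at least one member probe set in
#' each species; single-species components are dropped with a logged
#' count since no cross-species quantification is possible for them.
#'
#' @param rbh_pairs data.frame with columns `id_A`, `id_B` (transcript
#'   ids), as from [reciprocal_best_hits()].
#' @param links_A,links_B Named character vectors mapping probe-set id
#'   to transcript id for species A and B, as from
#'   [map_probeset_to_transcript()].
#' @return data.frame of class `metagene_map` with columns
#'   `metagene_id`, `species` (`"A"`/`"B"`), `probeset_id`, `type`
#'   (`"unique"` or `"component"`). The number of dropped
#'   single-species components is available as attribute
#'   `n_dropped_single_species`.
#' @export
build_metagene_map <- function(rbh_pairs, links_A, links_B) {
  stopifnot(all(c("id_A", "id_B") %in% names(rbh_pairs)))
  edge <- function(u, v) cbind(u, v)
  edges <- rbind(
    edge(paste0("A.tx:", rbh_pairs$id_A), paste0("B.tx:", rbh_pairs$id_B)),
    if (length(links_A))
      edge(paste0("A.ps:", names(links_A)), paste0("A.tx:", unname(links_A))),
    if (length(links_B))
      edge(paste0("B.ps:", names(links_B)), paste0("B.tx:", unname(links_B))))
  empty <- data.frame(metagene_id = character(0), species = character(0),
                      probeset_id = character(0), type = character(0))
  if (is.null(edges) || nrow(edges) == 0L) {
    attr(empty, "n_dropped_single_species") <- 0L
    class(empty) <- c("metagene_map", class(empty))
    return(empty)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  vnames <- igraph::V(g)$name
  members <- split(vnames, comp$membership)
  rows <- list(); dropped <- 0L
  for (mem in members) {
    ps_A <- sort(sub("^A\\.ps:", "", mem[startsWith(mem, "A.ps:")]))
    ps_B <- sort(sub("^B\\.ps:", "", mem[startsWith(mem, "B.ps:")]))
    if (length(ps_A) == 0L || length(ps_B) == 0L) {
      dropped <- dropped + 1L
      next
    }
    type <- if (length(ps_A) == 1L && length(ps_B) == 1L &&
                sum(startsWith(mem, "A.tx:")) == 1L &&
                sum(startsWith(mem, "B.tx:")) == 1L) "unique" else "component"
    rows[[length(rows) + 1L]] <- data.frame(
      key = ps_A[1L],
      species = rep(c("A", "B"), c(length(ps_A), length(ps_B))),
      probeset_id = c(ps_A, ps_B), type = type)
  }
  if (dropped > 0L)
    message("dropped ", dropped, " single-species component(s)")
  if (length(rows) == 0L) {
    attr(empty, "n_dropped_single_species") <- dropped
    class(empty) <- c("metagene_map", class(empty))
    return(empty)
  }
  out <- do.call(rbind, rows)
  # deterministic metagene ids ordered by smallest species-A member
  keys <- sort(unique(out$key))
  ids <- stats::setNames(sprintf("MG%06d", seq_along(keys)), keys)
  out <- data.frame(metagene_id = unname(ids[out$key]),
                    species = out$species, probeset_id = out$probeset_id,
                    type = out$type)
  out <- out[order(out$metagene_id, out$species, out$probeset_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$probeset_id[out$species == "A"]) ||
      anyDuplicated(out$probeset_id[out$species == "B"]))
    stop("internal error: probe set assigned to two metagenes")
  attr(out, "n_dropped_single_species") <- dropped
  class(out) <- c("metagene_map", class(out))
  out
}

#' Aggregate probe-set expression to metagene units
#'
#' Each metagene row is the per-array median over its member probe-set
#' rows for the given species; single-member metagenes equal their
#' member row exactly.
#'
#' @param expr Probe-set-level expression matrix for one species.
#' @param map Metagene map from [build_metagene_map()].
#' @param species `"A"` or `"B"`: which side of the map `expr` holds.
#' @return Metagene-level expression matrix (rows ordered by metagene
#'   id).
#' @export
aggregate_metagene_expression <- function(expr, map, species = c("A", "B")) {
  species <- match.arg(species)
  m <- map[map$species == species, , drop = FALSE]
  missing <- setdiff(m$probeset_id, rownames(expr))
  if (length(missing)) {
    mg <- m$metagene_id[match(missing[1L], m$probeset_id)]
    stop("metagene ", mg, ": member probe set '", missing[1L],
         "' has no row in the expression matrix")
  }
  ids <- sort(unique(m$metagene_id))
  out <- matrix(NA_real_, length(ids), ncol(expr),
                dimnames = list(ids, colnames(expr)))
  groups <- split(m$probeset_id, m$metagene_id)
  for (id in ids) {
    sub <- expr[groups[[id]], , drop = FALSE]
    out[id, ] <- if (nrow(sub) == 1L) sub[1L, ] else
      apply(sub, 2L, stats::median)
  }
  out
}

#' Write a metagene map as TSV
#' @param map Metagene map from [build_metagene_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metagene_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
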