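# Independent brute-force oracles used to pin the implementation.
# These deliberately share no code with the package internals.

# Best hit per query by plain row-by-row comparison: lowest e-value,
# then highest bitscore, then lexicographically smallest subject id.
oracle_best_hits <- function(hits, evalue_max = Inf) {
  out <- character(0)
  for (q in sort(unique(hits$qseqid))) {
    h <- hits[hits$qseqid == q & hits$evalue <= evalue_max, , drop = FALSE]
    if (nrow(h) == 0L) next
    best <- h[1L, ]
    if (nrow(h) > 1L) for (i in 2:nrow(h)) {
      r <- h[i, ]
      better <- r$evalue < best$evalue ||
        (r$evalue == best$evalue && r$bitscore > best$bitscore) ||
        (r$evalue == best$evalue && r$bitscore == best$bitscore &&
         r$sseqid < best$sseqid)
      if (better) best <- r
    }
    out[q] <- best$sseqid
  }
  out
}

oracle_rbh <- function(hits_ab, hits_ba, evalue_max) {
  fwd <- oracle_best_hits(hits_ab, evalue_max)
  rev <- oracle_best_hits(hits_ba, evalue_max)
  pairs <- list()
  for (a in names(fwd)) {
    b <- fwd[[a]]
    if (!is.na(rev[b]) && !is.null(rev[[b]]) && b %in% names(rev) &&
        rev[[b]] == a)
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (length(pairs) == 0L)
    return(data.frame(id_A = character(0), id_B = character(0)))
  m <- do.call(rbind, pairs)
  out <- data.frame(id_A = m[, 1L], id_B = m[, 2L])
  out[order(out$id_A), , drop = FALSE]
}

# Union-find connected components over a 2-column character edge list.
oracle_components <- function(edges) {
  nodes <- sort(unique(c(edges)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges[i, 1L]); rb <- find(edges[i, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(nodes, find, "")
  unname(lapply(split(nodes, roots), sort))
}

# Classical Benjamini-Hochberg step-up rejection set by enumeration.
oracle_bh_flags <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  flag <- rep(FALSE, m)
  if (k > 0L) flag[o[seq_len(k)]] <- TRUE
  flag
}

# Degeneracy of a codon position by direct enumeration of the three
# alternative bases under the standard genetic code.
oracle_degeneracy <- function(codon, pos) {
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- gc_tab[[codon]]
  if (aa == "*") return(NA_character_)
  n_syn <- 0L
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
    alt <- codon
    substr(alt, pos, pos) <- b
    if (gc_tab[[alt]] == aa) n_syn <- n_syn + 1L
  }
  if (n_syn == 0L) "nondegenerate" else if (n_syn == 3L) "fourfold"
  else "twofold"
}

# Random hit tables with deliberate score ties to stress tie-breaking.
random_hit_table <- function(queries, subjects, n_hits,
                             evalues = c(1e-20, 1e-10, 1e-10, 1e-6, 1e-3),
                             bitscores = c(100, 200, 200, 300)) {
  data.frame(qseqid = sample(queries, n_hits, replace = TRUE),
             sseqid = sample(subjects, n_hits, replace = TRUE),
             pident = 90, length = 500L, mismatch = 50L, gapopen = 0L,
             qstart = 1L, qend = 500L, sstart = 1L, send = 500L,
             evalue = sample(evalues, n_hits, replace = TRUE),
             bitscore = sample(bitscores, n_hits, replace = TRUE))
}

# Canonical form of a metagene partition: sorted list of
# "A-members|B-members" signatures, ignoring ids.
partition_signature <- function(map) {
  df <- as.data.frame(map)
  sigs <- vapply(split(df, df$metagene_id), function(g) {
    paste(paste(sort(g$probeset_id[g$species == "A"]), collapse = ","),
          paste(sort(g$probeset_id[g$species == "B"]), collapse = ","),
          sep = "|")
  }, "")
  sort(unname(sigs))
}
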