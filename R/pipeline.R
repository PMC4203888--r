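# End-to-end synthetic run: generate every input class from one root
# seed, write the inputs in their on-disk dialects, execute each
# pipeline stage on the written files, and write all result tables.
# Running it twice with the same seed must produce byte-identical
# files, which is the pipeline's determinism contract.

#' Run the full pipeline on simulated inputs
#'
#' Generates orthology tables, probe-set-level two-species expression,
#' codon alignments and intensity transects from sub-seeds derived
#' deterministically from `seed`, writes the inputs to `dir/inputs`,
#' then runs ortholog mapping, normalization, metagene aggregation,
#' the divergence table, top-set overlap, the rankmap curve, the rate
#' table and the transect summary, writing results to `dir/results`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Root seed; all randomness derives from it.
#' @param n_transcripts Ortholog pairs to simulate (default 120).
#' @param n_genes Genes in the expression simulation (default 2000).
#' @param n_rate_genes Codon alignments to simulate (default 20).
#' @param n_codons Codons per alignment (default 300).
#' @return Invisibly, a named character vector of every file written
#'   (relative paths), suitable for hashing.
#' @export
run_synthetic_pipeline <- function(dir, seed = 1L,
                                   n_transcripts = 120L,
                                   n_genes = 2000L,
                                   n_rate_genes = 20L,
                                   n_codons = 300L) {
  ind <- file.path(dir, "inputs"); res <- file.path(dir, "results")
  for (d in c(ind, res)) dir.create(d, recursive = TRUE,
                                    showWarnings = FALSE)
  cfg <- run_config(seed = seed)
  files <- character(0)
  put <- function(rel) { files <<- c(files, rel); file.path(dir, rel) }

  # --- orthology ---
  orth <- simulate_orthology_tables(n_transcripts,
                                    many_to_many_fraction = 0.3,
                                    seed = derive_seed(seed, "orthology"))
  write_blast_tab(orth$hits_ab, put("inputs/hits_ab.tsv"))
  write_blast_tab(orth$hits_ba, put("inputs/hits_ba.tsv"))
  write_blast_tab(orth$probe_hits_A, put("inputs/probe_hits_A.tsv"))
  write_blast_tab(orth$probe_hits_B, put("inputs/probe_hits_B.tsv"))
  utils::write.table(orth$probesets_A, put("inputs/probesets_A.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(orth$probesets_B, put("inputs/probesets_B.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rbh <- reciprocal_best_hits(read_blast_tab(file.path(ind, "hits_ab.tsv")),
                              read_blast_tab(file.path(ind, "hits_ba.tsv")),
                              cfg$evalue_max)
  links_A <- map_probeset_to_transcript(
    read_blast_tab(file.path(ind, "probe_hits_A.tsv")),
    utils::read.delim(file.path(ind, "probesets_A.tsv")))
  links_B <- map_probeset_to_transcript(
    read_blast_tab(file.path(ind, "probe_hits_B.tsv")),
    utils::read.delim(file.path(ind, "probesets_B.tsv")))
  map <- build_metagene_map(rbh, links_A, links_B)
  write_metagene_map(map, put("results/metagene_map.tsv"))

  # --- expression: metagene-level truth spread over member probe sets ---
  n_mg <- length(unique(map$metagene_id))
  sim <- simulate_two_species_expression(
    n_genes = n_mg, seed = derive_seed(seed, "expression"))
  mg_ids <- sort(unique(map$metagene_id))
  spread <- function(species, expr) {
    m <- map[map$species == species, , drop = FALSE]
    idx <- match(m$metagene_id, mg_ids)
    noise <- matrix(stats::rnorm(nrow(m) * ncol(expr), 0, 0.05),
                    nrow(m), ncol(expr))
    out <- expr[idx, , drop = FALSE] + noise
    rownames(out) <- m$probeset_id
    out
  }
  set.seed(derive_seed(seed, "probeset_noise"))
  ps_A <- spread("A", sim$expr_A)
  ps_B <- spread("B", sim$expr_B)
  write_expression_tsv(ps_A, put("inputs/expr_probeset_A.tsv"))
  write_expression_tsv(ps_B, put("inputs/expr_probeset_B.tsv"))

  norm_A <- median_center_scale(
    read_expression_tsv(file.path(ind, "expr_probeset_A.tsv")))
  norm_B <- median_center_scale(
    read_expression_tsv(file.path(ind, "expr_probeset_B.tsv")))
  mg_A <- aggregate_metagene_expression(norm_A, map, "A")
  mg_B <- aggregate_metagene_expression(norm_B, map, "B")
  write_expression_tsv(mg_A, put("results/metagene_expr_A.tsv"))
  write_expression_tsv(mg_B, put("results/metagene_expr_B.tsv"))

  div <- welch_ttest_table(mg_A, mg_B, q = cfg$fdr_q)
  utils::write.table(format(div, digits = 10),
                     put("results/divergence_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  top_A <- median_rank_top_set(mg_A, cfg$top_fraction)
  top_B <- median_rank_top_set(mg_B, cfg$top_fraction)
  ov <- data.frame(
    denominator = c("A", "B"),
    overlap = c(overlap_fraction(top_A, top_B, "A"),
                overlap_fraction(top_A, top_B, "B")))
  utils::write.table(ov, put("results/top_overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  k_max <- min(cfg$k_max, n_mg - 1L)
  rm_curve <- rank_concordance_curve(mg_A, mg_B, k_min = cfg$k_min,
                                     k_max = k_max,
                                     conf_level = cfg$conf_level,
                                     bonferroni_factor =
                                       cfg$bonferroni_factor)
  utils::write.table(format(rm_curve, digits = 10),
                     put("results/rankmap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- molecular evolution ---
  aln_dir <- file.path(ind, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (i in seq_len(n_rate_genes)) {
    pair <- simulate_codon_pair(
      n_codons = n_codons, t = 0.2, kappa = 2, omega = 0.2,
      seed = derive_seed(seed, paste0("codon", i)),
      gene_id = sprintf("gene%03d", i))
    write_fasta_alignment(
      list(ids = paste0(pair$gene_id, c("_A", "_B")),
           seq_A = pair$seq_A, seq_B = pair$seq_B,
           meta = list(c(species = "A", region = "cds"),
                       c(species = "B", region = "cds"))),
      put(sprintf("inputs/alignments/gene%03d.fasta", i)))
  }
  alns <- lapply(sort(list.files(aln_dir, full.names = TRUE)),
                 function(f) {
                   a <- read_fasta_alignment(f)
                   list(gene_id = sub("_A$", "", a$ids[1L]),
                        seq_A = a$seq_A, seq_B = a$seq_B)
                 })
  rates <- compute_rate_table(alns, min_aa = min(cfg$min_aa, n_codons))
  utils::write.table(format(rates$table, digits = 10),
                     put("results/rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(rates$summary, digits = 10),
                     put("results/rates_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- imaging ---
  tsim <- simulate_transects(n_cells = 3L, n_dendrites_per_cell = 3L,
                             planted_ratio = 0.2,
                             seed = derive_seed(seed, "transects"))
  utils::write.table(format(tsim$transects, digits = 10),
                     put("inputs/transects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(tsim$soma, digits = 10),
                     put("inputs/soma.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- summarize_transects(
    read_transects_tsv(file.path(ind, "transects.tsv")),
    read_soma_tsv(file.path(ind, "soma.tsv")),
    window = cfg$ds_window)
  utils::write.table(format(ds, digits = 10),
                     put("results/ds_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(files)
}
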