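# Seeded simulators for every input class of the pipeline. Defaults
# mirror the study design: 9 replicate arrays for species A (rat) and
# 14 for species B (C57BL/6 mouse), Gaussian replicate noise on the
# log-expression scale, a planted fraction of divergently expressed
# orthologs with effect sizes in units of the noise standard
# deviation, 11-probe/25-mer probe sets, and rodent-scale codon
# divergence.

#' Simulate two-species replicate log-expression matrices
#'
#' Every gene draws a shared baseline log expression; a
#' `divergent_fraction` of genes additionally receive a species-B shift
#' of `+-effect_size` (random sign). Replicates add i.i.d. Gaussian
#' noise with standard deviation `noise_sd`.
#'
#' @param n_genes Number of genes/metagenes (default 10833, the size of
#'   the conservative rat-mouse ortholog map).
#' @param n_reps_A,n_reps_B Replicate array counts (defaults 9 and 14).
#' @param divergent_fraction Fraction of genes with a planted
#'   expression shift (default 0.2).
#' @param effect_size Absolute shift in log-expression units
#'   (default 2; with the default `noise_sd` of 1 this is two noise
#'   standard deviations).
#' @param noise_sd Replicate noise standard deviation (default 1).
#' @param baseline_mean,baseline_sd Parameters of the Gaussian per-gene
#'   baseline (defaults 0 and 1.5).
#' @param seed Integer seed; the output is reproducible bit-for-bit.
#' @return List with `expr_A`, `expr_B` (matrices with gene rownames
#'   `g<i>` and replicate colnames) and `divergent_ids` (character
#'   vector of the planted set).
#' @export
simulate_two_species_expression <- function(n_genes = 10833L,
                                            n_reps_A = 9L, n_reps_B = 14L,
                                            divergent_fraction = 0.2,
                                            effect_size = 2,
                                            noise_sd = 1,
                                            baseline_mean = 0,
                                            baseline_sd = 1.5,
                                            seed = 1L) {
  stopifnot(n_genes >= 1, n_reps_A >= 1, n_reps_B >= 1,
            divergent_fraction >= 0, divergent_fraction <= 1,
            noise_sd > 0, baseline_sd >= 0, effect_size >= 0)
  set.seed(seed)
  ids <- sprintf("g%05d", seq_len(n_genes))
  base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  n_div <- round(divergent_fraction * n_genes)
  div <- sort(sample.int(n_genes, n_div))
  shift <- numeric(n_genes)
  if (n_div > 0L)
    shift[div] <- sample(c(-effect_size, effect_size), n_div,
                         replace = TRUE)
  expr_A <- matrix(stats::rnorm(n_genes * n_reps_A, base, noise_sd),
                   n_genes, n_reps_A,
                   dimnames = list(ids, sprintf("A_rep%02d",
                                                seq_len(n_reps_A))))
  expr_B <- matrix(stats::rnorm(n_genes * n_reps_B, base + shift, noise_sd),
                   n_genes, n_reps_B,
                   dimnames = list(ids, sprintf("B_rep%02d",
                                                seq_len(n_reps_B))))
  list(expr_A = expr_A, expr_B = expr_B, divergent_ids = ids[div])
}

blast_row <- function(q, s, pident, len, mism, evalue, bitscore) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = mism, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue,
             bitscore = bitscore)
}

#' Simulate orthology hit tables with a known metagene partition
#'
#' Generates `n_transcripts` true ortholog transcript pairs with
#' reciprocal best blast hits (plus decoy secondary hits and
#' above-threshold noise hits), per-species probe-set membership tables
#' (11 probes of 25 bases each), and probe-vs-transcript hit tables.
#' A `many_to_many_fraction` of transcripts carry two probe sets on a
#' given side, which is what collapses into multi-member metagenes.
#' Optionally injects probe sets whose probes match at only 23/25
#' bases; these fail the per-probe constraint and must be absent from
#' the mapping.
#'
#' @param n_transcripts Number of ortholog transcript pairs.
#' @param many_to_many_fraction Probability that a transcript carries a
#'   second probe set (drawn independently per species side).
#' @param n_subthreshold Number of extra sub-threshold probe sets to
#'   inject per species (default 0).
#' @param seed Integer seed.
#' @return List with `hits_ab`, `hits_ba`, `probe_hits_A`,
#'   `probe_hits_B` (outfmt-6 data.frames), `probesets_A`,
#'   `probesets_B` (long membership tables), `truth` (metagene map
#'   data.frame in the layout of [build_metagene_map()]) and
#'   `subthreshold_probesets` (ids that must stay unmapped).
#' @export
simulate_orthology_tables <- function(n_transcripts = 200L,
                                      many_to_many_fraction = 0.3,
                                      n_subthreshold = 0L,
                                      seed = 1L) {
  stopifnot(n_transcripts >= 1, many_to_many_fraction >= 0,
            many_to_many_fraction <= 1)
  set.seed(seed)
  txA <- sprintf("txA%04d", seq_len(n_transcripts))
  txB <- sprintf("txB%04d", seq_len(n_transcripts))
  # reciprocal best hits + worse-scoring decoys + above-threshold noise
  hits_ab <- blast_row(txA, txB, 97, 1000L, 30L, 1e-50, 900)
  hits_ba <- blast_row(txB, txA, 97, 1000L, 30L, 1e-50, 900)
  decoy <- which(stats::runif(n_transcripts) < 0.3 &
                 seq_len(n_transcripts) < n_transcripts)
  if (length(decoy)) {
    hits_ab <- rbind(hits_ab,
                     blast_row(txA[decoy], txB[decoy + 1L], 80, 400L,
                               80L, 1e-8, 120))
    hits_ba <- rbind(hits_ba,
                     blast_row(txB[decoy + 1L], txA[decoy], 80, 400L,
                               80L, 1e-8, 120))
  }
  weak <- which(stats::runif(n_transcripts) < 0.2)
  if (length(weak))
    hits_ab <- rbind(hits_ab,
                     blast_row(txA[weak],
                               txB[(weak %% n_transcripts) + 1L],
                               60, 100L, 40L, 1e-3, 40))
  probeset_side <- function(tx, side) {
    extra <- stats::runif(length(tx)) < many_to_many_fraction
    ps_ids <- c(paste0(sub("tx", "ps", tx), "_1"),
                if (any(extra)) paste0(sub("tx", "ps", tx[extra]), "_2"))
    ps_tx <- c(tx, tx[extra])
    probes <- data.frame(
      probeset_id = rep(ps_ids, each = 11L),
      probe_id = paste0(rep(ps_ids, each = 11L),
                        sprintf(".p%02d", sequence(rep(11L,
                                                       length(ps_ids))))))
    # most probes match perfectly; a few have 1 mismatch (still >= 24)
    mism <- ifelse(stats::runif(nrow(probes)) < 0.1, 1L, 0L)
    hits <- blast_row(probes$probe_id,
                      rep(ps_tx, each = 11L),
                      100 * (25L - mism) / 25L, 25L, mism, 1e-10, 50)
    list(probesets = probes, hits = hits,
         links = stats::setNames(ps_tx, ps_ids))
  }
  sideA <- probeset_side(txA, "A")
  sideB <- probeset_side(txB, "B")
  sub_ids <- character(0)
  if (n_subthreshold > 0L) {
    for (side in c("A", "B")) {
      obj <- if (side == "A") sideA else sideB
      tx <- if (side == "A") txA else txB
      host <- sample(tx, n_subthreshold)
      ids <- paste0(sub("tx", "ps", host), "_sub")
      probes <- data.frame(
        probeset_id = rep(ids, each = 11L),
        probe_id = paste0(rep(ids, each = 11L),
                          sprintf(".p%02d", sequence(rep(11L,
                                                         length(ids))))))
      hits <- blast_row(probes$probe_id, rep(host, each = 11L),
                        92, 25L, 2L, 1e-6, 35)  # 23/25 matched: below cut
      obj$probesets <- rbind(obj$probesets, probes)
      obj$hits <- rbind(obj$hits, hits)
      if (side == "A") sideA <- obj else sideB <- obj
      sub_ids <- c(sub_ids, ids)
    }
  }
  # ground truth: each ortholog pair plus its (mapped) probe sets
  rows <- lapply(seq_len(n_transcripts), function(i) {
    ps_A <- sort(names(sideA$links)[sideA$links == txA[i]])
    ps_B <- sort(names(sideB$links)[sideB$links == txB[i]])
    data.frame(key = ps_A[1L],
               species = rep(c("A", "B"), c(length(ps_A), length(ps_B))),
               probeset_id = c(ps_A, ps_B),
               type = if (length(ps_A) == 1L && length(ps_B) == 1L)
                 "unique" else "component")
  })
  truth <- do.call(rbind, rows)
  keys <- sort(unique(truth$key))
  mg <- stats::setNames(sprintf("MG%06d", seq_along(keys)), keys)
  truth <- data.frame(metagene_id = unname(mg[truth$key]),
                      species = truth$species,
                      probeset_id = truth$probeset_id, type = truth$type)
  truth <- truth[order(truth$metagene_id, truth$species,
                       truth$probeset_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(hits_ab = hits_ab, hits_ba = hits_ba,
       probe_hits_A = sideA$hits, probe_hits_B = sideB$hits,
       probesets_A = sideA$probesets, probesets_B = sideB$probesets,
       truth = truth, subthreshold_probesets = sub_ids)
}

.ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
.tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))

#' Simulate a diverged codon sequence pair with an event log
#'
#' Evolves two descendants from a random ancestor of sense codons
#' under a Kimura two-parameter mutation process (transition:
#' transversion rate ratio `kappa` : 2, i.e. a proposed change is a
#' transition with probability `kappa / (kappa + 2)`). Proposed
#' non-synonymous substitutions are accepted with probability `omega`;
#' proposals creating stop codons are rejected. The event log records
#' every accepted substitution's branch, site, codon position, site
#' class (degeneracy of the pre-mutation codon), substitution type and
#' synonymy.
#'
#' @param n_codons Number of codons (default 500).
#' @param t Expected number of proposed substitutions per site summed
#'   over both branches (neutral-equivalent divergence; default 0.2,
#'   rodent scale).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param omega Acceptance probability of non-synonymous changes
#'   (default 1 = neutral).
#' @param seed Integer seed.
#' @param gene_id Identifier carried into the output (default
#'   `"gene1"`).
#' @return List with `gene_id`, `seq_A`, `seq_B`, `ancestor` (character
#'   strings) and `events` (data.frame with columns `branch`, `site`,
#'   `codon_index`, `pos`, `class`, `type`, `synonymous`).
#' @export
simulate_codon_pair <- function(n_codons = 500L, t = 0.2, kappa = 2,
                                omega = 1, seed = 1L,
                                gene_id = "gene1") {
  stopifnot(n_codons >= 1, t >= 0, kappa > 0, omega >= 0)
  set.seed(seed)
  gc_tab <- Biostrings::GENETIC_CODE
  deg <- degeneracy_table()
  sense <- names(gc_tab)[gc_tab != "*"]
  anc <- sample(sense, n_codons, replace = TRUE)
  evolve <- function(codons, branch) {
    n_events <- stats::rpois(1L, 3 * n_codons * t / 2)
    log <- vector("list", n_events)
    if (n_events > 0L) {
      sites <- sample.int(3L * n_codons, n_events, replace = TRUE)
      is_ts <- stats::runif(n_events) < kappa / (kappa + 2)
      u_sel <- stats::runif(n_events)
      tv_pick <- sample.int(2L, n_events, replace = TRUE)
      for (e in seq_len(n_events)) {
        site <- sites[e]
        ci <- (site - 1L) %/% 3L + 1L
        pos <- (site - 1L) %% 3L + 1L
        cod <- codons[ci]
        base <- substr(cod, pos, pos)
        newbase <- if (is_ts[e]) .ts_partner[[base]] else
          .tv_partners[[base]][tv_pick[e]]
        newcod <- cod
        substr(newcod, pos, pos) <- newbase
        if (gc_tab[[newcod]] == "*") next
        syn <- gc_tab[[newcod]] == gc_tab[[cod]]
        if (!syn && u_sel[e] > omega) next
        log[[e]] <- data.frame(branch = branch, site = site,
                               codon_index = ci, pos = pos,
                               class = deg[cod, pos],
                               type = if (is_ts[e]) "transition" else
                                 "transversion",
                               synonymous = syn)
        codons[ci] <- newcod
      }
    }
    log <- log[!vapply(log, is.null, TRUE)]
    list(codons = codons,
         events = if (length(log)) do.call(rbind, log) else
           data.frame(branch = character(0), site = integer(0),
                      codon_index = integer(0), pos = integer(0),
                      class = character(0), type = character(0),
                      synonymous = logical(0)))
  }
  a <- evolve(anc, "A")
  b <- evolve(anc, "B")
  events <- rbind(a$events, b$events)
  rownames(events) <- NULL
  list(gene_id = gene_id,
       seq_A = paste(a$codons, collapse = ""),
       seq_B = paste(b$codons, collapse = ""),
       ancestor = paste(anc, collapse = ""),
       events = events)
}

#' Simulate soma/dendrite intensity transects at a planted D/S ratio
#'
#' Soma pixel samples scatter around `soma_mean`; dendrite samples
#' scatter around `planted_ratio * soma_mean` modulated by a
#' distance-dependent shape normalized so the in-window median equals
#' the planted ratio. Each dendrite carries a multiplicative
#' log-normal deviation with log-sd `noise_sd_log` (so `planted_ratio`
#' is the population geometric mean of per-dendrite ratios), plus
#' per-sample multiplicative noise with log-sd `sample_noise_sd_log`.
#'
#' @param n_cells Number of cells (default 3; the study traced about 3
#'   somas and 9 dendrites per probe and species).
#' @param n_dendrites_per_cell Dendrites traced per cell (default 3).
#' @param planted_ratio True D/S ratio (> 0; default 0.2).
#' @param soma_mean Mean soma pixel intensity (default 1000).
#' @param decay `"flat"` (default) or `"linear"` distance shape.
#' @param noise_sd_log Between-dendrite log-sd (default 0.1).
#' @param sample_noise_sd_log Per-sample log-sd (default 0.02).
#' @param n_soma_samples Soma pixel samples per cell (default 50).
#' @param step Transect sampling step in micrometres (default 0.5).
#' @param max_dist Maximum transect distance (default 40).
#' @param window In-window interval used to normalize the shape
#'   (default `c(5, 40)`, matching the summary window).
#' @param seed Integer seed.
#' @return List with `transects` and `soma` data.frames (layouts of
#'   [read_transects_tsv()] / [read_soma_tsv()]) and
#'   `dendrite_multipliers` (the realized per-dendrite log-normal
#'   deviations, named `cell:dendrite`).
#' @export
simulate_transects <- function(n_cells = 3L, n_dendrites_per_cell = 3L,
                               planted_ratio = 0.2, soma_mean = 1000,
                               decay = c("flat", "linear"),
                               noise_sd_log = 0.1,
                               sample_noise_sd_log = 0.02,
                               n_soma_samples = 50L, step = 0.5,
                               max_dist = 40, window = c(5, 40),
                               seed = 1L) {
  decay <- match.arg(decay)
  stopifnot(planted_ratio > 0, soma_mean > 0, noise_sd_log >= 0,
            sample_noise_sd_log >= 0, step > 0, max_dist > window[1])
  set.seed(seed)
  d <- seq(0, max_dist, by = step)
  shape <- switch(decay,
                  flat = rep(1, length(d)),
                  linear = 1.3 - 0.012 * d)
  inwin <- d >= window[1] & d <= window[2]
  shape <- shape / stats::median(shape[inwin])
  trans <- list(); soma <- list(); mult <- numeric(0)
  for (ci in seq_len(n_cells)) {
    cell <- sprintf("cell%02d", ci)
    s_noise <- if (sample_noise_sd_log > 0)
      exp(stats::rnorm(n_soma_samples, 0, sample_noise_sd_log)) else
      rep(1, n_soma_samples)
    soma[[ci]] <- data.frame(cell_id = cell,
                             intensity = soma_mean * s_noise)
    for (di in seq_len(n_dendrites_per_cell)) {
      dend <- sprintf("dend%02d", di)
      m <- if (noise_sd_log > 0) exp(stats::rnorm(1L, 0, noise_sd_log))
           else 1
      mult[paste0(cell, ":", dend)] <- m
      p_noise <- if (sample_noise_sd_log > 0)
        exp(stats::rnorm(length(d), 0, sample_noise_sd_log)) else
        rep(1, length(d))
      trans[[length(trans) + 1L]] <- data.frame(
        cell_id = cell, dendrite_id = dend, distance_um = d,
        intensity = planted_ratio * soma_mean * m * shape * p_noise)
    }
  }
  list(transects = do.call(rbind, trans), soma = do.call(rbind, soma),
       dendrite_multipliers = mult)
}
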