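# Substitution-rate estimation from pairwise codon alignments.
#
# Site classes follow codon-position degeneracy under the standard
# genetic code: a position is nondegenerate when no nucleotide change
# there is synonymous, fourfold when every change is synonymous, and
# twofold otherwise (three-fold degenerate positions, i.e. Ile, are
# pooled with twofold). Transition (P) and transversion (Q) proportions
# per class feed Kimura two-parameter distance components, combined
# into Ka and Ks with the Li (1993) / Pamilo-Bianchi estimator:
#   Ks = (L2*A2 + L4*A4) / (L2 + L4) + B4
#   Ka = A0 + (L0*B0 + L2*B2) / (L0 + L2)

.molevol_cache <- new.env(parent = emptyenv())

degeneracy_table <- function() {
  if (!is.null(.molevol_cache$deg)) return(.molevol_cache$deg)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)
  bases <- c("A", "C", "G", "T")
  deg <- matrix(NA_character_, length(codons), 3L,
                dimnames = list(codons, c("1", "2", "3")))
  for (cod in codons) {
    aa <- gc_tab[[cod]]
    if (aa == "*") next  # stop codons are skipped entirely
    for (pos in 1:3) {
      n_syn <- 0L
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (gc_tab[[alt]] == aa) n_syn <- n_syn + 1L
      }
      deg[cod, pos] <- if (n_syn == 0L) "nondegenerate"
                       else if (n_syn == 3L) "fourfold"
                       else "twofold"
    }
  }
  .molevol_cache$deg <- deg
  deg
}

#' Classify a codon position by fold degeneracy
#'
#' Under the standard genetic code, a codon position is
#' `"nondegenerate"` if no nucleotide substitution there preserves the
#' amino acid, `"fourfold"` if all three do, and `"twofold"` otherwise
#' (three-fold degenerate positions are pooled with twofold).
#'
#' @param codon Character vector of 3-mers over A/C/G/T.
#' @param position Integer vector in 1..3 (recycled).
#' @return Character vector of classes; `NA` for stop codons or codons
#'   containing ambiguous bases.
#' @export
classify_codon_degeneracy <- function(codon, position) {
  codon <- toupper(codon)
  stopifnot(all(position %in% 1:3))
  n <- max(length(codon), length(position))
  codon <- rep_len(codon, n); position <- rep_len(position, n)
  deg <- degeneracy_table()
  out <- rep(NA_character_, n)
  ok <- codon %in% rownames(deg)
  out[ok] <- deg[cbind(codon[ok], as.character(position[ok]))]
  out
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Count per-class sites and substitution proportions for a codon pair
#'
#' Splits an aligned coding sequence pair into codons, drops codon
#' columns containing gaps, stop codons or ambiguous bases (logged in
#' the output), and tallies nondegenerate / twofold / fourfold site
#' counts and the transition and transversion proportions within each
#' class. Site counts `L_i` are the mean of the two sequences' counts;
#' a differing site contributes weight 1/2 to the class it has in each
#' sequence.
#'
#' @param seq_A,seq_B Aligned coding sequences of equal length
#'   (alphabet A/C/G/T/N/-); length need not be a multiple of three
#'   after gap removal, but incomplete trailing codons are dropped.
#' @return List with `L`, `ts`, `tv`, `P`, `Q` (each a named vector
#'   over classes `nondegenerate`, `twofold`, `fourfold`), `n_codons`
#'   (compared codons) and `n_skipped` (codon columns dropped).
#' @export
count_pairwise_substitutions <- function(seq_A, seq_B) {
  seq_A <- toupper(seq_A); seq_B <- toupper(seq_B)
  if (nchar(seq_A) != nchar(seq_B))
    stop("aligned sequences have unequal lengths")
  n_cod <- nchar(seq_A) %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  codA <- substring(seq_A, starts, starts + 2L)
  codB <- substring(seq_B, starts, starts + 2L)
  deg <- degeneracy_table()
  sense <- rownames(deg)[!is.na(deg[, 1L])]
  keep <- codA %in% sense & codB %in% sense
  n_skipped <- sum(!keep) + (nchar(seq_A) %% 3L > 0L)
  codA <- codA[keep]; codB <- codB[keep]
  classes <- c("nondegenerate", "twofold", "fourfold")
  L <- ts <- tv <- stats::setNames(numeric(3L), classes)
  if (length(codA) > 0L) {
    for (pos in 1:3) {
      clsA <- deg[cbind(codA, as.character(pos))]
      clsB <- deg[cbind(codB, as.character(pos))]
      tA <- table(factor(clsA, classes))
      tB <- table(factor(clsB, classes))
      L <- L + 0.5 * (as.numeric(tA) + as.numeric(tB))
      a <- substr(codA, pos, pos); b <- substr(codB, pos, pos)
      diff <- a != b
      if (!any(diff)) next
      tsite <- is_transition(a[diff], b[diff])
      for (w in list(clsA[diff], clsB[diff])) {
        ts <- ts + 0.5 * as.numeric(table(factor(w[tsite], classes)))
        tv <- tv + 0.5 * as.numeric(table(factor(w[!tsite], classes)))
      }
    }
    names(ts) <- names(tv) <- classes
  }
  if (any(L == 0 & (ts + tv) > 0))
    stop("inconsistent state: differences observed in a class with zero sites")
  P <- ifelse(L > 0, ts / L, 0)
  Q <- ifelse(L > 0, tv / L, 0)
  names(P) <- names(Q) <- classes
  list(L = L, ts = ts, tv = tv, P = P, Q = Q,
       n_codons = length(codA), n_skipped = n_skipped)
}

#' Kimura two-parameter distance components
#'
#' For transition proportion P and transversion proportion Q:
#' `A = 1/2 log(1 / (1 - 2P - Q)) - 1/4 log(1 / (1 - 2Q))` (transition
#' component), `B = 1/2 log(1 / (1 - 2Q))` (transversion component) and
#' `K = A + B`. Outside the validity domain (`1 - 2P - Q <= 0` or
#' `1 - 2Q <= 0`) the estimate is saturated and returned as `NA` with
#' `saturated = TRUE`.
#'
#' @param P,Q Transition and transversion proportions (vectors of equal
#'   length, each in \[0, 1\]).
#' @return List with numeric vectors `A`, `B`, `K` and logical
#'   `saturated`.
#' @export
k2p_components <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  if (any(P < 0 | Q < 0 | P > 1 | Q > 1)) stop("P, Q must lie in [0, 1]")
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  sat <- w1 <= 0 | w2 <= 0
  A <- B <- rep(NA_real_, length(P))
  A[!sat] <- 0.5 * log(1 / w1[!sat]) - 0.25 * log(1 / w2[!sat])
  B[!sat] <- 0.5 * log(1 / w2[!sat])
  list(A = A, B = B, K = A + B, saturated = sat)
}

#' Li (1993) / Pamilo-Bianchi Ka and Ks from per-class counts
#'
#' Combines per-class Kimura components into the synonymous rate
#' `Ks = (L2*A2 + L4*A4) / (L2 + L4) + B4` and the non-synonymous rate
#' `Ka = A0 + (L0*B0 + L2*B2) / (L0 + L2)` (transitions at twofold
#' sites count as synonymous, transversions as non-synonymous). A gene
#' whose required components are saturated is flagged degenerate.
#'
#' @param counts List as returned by
#'   [count_pairwise_substitutions()] (`L`, `P`, `Q` over the three
#'   classes).
#' @return List with `Ka`, `Ks`, `KaKs` (NA when undefined),
#'   per-class `A`, `B`, and `degenerate` flag.
#' @export
li_ka_ks <- function(counts) {
  L <- counts$L; P <- counts$P; Q <- counts$Q
  comp <- k2p_components(P, Q)
  A <- comp$A; B <- comp$B
  # classes with no sites contribute nothing
  A[L == 0] <- 0; B[L == 0] <- 0
  sat <- comp$saturated & L > 0
  degenerate <- any(sat) || (L[2] + L[3]) == 0 || (L[1] + L[2]) == 0
  if (degenerate)
    return(list(Ka = NA_real_, Ks = NA_real_, KaKs = NA_real_,
                A = A, B = B, degenerate = TRUE))
  Ks <- (L[2] * A[2] + L[3] * A[3]) / (L[2] + L[3]) + B[3]
  Ka <- A[1] + (L[1] * B[1] + L[2] * B[2]) / (L[1] + L[2])
  KaKs <- if (Ks > 0) Ka / Ks else if (Ka == 0) NA_real_ else NA_real_
  list(Ka = unname(Ka), Ks = unname(Ks), KaKs = unname(KaKs),
       A = A, B = B, degenerate = FALSE)
}

#' Kimura two-parameter distance for a non-coding alignment
#'
#' Computed over non-gap, unambiguous aligned columns only.
#'
#' @param seq_A,seq_B Aligned sequences of equal length.
#' @return List with `K`, `P`, `Q`, `n_sites`, `saturated`.
#' @export
utr_k2p <- function(seq_A, seq_B) {
  seq_A <- toupper(seq_A); seq_B <- toupper(seq_B)
  if (nchar(seq_A) != nchar(seq_B))
    stop("aligned sequences have unequal lengths")
  a <- strsplit(seq_A, "")[[1]]
  b <- strsplit(seq_B, "")[[1]]
  bases <- c("A", "C", "G", "T")
  keep <- a %in% bases & b %in% bases
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L)
    return(list(K = NA_real_, P = NA_real_, Q = NA_real_, n_sites = 0L,
                saturated = TRUE))
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / n
  Q <- sum(diff & !is_transition(a, b)) / n
  comp <- k2p_components(P, Q)
  list(K = comp$K, P = P, Q = Q, n_sites = n, saturated = comp$saturated)
}

#' Per-gene rate table and summary over a set of codon alignments
#'
#' Applies the minimum aligned-length filter (at least `min_aa`
#' compared amino acids) and the non-degenerate-estimate filter, then
#' reports per-gene site counts, substitution proportions, Ka, Ks,
#' Ka/Ks and optional UTR K2P distances, plus across-gene means and
#' standard errors for Ks, Ka and Ka/Ks.
#'
#' @param alignments List of alignments; each element is a list with
#'   `gene_id`, `seq_A`, `seq_B` and optionally `utr5_A`, `utr5_B`,
#'   `utr3_A`, `utr3_B`.
#' @param min_aa Minimum compared amino-acid length (default 100).
#' @return List with `table` (per-gene data.frame over retained genes),
#'   `summary` (data.frame of mean and standard error for Ks, Ka,
#'   KaKs), `n_excluded_length`, `n_excluded_degenerate`.
#' @export
compute_rate_table <- function(alignments, min_aa = 100L) {
  rows <- list(); n_len <- 0L; n_deg <- 0L
  for (aln in alignments) {
    counts <- count_pairwise_substitutions(aln$seq_A, aln$seq_B)
    if (counts$n_codons < min_aa) { n_len <- n_len + 1L; next }
    est <- li_ka_ks(counts)
    if (est$degenerate) { n_deg <- n_deg + 1L; next }
    k5 <- if (!is.null(aln$utr5_A)) utr_k2p(aln$utr5_A, aln$utr5_B)$K
          else NA_real_
    k3 <- if (!is.null(aln$utr3_A)) utr_k2p(aln$utr3_A, aln$utr3_B)$K
          else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = if (is.null(aln$gene_id)) NA_character_ else aln$gene_id,
      aa_length = counts$n_codons,
      L0 = counts$L[1], L2 = counts$L[2], L4 = counts$L[3],
      P0 = counts$P[1], P2 = counts$P[2], P4 = counts$P[3],
      Q0 = counts$Q[1], Q2 = counts$Q[2], Q4 = counts$Q[3],
      A0 = est$A[1], A2 = est$A[2], A4 = est$A[3],
      B0 = est$B[1], B2 = est$B[2], B4 = est$B[3],
      Ka = est$Ka, Ks = est$Ks, KaKs = est$KaKs,
      K_utr5 = k5, K_utr3 = k3)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0))
  rownames(tab) <- NULL
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  summary <- if (nrow(tab)) data.frame(
    statistic = c("Ks", "Ka", "KaKs"),
    mean = c(mean(tab$Ks), mean(tab$Ka), mean(tab$KaKs, na.rm = TRUE)),
    stderr = c(se(tab$Ks), se(tab$Ka), se(tab$KaKs))) else
    data.frame(statistic = character(0), mean = numeric(0),
               stderr = numeric(0))
  list(table = tab, summary = summary,
       n_excluded_length = n_len, n_excluded_degenerate = n_deg)
}

#' Kruskal-Wallis comparison of rates between gene groups
#'
#' Non-parametric rank test (with tie correction, chi-square reference)
#' for whether substitution rates differ between groups, e.g. between
#' expression-divergent and non-divergent genes.
#'
#' @param values Numeric vector of rate values.
#' @param groups Grouping vector of the same length (>= 2 groups, each
#'   with >= 2 values).
#' @return List with `H` (statistic), `df`, `p_value`.
#' @export
kruskal_wallis_rates <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need >= 2 groups")
  if (any(table(droplevels(groups)) < 2L))
    stop("every group needs >= 2 values")
  ht <- stats::kruskal.test(values, groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
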