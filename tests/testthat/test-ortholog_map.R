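hit <- function(q, s, evalue = 1e-20, bitscore = 500, len = 500L,
                mism = 0L) {
  data.frame(qseqid = q, sseqid = s, pident = 99, length = len,
             mismatch = mism, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue,
             bitscore = bitscore)
}

test_that("a single mutual best pair is returned and non-reciprocal pairs are excluded", {
  ab <- hit("A1", "B1")
  ba <- hit("B1", "A1")
  expect_equal(reciprocal_best_hits(ab, ba),
               data.frame(id_A = "A1", id_B = "B1"))

  # B1's best hit is A2, so A1-B1 is not reciprocal
  ba2 <- rbind(hit("B1", "A2", evalue = 1e-30),
               hit("B1", "A1", evalue = 1e-10))
  expect_equal(nrow(reciprocal_best_hits(ab, ba2)), 0L)

  # empty input is not an error
  empty <- ab[0L, ]
  expect_equal(nrow(reciprocal_best_hits(empty, empty)), 0L)
})

test_that("the e-value threshold removes weak hits before best-hit ranking", {
  ab <- rbind(hit("A1", "B1", evalue = 1e-3),
              hit("A1", "B2", evalue = 1e-8))
  ba <- rbind(hit("B2", "A1", evalue = 1e-8),
              hit("B1", "A1", evalue = 1e-3))
  got <- reciprocal_best_hits(ab, ba, evalue_max = 1e-5)
  expect_equal(got, data.frame(id_A = "A1", id_B = "B2"))
})

test_that("random tied hit tables match the brute-force reciprocal-best-hit oracle", {
  set.seed(101)
  for (rep in 1:30) {
    qa <- sprintf("A%02d", 1:20); qb <- sprintf("B%02d", 1:20)
    ab <- random_hit_table(qa, qb, 60L)
    ba <- random_hit_table(qb, qa, 60L)
    got <- reciprocal_best_hits(ab, ba, 1e-5)
    want <- oracle_rbh(ab, ba, 1e-5)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("reciprocal best hits are symmetric under species swap", {
  set.seed(202)
  for (rep in 1:10) {
    qa <- sprintf("A%02d", 1:15); qb <- sprintf("B%02d", 1:15)
    ab <- random_hit_table(qa, qb, 50L)
    ba <- random_hit_table(qb, qa, 50L)
    fwd <- reciprocal_best_hits(ab, ba, 1e-5)
    swp <- reciprocal_best_hits(ba, ab, 1e-5)
    expect_setequal(paste(fwd$id_A, fwd$id_B),
                    paste(swp$id_B, swp$id_A))
  }
})

test_that("probe-set mapping enforces the 24/25 per-probe and 9/11 quorum rules", {
  probes <- sprintf("ps1.p%02d", 1:11)
  probesets <- data.frame(probeset_id = "ps1", probe_id = probes)

  # 10 probes call T1 at 25/25: clear quorum
  hits <- hit(probes[1:10], "T1", len = 25L, mism = 0L)
  expect_equal(map_probeset_to_transcript(hits, probesets),
               c(ps1 = "T1"))

  # 8 call T1, 3 call T2: quorum of 9 fails, probe set unmapped
  hits2 <- rbind(hit(probes[1:8], "T1", len = 25L),
                 hit(probes[9:11], "T2", len = 25L))
  expect_equal(length(map_probeset_to_transcript(hits2, probesets)), 0L)

  # a 23/25 probe contributes no call: 9 clean + 2 sub-threshold fails
  hits3 <- rbind(hit(probes[1:8], "T1", len = 25L, mism = 0L),
                 hit(probes[9:11], "T1", len = 25L, mism = 2L))
  expect_equal(length(map_probeset_to_transcript(hits3, probesets)), 0L)
  # but 9 clean + 2 sub-threshold on the same transcript still passes
  # once one of them is 24/25
  hits4 <- rbind(hit(probes[1:8], "T1", len = 25L, mism = 0L),
                 hit(probes[9], "T1", len = 25L, mism = 1L),
                 hit(probes[10:11], "T1", len = 25L, mism = 2L))
  expect_equal(map_probeset_to_transcript(hits4, probesets),
               c(ps1 = "T1"))
})

test_that("hits from probes outside any probe set are ignored with a warning", {
  probesets <- data.frame(probeset_id = "ps1",
                          probe_id = sprintf("ps1.p%02d", 1:11))
  hits <- rbind(hit(sprintf("ps1.p%02d", 1:9), "T1", len = 25L),
                hit("ghost.p01", "T9", len = 25L))
  expect_warning(got <- map_probeset_to_transcript(hits, probesets),
                 "not in any probe set")
  expect_equal(got, c(ps1 = "T1"))
})

test_that("metagene construction passes unique matches through and closes chains", {
  # single 1:1 match
  m <- build_metagene_map(data.frame(id_A = "t1", id_B = "u1"),
                          c(a1 = "t1"), c(b1 = "u1"))
  expect_equal(nrow(m), 2L)
  expect_equal(unique(m$type), "unique")
  expect_setequal(m$probeset_id, c("a1", "b1"))

  # chain a1-t1-u1-{b1,b2} with a2 also on t1: one metagene
  m2 <- build_metagene_map(data.frame(id_A = "t1", id_B = "u1"),
                           c(a1 = "t1", a2 = "t1"),
                           c(b1 = "u1", b2 = "u1"))
  expect_equal(length(unique(m2$metagene_id)), 1L)
  expect_setequal(m2$probeset_id, c("a1", "a2", "b1", "b2"))
  expect_equal(unique(m2$type), "component")
})

test_that("single-species components are dropped with a logged count", {
  expect_message(
    m <- build_metagene_map(data.frame(id_A = "t1", id_B = "u1"),
                            c(a1 = "t1", a9 = "t9"), c(b1 = "u1")),
    "dropped 1 single-species component")
  expect_setequal(m$probeset_id, c("a1", "b1"))
  expect_equal(attr(m, "n_dropped_single_species"), 1L)
})

test_that("random bipartite instances match the union-find partition oracle", {
  set.seed(303)
  for (rep in 1:30) {
    n <- sample(20:80, 1L)
    tA <- sprintf("t%03d", 1:n); tB <- sprintf("u%03d", 1:n)
    pairs <- data.frame(id_A = tA, id_B = tB)
    # random probe-set links, sometimes several per transcript
    links_A <- stats::setNames(sample(tA, round(1.3 * n), replace = TRUE),
                               sprintf("a%03d", seq_len(round(1.3 * n))))
    links_B <- stats::setNames(sample(tB, round(1.3 * n), replace = TRUE),
                               sprintf("b%03d", seq_len(round(1.3 * n))))
    got <- build_metagene_map(pairs, links_A, links_B)

    edges <- rbind(cbind(paste0("A.tx:", pairs$id_A),
                         paste0("B.tx:", pairs$id_B)),
                   cbind(paste0("A.ps:", names(links_A)),
                         paste0("A.tx:", unname(links_A))),
                   cbind(paste0("B.ps:", names(links_B)),
                         paste0("B.tx:", unname(links_B))))
    comps <- oracle_components(edges)
    sigs <- vapply(comps, function(mem) {
      a <- sort(sub("^A\\.ps:", "", mem[grepl("^A\\.ps:", mem)]))
      b <- sort(sub("^B\\.ps:", "", mem[grepl("^B\\.ps:", mem)]))
      if (length(a) == 0L || length(b) == 0L) return(NA_character_)
      paste(paste(a, collapse = ","), paste(b, collapse = ","), sep = "|")
    }, "")
    expect_setequal(partition_signature(got), sigs[!is.na(sigs)])

    # true partition: each probe set in exactly one metagene
    df <- as.data.frame(got)
    expect_false(anyDuplicated(df[df$species == "A", "probeset_id"]) > 0)
    expect_false(anyDuplicated(df[df$species == "B", "probeset_id"]) > 0)
  }
})

test_that("metagene aggregation takes per-array medians and is exact for singletons", {
  map <- build_metagene_map(data.frame(id_A = "t1", id_B = "u1"),
                            c(a1 = "t1", a2 = "t1", a3 = "t1"),
                            c(b1 = "u1"))
  expr_A <- matrix(c(1, 3, 10, 4, 6, 2), 3L, 2L,
                   dimnames = list(c("a1", "a2", "a3"), c("r1", "r2")))
  agg <- aggregate_metagene_expression(expr_A, map, "A")
  expect_equal(unname(agg[1L, ]), c(3, 4))

  # even-count median: mean of the two central values
  expr_A2 <- expr_A[1:2, , drop = FALSE]
  map2 <- build_metagene_map(data.frame(id_A = "t1", id_B = "u1"),
                             c(a1 = "t1", a2 = "t1"), c(b1 = "u1"))
  agg2 <- aggregate_metagene_expression(expr_A2, map2, "A")
  expect_equal(unname(agg2[1L, ]), c(2, 5))

  # singleton metagene: identity
  expr_B <- matrix(c(7, 8), 1L, 2L,
                   dimnames = list("b1", c("r1", "r2")))
  aggB <- aggregate_metagene_expression(expr_B, map, "B")
  expect_equal(unname(aggB[1L, ]), c(7, 8))

  # missing member row is a named error
  expect_error(aggregate_metagene_expression(expr_A[1:2, ], map, "A"),
               "a3")
})
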