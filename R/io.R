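#' Read a tab-delimited expression matrix
#'
#' Reads a TSV file whose first column holds row identifiers (probes,
#' probe sets or metagenes) and whose remaining columns hold numeric
#' log-scale intensities, one column per replicate array.
#'
#' Missing or non-numeric cells are rejected rather than imputed: the
#' downstream statistics assume a complete matrix.
#'
#' @param path Path to a TSV file with a header line of array labels.
#' @return Numeric matrix with row ids as rownames and array labels as
#'   colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression TSV needs a row-id column plus >= 1 array column: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- is.na(storage) | body == ""
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop("missing or non-numeric cell in ", path, " at row id '",
         ids[i[1L]], "', column '", colnames(body)[i[2L]], "'")
  }
  dimnames(storage) <- list(ids, colnames(df)[-1L])
  storage
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; the first column is named `id`.
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
.blast_numeric <- c("pident", "length", "mismatch", "gapopen", "qstart",
                    "qend", "sstart", "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the standard 12-column blastn tabular dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Lines starting with `#` are skipped.
#'
#' @param path Path to the tabular file.
#' @return data.frame with the 12 outfmt-6 columns, typed.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12L), .blast_cols))
    for (cc in .blast_numeric) out[[cc]] <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop("line ", lineno[bad], " of ", path, " has ", nf[bad],
         " columns (expected 12)")
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .blast_cols
  for (cc in .blast_numeric) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("line ", lineno[bad], " of ", path,
           ": non-numeric value in column '", cc, "'")
    }
    out[[cc]] <- v
  }
  validate_blast_hits(out, path)
  out
}

validate_blast_hits <- function(hits, label = "hit table") {
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$length < 1L))
    stop(label, ": alignment_length must be >= 1")
  if (any(hits$evalue < 0))
    stop(label, ": evalue must be >= 0")
  if (any(hits$pident < 0 | hits$pident > 100))
    stop(label, ": pct_identity must lie in [0, 100]")
  invisible(hits)
}

#' Write a hit table in BLAST outfmt-6 dialect
#' @param hits data.frame with the 12 outfmt-6 columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(.blast_cols %in% names(hits)))
  utils::write.table(hits[, .blast_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-record aligned FASTA file as a pairwise alignment
#'
#' The file must hold exactly two records of equal aligned length over
#' the alphabet `A C G T N -`. Header metadata follows a `key=value`
#' convention after the record id, e.g.
#' `>geneX_rat species=A region=cds`.
#'
#' @param path Path to an aligned FASTA file.
#' @return List with `ids`, `seq_A`, `seq_B` (uppercased character
#'   strings) and `meta` (list of named character vectors parsed from
#'   the headers).
#' @export
read_fasta_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 2L)
    stop(path, ": expected exactly 2 records, found ", length(set))
  seqs <- toupper(as.character(set))
  if (nchar(seqs[1L]) != nchar(seqs[2L]))
    stop(path, ": records have unequal aligned lengths (",
         nchar(seqs[1L]), " vs ", nchar(seqs[2L]), ")")
  bad <- gsub("[ACGTN-]", "", seqs)
  if (any(nzchar(bad)))
    stop(path, ": invalid characters in alignment: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = " "))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  meta <- lapply(headers, function(h) {
    toks <- strsplit(h, "\\s+")[[1]][-1]
    toks <- toks[grepl("=", toks, fixed = TRUE)]
    if (length(toks) == 0L) return(character(0))
    kv <- strsplit(toks, "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  })
  names(meta) <- ids
  list(ids = ids, seq_A = unname(seqs[1L]), seq_B = unname(seqs[2L]),
       meta = meta)
}

#' Write a pairwise alignment as a two-record FASTA file
#' @param aln List as returned by [read_fasta_alignment()] (fields
#'   `ids`, `seq_A`, `seq_B`; optional `meta`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  hdr <- aln$ids
  if (!is.null(aln$meta)) {
    hdr <- vapply(seq_along(aln$ids), function(i) {
      m <- aln$meta[[i]]
      if (length(m) == 0L) return(aln$ids[i])
      paste(aln$ids[i], paste(names(m), m, sep = "=", collapse = " "))
    }, "")
  }
  writeLines(c(paste0(">", hdr[1L]), aln$seq_A,
               paste0(">", hdr[2L]), aln$seq_B), path)
  invisible(path)
}

#' Read dendrite transect samples from TSV
#'
#' Expected columns: `cell_id`, `dendrite_id`, `distance_um`,
#' `intensity`. Distances must be non-negative and intensities
#' non-negative (background subtraction is assumed done upstream; pass
#' `background` to subtract a constant offset, clamping at zero).
#'
#' @param path Path to the transect TSV.
#' @param background Constant background offset to subtract (default 0).
#' @return data.frame of transect samples.
#' @export
read_transects_tsv <- function(path, background = 0) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("cell_id", "dendrite_id", "distance_um", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$distance_um)) || any(df$distance_um < 0))
    stop(path, ": distances must be finite and non-negative")
  df$intensity <- pmax(df$intensity - background, 0)
  if (any(!is.finite(df$intensity)))
    stop(path, ": intensities must be finite")
  df
}

#' Read soma reference pixel samples from TSV
#'
#' Expected columns: `cell_id`, `intensity`.
#'
#' @inheritParams read_transects_tsv
#' @return data.frame of soma pixel samples.
#' @export
read_soma_tsv <- function(path, background = 0) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("cell_id", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df$intensity <- pmax(df$intensity - background, 0)
  if (nrow(df) == 0L) stop(path, ": soma sample table is empty")
  df
}
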