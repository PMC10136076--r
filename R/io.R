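#' Read a differential-expression table
#'
#' Parses a tab-separated table with header columns `gene_id`, `log2fc`,
#' `qvalue`. `log2fc` is the log2 fold change fiber/epithelial; `qvalue` the
#' multiple-testing-adjusted p-value.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `gene_id` (character), `log2fc`
#'   (numeric), `qvalue` (numeric), one row per input row, order preserved.
#' @export
read_de_table <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "log2fc", "qvalue")
  .check(all(need %in% names(df)),
         "DE table must have header columns gene_id, log2fc, qvalue: ", path)
  df <- df[, need, drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      qvalue = numeric(), stringsAsFactors = FALSE))
  }
  for (col in c("log2fc", "qvalue")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    # header is line 1, so data row i is file line i + 1
    .check(length(bad) == 0L, "non-numeric ", col, " at line ", bad[1] + 1L,
           " of ", path)
    df[[col]] <- v
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  .check(length(dup) == 0L, "duplicate gene_id in DE table: ", dup[1])
  .check(all(is.finite(df$log2fc)), "log2fc must be finite")
  .check(all(df$qvalue >= 0 & df$qvalue <= 1), "qvalue must lie in [0, 1]")
  df
}

#' Write a differential-expression table
#'
#' @param de A data.frame as returned by [read_de_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(de[, c("gene_id", "log2fc", "qvalue")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read differential ATAC-seq peaks (BED6+2)
#'
#' The dialect is BED6 plus two extra columns: chrom, start, end, peak_id,
#' score (ignored), strand, log2fc (fiber/epithelial accessibility), qvalue.
#' Coordinates are 0-based half-open.
#'
#' @param path Path to a BED6+2 file (no header).
#' @return A data.frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `score`, `strand`, `log2fc`, `qvalue`.
#' @export
read_diff_peaks <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      peak_id = character(), score = numeric(),
                      strand = character(), log2fc = numeric(),
                      qvalue = numeric(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  .check(all(nf == 8L), "expected 8 tab-separated fields at line ",
         which(nf != 8L)[1], " of ", path)
  m <- do.call(rbind, parts)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v))
    .check(length(bad) == 0L, "non-numeric ", name, " at line ", bad[1],
           " of ", path)
    v
  }
  df <- data.frame(chrom = m[, 1], start = as.integer(num(2, "start")),
                   end = as.integer(num(3, "end")), peak_id = m[, 4],
                   score = num(5, "score"), strand = m[, 6],
                   log2fc = num(7, "log2fc"), qvalue = num(8, "qvalue"),
                   stringsAsFactors = FALSE)
  bad <- which(!(df$start >= 0L & df$start < df$end))
  .check(length(bad) == 0L,
         "invalid interval (need 0 <= start < end) at line ", bad[1],
         " of ", path)
  .check(all(df$qvalue >= 0 & df$qvalue <= 1), "qvalue must lie in [0, 1]")
  .check(all(df$strand %in% c("+", "-", ".")), "strand must be +, - or .")
  df
}

#' Write differential ATAC-seq peaks (BED6+2)
#'
#' Inverse of [read_diff_peaks()]; a write/read/write round trip is
#' byte-identical.
#'
#' @param peaks A data.frame as returned by [read_diff_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_peaks <- function(peaks, path) {
  lines <- paste(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                 peaks$score, peaks$strand, peaks$log2fc, peaks$qvalue,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read TSS annotations from BED6
#'
#' BED intervals are 0-based half-open; the TSS of a `+`-strand gene is
#' `start` and of a `-`-strand gene is `end - 1` (the last covered base).
#' Strand is required because promoter windows are strand-aware.
#'
#' @param path Path to a BED6 file (no header); column 4 is the gene_id.
#' @return A data.frame with columns `gene_id`, `chrom`, `pos` (0-based TSS
#'   coordinate), `strand`.
#' @export
read_tss_bed <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  .check(all(nf >= 6L), "expected >= 6 BED fields at line ",
         which(nf < 6L)[1], " of ", path)
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  strand <- m[, 6]
  bad <- which(!strand %in% c("+", "-"))
  .check(length(bad) == 0L,
         "strand must be + or - (promoter windows are strand-aware); line ",
         bad[1], " of ", path)
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  .check(all(!is.na(start) & !is.na(end) & start >= 0L & start < end),
         "invalid BED interval in ", path)
  df <- data.frame(gene_id = m[, 4], chrom = m[, 1],
                   pos = ifelse(strand == "+", start, end - 1L),
                   strand = strand, stringsAsFactors = FALSE)
  dup <- df$gene_id[duplicated(df$gene_id)]
  .check(length(dup) == 0L, "duplicate gene_id in TSS BED: ", dup[1])
  df
}

#' Write TSS annotations as BED6
#'
#' Each TSS is written as a 1-bp interval so that reading it back recovers the
#' same 0-based position on either strand.
#'
#' @param tss A data.frame as returned by [read_tss_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  lines <- paste(tss$chrom, tss$pos, tss$pos + 1L, tss$gene_id, 0L,
                 tss$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the JASPAR 2016+ text format: a `>ID NAME` header line followed by
#' four rows of counts for A, C, G, T, optionally wrapped as `A [ 1 2 3 ]`.
#' Multiple concatenated records are supported.
#'
#' @param path Path to a JASPAR-format motif file.
#' @return A list of PFMs; each element is a list with `motif_id`, `tf_name`
#'   and `counts` (a 4 x W numeric matrix with rownames A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  .check(length(hdr) > 0L, "no JASPAR records (no '>' header) in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    block <- lines[hdr[i]:(bounds[i + 1L] - 1L)]
    head_fields <- strsplit(sub("^>", "", block[1]), "[ \t]+")[[1]]
    motif_id <- head_fields[1]
    tf_name <- if (length(head_fields) >= 2L) head_fields[2] else motif_id
    .check(length(block) == 5L, "motif ", motif_id,
           ": expected 4 count rows, got ", length(block) - 1L)
    rows <- lapply(block[2:5], function(x) {
      x <- gsub("^[ACGTacgt]\\s*", "", x)
      x <- gsub("\\[|\\]", " ", x)
      as.numeric(strsplit(trimws(x), "[ \t]+")[[1]])
    })
    w <- lengths(rows)
    .check(length(unique(w)) == 1L,
           "motif ", motif_id, ": count rows have unequal widths")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    .check(!anyNA(counts) && all(counts >= 0),
           "motif ", motif_id, ": counts must be non-negative numbers")
    .check(ncol(counts) >= 1L && all(colSums(counts) > 0),
           "motif ", motif_id, ": every column sum must be > 0")
    out[[i]] <- list(motif_id = motif_id, tf_name = tf_name, counts = counts)
  }
  names(out) <- vapply(out, `[[`, "", "motif_id")
  out
}

#' Write position frequency matrices in JASPAR text format
#'
#' @param pfms A list of PFMs as returned by [read_jaspar_pfm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$motif_id, " ", p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, " [ ", paste(p$counts[b, ], collapse = " "), " ]"),
                 con)
    }
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields set_id, description,
#' then member gene ids. Duplicate members within a set are removed with a
#' warning.
#'
#' @param path Path to a GMT file.
#' @return A named list of gene sets; each element is a list with `set_id`,
#'   `description` and `members` (character vector, unique).
#' @export
read_gmt <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    .check(length(f) >= 3L, "GMT line ", lineno[i],
           ": expected >= 3 tab-separated fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT set ", f[1], ": duplicate members removed", call. = FALSE)
      members <- unique(members)
    }
    out[[i]] <- list(set_id = f[1], description = f[2], members = members)
  }
  names(out) <- vapply(out, `[[`, "", "set_id")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of gene sets as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog map, enforcing one-to-one pairs
#'
#' Pairs in which either gene id appears more than once are dropped (with a
#' message giving the count), so the retained pairs form a one-to-one
#' correspondence between the two species.
#'
#' @param path Path to a headerless two-column TSV (gene_a, gene_b).
#' @return A data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_map <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  .check(all(nf == 2L), "ortholog map line ", lineno[nf != 2L][1],
         ": expected exactly 2 tab-separated fields")
  m <- do.call(rbind, parts)
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
  amb <- df$gene_a %in% df$gene_a[duplicated(df$gene_a)] |
    df$gene_b %in% df$gene_b[duplicated(df$gene_b)]
  if (any(amb)) {
    message(sum(amb), " ambiguous (non one-to-one) ortholog pairs dropped")
    df <- df[!amb, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write an ortholog map
#'
#' @param orthologs A data.frame with columns `gene_a`, `gene_b`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(orthologs, path) {
  writeLines(paste(orthologs$gene_a, orthologs$gene_b, sep = "\t"), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' Soft-masked (lowercase) bases are uppercased; `N` bases are kept and score
#' `-Inf` at any motif placement covering them.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A named character vector, one element per sequence; names are the
#'   first word of each FASTA header.
#' @export
read_genome_fasta <- function(path) {
  .check(file.exists(path), "file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]+"), `[`, "", 1)
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract forward-strand sequences for genomic intervals
#'
#' Sequences are always returned on the forward strand and uppercased,
#' regardless of any strand attribute of the interval: downstream motif
#' scanning examines both strands, so reverse-complementing here would be
#' redundant.
#'
#' @param genome A named character vector (see [read_genome_fasta()]) or a
#'   path to a FASTA file.
#' @param intervals A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A character vector of sequences, one per interval, named by
#'   `intervals$peak_id` when present.
#' @export
extract_sequences <- function(genome, intervals) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  n <- nrow(intervals)
  out <- character(n)
  lens <- vapply(genome, nchar, 0L)
  for (i in seq_len(n)) {
    chrom <- intervals$chrom[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    .check(chrom %in% names(genome), "unknown chromosome: ", chrom)
    .check(s >= 0 && s < e, "invalid interval ", chrom, ":", s, "-", e)
    .check(e <= lens[[chrom]], "interval beyond chromosome end: ",
           chrom, ":", s, "-", e, " (length ", lens[[chrom]], ")")
    out[i] <- toupper(substr(genome[[chrom]], s + 1L, e))
  }
  if (!is.null(intervals$peak_id)) names(out) <- intervals$peak_id
  out
}
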