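#' Read a FASTA file of scaffolds
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any residual symbol
#' outside `{A,C,G,T,N}` is mapped to `N` (a warning reports how many bases
#' were replaced). Scaffolds shorter than `min_len` are dropped, mirroring
#' the assembly-level filter applied to short scaffolds before analysis.
#'
#' @param path FASTA file.
#' @param min_len drop scaffolds shorter than this many bp (0 keeps all).
#' @return named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, min_len = 0L) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header: ", ids[duplicated(ids)][1L])
  }
  s <- toupper(as.character(x))
  s <- chartr("U", "T", s)
  n_bad <- sum(nchar(gsub("[ACGTN]", "", s)))
  if (n_bad > 0L) {
    warning(sprintf("%d non-ACGTN bases replaced with N", n_bad))
    s <- gsub("[^ACGTN]", "N", s)
  }
  names(s) <- ids
  if (min_len > 0L) s <- s[nchar(s) >= min_len]
  s
}

#' Write scaffolds to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a nine-column alignment coordinate table
#'
#' The dialect is the tab-separated nine-column show-coords layout:
#' `S1 E1 S2 E2 LEN1 LEN2 %IDY REF_ID QRY_ID`, with 1-based inclusive
#' coordinates and reverse strand encoded as `S2 > E2`. Conversion to the
#' package-internal 0-based half-open convention happens here and only
#' here.
#'
#' @param path coords file.
#' @return alignment block data.frame with columns `ref_id, ref_start,
#'   ref_end, qry_id, qry_start, qry_end, strand, identity, len1, len2`
#'   (0-based half-open; identity as a fraction).
#' @export
read_coords_table <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c(rep("character", 7L), "character", "character"),
                           col.names = c("S1", "E1", "S2", "E2", "LEN1", "LEN2",
                                         "IDY", "REF", "QRY"),
                           quote = "", comment.char = "")
  num <- suppressWarnings(lapply(raw[1:6], as.numeric))
  if (any(vapply(num, anyNA, logical(1))) ||
      any(vapply(num, function(z) any(z != floor(z)), logical(1)))) {
    stop("non-integer coordinate in coords table")
  }
  s1 <- as.integer(num$S1); e1 <- as.integer(num$E1)
  s2 <- as.integer(num$S2); e2 <- as.integer(num$E2)
  if (any(s1 > e1)) stop("reversed reference coordinates (S1 > E1)")
  idy <- suppressWarnings(as.numeric(raw$IDY))
  if (anyNA(idy)) stop("non-numeric identity column")
  rev <- s2 > e2
  data.frame(
    ref_id = raw$REF,
    ref_start = s1 - 1L,
    ref_end = e1,
    qry_id = raw$QRY,
    qry_start = ifelse(rev, e2 - 1L, s2 - 1L),
    qry_end = ifelse(rev, s2, e2),
    strand = ifelse(rev, "-", "+"),
    identity = idy / 100,
    len1 = as.integer(num$LEN1),
    len2 = as.integer(num$LEN2),
    stringsAsFactors = FALSE
  )
}

#' Write alignment blocks as a nine-column coordinate table
#'
#' Exact inverse of [read_coords_table()]: internal 0-based half-open
#' blocks become 1-based inclusive rows, reverse strand as `S2 > E2`.
#'
#' @param blocks alignment block data.frame.
#' @param path output file.
#' @export
write_coords_table <- function(blocks, path) {
  rev <- blocks$strand == "-"
  out <- data.frame(
    S1 = blocks$ref_start + 1L,
    E1 = blocks$ref_end,
    S2 = ifelse(rev, blocks$qry_end, blocks$qry_start + 1L),
    E2 = ifelse(rev, blocks$qry_start + 1L, blocks$qry_end),
    LEN1 = blocks$len1 %||% (blocks$ref_end - blocks$ref_start),
    LEN2 = blocks$len2 %||% (blocks$qry_end - blocks$qry_start),
    IDY = formatC(blocks$identity * 100, format = "f", digits = 2),
    REF = blocks$ref_id,
    QRY = blocks$qry_id
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED3+ intervals
#'
#' Intervals are 0-based half-open on both sides of the round trip; extra
#' name/score columns are preserved.
#'
#' @param intervals data.frame with columns `chrom, start, end` and
#'   optionally `name, score`.
#' @param path file path.
#' @return `read_bed` returns the interval data.frame.
#' @export
write_bed <- function(intervals, path) {
  .check_bed(intervals)
  keep <- intersect(c("chrom", "start", "end", "name", "score"),
                    names(intervals))
  utils::write.table(intervals[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (ncol(raw) >= 4L) names(raw)[4L] <- "name"
  if (ncol(raw) >= 5L) names(raw)[5L] <- "score"
  raw$start <- as.integer(raw$start)
  raw$end <- as.integer(raw$end)
  .check_bed(raw)
  raw
}

.check_bed <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && (any(x$start < 0L) || any(x$end <= x$start))) {
    stop("invalid BED interval: start must be >= 0 and end > start")
  }
  invisible(TRUE)
}

#' Read a chromosome-size table
#'
#' Three tab-separated columns: chromosome id, length in bp, and a sex
#' flag (`autosome`, `Z`, `W`, or `unknown`; `0/1` is accepted as
#' autosome/Z for terseness).
#'
#' @param path TSV file.
#' @return data.frame with `chrom, length, sex`.
#' @export
read_chrom_sizes <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(raw[[1L]]),
                    length = as.numeric(raw[[2L]]),
                    sex = if (ncol(raw) >= 3L) as.character(raw[[3L]])
                          else "autosome",
                    stringsAsFactors = FALSE)
  out$sex[out$sex %in% c("0", "FALSE")] <- "autosome"
  out$sex[out$sex %in% c("1", "TRUE")] <- "Z"
  if (any(out$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(out$chrom)) stop("duplicate chromosome id in size table")
  out
}

#' Write chromosome sizes
#' @param sizes data.frame with `chrom, length` and optional `sex`.
#' @param path output TSV.
#' @export
write_chrom_sizes <- function(sizes, path) {
  out <- data.frame(sizes$chrom, sizes$length,
                    sizes$sex %||% "autosome")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write small variants as a minimal VCF 4.2
#'
#' Variants must already be normalized (left-aligned, minimal, anchored):
#' SNVs carry single-base alleles; indels share exactly one leading anchor
#' base and no common trailing base. Positions are internal 0-based and
#' become 1-based `POS` on output; records are sorted by (scaffold, POS).
#'
#' @param variants data.frame with `ref_id, pos, ref, alt` and optionally
#'   `genome_id, zygosity`.
#' @param reference_id label written into the `##reference` header line.
#' @param path output file.
#' @export
write_vcf_minimal <- function(variants, reference_id, path) {
  v <- variants
  if (nrow(v)) {
    bad <- !vcf_normalized(v$ref, v$alt)
    if (any(bad)) {
      stop(sprintf("%d unnormalized variant(s); left-align first", sum(bad)))
    }
    v <- v[order(v$ref_id, v$pos), , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##reference=", reference_id),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(v)) {
    info <- if (!is.null(v$zygosity)) paste0("ZYG=", v$zygosity) else "."
    writeLines(paste(v$ref_id, v$pos + 1L, ".", v$ref, v$alt, ".", "PASS",
                     info, sep = "\t"), con)
  }
  invisible(path)
}

# minimal-representation check used by the VCF writer: alleles must not
# share a trailing base, and indel alleles must share exactly the single
# leading anchor base
vcf_normalized <- function(ref, alt) {
  n_ref <- nchar(ref); n_alt <- nchar(alt)
  ok <- rep(TRUE, length(ref))
  snv <- n_ref == 1L & n_alt == 1L
  ok[snv] <- ref[snv] != alt[snv]
  ind <- !snv
  if (any(ind)) {
    same_tail <- substr(ref[ind], n_ref[ind], n_ref[ind]) ==
      substr(alt[ind], n_alt[ind], n_alt[ind]) & pmin(n_ref[ind], n_alt[ind]) > 1L
    anchored <- substr(ref[ind], 1L, 1L) == substr(alt[ind], 1L, 1L) &
      pmin(n_ref[ind], n_alt[ind]) == 1L
    ok[ind] <- anchored & !same_tail
  }
  ok
}

#' Read a minimal VCF back into a variant table
#' @param path VCF file.
#' @return data.frame with `ref_id, pos, ref, alt, zygosity` (0-based pos).
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(ref_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      zygosity = character(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  data.frame(
    ref_id = vapply(f, `[`, "", 1L),
    pos = as.integer(vapply(f, `[`, "", 2L)) - 1L,
    ref = vapply(f, `[`, "", 4L),
    alt = vapply(f, `[`, "", 5L),
    zygosity = sub("^ZYG=", "", vapply(f, `[`, "", 8L)),
    stringsAsFactors = FALSE
  )
}
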