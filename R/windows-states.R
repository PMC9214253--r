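# Fixed-window annotation: nonoverlapping windows, base composition and
# CpG counts, isochore families, feature aggregation, and the
# ancestral/current chromosome-state assignment by multi-assembly
# size-class consensus.

#' Chromosome size-class thresholds
#'
#' Defaults follow the avian convention: microchromosomes < 20 Mb,
#' intermediate 20-40 Mb, macrochromosomes > 40 Mb; "large" is anything
#' above `micro_max`. Scaled-down simulations pass smaller thresholds.
#'
#' @param micro_max upper bound (bp) of the micro class.
#' @param intermediate_max upper bound (bp) of the intermediate class.
#' @return a `size_class_config` list.
#' @export
size_class_config <- function(micro_max = 20e6, intermediate_max = 40e6) {
  stopifnot(micro_max <= intermediate_max)
  structure(list(micro_max = micro_max,
                 intermediate_max = intermediate_max),
            class = "size_class_config")
}

#' Size class of a chromosome length
#' @param length chromosome length(s) in bp.
#' @param config a [size_class_config()].
#' @return character vector `micro`/`intermediate`/`macro`.
#' @export
size_class <- function(length, config = size_class_config()) {
  ifelse(length < config$micro_max, "micro",
         ifelse(length < config$intermediate_max, "intermediate", "macro"))
}

#' Tile a genome into nonoverlapping fixed windows
#'
#' Windows start at position 0 on every scaffold; a trailing partial
#' window is dropped, so scaffolds shorter than `size` contribute none.
#'
#' @param seqs named character vector (or named lengths).
#' @param size window size in bp (100 kb and 1 Mb are the conventional
#'   isochore scales).
#' @return data.frame `chrom, start, end`.
#' @export
make_windows <- function(seqs, size = 100000L) {
  lens <- if (is.character(seqs)) nchar(seqs) else seqs
  out <- list()
  for (ch in names(lens)) {
    k <- lens[[ch]] %/% size
    if (k == 0L) next
    st <- (seq_len(k) - 1L) * size
    out[[ch]] <- data.frame(chrom = ch, start = as.integer(st),
                            end = as.integer(st + size),
                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
}

#' Base composition of windows
#'
#' `gc_pct` is (G+C)/(A+C+G+T) * 100 over non-N bases; `cpg_count` is
#' the number of CG dinucleotides (overlapping scan; pairs containing N
#' never count). An all-N window gets `NA` and should be excluded.
#'
#' @param windows window data.frame from [make_windows()].
#' @param seqs named character vector of scaffolds.
#' @return `windows` with `gc_pct` and `cpg_count` columns.
#' @export
window_composition <- function(windows, seqs) {
  n <- nrow(windows)
  gc <- numeric(n); cpg <- integer(n)
  for (ch in unique(windows$chrom)) {
    v <- seq_encode(seqs[[ch]])
    isgc <- as.integer(v == .CODE_C | v == .CODE_G)
    isn <- as.integer(v == .CODE_N)
    iscg <- c(as.integer(v[-length(v)] == .CODE_C & v[-1L] == .CODE_G), 0L)
    cum_gc <- cumsum(isgc); cum_n <- cumsum(isn); cum_cg <- cumsum(iscg)
    sel <- which(windows$chrom == ch)
    s <- windows$start[sel]; e <- windows$end[sel]
    n_gc <- cum_gc[e] - ifelse(s > 0L, cum_gc[s], 0L)
    n_n <- cum_n[e] - ifelse(s > 0L, cum_n[s], 0L)
    # CG pairs fully inside the window: starts in [s+1, e-1] (1-based)
    n_cg <- cum_cg[e - 1L] - ifelse(s > 0L, cum_cg[s], 0L)
    denom <- (e - s) - n_n
    gc[sel] <- ifelse(denom > 0L, 100 * n_gc / denom, NA_real_)
    cpg[sel] <- as.integer(n_cg)
  }
  windows$gc_pct <- gc
  windows$cpg_count <- cpg
  windows
}

#' Isochore family of a GC percentage
#'
#' Classical isochore families by percent GC: L1 < 37, L2 [37, 41),
#' H1 [41, 46), H2 [46, 53), H3 >= 53.
#'
#' @param gc_pct numeric GC percentages.
#' @return character vector of family labels.
#' @export
isochore_family <- function(gc_pct) {
  cut(gc_pct, breaks = c(-Inf, 37, 41, 46, 53, Inf),
      labels = c("L1", "L2", "H1", "H2", "H3"), right = FALSE) |>
    as.character()
}

#' Assign chromosome states to windows by size-class consensus
#'
#' For each window, collect the size class of every chromosome it aligns
#' to (a block of at least `min_block` bp overlapping the window) in
#' every assembly of the role set. All collected classes identical
#' across all alignments and assemblies gives that state; any
#' disagreement gives `ambiguous`; no alignment gives `unaligned`.
#' Windows aligning to an annotated sex chromosome get the corresponding
#' `sex_flag`.
#'
#' @param windows window data.frame (focal-genome coordinates).
#' @param assemblies list of role assemblies, each
#'   `list(blocks, sizes)`: alignment blocks with the focal genome as
#'   query, and the assembly's chromosome size table (`chrom, length`,
#'   optional `sex`).
#' @param config a [size_class_config()].
#' @param min_block minimum block length for a window to "align to" a
#'   chromosome.
#' @return `windows` with `state` and `sex_flag` columns.
#' @export
assign_state <- function(windows, assemblies, config = size_class_config(),
                         min_block = 100L) {
  n <- nrow(windows)
  state <- rep("unaligned", n)
  sexf <- rep("autosome", n)
  per_win_classes <- vector("list", n)
  for (asm in assemblies) {
    if (is.null(asm$sizes)) stop("assembly without a chromosome size table")
    sizes <- asm$sizes
    cls <- size_class(sizes$length, config)
    names(cls) <- sizes$chrom
    sex <- sizes$sex %||% rep("autosome", nrow(sizes))
    names(sex) <- sizes$chrom
    b <- asm$blocks
    b <- b[(b$qry_end - b$qry_start) >= min_block, , drop = FALSE]
    if (!nrow(b)) next
    for (ch in unique(windows$chrom)) {
      wsel <- which(windows$chrom == ch)
      bb <- b[b$qry_id == ch, , drop = FALSE]
      if (!nrow(bb)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(windows$start[wsel] + 1L, windows$end[wsel]),
        IRanges::IRanges(bb$qry_start + 1L, bb$qry_end))
      if (!length(ov)) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      for (i in unique(qh)) {
        chroms <- unique(bb$ref_id[sh[qh == i]])
        wi <- wsel[i]
        per_win_classes[[wi]] <- c(per_win_classes[[wi]],
                                   unname(cls[chroms]))
        sx <- setdiff(unique(sex[chroms]), "autosome")
        if (length(sx)) sexf[wi] <- sx[1L]
      }
    }
  }
  for (i in seq_len(n)) {
    cl <- per_win_classes[[i]]
    if (is.null(cl) || !length(cl)) next
    if (anyNA(cl)) stop("block aligned to a chromosome missing from the size table")
    state[i] <- if (length(unique(cl)) == 1L) cl[1L] else "ambiguous"
  }
  windows$state <- state
  windows$sex_flag <- sexf
  windows
}

.count_in_windows <- function(windows, chr, pos) {
  n <- nrow(windows)
  counts <- integer(n)
  for (ch in unique(chr)) {
    wsel <- which(windows$chrom == ch)
    if (!length(wsel)) next
    p <- pos[chr == ch]
    idx <- findInterval(p, windows$start[wsel])
    ok <- idx >= 1L & p < windows$end[wsel][pmax(idx, 1L)]
    tb <- table(idx[ok])
    counts[wsel[as.integer(names(tb))]] <-
      counts[wsel[as.integer(names(tb))]] + as.integer(tb)
  }
  counts
}

#' Aggregate variant, SV, repeat and NUMT features into windows
#'
#' Point features (variants, SVs, NUMTs) are assigned to the window
#' containing their start position; repeat bp are clipped to the window.
#' `net_indel_bp` sums inserted minus deleted bp over private small
#' indels and private large INS/DEL.
#'
#' @param windows window data.frame in focal-genome coordinates (with
#'   composition columns if already computed).
#' @param variants private small variants in focal coordinates
#'   (`ref_id` = focal scaffold here, or pass `chrom`/`pos` columns).
#' @param svs private SVs in focal coordinates (uses `qry_id`,
#'   `qry_start`, `svtype`, `length_bp`).
#' @param repeats repeat BED (`chrom, start, end`).
#' @param numts NUMT hits (`scaffold, start`).
#' @return `windows` with feature columns
#'   `n_snv, n_small_indel, net_indel_bp, n_sv_*, te_bases, numt_count,
#'   or_upper` (window pseudocount odds ratio needs `n_gc_to_at`/
#'   `n_at_to_gc` columns added by the caller when available).
#' @export
aggregate_features <- function(windows, variants = NULL, svs = NULL,
                               repeats = NULL, numts = NULL) {
  n <- nrow(windows)
  windows$n_snv <- integer(n)
  windows$n_small_indel <- integer(n)
  windows$net_indel_bp <- numeric(n)
  for (tp in c("INS", "DEL", "INV", "SEGDUP", "SEGDEL")) {
    windows[[paste0("n_sv_", tolower(tp))]] <- integer(n)
  }
  windows$te_bases <- numeric(n)
  windows$numt_count <- integer(n)

  if (!is.null(variants) && nrow(variants)) {
    chr <- variants$chrom %||% variants$ref_id
    pos <- variants$pos
    snv <- variants$vclass == "SNV"
    windows$n_snv <- .count_in_windows(windows, chr[snv], pos[snv])
    ind <- !snv
    windows$n_small_indel <- .count_in_windows(windows, chr[ind], pos[ind])
    if (any(ind)) {
      delta <- nchar(variants$alt) - nchar(variants$ref)
      net <- numeric(n)
      for (ch in unique(chr[ind])) {
        wsel <- which(windows$chrom == ch)
        if (!length(wsel)) next
        sel <- which(ind & chr == ch)
        idx <- findInterval(pos[sel], windows$start[wsel])
        ok <- idx >= 1L & pos[sel] < windows$end[wsel][pmax(idx, 1L)]
        for (j in which(ok)) {
          wi <- wsel[idx[j]]
          net[wi] <- net[wi] + delta[sel[j]]
        }
      }
      windows$net_indel_bp <- net
    }
  }
  if (!is.null(svs) && nrow(svs)) {
    chr <- svs$chrom %||% svs$qry_id
    pos <- svs$start %||% svs$qry_start
    for (tp in unique(svs$svtype)) {
      sel <- svs$svtype == tp
      cnt <- .count_in_windows(windows, chr[sel], pos[sel])
      windows[[paste0("n_sv_", tolower(tp))]] <- cnt
    }
    signed <- ifelse(svs$svtype == "INS", svs$length_bp,
                     ifelse(svs$svtype == "DEL", -svs$length_bp, 0))
    for (ch in unique(chr)) {
      wsel <- which(windows$chrom == ch)
      if (!length(wsel)) next
      sel <- which(chr == ch & signed != 0)
      if (!length(sel)) next
      idx <- findInterval(pos[sel], windows$start[wsel])
      ok <- idx >= 1L & pos[sel] < windows$end[wsel][pmax(idx, 1L)]
      for (j in which(ok)) {
        wi <- wsel[idx[j]]
        windows$net_indel_bp[wi] <- windows$net_indel_bp[wi] + signed[sel[j]]
      }
    }
  }
  if (!is.null(repeats) && nrow(repeats)) {
    for (ch in unique(repeats$chrom)) {
      wsel <- which(windows$chrom == ch)
      if (!length(wsel)) next
      r <- repeats[repeats$chrom == ch, , drop = FALSE]
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(windows$start[wsel] + 1L, windows$end[wsel]),
        IRanges::IRanges(r$start + 1L, r$end))
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      if (length(ov)) {
        clipped <- pmin(windows$end[wsel][qh], r$end[sh]) -
          pmax(windows$start[wsel][qh], r$start[sh])
        agg <- tapply(clipped, qh, sum)
        windows$te_bases[wsel[as.integer(names(agg))]] <- as.numeric(agg)
      }
    }
  }
  if (!is.null(numts) && nrow(numts)) {
    windows$numt_count <- .count_in_windows(windows, numts$scaffold,
                                            numts$start)
  }
  windows
}
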