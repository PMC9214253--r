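# Structural-variant classification from alignment block geometry: large
# insertions/deletions from anchor-gap pairs, inversions from reversals
# against the majority direction, segmental duplications/deletions from
# multi-block matches onto single proximal loci, the duplicated-region
# exclusion, and the cross-genome private filter.

#' Structural-variant classification settings
#'
#' @param min_sv_len minimum SV length (bp); gap pairs and reversals
#'   below this stay unclassified.
#' @param slack maximum tolerated break on the unbroken side of a large
#'   indel (0 = "without any break in alignment on the other").
#' @param proximal_bp maximum separation of tandem copies.
#' @param tandem_overlap_min minimum mutual overlap of the single locus
#'   matched by tandem copies (bp).
#' @return an `sv_config` list.
#' @export
sv_config <- function(min_sv_len = 50L, slack = 0L, proximal_bp = 1000L,
                      tandem_overlap_min = 50L) {
  stopifnot(min_sv_len >= 1L, slack < min_sv_len)
  structure(list(min_sv_len = as.integer(min_sv_len),
                 slack = as.integer(slack),
                 proximal_bp = as.integer(proximal_bp),
                 tandem_overlap_min = as.integer(tandem_overlap_min)),
            class = "sv_config")
}

.empty_svs <- function() {
  data.frame(svtype = character(0), ref_id = character(0),
             ref_start = integer(0), ref_end = integer(0),
             qry_id = character(0), qry_start = integer(0),
             qry_end = integer(0), length_bp = integer(0),
             stringsAsFactors = FALSE)
}

#' Classify large insertions and deletions from anchor-gap pairs
#'
#' A gap pair `(g_ref, g_qry)` between adjacent anchors of a collinear
#' run is a deletion when the break is on the reference side only
#' (`g_ref >= min_sv_len`, `g_qry <= slack`) and an insertion in the
#' mirror case; pairs broken on both sides are left unclassified.
#'
#' @param runs collinear runs from [collinear_runs()].
#' @param config an [sv_config()].
#' @return SV data.frame.
#' @export
classify_large_indels <- function(runs, config = sv_config()) {
  out <- list()
  for (run in runs) {
    n <- nrow(run)
    if (n < 2L) next
    fwd <- run$strand[1L] == "+"
    for (i in seq_len(n - 1L)) {
      g_ref <- run$ref_start[i + 1L] - run$ref_end[i]
      g_qry <- if (fwd) run$qry_start[i + 1L] - run$qry_end[i]
               else run$qry_start[i] - run$qry_end[i + 1L]
      if (g_ref < 0L || g_qry < 0L) {
        warning("negative anchor gap skipped")
        next
      }
      qs <- if (fwd) run$qry_end[i] else run$qry_end[i + 1L]
      qe <- if (fwd) run$qry_start[i + 1L] else run$qry_start[i]
      svtype <- if (g_ref >= config$min_sv_len && g_qry <= config$slack) {
        "DEL"
      } else if (g_qry >= config$min_sv_len && g_ref <= config$slack) {
        "INS"
      } else next
      out[[length(out) + 1L]] <- data.frame(
        svtype = svtype, ref_id = run$ref_id[i],
        ref_start = run$ref_end[i], ref_end = run$ref_start[i + 1L],
        qry_id = run$qry_id[i], qry_start = qs, qry_end = qe,
        length_bp = if (svtype == "DEL") g_ref else g_qry,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else .empty_svs()
}

#' Classify inversions from strand reversals against the majority
#'
#' Per scaffold pair, the majority direction is the strand carrying more
#' aligned reference bp (ties to `+`); each maximal run of
#' minority-strand blocks totalling at least `min_sv_len` aligned bp is
#' one inversion whose length is the summed aligned bp of the run.
#'
#' @param blocks alignment blocks for one or more scaffold pairs.
#' @param config an [sv_config()].
#' @return SV data.frame.
#' @export
classify_inversions <- function(blocks, config = sv_config()) {
  out <- list()
  if (!nrow(blocks)) return(.empty_svs())
  key <- paste(blocks$ref_id, blocks$qry_id, sep = "\r")
  for (k in unique(key)) {
    b <- blocks[key == k, , drop = FALSE]
    b <- b[order(b$ref_start), , drop = FALSE]
    w <- b$ref_end - b$ref_start
    bp_fwd <- sum(w[b$strand == "+"]); bp_rev <- sum(w[b$strand == "-"])
    maj <- if (bp_rev > bp_fwd) "-" else "+"
    minority <- b$strand != maj
    if (!any(minority)) next
    r <- rle(minority)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      len <- sum(w[idx])
      if (len < config$min_sv_len) next
      out[[length(out) + 1L]] <- data.frame(
        svtype = "INV", ref_id = b$ref_id[1L],
        ref_start = min(b$ref_start[idx]), ref_end = max(b$ref_end[idx]),
        qry_id = b$qry_id[1L],
        qry_start = min(b$qry_start[idx]), qry_end = max(b$qry_end[idx]),
        length_bp = len, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else .empty_svs()
}

# connected components over a logical adjacency matrix
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cid
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

#' Classify segmental duplications and deletions
#'
#' Two or more query blocks with disjoint, proximal query intervals whose
#' reference intervals mutually overlap by at least
#' `tandem_overlap_min` bp form a segmental duplication (tandem copies in
#' the query matching a single reference locus); the mirror case forms a
#' segmental deletion. Event length is the extra copies' bp (total minus
#' the largest block).
#'
#' @param blocks alignment blocks.
#' @param config an [sv_config()].
#' @return SV data.frame.
#' @export
classify_segmental <- function(blocks, config = sv_config()) {
  out <- list()
  if (!nrow(blocks)) return(.empty_svs())
  key <- paste(blocks$ref_id, blocks$qry_id, sep = "\r")
  for (k in unique(key)) {
    b <- blocks[key == k, , drop = FALSE]
    n <- nrow(b)
    if (n < 2L) next
    for (mode in c("SEGDUP", "SEGDEL")) {
      # SEGDUP: disjoint on qry, shared ref locus; SEGDEL: mirror
      if (mode == "SEGDUP") {
        d_s <- b$qry_start; d_e <- b$qry_end   # disjoint side
        s_s <- b$ref_start; s_e <- b$ref_end   # shared side
      } else {
        d_s <- b$ref_start; d_e <- b$ref_end
        s_s <- b$qry_start; s_e <- b$qry_end
      }
      adj <- matrix(FALSE, n, n)
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          disjoint <- d_e[i] <= d_s[j] || d_e[j] <= d_s[i]
          gap <- max(d_s[i], d_s[j]) - min(d_e[i], d_e[j])
          shared <- min(s_e[i], s_e[j]) - max(s_s[i], s_s[j])
          if (disjoint && gap <= config$proximal_bp &&
              shared >= config$tandem_overlap_min) {
            adj[i, j] <- adj[j, i] <- TRUE
          }
        }
      }
      if (!any(adj)) next
      comp <- .components(adj)
      for (cid in unique(comp)) {
        idx <- which(comp == cid)
        if (length(idx) < 2L || !any(adj[idx, idx])) next
        sz <- d_e[idx] - d_s[idx]
        len <- sum(sz) - max(sz)
        if (len < config$min_sv_len) next
        # event locus: the extra copies only, not the primary match span
        extras <- idx[-which.max(sz)]
        if (mode == "SEGDUP") {
          rs <- min(s_s[extras]); re <- max(s_e[extras])
          qs <- min(d_s[extras]); qe <- max(d_e[extras])
        } else {
          rs <- min(d_s[extras]); re <- max(d_e[extras])
          qs <- min(s_s[extras]); qe <- max(s_e[extras])
        }
        out[[length(out) + 1L]] <- data.frame(
          svtype = mode, ref_id = b$ref_id[1L],
          ref_start = rs, ref_end = re,
          qry_id = b$qry_id[1L], qry_start = qs, qry_end = qe,
          length_bp = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else .empty_svs()
}

.dup_regions <- function(blocks, side = c("ref", "qry")) {
  side <- match.arg(side)
  id <- blocks[[paste0(side, "_id")]]
  st <- blocks[[paste0(side, "_start")]]
  en <- blocks[[paste0(side, "_end")]]
  out <- list()
  for (ch in unique(id)) {
    sel <- id == ch
    cov <- IRanges::coverage(IRanges::IRanges(st[sel] + 1L, en[sel]))
    multi <- IRanges::slice(cov, lower = 2L, rangesOnly = TRUE)
    if (length(multi)) {
      out[[ch]] <- data.frame(chrom = ch,
                              start = IRanges::start(multi) - 1L,
                              end = IRanges::end(multi),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
}

.overlaps_any <- function(chrom, start, end, regions) {
  if (!length(chrom) || !nrow(regions)) return(rep(FALSE, length(chrom)))
  hit <- rep(FALSE, length(chrom))
  for (ch in unique(chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (!nrow(r)) next
    sel <- which(chrom == ch)
    ov <- IRanges::overlapsAny(
      IRanges::IRanges(start[sel] + 1L, pmax(end[sel], start[sel] + 1L)),
      IRanges::IRanges(r$start + 1L, r$end))
    hit[sel] <- ov
  }
  hit
}

#' Exclude INS/DEL/INV calls matching duplicated regions
#'
#' Duplicated regions are reference or query intervals covered by more
#' than one alignment block, together with the loci of segmental events
#' (which necessarily induce spurious gap calls in the one-to-one anchor
#' chain). Any insertion, deletion or inversion overlapping such a
#' region on either genome is removed; segmental events themselves are
#' exempt from this filter.
#'
#' @param svs SV data.frame of INS/DEL/INV calls.
#' @param blocks all alignment blocks (including off-chain blocks).
#' @param seg_svs segmental SV calls whose loci also count as duplicated.
#' @return the filtered SV data.frame.
#' @export
exclude_duplicated <- function(svs, blocks, seg_svs = NULL) {
  if (!nrow(svs) || !nrow(blocks)) return(svs)
  dup_ref <- .dup_regions(blocks, "ref")
  dup_qry <- .dup_regions(blocks, "qry")
  if (!is.null(seg_svs) && nrow(seg_svs)) {
    dup_ref <- rbind(dup_ref, data.frame(chrom = seg_svs$ref_id,
                                         start = seg_svs$ref_start,
                                         end = seg_svs$ref_end,
                                         stringsAsFactors = FALSE))
    dup_qry <- rbind(dup_qry, data.frame(chrom = seg_svs$qry_id,
                                         start = seg_svs$qry_start,
                                         end = seg_svs$qry_end,
                                         stringsAsFactors = FALSE))
  }
  drop <- .overlaps_any(svs$ref_id, svs$ref_start, svs$ref_end, dup_ref) |
    .overlaps_any(svs$qry_id, svs$qry_start, svs$qry_end, dup_qry)
  out <- svs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reduce SV catalogs to private variants per genome
#'
#' An SV is private when no same-type SV from any *other* genome overlaps
#' it by at least one bp in shared (outgroup) reference coordinates;
#' non-private SVs are removed from every genome. SVs of different types
#' never mask one another.
#'
#' @param catalog combined SV data.frame with a `genome_id` column, all
#'   in outgroup reference coordinates.
#' @return the private subset of `catalog`.
#' @export
private_filter <- function(catalog) {
  if (!nrow(catalog)) return(catalog)
  keep <- rep(TRUE, nrow(catalog))
  # INS calls have zero reference width; give every interval >= 1 bp for
  # the overlap test
  st <- catalog$ref_start
  en <- pmax(catalog$ref_end, st + 1L)
  for (tp in unique(catalog$svtype)) {
    sel <- which(catalog$svtype == tp)
    for (ch in unique(catalog$ref_id[sel])) {
      ss <- sel[catalog$ref_id[sel] == ch]
      if (length(ss) < 2L) next
      ir <- IRanges::IRanges(st[ss] + 1L, en[ss])
      ov <- IRanges::findOverlaps(ir, ir)
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      cross <- qh != sh &
        catalog$genome_id[ss][qh] != catalog$genome_id[ss][sh]
      keep[ss[unique(qh[cross])]] <- FALSE
    }
  }
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify all structural variants for one focal haplotype
#'
#' Runs the full SV layer in order: large indels from chain gaps,
#' inversions, segmental events, then the duplicated-region exclusion of
#' INS/DEL/INV.
#'
#' @param blocks all alignment blocks for the genome pair.
#' @param runs collinear runs from [collinear_runs()] (computed from
#'   `blocks` when NULL).
#' @param config an [sv_config()].
#' @return SV data.frame with all five classes.
#' @export
classify_svs <- function(blocks, runs = NULL, config = sv_config()) {
  if (is.null(runs)) runs <- collinear_runs(blocks)$runs
  indels <- classify_large_indels(runs, config)
  invs <- classify_inversions(blocks, config)
  segs <- classify_segmental(blocks, config)
  core <- exclude_duplicated(rbind(indels, invs), blocks, seg_svs = segs)
  out <- rbind(core, segs)
  rownames(out) <- NULL
  out
}
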