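# Emission of aligner-style coordinate tables from the simulator's truth
# homology maps: the blocks a whole-genome aligner would anchor between a
# focal genome and the reference/outgroup, including cross-copy (paralog)
# anchors at loci where a segmental event created copy-number asymmetry.

# merge adjacent map pieces that are contiguous on both sides
merge_map_pieces <- function(map) {
  if (nrow(map) < 2L) return(map)
  df <- as.data.frame(map)
  df <- df[order(df$f_chr, df$f_start), , drop = FALSE]
  out <- list()
  cur <- df[1L, ]
  for (i in 2:nrow(df)) {
    nx <- df[i, ]
    joinable <- nx$f_chr == cur$f_chr && nx$f_start == cur$f_end &&
      nx$r_chr == cur$r_chr && nx$strand == cur$strand &&
      ((cur$strand == "+" && nx$r_start == cur$r_end) ||
         (cur$strand == "-" && nx$r_end == cur$r_start))
    if (joinable) {
      cur$f_end <- nx$f_end
      if (cur$strand == "+") cur$r_end <- nx$r_end else cur$r_start <- nx$r_start
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nx
    }
  }
  out[[length(out) + 1L]] <- cur
  homology_map(do.call(rbind, out))
}

# per-block identity by direct sequence comparison
.block_identity <- function(blocks, ref_seqs, qry_seqs) {
  n <- nrow(blocks)
  idy <- numeric(n)
  for (i in seq_len(n)) {
    r <- seq_encode(substr(ref_seqs[[blocks$ref_id[i]]],
                           blocks$ref_start[i] + 1L, blocks$ref_end[i]))
    q <- seq_encode(substr(qry_seqs[[blocks$qry_id[i]]],
                           blocks$qry_start[i] + 1L, blocks$qry_end[i]))
    if (blocks$strand[i] == "-") q <- revcomp_int(q)
    idy[i] <- mean(r == q)
  }
  idy
}

#' Emit truth-derived alignment blocks for a genome pair
#'
#' Composes the focal haplotype's homology map with the outgroup's to
#' produce the gapless anchor blocks of the true alignment (reference =
#' outgroup, query = focal). Blocks break only at indel/SV breakpoints;
#' substitutions stay inside blocks and lower the identity column, as in
#' real aligner output. Blocks shorter than `min_block` are dropped,
#' mirroring the aligner's minimum alignment length. Paralog anchors for
#' segmental events are appended when supplied.
#'
#' @param focal_map focal haplotype map (current -> focal root space).
#' @param outgroup_map outgroup map (current -> ancestor space).
#' @param focal_seqs,outgroup_seqs named character vectors of scaffolds.
#' @param root_to_anc optional map from the focal root space to ancestor
#'   space (the fusion map); NULL if they coincide.
#' @param paralogs optional data.frame of cross-copy anchor seeds with
#'   columns `f_chr, f_start, f_end` (focal root space) and
#'   `r_chr, r_start, r_end` (ancestor space).
#' @param min_block drop blocks shorter than this (bp).
#' @return alignment block data.frame as from [read_coords_table()].
#' @export
emit_truth_alignments <- function(focal_map, outgroup_map,
                                  focal_seqs, outgroup_seqs,
                                  root_to_anc = NULL, paralogs = NULL,
                                  min_block = 100L) {
  f2a <- if (is.null(root_to_anc)) focal_map
         else compose_maps(focal_map, root_to_anc)
  comp <- compose_maps(f2a, invert_map(outgroup_map))
  comp <- merge_map_pieces(comp)
  blocks <- map_to_blocks(comp)

  if (!is.null(paralogs) && nrow(paralogs)) {
    extra <- list()
    inv_f <- invert_map(focal_map)
    inv_o <- invert_map(outgroup_map)
    for (i in seq_len(nrow(paralogs))) {
      pf <- lift_interval(inv_f, paralogs$f_chr[i],
                          paralogs$f_start[i], paralogs$f_end[i])
      po <- lift_interval(inv_o, paralogs$r_chr[i],
                          paralogs$r_start[i], paralogs$r_end[i])
      if (nrow(pf) != 1L || nrow(po) != 1L) next
      Lf <- pf$end - pf$start; Lo <- po$end - po$start
      L0 <- paralogs$f_end[i] - paralogs$f_start[i]
      if (min(Lf, Lo) < 0.9 * L0) next
      L <- min(Lf, Lo)
      strand <- if (pf$strand == po$strand) "+" else "-"
      extra[[length(extra) + 1L]] <- data.frame(
        ref_id = po$chr, ref_start = po$start, ref_end = po$start + L,
        qry_id = pf$chr, qry_start = pf$start, qry_end = pf$start + L,
        strand = strand, identity = NA_real_,
        len1 = L, len2 = L, stringsAsFactors = FALSE)
    }
    if (length(extra)) blocks <- rbind(blocks, do.call(rbind, extra))
  }

  blocks <- blocks[(blocks$ref_end - blocks$ref_start) >= min_block, ,
                   drop = FALSE]
  if (nrow(blocks)) {
    blocks$identity <- .block_identity(blocks, outgroup_seqs, focal_seqs)
    blocks <- blocks[order(blocks$ref_id, blocks$ref_start), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  blocks
}
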