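# Truth-table utilities: express the simulator's planted events in
# outgroup (reference) or focal coordinates so pipeline output can be
# scored against them.

# map from the focal root (fused) space to outgroup coordinates
panel_root_to_outgroup <- function(panel) {
  compose_maps(panel$fused$map, invert_map(panel$outgroup$map))
}

#' Expected small-variant calls for one focal genome
#'
#' Collapses the planted substitution and small-indel events on the
#' genome's root-to-tip paths into the variant calls an exact caller
#' should report against the outgroup: events are netted per site,
#' sites lost from either the focal haplotype or the outgroup are
#' dropped, insertion alleles are read out of the final haplotype
#' sequence, and everything is left-align normalized.
#'
#' @param panel a [simulate_panel()] result.
#' @param genome_id focal genome.
#' @return list with `hap1` and `hap2` normalized variant data.frames
#'   (reference coordinates) and `diploid` (genotype-merged).
#' @export
truth_expected_small_variants <- function(panel, genome_id) {
  r2o <- panel_root_to_outgroup(panel)
  og_events <- panel$outgroup$events[[panel$outgroup_id]]
  og_sub_sites <- if (!is.null(og_events$snvs)) {
    paste(og_events$snvs$root_chr, og_events$snvs$root_pos, sep = "\r")
  } else character(0)

  hap_calls <- list()
  for (hap in 1:2) {
    hp <- panel$genomes[[genome_id]][[paste0("hap", hap)]]
    inv_tip <- invert_map(hp$map)
    edges <- .path_edges(panel, genome_id, hap)
    snvs <- do.call(rbind, lapply(edges, function(e) {
      panel$events[[e]]$snvs
    }))
    edits <- do.call(rbind, lapply(edges, function(e) {
      panel$events[[e]]$edits
    }))
    vars <- list()
    if (!is.null(snvs) && nrow(snvs)) {
      snvs <- snvs[!is.na(snvs$root_pos), , drop = FALSE]
      key <- paste(snvs$root_chr, snvs$root_pos, sep = "\r")
      # net change per site, in event order
      for (k in unique(key)) {
        ev <- snvs[key == k, , drop = FALSE]
        anc_base <- ev$old[1L]; final <- ev$new[nrow(ev)]
        if (anc_base == final) next
        rchr <- ev$root_chr[1L]; rpos <- ev$root_pos[1L]
        # mutated on the outgroroup branch too? then the reference allele
        # is not the ancestral allele; the caller still sees a mismatch
        # but polarization is compromised -- keep the call with the
        # outgroup base as REF
        # site must survive in the focal haplotype
        tip <- lift_positions(inv_tip, rchr, rpos)
        if (is.na(tip$pos)) next
        ref <- lift_positions(r2o, rchr, rpos)
        if (is.na(ref$pos)) next
        ref_base <- substr(panel$outgroup$seqs[[ref$chr]], ref$pos + 1L,
                           ref$pos + 1L)
        alt_base <- if (ref$strand == "-" ||
                        (!is.na(tip$strand) && tip$strand == "-")) {
          # orientation flips between focal and reference
          NA_character_
        } else .BASES[final]
        if (is.na(alt_base)) next     # inside an inversion: not called
        if (ref_base == alt_base) next
        vars[[length(vars) + 1L]] <- data.frame(
          ref_id = ref$chr, pos = ref$pos, ref = ref_base, alt = alt_base,
          vclass = "SNV", stringsAsFactors = FALSE)
      }
    }
    if (!is.null(edits) && nrow(edits)) {
      sm <- edits[edits$kind %in% c("SMALL_INS", "SMALL_DEL"), ,
                  drop = FALSE]
      for (i in seq_len(nrow(sm))) {
        if (sm$kind[i] == "SMALL_DEL") {
          if (sm$n_root_pieces[i] != 1L || is.na(sm$root_chr[i])) next
          ref_iv <- .lift_clean(r2o, sm$root_chr[i], sm$root_start[i],
                                sm$root_end[i])
          if (is.null(ref_iv) || ref_iv$strand == "-") next
          anchor_pos <- ref_iv$start - 1L
          if (anchor_pos < 0L) next
          ref_seq <- panel$outgroup$seqs[[ref_iv$chr]]
          del <- substr(ref_seq, ref_iv$start + 1L, ref_iv$end)
          anchor <- substr(ref_seq, anchor_pos + 1L, anchor_pos + 1L)
          vars[[length(vars) + 1L]] <- data.frame(
            ref_id = ref_iv$chr, pos = anchor_pos,
            ref = paste0(anchor, del), alt = anchor, vclass = "DEL",
            stringsAsFactors = FALSE)
        } else {
          # insertion: content read from the final haplotype sequence
          tip_iv <- .lift_clean(inv_tip, sm$vchr[i], 0L, sm$length[i])
          if (is.null(tip_iv) || tip_iv$strand == "-") next
          ins <- substr(hp$seqs[[tip_iv$chr]], tip_iv$start + 1L,
                        tip_iv$end)
          ref_anchor <- lift_positions(r2o, sm$root_chr[i],
                                       sm$root_start[i])
          if (is.na(ref_anchor$pos) || ref_anchor$strand == "-") next
          ref_seq <- panel$outgroup$seqs[[ref_anchor$chr]]
          anchor <- substr(ref_seq, ref_anchor$pos + 1L,
                           ref_anchor$pos + 1L)
          vars[[length(vars) + 1L]] <- data.frame(
            ref_id = ref_anchor$chr, pos = ref_anchor$pos,
            ref = anchor, alt = paste0(anchor, ins), vclass = "INS",
            stringsAsFactors = FALSE)
        }
      }
    }
    v <- if (length(vars)) do.call(rbind, c(vars, make.row.names = FALSE))
         else .empty_variants()
    if (nrow(v)) v <- normalize_variants(v, panel$outgroup$seqs)
    hap_calls[[hap]] <- v
  }
  list(hap1 = hap_calls[[1L]], hap2 = hap_calls[[2L]],
       diploid = genotype_merge(hap_calls[[1L]], hap_calls[[2L]]))
}

#' Planted structural variants of one focal genome in reference
#' coordinates
#'
#' NUMT insertions long enough to be SV calls are included as INS.
#'
#' @param panel a [simulate_panel()] result.
#' @param genome_id focal genome.
#' @param haplotype 1, 2 or NULL (both, deduplicated by shared events).
#' @param min_len include only events of at least this length.
#' @return data.frame `svtype, ref_id, ref_start, ref_end, length_bp,
#'   edge, zygosity`.
#' @export
truth_sv_table <- function(panel, genome_id, haplotype = NULL,
                           min_len = 50L) {
  r2o <- panel_root_to_outgroup(panel)
  edges <- unique(.path_edges(panel, genome_id, haplotype))
  rows <- list()
  for (e in edges) {
    ed <- panel$events[[e]]$edits
    if (is.null(ed)) next
    zyg <- if (grepl("::hap", e)) "het" else "fixed"
    for (i in seq_len(nrow(ed))) {
      kind <- ed$kind[i]
      if (kind %in% c("SMALL_INS", "SMALL_DEL")) next
      if (ed$length[i] < min_len) next
      svtype <- if (kind == "NUMT") "INS" else kind
      if (svtype %in% c("DEL", "INV", "SEGDEL")) {
        iv <- .lift_clean(r2o, ed$root_chr[i], ed$root_start[i],
                          ed$root_end[i], min_frac = 0.5,
                          allow_range = TRUE)
        if (kind == "SEGDEL" && !is.null(panel$registry)) {
          tp <- panel$registry[panel$registry$pair_id == ed$pair_id[i], ]
          if (nrow(tp)) {
            iv <- .lift_clean(r2o, tp$root_chr, tp$c2_start, tp$c2_end,
                              min_frac = 0.5, allow_range = TRUE)
          }
        }
        if (is.null(iv)) next
        rows[[length(rows) + 1L]] <- data.frame(
          svtype = svtype, ref_id = iv$chr, ref_start = iv$start,
          ref_end = iv$end, length_bp = ed$length[i], edge = e,
          zygosity = zyg, stringsAsFactors = FALSE)
      } else {
        # insertion-like: anchored at a reference point
        anchor <- if (kind == "SEGDUP") {
          c(ed$src_root_chr[i], ed$src_root_end[i] - 1L)
        } else {
          c(ed$root_chr[i], ed$root_start[i])
        }
        if (is.na(anchor[1L])) next
        ref <- lift_positions(r2o, anchor[1L], as.integer(anchor[2L]))
        if (is.na(ref$pos)) next
        rows[[length(rows) + 1L]] <- data.frame(
          svtype = svtype, ref_id = ref$chr, ref_start = ref$pos,
          ref_end = ref$pos, length_bp = ed$length[i], edge = e,
          zygosity = zyg, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    out[!duplicated(out[c("svtype", "ref_id", "ref_start", "edge")]), ,
        drop = FALSE]
  } else {
    data.frame(svtype = character(0), ref_id = character(0),
               ref_start = integer(0), ref_end = integer(0),
               length_bp = integer(0), edge = character(0),
               zygosity = character(0), stringsAsFactors = FALSE)
  }
}

#' Planted NUMTs of one focal haplotype in its own coordinates
#'
#' @param panel a [simulate_panel()] result.
#' @param genome_id focal genome.
#' @param haplotype 1 or 2.
#' @return data.frame `scaffold, start, end, mito_start, mito_end,
#'   strand, length_bp, edge`.
#' @export
truth_numts <- function(panel, genome_id, haplotype) {
  hp <- panel$genomes[[genome_id]][[paste0("hap", haplotype)]]
  inv_tip <- invert_map(hp$map)
  edges <- .path_edges(panel, genome_id, haplotype)
  rows <- list()
  for (e in edges) {
    ed <- panel$events[[e]]$edits
    if (is.null(ed)) next
    nm <- ed[ed$kind == "NUMT", , drop = FALSE]
    for (i in seq_len(nrow(nm))) {
      iv <- .lift_clean(inv_tip, nm$vchr[i], 0L, nm$length[i],
                        min_frac = 0.9)
      if (is.null(iv)) next
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = iv$chr, start = iv$start, end = iv$end,
        mito_start = nm$mito_start[i], mito_end = nm$mito_end[i],
        strand = nm$mito_strand[i], length_bp = nm$length[i], edge = e,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(scaffold = character(0), start = integer(0),
                  end = integer(0), mito_start = integer(0),
                  mito_end = integer(0), strand = character(0),
                  length_bp = integer(0), edge = character(0),
                  stringsAsFactors = FALSE)
}

#' Planted junction telomere arrays in one focal haplotype's coordinates
#'
#' @param panel a [simulate_panel()] result.
#' @param genome_id focal genome.
#' @param haplotype 1 or 2.
#' @return data.frame `scaffold, start, end, units`.
#' @export
truth_junction_telomeres <- function(panel, genome_id, haplotype) {
  jt <- panel$fused$junction_telomeres
  if (is.null(jt)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), units = integer(0),
                      stringsAsFactors = FALSE))
  }
  hp <- panel$genomes[[genome_id]][[paste0("hap", haplotype)]]
  inv_tip <- invert_map(hp$map)
  rows <- list()
  for (i in seq_len(nrow(jt))) {
    iv <- .lift_clean(inv_tip, jt$chrom[i], jt$start[i], jt$end[i],
                      min_frac = 0.8)
    if (is.null(iv)) next
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold = iv$chr, start = iv$start, end = iv$end,
      units = jt$units[i], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(scaffold = character(0), start = integer(0),
                  end = integer(0), units = integer(0),
                  stringsAsFactors = FALSE)
}

#' Ancestral chromosome class of focal-genome windows, from the truth map
#'
#' @param panel a [simulate_panel()] result.
#' @param genome_id focal genome.
#' @param haplotype 1 or 2.
#' @param windows window data.frame in that haplotype's coordinates.
#' @return character vector: ancestral size class per window
#'   (`micro`/`intermediate`/`macro`, `mixed` when a window spans
#'   classes, NA when unmapped).
#' @export
truth_window_anc_class <- function(panel, genome_id, haplotype, windows) {
  hp <- panel$genomes[[genome_id]][[paste0("hap", haplotype)]]
  anc_cls <- stats::setNames(panel$ancestor$sizes$size_class,
                             panel$ancestor$sizes$chrom)
  tip_to_anc <- compose_maps(hp$map, panel$fused$map)
  out <- rep(NA_character_, nrow(windows))
  for (i in seq_len(nrow(windows))) {
    r <- lift_interval(tip_to_anc, windows$chrom[i], windows$start[i],
                       windows$end[i])
    if (!nrow(r)) next
    cls <- unique(anc_cls[unique(r$chr)])
    out[i] <- if (length(cls) == 1L) cls else "mixed"
  }
  out
}
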