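# Panel orchestration: build an ancestor, fuse microchromosomes on the
# ingroup stem, evolve the outgroup and a tree of focal diploid genomes,
# and collect every truth structure downstream recovery checks need.

#' A scaled-down default ancestral karyotype
#'
#' Two macro-, two intermediate- and four micro-chromosomes (~9.4 Mb
#' total), micros with higher GC and CpG, meant to be used with
#' correspondingly scaled [size_class_config()] thresholds.
#'
#' @param scale multiply all chromosome lengths by this factor.
#' @param ... passed through to [ancestor_spec()].
#' @return an [ancestor_spec()].
#' @export
default_ancestor_spec <- function(scale = 1, ...) {
  ch <- data.frame(
    chrom = c("macro1", "macro2", "int1", "int2",
              "micro1", "micro2", "micro3", "micro4"),
    length = round(scale * c(3e6, 2.4e6, 1.2e6, 1.2e6,
                             5e5, 4e5, 4e5, 3e5)),
    gc = c(0.40, 0.41, 0.44, 0.44, 0.50, 0.51, 0.52, 0.50),
    # vertebrate genomes are CpG-depleted relative to iid expectation;
    # micros keep relatively more CpG (island-rich), macros less
    cpg = c(0.012, 0.0126, 0.0145, 0.0145, 0.028, 0.029, 0.030, 0.028),
    size_class = c("macro", "macro", "intermediate", "intermediate",
                   "micro", "micro", "micro", "micro"),
    stringsAsFactors = FALSE)
  ancestor_spec(ch, telomere_units = 25L, ...)
}

#' Scaled size-class thresholds matching [default_ancestor_spec()]
#' @export
default_size_classes <- function() {
  size_class_config(micro_max = 1e6, intermediate_max = 2e6)
}

#' Default fusion plan: two microchromosomes fused onto a macrochromosome
#' @export
default_fusion_plan <- function() {
  fusion_plan(junctions = data.frame(
    a = c("macro1", "macro1+micro1"), b = c("micro1", "micro2"),
    telomere = TRUE, stringsAsFactors = FALSE))
}

# lift one interval, demanding a single clean piece; NULL otherwise.
# allow_range = TRUE accepts a multi-piece lift when all pieces land on
# one scaffold on the forward strand, returning the covering range.
.lift_clean <- function(map, chr, start, end, min_frac = 1,
                        allow_range = FALSE) {
  if (is.na(chr) || is.na(start) || is.na(end) || end <= start) return(NULL)
  r <- lift_interval(map, chr, start, end)
  if (!nrow(r)) return(NULL)
  if (nrow(r) > 1L) {
    if (!allow_range || length(unique(r$chr)) != 1L ||
        any(r$strand == "-")) {
      return(NULL)
    }
    r <- data.frame(chr = r$chr[1L], start = min(r$start),
                    end = max(r$end), strand = "+",
                    partial = r$partial[1L], split = TRUE,
                    stringsAsFactors = FALSE)
  }
  covered <- sum(r$end - r$start)
  if (covered < min_frac * (end - start)) return(NULL)
  r
}

#' Simulate a full panel: ancestor, fusion, outgroup and focal genomes
#'
#' The outgroup evolves from the unfused ancestor (it retains the
#' ancestral karyotype); the focal genomes evolve from the fused
#' karyotype down `tree`, splitting into two haplotypes at the tips.
#'
#' @param spec an [ancestor_spec()].
#' @param plan a [fusion_plan()] applied on the ingroup stem (NULL =
#'   none).
#' @param tree rooted `ape::phylo` of the focal genomes.
#' @param params [evolution_params()] for the focal lineages.
#' @param outgroup_params parameters for the outgroup branch; defaults
#'   to `params` with SV/NUMT rates zeroed and `het_depth = 0` (the
#'   outgroup is assembled haploid and serves as the reference).
#' @param outgroup_branch branch length ancestor -> outgroup.
#' @param outgroup_id label of the outgroup genome.
#' @param tel_units TTAGGG units inserted at fusion junctions.
#' @param size_classes a [size_class_config()] on the simulated scale
#'   (drives the NUMT micro-chromosome bias and state truth).
#' @param seed integer seed.
#' @return a `flux_panel` list; see Details in the package vignette.
#' @export
simulate_panel <- function(spec = default_ancestor_spec(),
                           plan = default_fusion_plan(),
                           tree = ape::read.tree(
                             text = "((gA:0.25,gB:0.25):0.25,gC:0.5);"),
                           params = evolution_params(),
                           outgroup_params = NULL,
                           outgroup_branch = 0.5,
                           outgroup_id = "outgroup",
                           tel_units = 50L,
                           size_classes = default_size_classes(),
                           seed = 1L) {
  anc <- build_ancestor(spec, seed = seed)

  if (is.null(outgroup_params)) {
    outgroup_params <- params
    outgroup_params$sv_rates[] <- 0
    outgroup_params$numt_rate <- 0
    outgroup_params$het_depth <- 0
  }
  # outgroup: one haploid lineage from the unfused ancestor
  og_tree <- structure(list(edge = matrix(c(2L, 1L), 1L),
                            edge.length = outgroup_branch,
                            tip.label = outgroup_id, Nnode = 1L),
                       class = "phylo")
  og_registry <- if (!is.null(anc$tandem_pairs)) {
    data.frame(pair_id = anc$tandem_pairs$pair_id,
               root_chr = anc$tandem_pairs$chrom,
               c1_start = anc$tandem_pairs$c1_start,
               c1_end = anc$tandem_pairs$c1_end,
               c2_start = anc$tandem_pairs$c2_start,
               c2_end = anc$tandem_pairs$c2_end,
               stringsAsFactors = FALSE)
  } else NULL
  og <- evolve_panel(anc$seqs, anc$mito, outgroup_params, og_tree,
                     tandem_pairs = og_registry, seed = seed + 1L)
  outgroup <- og$tips[[outgroup_id]]$hap1

  # ingroup: fuse, then evolve down the tree
  fused <- if (is.null(plan)) {
    list(seqs = anc$seqs, map = identity_map(anc$seqs),
         junction_telomeres = NULL)
  } else {
    apply_fusion_plan(anc$seqs, plan, tel_units = tel_units)
  }
  micro_flags <- stats::setNames(
    size_class(nchar(fused$seqs), size_classes) == "micro",
    names(fused$seqs))

  # tandem registry translated to fused coordinates
  registry <- NULL
  if (!is.null(anc$tandem_pairs)) {
    inv_f <- invert_map(fused$map)
    rows <- list()
    for (i in seq_len(nrow(anc$tandem_pairs))) {
      tp <- anc$tandem_pairs[i, ]
      c1 <- .lift_clean(inv_f, tp$chrom, tp$c1_start, tp$c1_end)
      c2 <- .lift_clean(inv_f, tp$chrom, tp$c2_start, tp$c2_end)
      if (is.null(c1) || is.null(c2) || c1$chr != c2$chr) next
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = tp$pair_id, root_chr = c1$chr,
        c1_start = c1$start, c1_end = c1$end,
        c2_start = c2$start, c2_end = c2$end,
        anc_chr = tp$chrom,
        anc_c1_start = tp$c1_start, anc_c1_end = tp$c1_end,
        anc_c2_start = tp$c2_start, anc_c2_end = tp$c2_end,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) registry <- do.call(rbind, rows)
  }

  # junction telomere arrays (and terminal arrays) keep their planted
  # loci: structural edits are barred there so the telomere truth stays
  # addressable (substitutions still accumulate)
  protect <- NULL
  if (!is.null(fused$junction_telomeres)) {
    jt <- fused$junction_telomeres
    protect <- data.frame(chr = jt$chrom, start = jt$start - 30L,
                          end = jt$end + 30L, stringsAsFactors = FALSE)
  }
  ing <- evolve_panel(fused$seqs, anc$mito, params, tree,
                      micro_flags = micro_flags,
                      tandem_pairs = registry, protected = protect,
                      seed = seed + 2L)

  structure(list(
    ancestor = anc, fused = fused, registry = registry,
    outgroup_id = outgroup_id,
    outgroup = list(seqs = outgroup$seqs, map = outgroup$map,
                    mito = og$tips[[outgroup_id]]$mito,
                    events = og$events),
    genomes = ing$tips, events = ing$events, edge_tips = ing$edge_tips,
    tree = tree, params = params, outgroup_params = outgroup_params,
    size_classes = size_classes, seed = seed),
    class = "flux_panel")
}

#' @export
print.flux_panel <- function(x, ...) {
  cat("simulated genome panel\n")
  cat(sprintf("  ancestor: %d chromosomes, %.2f Mb\n",
              length(x$ancestor$seqs),
              sum(nchar(x$ancestor$seqs)) / 1e6))
  cat(sprintf("  focal genomes: %s (diploid)\n",
              paste(names(x$genomes), collapse = ", ")))
  cat(sprintf("  outgroup: %s (haploid reference)\n", x$outgroup_id))
  invisible(x)
}

# edges on the root-to-tip path of (genome, haplotype)
.path_edges <- function(panel, genome_id, haplotype = NULL) {
  labs <- names(panel$edge_tips)
  shared <- labs[vapply(panel$edge_tips[labs], function(tp) {
    genome_id %in% tp
  }, TRUE) & !grepl("::hap", labs)]
  if (is.null(haplotype)) {
    c(shared, paste0(genome_id, "::hap1"), paste0(genome_id, "::hap2"))
  } else {
    c(shared, paste0(genome_id, "::hap", haplotype))
  }
}

# paralog anchor seeds (focal root space vs ancestor space) for the
# segmental events on one haplotype's path
panel_paralog_seeds <- function(panel, genome_id, haplotype) {
  edges <- .path_edges(panel, genome_id, haplotype)
  rows <- list()
  for (e in edges) {
    ed <- panel$events[[e]]$edits
    if (is.null(ed)) next
    for (i in seq_len(nrow(ed))) {
      if (ed$kind[i] == "SEGDUP") {
        src <- .lift_clean(panel$fused$map, ed$src_root_chr[i],
                           ed$src_root_start[i], ed$src_root_end[i],
                           min_frac = 0.9)
        if (is.null(src)) next
        rows[[length(rows) + 1L]] <- data.frame(
          f_chr = ed$vchr[i], f_start = 0L, f_end = ed$length[i],
          r_chr = src$chr, r_start = src$start, r_end = src$end,
          stringsAsFactors = FALSE)
      } else if (ed$kind[i] == "SEGDEL" && !is.null(panel$registry)) {
        tp <- panel$registry[panel$registry$pair_id == ed$pair_id[i], ]
        if (!nrow(tp)) next
        rows[[length(rows) + 1L]] <- data.frame(
          f_chr = tp$root_chr, f_start = tp$c1_start, f_end = tp$c1_end,
          r_chr = tp$anc_chr, r_start = tp$anc_c2_start,
          r_end = tp$anc_c2_end, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Emit aligner-style coordinate tables for every focal haplotype
#'
#' @param panel a [simulate_panel()] result.
#' @param min_block minimum emitted block length (bp).
#' @return nested list `blocks[[genome]][[hap]]` of alignment block
#'   data.frames (reference = outgroup).
#' @export
panel_alignments <- function(panel, min_block = 100L) {
  out <- list()
  for (g in names(panel$genomes)) {
    out[[g]] <- list()
    for (hap in 1:2) {
      hp <- panel$genomes[[g]][[paste0("hap", hap)]]
      par <- panel_paralog_seeds(panel, g, hap)
      out[[g]][[hap]] <- emit_truth_alignments(
        hp$map, panel$outgroup$map, hp$seqs, panel$outgroup$seqs,
        root_to_anc = panel$fused$map, paralogs = par,
        min_block = min_block)
    }
  }
  out
}
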