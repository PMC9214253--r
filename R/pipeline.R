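# Pipeline orchestration: validate a run configuration, then drive
# simulate -> align -> call -> polarize -> window -> test from a single
# config with one seed, writing every artifact to an output directory.

.CONFIG_DEFAULTS <- list(
  seed = 1L,
  outdir = "flux_run",
  outgroup_id = "outgroup",
  tree = "((gA:0.25,gB:0.25):0.25,gC:0.5);",
  outgroup_branch = 0.5,
  scale = 1,
  window_size = 50000L,
  micro_max = 1e6,
  intermediate_max = 2e6,
  tel_units = 50L,
  min_block = 100L,
  max_gap = 500L,
  alpha = 0.05,
  write_fasta = FALSE,
  stages = c("simulate", "variants", "svs", "spectrum", "windows",
             "numts", "telomeres", "stats"),
  evolution = list(),
  sv = list(),
  numt_search = list()
)

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys raise an
#' error naming the valid ones; defaults fill the gaps; tree tips must
#' not include the outgroup. Validation is idempotent: re-validating
#' the returned config is a no-op.
#'
#' @param config YAML path or named list.
#' @return a `flux_config` list with all defaults applied.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "flux_config")) config <- unclass(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(names(.CONFIG_DEFAULTS), collapse = ", "))
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, config)
  bad_stage <- setdiff(cfg$stages, .CONFIG_DEFAULTS$stages)
  if (length(bad_stage)) stop("unknown stage(s): ",
                              paste(bad_stage, collapse = ", "))
  tree <- ape::read.tree(text = cfg$tree)
  if (is.null(tree)) stop("tree is not valid Newick")
  if (cfg$outgroup_id %in% tree$tip.label) {
    stop("outgroup '", cfg$outgroup_id,
         "' must not be among the focal (tree tip) genomes")
  }
  if (is.null(cfg$seed)) stop("seed is required")
  structure(cfg, class = "flux_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline from a config
#'
#' Deterministic given (config, seed). Writes VCFs, SV catalogs,
#' spectrum tables, the odds-ratio/equilibrium report, window feature
#' tables and state assignments, NUMT and telomere catalogs, a
#' statistics table with its test manifest, and a log, all under
#' `config$outdir`.
#'
#' @param config a [validate_config()] input.
#' @param panel optional pre-built [simulate_panel()] result; when given
#'   the simulate stage uses it (with its own size-class thresholds)
#'   instead of simulating from the config.
#' @return (invisibly) a `flux_run` list with all in-memory results.
#' @export
run_pipeline <- function(config = list(), panel = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$outdir, "log.txt")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))
  res <- list(config = cfg)
  stages <- cfg$stages
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      stop("stage '", stage, "' needs '", what,
           "' but its producing stage was not run")
    }
  }

  # size-class thresholds are stated on the scale-1 karyotype and track
  # the simulated genome size
  size_classes <- if (!is.null(panel)) {
    panel$size_classes
  } else {
    size_class_config(cfg$micro_max * cfg$scale,
                      cfg$intermediate_max * cfg$scale)
  }
  sv_cfg <- do.call(sv_config, cfg$sv)
  numt_cfg <- do.call(numt_search_params, cfg$numt_search)

  if ("simulate" %in% stages) {
    log_line("simulate: building ancestor and evolving panel")
    if (is.null(panel)) {
      evo <- do.call(evolution_params, cfg$evolution)
      panel <- simulate_panel(
        spec = default_ancestor_spec(scale = cfg$scale),
        plan = default_fusion_plan(),
        tree = ape::read.tree(text = cfg$tree),
        params = evo, outgroup_branch = cfg$outgroup_branch,
        outgroup_id = cfg$outgroup_id, tel_units = cfg$tel_units,
        size_classes = size_classes, seed = cfg$seed)
    }
    res$panel <- panel
    res$blocks <- panel_alignments(panel, min_block = cfg$min_block)
    if (isTRUE(cfg$write_fasta)) {
      for (g in names(panel$genomes)) {
        for (hap in 1:2) {
          write_fasta(unlist(panel$genomes[[g]][[paste0("hap", hap)]]$seqs),
                      file.path(cfg$outdir,
                                sprintf("%s_hap%d.fasta", g, hap)))
        }
      }
      write_fasta(unlist(panel$outgroup$seqs),
                  file.path(cfg$outdir, "outgroup.fasta"))
    }
    for (g in names(res$blocks)) {
      for (hap in 1:2) {
        write_coords_table(res$blocks[[g]][[hap]],
                           file.path(cfg$outdir,
                                     sprintf("%s_hap%d.coords", g, hap)))
      }
    }
    write_chrom_sizes(
      data.frame(chrom = names(panel$outgroup$seqs),
                 length = nchar(panel$outgroup$seqs)),
      file.path(cfg$outdir, "outgroup.sizes"))
  }

  genomes <- names(res$panel$genomes)
  og_seqs <- res$panel$outgroup$seqs

  if ("variants" %in% stages) {
    need("blocks", "variants")
    log_line("variants: calling small variants per haplotype")
    res$calls <- list()
    res$callable <- list()
    res$chain_maps <- list()
    for (g in genomes) {
      haps <- lapply(1:2, function(hap) {
        hp <- res$panel$genomes[[g]][[paste0("hap", hap)]]
        call_small_variants(res$blocks[[g]][[hap]], og_seqs, hp$seqs,
                            max_gap = cfg$max_gap)
      })
      dip <- genotype_merge(haps[[1L]]$variants, haps[[2L]]$variants)
      res$calls[[g]] <- list(hap1 = haps[[1L]], hap2 = haps[[2L]],
                             diploid = dip)
      res$chain_maps[[g]] <- lapply(haps, function(h) {
        blocks_to_map(do.call(rbind, h$runs))
      })
      res$callable[[g]] <- .intersect_regions(haps[[1L]]$callable,
                                              haps[[2L]]$callable)
      write_vcf_minimal(dip, cfg$outgroup_id,
                        file.path(cfg$outdir, paste0(g, ".vcf")))
    }
  }

  if ("svs" %in% stages) {
    need("calls", "svs")
    log_line("svs: classifying structural variants")
    cat_rows <- list()
    for (g in genomes) {
      for (hap in 1:2) {
        sv <- classify_svs(res$blocks[[g]][[hap]],
                           runs = res$calls[[g]][[paste0("hap", hap)]]$runs,
                           config = sv_cfg)
        if (nrow(sv)) {
          sv$genome_id <- g
          sv$haplotype <- hap
          cat_rows[[paste(g, hap)]] <- sv
        }
      }
    }
    catalog <- if (length(cat_rows)) {
      do.call(rbind, c(cat_rows, make.row.names = FALSE))
    } else cbind(.empty_svs(), genome_id = character(0),
                 haplotype = integer(0))
    res$sv_catalog <- catalog
    res$sv_private <- private_filter(catalog)
    .write_tsv(res$sv_private, file.path(cfg$outdir, "svs_private.tsv"))
    for (tp in unique(res$sv_private$svtype)) {
      sel <- res$sv_private$svtype == tp
      write_bed(data.frame(chrom = res$sv_private$ref_id[sel],
                           start = res$sv_private$ref_start[sel],
                           end = pmax(res$sv_private$ref_end[sel],
                                      res$sv_private$ref_start[sel] + 1L),
                           name = res$sv_private$genome_id[sel]),
                file.path(cfg$outdir, sprintf("svs_%s.bed", tolower(tp))))
    }
  }

  if ("spectrum" %in% stages) {
    need("calls", "spectrum")
    log_line("spectrum: CpG mask, private variants, odds ratios")
    mask_panel <- list()
    for (g in genomes) {
      for (hap in 1:2) {
        hp <- res$panel$genomes[[g]][[paste0("hap", hap)]]
        mask_panel[[paste(g, hap)]] <-
          list(seqs = hp$seqs, map = res$chain_maps[[g]][[hap]])
      }
    }
    res$cpg_mask <- build_cpg_mask(og_seqs, mask_panel)
    variant_sets <- lapply(res$calls, `[[`, "diploid")
    res$private <- select_private_small_variants(variant_sets,
                                                 res$callable)
    strata <- expand.grid(zyg = c("fixed", "het"),
                          mode = c("with_cpg", "no_cpg"),
                          stringsAsFactors = FALSE)
    or_rows <- list()
    pooled <- do.call(rbind, c(res$private, make.row.names = FALSE))
    for (i in seq_len(nrow(strata))) {
      sp <- tabulate_spectrum(pooled, res$cpg_mask, mode = strata$mode[i],
                              zygosity = strata$zyg[i])
      or <- odds_ratio_test(sp)
      or_rows[[i]] <- data.frame(
        genome = "pooled", zygosity = strata$zyg[i], mode = strata$mode[i],
        n_gc_to_at = or$n_gc_to_at, n_at_to_gc = or$n_at_to_gc,
        or_value = or$or_value, chi2 = or$chi2, p = or$p,
        stringsAsFactors = FALSE)
    }
    eq_rows <- list()
    for (g in genomes) {
      sp <- tabulate_spectrum(res$private[[g]], res$cpg_mask,
                              mode = "with_cpg", zygosity = "fixed")
      if (sp$n_gc_to_at + sp$n_at_to_gc == 0) next
      or <- odds_ratio_test(sp)
      cur_gc <- gc_fraction(paste(unlist(
        res$panel$genomes[[g]]$hap1$seqs), collapse = ""))
      eq <- equilibrium_gc(or, cur_gc)
      or_rows[[length(or_rows) + 1L]] <- data.frame(
        genome = g, zygosity = "fixed", mode = "with_cpg",
        n_gc_to_at = or$n_gc_to_at, n_at_to_gc = or$n_at_to_gc,
        or_value = or$or_value, chi2 = or$chi2, p = or$p,
        stringsAsFactors = FALSE)
      eq_rows[[g]] <- data.frame(
        genome = g, or_value = or$or_value, eq_gc = eq$eq_gc,
        current_gc = cur_gc, delta_pct = eq$delta_pct,
        stringsAsFactors = FALSE)
    }
    res$or_table <- do.call(rbind, c(or_rows, make.row.names = FALSE))
    res$equilibrium <- if (length(eq_rows)) {
      do.call(rbind, c(eq_rows, make.row.names = FALSE))
    } else NULL
    .write_tsv(res$or_table, file.path(cfg$outdir, "odds_ratios.tsv"))
    if (!is.null(res$equilibrium)) {
      .write_tsv(res$equilibrium,
                 file.path(cfg$outdir, "equilibrium_gc.tsv"))
    }
  }

  if ("numts" %in% stages) {
    need("panel", "numts")
    log_line("numts: seed-and-extend search, zygosity, synteny, clusters")
    res$numt_hits <- list()
    all_hits <- list()
    for (g in genomes) {
      tmpl <- prepare_template(res$panel$genomes[[g]]$mito)
      haps <- lapply(1:2, function(hap) {
        hp <- res$panel$genomes[[g]][[paste0("hap", hap)]]
        detect_numts(unlist(hp$seqs), tmpl, numt_cfg)
      })
      maps <- if (!is.null(res$chain_maps[[g]])) res$chain_maps[[g]]
              else list(NULL, NULL)
      hz <- numt_zygosity(haps[[1L]], haps[[2L]], maps[[1L]], maps[[2L]])
      hz$genome_id <- rep(g, nrow(hz))
      res$numt_hits[[g]] <- hz
      all_hits[[g]] <- hz
    }
    pooled <- do.call(rbind, c(all_hits, make.row.names = FALSE))
    if (nrow(pooled)) {
      # haplotype-deduplicated set: fixed insertions once, hets as seen
      dedup <- pooled[!(pooled$zygosity == "fixed" &
                          pooled$haplotype == 2L), , drop = FALSE]
      res$numt_catalog <- numt_synteny(dedup)
      .write_tsv(res$numt_catalog, file.path(cfg$outdir, "numts.tsv"))
      seqs <- vapply(seq_len(nrow(res$numt_catalog)), function(i) {
        h <- res$numt_catalog[i, ]
        hp <- res$panel$genomes[[h$genome_id]][[paste0("hap",
                                                       h$haplotype)]]
        substr(hp$seqs[[h$scaffold]], h$start + 1L, h$end)
      }, "")
      names(seqs) <- sprintf("%s_h%d_%s_%d", res$numt_catalog$genome_id,
                             res$numt_catalog$haplotype,
                             res$numt_catalog$scaffold,
                             res$numt_catalog$start)
      res$numt_clusters <- cluster_numts(seqs, threshold = 0.80)
      .write_tsv(res$numt_clusters,
                 file.path(cfg$outdir, "numt_clusters.tsv"))
    } else {
      res$numt_catalog <- pooled
      res$numt_clusters <- NULL
    }
  }

  if ("telomeres" %in% stages) {
    need("panel", "telomeres")
    log_line("telomeres: scanning for interstitial arrays")
    tel_rows <- list()
    for (g in genomes) {
      hp <- res$panel$genomes[[g]]$hap1
      th <- scan_interstitial_telomeres(unlist(hp$seqs))
      if (nrow(th)) {
        th$genome_id <- g
        tel_rows[[g]] <- th
      }
    }
    res$telomeres <- if (length(tel_rows)) {
      do.call(rbind, c(tel_rows, make.row.names = FALSE))
    } else scan_interstitial_telomeres(character(0))
    if (nrow(res$telomeres)) {
      write_bed(data.frame(chrom = res$telomeres$scaffold,
                           start = res$telomeres$start,
                           end = res$telomeres$end,
                           name = paste0(res$telomeres$genome_id, ":",
                                         res$telomeres$motif),
                           score = res$telomeres$unit_count),
                file.path(cfg$outdir, "telomeres.bed"))
    }
  }

  if ("windows" %in% stages) {
    need("panel", "windows")
    log_line("windows: composition, isochores, chromosome states")
    win_rows <- list()
    for (g in genomes) {
      hp <- res$panel$genomes[[g]]$hap1
      w <- make_windows(vapply(hp$seqs, nchar, 0L), cfg$window_size)
      if (!nrow(w)) next
      w <- window_composition(w, hp$seqs)
      w$isochore <- isochore_family(w$gc_pct)
      own_sizes <- data.frame(chrom = names(hp$seqs),
                              length = vapply(hp$seqs, nchar, 0L),
                              stringsAsFactors = FALSE)
      og_sizes <- data.frame(chrom = names(og_seqs),
                             length = nchar(og_seqs),
                             stringsAsFactors = FALSE)
      blocks <- res$blocks[[g]][[1L]]
      anc <- assign_state(w, list(list(blocks = blocks, sizes = og_sizes)),
                          config = size_classes,
                          min_block = cfg$min_block)
      self_blocks <- map_to_blocks(identity_map(unlist(hp$seqs)))
      cur <- assign_state(w, list(list(blocks = self_blocks,
                                       sizes = own_sizes)),
                          config = size_classes,
                          min_block = cfg$min_block)
      w$anc_state <- anc$state
      w$cur_state <- cur$state
      w$sex_flag <- anc$sex_flag
      # features in focal coordinates
      vars_focal <- NULL
      if (!is.null(res$private[[g]]) && nrow(res$private[[g]])) {
        v <- res$private[[g]]
        lifted <- lift_positions(invert_map(res$chain_maps[[g]][[1L]]),
                                 v$ref_id, v$pos)
        v$chrom <- lifted$chr
        v$fpos <- lifted$pos
        vars_focal <- v[!is.na(v$fpos), , drop = FALSE]
        # direction classes for the window odds ratio
        vars_focal$dir <- ifelse(
          vars_focal$ref %in% c("G", "C") &
            vars_focal$alt %in% c("A", "T"), "gc_at",
          ifelse(vars_focal$ref %in% c("A", "T") &
                   vars_focal$alt %in% c("G", "C"), "at_gc", "other"))
      }
      svs_g <- NULL
      if (!is.null(res$sv_private) && nrow(res$sv_private)) {
        svs_g <- res$sv_private[res$sv_private$genome_id == g &
                                  res$sv_private$haplotype == 1L, ,
                                drop = FALSE]
      }
      repeats_focal <- .lift_repeats(res$panel, g, 1L)
      numts_g <- if (!is.null(res$numt_hits[[g]])) {
        h <- res$numt_hits[[g]]
        h[h$haplotype == 1L, , drop = FALSE]
      } else NULL
      vf <- if (!is.null(vars_focal)) {
        data.frame(chrom = vars_focal$chrom, pos = vars_focal$fpos,
                   ref = vars_focal$ref, alt = vars_focal$alt,
                   vclass = vars_focal$vclass, stringsAsFactors = FALSE)
      } else NULL
      w <- aggregate_features(w, vf, svs_g, repeats_focal, numts_g)
      if (!is.null(vars_focal) && nrow(vars_focal)) {
        snv <- vars_focal[vars_focal$vclass == "SNV", , drop = FALSE]
        n_ga <- .count_in_windows(w, snv$chrom[snv$dir == "gc_at"],
                                  snv$fpos[snv$dir == "gc_at"])
        n_ag <- .count_in_windows(w, snv$chrom[snv$dir == "at_gc"],
                                  snv$fpos[snv$dir == "at_gc"])
        w$n_gc_to_at <- n_ga
        w$n_at_to_gc <- n_ag
        w$or_upper <- window_odds_ratio(n_ga, n_ag)
      } else {
        w$n_gc_to_at <- 0L; w$n_at_to_gc <- 0L
        w$or_upper <- 1
      }
      w$genome_id <- g
      win_rows[[g]] <- w
    }
    res$windows <- do.call(rbind, c(win_rows, make.row.names = FALSE))
    .write_tsv(res$windows, file.path(cfg$outdir, "windows.tsv"))
    write_bed(data.frame(chrom = res$windows$chrom,
                         start = res$windows$start,
                         end = res$windows$end,
                         name = paste0(res$windows$genome_id, ":",
                                       res$windows$anc_state, "|",
                                       res$windows$cur_state)),
              file.path(cfg$outdir, "window_states.bed"))
  }



  if ("stats" %in% stages) {
    need("calls", "stats")
    log_line("stats: balance tests, insertion-bias tests, manifest")
    rows <- list()
    add <- function(label, t) {
      if (is.null(t)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        test = label, method = t$method, statistic = t$statistic,
        p = t$p, estimate = t$estimate %||% NA_real_,
        ci_lo = if (!is.null(t$ci)) t$ci[1L] else NA_real_,
        ci_hi = if (!is.null(t$ci)) t$ci[2L] else NA_real_,
        stringsAsFactors = FALSE)
    }
    for (g in genomes) {
      priv <- res$private[[g]] %||% res$calls[[g]]$diploid
      svp <- if (!is.null(res$sv_private)) {
        res$sv_private[res$sv_private$genome_id == g, , drop = FALSE]
      } else NULL
      ib <- indel_balance(priv, svp)
      add(paste0(g, ":small_indel_count"), ib$small$count_test)
      add(paste0(g, ":small_indel_length"), ib$small$length_test)
      if (!is.null(ib$large)) {
        add(paste0(g, ":large_indel_count"), ib$large$count_test)
      }
    }
    if (!is.null(res$windows) && !is.null(res$numt_catalog) &&
        nrow(res$numt_catalog)) {
      w <- res$windows
      cur_known <- w$cur_state %in% c("micro", "intermediate", "macro")
      anc_known <- w$anc_state %in% c("micro", "intermediate", "macro")
      if (any(cur_known)) {
        p_micro_cur <- mean(w$cur_state[cur_known] == "micro")
        nm <- res$numt_catalog
        numt_cur_micro <- sum(size_class(
          vapply(seq_len(nrow(nm)), function(i) {
            nchar(res$panel$genomes[[nm$genome_id[i]]][[
              paste0("hap", nm$haplotype[i])]]$seqs[[nm$scaffold[i]]])
          }, 0), size_classes) == "micro")
        if (p_micro_cur > 0 && p_micro_cur < 1) {
          add("numt_bias_current",
              insertion_bias_test(numt_cur_micro, nrow(nm), p_micro_cur))
        }
      }
      if (any(anc_known)) {
        p_micro_anc <- mean(w$anc_state[anc_known] == "micro")
        anc_micro_n <- .numts_on_anc_micro(res)
        if (!is.na(anc_micro_n) && p_micro_anc > 0 && p_micro_anc < 1) {
          add("numt_bias_ancestral",
              insertion_bias_test(anc_micro_n, nrow(res$numt_catalog),
                                  p_micro_anc))
        }
      }
    }
    res$stats <- if (length(rows)) {
      do.call(rbind, c(rows, make.row.names = FALSE))
    } else NULL
    m <- length(rows)
    res$alpha_corrected <- dunn_sidak(cfg$alpha, max(m, 1L))
    if (!is.null(res$stats)) {
      res$stats$alpha_corrected <- res$alpha_corrected
      .write_tsv(res$stats, file.path(cfg$outdir, "stats.tsv"))
    }
    writeLines(c(sprintf("tests: %d", m),
                 sprintf("alpha: %g", cfg$alpha),
                 sprintf("alpha_corrected: %.6f", res$alpha_corrected)),
               file.path(cfg$outdir, "test_manifest.txt"))
  }

  log_line("done")
  class(res) <- "flux_run"
  invisible(res)
}

# windows the NUMTs fall in, scored by ancestral state
.numts_on_anc_micro <- function(res) {
  nm <- res$numt_catalog
  w <- res$windows
  n <- 0L
  for (i in seq_len(nrow(nm))) {
    wi <- which(w$genome_id == nm$genome_id[i] &
                  w$chrom == nm$scaffold[i] &
                  w$start <= nm$start[i] & w$end > nm$start[i])
    if (length(wi) && w$anc_state[wi[1L]] == "micro") n <- n + 1L
  }
  n
}

# repeats lifted from ancestor coordinates into one haplotype's
.lift_repeats <- function(panel, genome_id, haplotype) {
  rep_anc <- panel$ancestor$repeats
  if (is.null(rep_anc)) return(NULL)
  hp <- panel$genomes[[genome_id]][[paste0("hap", haplotype)]]
  anc_to_tip <- invert_map(compose_maps(hp$map, panel$fused$map))
  rows <- list()
  for (i in seq_len(nrow(rep_anc))) {
    iv <- .lift_clean(anc_to_tip, rep_anc$chrom[i], rep_anc$start[i],
                      rep_anc$end[i], min_frac = 0.5)
    if (is.null(iv)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = iv$chr, start = iv$start, end = iv$end,
      class = rep_anc$class[i], stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else NULL
}

.intersect_regions <- function(a, b) {
  if (is.null(a) || is.null(b) || !nrow(a) || !nrow(b)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- IRanges::IRanges(a$start[a$chrom == ch] + 1L,
                           a$end[a$chrom == ch])
    ib <- IRanges::IRanges(b$start[b$chrom == ch] + 1L,
                           b$end[b$chrom == ch])
    x <- IRanges::intersect(ia, ib)
    if (length(x)) {
      out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(x) - 1L,
                              end = IRanges::end(x),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), stringsAsFactors = FALSE)
}

#' @export
print.flux_run <- function(x, ...) {
  cat("genomeflux pipeline run\n")
  if (!is.null(x$or_table)) {
    cat("pooled odds ratios:\n")
    print(x$or_table[x$or_table$genome == "pooled",
                     c("zygosity", "mode", "or_value", "chi2")])
  }
  if (!is.null(x$sv_private)) {
    cat(sprintf("private SVs: %d\n", nrow(x$sv_private)))
  }
  if (!is.null(x$numt_catalog)) {
    cat(sprintf("NUMTs (deduplicated): %d\n", nrow(x$numt_catalog)))
  }
  invisible(x)
}
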