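one_chrom_spec <- function(len = 1e6, gc = 0.5, cpg = NA, ...) {
  ancestor_spec(data.frame(chrom = "c1", length = len, gc = gc, cpg = cpg,
                           size_class = "macro", stringsAsFactors = FALSE),
                repeat_density = 0, n_tandem_pairs = 0, ...)
}

test_that("ancestor realizes its GC and CpG targets deterministically", {
  spec <- one_chrom_spec(1e6, 0.5)
  a <- build_ancestor(spec, seed = 21)
  g <- sum(strsplit(a$seqs[["c1"]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_gte(g, 0.49); expect_lte(g, 0.51)
  b <- build_ancestor(spec, seed = 21)
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$mito, b$mito)
  c2 <- build_ancestor(spec, seed = 22)
  expect_false(identical(a$seqs, c2$seqs))
})

test_that("CpG enrichment is realized and impossible targets error", {
  spec <- one_chrom_spec(5e5, 0.5, cpg = 0.09)
  a <- build_ancestor(spec, seed = 3)
  v <- strsplit(a$seqs[["c1"]], "")[[1]]
  n_cg <- sum(v[-length(v)] == "C" & v[-1] == "G")
  expect_gt(n_cg / 5e5, 0.09 * 0.8)
  expect_lt(n_cg / 5e5, 0.09 * 1.2)
  expect_error(build_ancestor(one_chrom_spec(1e5, 0.4, cpg = 0.35),
                              seed = 1), "incompatible")
  expect_error(ancestor_spec(data.frame(chrom = "c", length = 1e5,
                                        gc = 1.0, size_class = "macro")))
})

test_that("fusion arithmetic, identity plan, and junction maps are exact", {
  set.seed(30)
  seqs <- c(a = paste(sample(c("A", "C", "G", "T"), 1e6, TRUE),
                      collapse = ""),
            b = paste(sample(c("A", "C", "G", "T"), 1e6, TRUE),
                      collapse = ""))
  plan <- fusion_plan(junctions = data.frame(a = "a", b = "b",
                                             telomere = TRUE))
  fused <- apply_fusion_plan(seqs, plan, tel_units = 10L)
  expect_equal(nchar(fused$seqs[["a+b"]]), 2000060L)
  expect_equal(fused$junction_telomeres$start, 1000000L)
  expect_equal(fused$junction_telomeres$end, 1000060L)

  # total non-telomere sequence conserved
  expect_equal(nchar(fused$seqs[["a+b"]]) - 60L, sum(nchar(seqs)))

  # map round trip off the junction is the identity
  pos <- c(0L, 999999L, 1000060L, 2000059L)
  anc <- lift_positions(fused$map, "a+b", pos)
  expect_equal(anc$chr, c("a", "a", "b", "b"))
  back <- lift_positions(invert_map(fused$map), anc$chr, anc$pos)
  expect_equal(back$pos, pos)
  # the junction telomere maps nowhere in the ancestor
  expect_true(is.na(lift_positions(fused$map, "a+b", 1000030L)$pos))

  empty <- apply_fusion_plan(seqs, fusion_plan())
  expect_identical(empty$seqs, seqs)
  expect_equal(nrow(empty$map), 2L)

  bad <- fusion_plan(junctions = data.frame(a = "a", b = "zzz"))
  expect_error(apply_fusion_plan(seqs, bad), "unknown scaffold")
})

test_that("translocations move sequence and keep the map a bijection", {
  set.seed(31)
  seqs <- c(a = paste(sample(c("A", "C", "G", "T"), 10000, TRUE),
                      collapse = ""),
            b = paste(sample(c("A", "C", "G", "T"), 8000, TRUE),
                      collapse = ""))
  plan <- fusion_plan(translocations = data.frame(
    src = "a", src_start = 2000L, src_end = 3000L,
    dest = "b", dest_offset = 4000L))
  out <- apply_fusion_plan(seqs, plan)
  expect_equal(nchar(out$seqs[["a"]]), 9000L)
  expect_equal(nchar(out$seqs[["b"]]), 9000L)
  # the moved kilobase reads identically at its new home
  expect_equal(substr(out$seqs[["b"]], 4001, 5000),
               substr(seqs[["a"]], 2001, 3000))
  # every derived base still maps somewhere, and uniquely
  expect_equal(sum(out$map$f_end - out$map$f_start), 18000L)
})

test_that("zero rates leave the descendant identical to the ancestor", {
  spec <- one_chrom_spec(2e5, 0.45)
  a <- build_ancestor(spec, seed = 2)
  p0 <- evolution_params(rate_gc_to_at = 0, rate_at_to_gc = 0,
                         rate_other = 0, indel_rate = 0,
                         sv_rates = c(INS = 0, DEL = 0, INV = 0,
                                      SEGDUP = 0, SEGDEL = 0),
                         numt_rate = 0, het_depth = 0, mito_rate = 0)
  tree <- ape::read.tree(text = "(t1:1,t2:1);")
  ev <- evolve_panel(a$seqs, a$mito, p0, tree, seed = 4)
  expect_identical(ev$tips$t1$hap1$seqs[["c1"]], a$seqs[["c1"]])
  expect_identical(ev$tips$t1$mito, a$mito)
})

test_that("substitution counts realize the u/v ratio and CpG multiplier", {
  spec <- one_chrom_spec(2e6, 0.5)
  a <- build_ancestor(spec, seed = 6)
  p <- evolution_params(rate_gc_to_at = 2e-3, rate_at_to_gc = 1e-3,
                        rate_other = 0, cpg_multiplier = 1,
                        indel_rate = 0,
                        sv_rates = c(INS = 0, DEL = 0, INV = 0,
                                     SEGDUP = 0, SEGDEL = 0),
                        numt_rate = 0, het_depth = 0)
  tree <- ape::read.tree(text = "(t1:1);")
  ev <- evolve_panel(a$seqs, a$mito, p, tree, seed = 7)
  s <- ev$events$t1$snvs
  gc_at <- sum(s$old %in% c(2L, 3L) & s$new %in% c(1L, 4L))
  at_gc <- sum(s$old %in% c(1L, 4L) & s$new %in% c(2L, 3L))
  # expected ratio 2.0 at 50% GC; check within a generous binomial window
  expect_gt(gc_at / at_gc, 1.8)
  expect_lt(gc_at / at_gc, 2.2)

  # CpG multiplier lifts the per-site substitution density ~10x
  p2 <- evolution_params(rate_gc_to_at = 1e-3, rate_at_to_gc = 1e-3,
                         rate_other = 0, cpg_multiplier = 10,
                         indel_rate = 0,
                         sv_rates = c(INS = 0, DEL = 0, INV = 0,
                                      SEGDUP = 0, SEGDEL = 0),
                         numt_rate = 0, het_depth = 0)
  ev2 <- evolve_panel(a$seqs, a$mito, p2, tree, seed = 8)
  s2 <- ev2$events$t1$snvs
  v <- strsplit(a$seqs[["c1"]], "")[[1]]
  cg <- which(v[-length(v)] == "C" & v[-1] == "G")
  n_cpg_sites <- length(unique(c(cg, cg + 1L)))
  n_sites <- length(v)
  dens_cpg <- sum(s2$cpg) / n_cpg_sites
  dens_non <- sum(!s2$cpg) / (n_sites - n_cpg_sites)
  expect_gt(dens_cpg / dens_non, 7)
  expect_lt(dens_cpg / dens_non, 13)
})

test_that("length bookkeeping is conserved through planted indels and SVs", {
  fx <- small_panel()
  panel <- fx$panel
  for (g in names(panel$genomes)) {
    for (hap in 1:2) {
      hp <- panel$genomes[[g]][[paste0("hap", hap)]]
      edges <- getFromNamespace(".path_edges", "genomeflux")(panel, g, hap)
      delta <- 0L
      for (e in edges) {
        ed <- panel$events[[e]]$edits
        if (is.null(ed)) next
        ins <- ed$kind %in% c("SMALL_INS", "INS", "SEGDUP", "NUMT")
        del <- ed$kind %in% c("SMALL_DEL", "DEL", "SEGDEL")
        delta <- delta + sum(ed$length[ins]) - sum(ed$length[del])
      }
      expect_equal(sum(nchar(unlist(hp$seqs))),
                   sum(nchar(panel$fused$seqs)) + delta)
    }
  }
})

test_that("determinism: identical seeds give identical panels", {
  spec <- one_chrom_spec(1e5, 0.45)
  args <- list(spec = spec, plan = NULL,
               tree = ape::read.tree(text = "(x:0.3,y:0.3);"),
               params = evolution_params(), outgroup_branch = 0.2,
               seed = 99)
  p1 <- do.call(simulate_panel, args)
  p2 <- do.call(simulate_panel, args)
  expect_identical(p1$genomes$x$hap1$seqs, p2$genomes$x$hap1$seqs)
  expect_identical(p1$outgroup$seqs, p2$outgroup$seqs)
  expect_identical(p1$events, p2$events)
})

test_that("truth alignments show the planted geometry", {
  set.seed(40)
  seqs <- c(s = paste(sample(c("A", "C", "G", "T"), 50000, TRUE),
                      collapse = ""))
  # identical genomes: a single full-length block
  idm <- identity_map(seqs)
  b <- emit_truth_alignments(idm, idm, seqs, seqs)
  expect_equal(nrow(b), 1L)
  expect_equal(b$ref_end - b$ref_start, 50000L)
  expect_equal(b$identity, 1)

  # one 100 bp insertion: two anchors, qry gap 100, ref gap 0
  ins <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  qry <- c(s = paste0(substr(seqs, 1, 20000), ins, substring(seqs, 20001)))
  qmap <- homology_map(data.frame(
    f_chr = "s", f_start = c(0L, 20100L), f_end = c(20000L, 50100L),
    r_chr = "s", r_start = c(0L, 20000L), r_end = c(20000L, 50000L),
    strand = "+"))
  b2 <- emit_truth_alignments(qmap, idm, qry, seqs)
  expect_equal(nrow(b2), 2L)
  expect_equal(b2$ref_start[2] - b2$ref_end[1], 0L)
  expect_equal(b2$qry_start[2] - b2$qry_end[1], 100L)

  # a planted inversion is written with S2 > E2
  imap <- homology_map(data.frame(
    f_chr = "s", f_start = c(0L, 20000L, 21000L),
    f_end = c(20000L, 21000L, 50000L),
    r_chr = "s", r_start = c(0L, 20000L, 21000L),
    r_end = c(20000L, 21000L, 50000L),
    strand = c("+", "-", "+")))
  qry3 <- seqs
  substr(qry3, 20001, 21000) <- genomeflux::revcomp(substr(seqs, 20001,
                                                           21000))
  names(qry3) <- "s"
  b3 <- emit_truth_alignments(imap, idm, qry3, seqs)
  f <- withr::local_tempfile()
  write_coords_table(b3, f)
  raw <- read.table(f, sep = "\t")
  expect_true(any(raw$V3 > raw$V4))
})
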