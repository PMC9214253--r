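test_that("the CpG mask covers both bases of CG in any panel genome", {
  ref <- c(r = "AACGTTAAAA")            # CG at positions 2,3
  mask <- build_cpg_mask(ref)
  expect_equal(mask$r, c(2L, 3L))

  # a CG present only in one aligned panel genome still masks the site
  qry <- c(q = "AATTTTCGAA")            # CG at q positions 6,7
  map <- homology_map(data.frame(
    f_chr = "q", f_start = 0L, f_end = 10L,
    r_chr = "r", r_start = 0L, r_end = 10L, strand = "+"))
  mask2 <- build_cpg_mask(ref, list(list(seqs = qry, map = map)))
  expect_equal(mask2$r, c(2L, 3L, 6L, 7L))

  # an all-AT panel has an empty mask
  mask3 <- build_cpg_mask(c(r = "ATATATAT"))
  expect_length(mask3$r, 0L)
})

test_that("private selection needs a unique site callable in all genomes", {
  v <- function(pos) data.frame(ref_id = "r", pos = pos, ref = "A",
                                alt = "G", vclass = "SNV",
                                zygosity = "fixed",
                                stringsAsFactors = FALSE)
  callable_all <- list(
    g1 = data.frame(chrom = "r", start = 0L, end = 1000L),
    g2 = data.frame(chrom = "r", start = 0L, end = 1000L),
    g3 = data.frame(chrom = "r", start = 0L, end = 500L))
  sets <- list(g1 = rbind(v(10L), v(700L)), g2 = v(10L), g3 = v(200L))
  out <- select_private_small_variants(sets, callable_all)
  # pos 10 is shared by g1 and g2 -> private to neither
  expect_equal(nrow(out$g1) + 0, 0)   # 700 not callable in g3, 10 shared
  expect_equal(nrow(out$g2), 0L)
  expect_equal(out$g3$pos, 200L)
})

test_that("spectrum tabulation matches a brute-force tally", {
  toy <- data.frame(
    ref_id = "r", pos = c(1L, 5L, 9L, 13L, 17L, 21L),
    ref = c("A", "G", "C", "T", "G", "A"),
    alt = c("G", "A", "T", "C", "T", "T"),
    vclass = "SNV", zygosity = c("fixed", "fixed", "het", "fixed",
                                 "fixed", "het"),
    stringsAsFactors = FALSE)
  sp <- tabulate_spectrum(toy, cpg_mask = NULL, mode = "with_cpg")
  # brute force: count each (anc, derived) pair by hand
  expect_equal(sp$counts["A", "G"], 1L)
  expect_equal(sp$counts["G", "A"], 1L)
  expect_equal(sp$counts["C", "T"], 1L)
  expect_equal(sp$counts["T", "C"], 1L)
  expect_equal(sp$counts["G", "T"], 1L)
  expect_equal(sp$counts["A", "T"], 1L)
  # GC->AT here: G->A, C->T, G->T = 3; AT->GC: A->G, T->C = 2
  expect_equal(sp$n_gc_to_at, 3L)
  expect_equal(sp$n_at_to_gc, 2L)

  fixed <- tabulate_spectrum(toy, NULL, "with_cpg", zygosity = "fixed")
  expect_equal(sum(fixed$counts), 4L)

  # masking removes a variant at a masked site in no_cpg mode
  mask <- list(r = c(5L))
  sp2 <- tabulate_spectrum(toy, mask, "no_cpg")
  expect_equal(sum(sp2$counts), 5L)
  expect_equal(sp2$counts["G", "A"], 0L)
})

test_that("odds ratio and chi-square follow their closed forms", {
  sp <- list(n_gc_to_at = 20, n_at_to_gc = 10)
  res <- odds_ratio_test(sp)
  expect_equal(res$or_value, 2)
  expect_equal(res$chi2, (20 - 10)^2 / 30, tolerance = 1e-12)
  expect_equal(res$p, pchisq(res$chi2, 1, lower.tail = FALSE))

  eq <- odds_ratio_test(list(n_gc_to_at = 15, n_at_to_gc = 15))
  expect_equal(eq$or_value, 1)
  expect_equal(eq$chi2, 0)

  # counts on a genome-wide scale reproduce the published falcon ratio
  big <- odds_ratio_test(list(n_gc_to_at = 62000, n_at_to_gc = 44740))
  expect_equal(round(big$or_value, 3), 1.386)

  zero <- odds_ratio_test(list(n_gc_to_at = 0, n_at_to_gc = 9))
  expect_true(zero$pseudocount)
  expect_equal(zero$or_value, 0.1)
})

test_that("equilibrium GC follows 1/(1+OR) and is monotone in OR", {
  expect_equal(equilibrium_gc(1)$eq_gc, 0.5)
  expect_equal(round(equilibrium_gc(1.386)$eq_gc, 4), 0.4191)
  expect_lt(equilibrium_gc(1e6)$eq_gc, 1e-5)
  ors <- c(0.5, 0.9, 1, 1.2, 2, 5)
  eqs <- vapply(ors, function(o) equilibrium_gc(o)$eq_gc, 0)
  expect_true(all(diff(eqs) < 0))
  res <- equilibrium_gc(1.5, current_gc = 0.42)
  expect_equal(res$delta_pct, (1 / 2.5 - 0.42) * 100)
})

test_that("window odds ratio adds one substitution of each type", {
  expect_equal(window_odds_ratio(0, 0), 1)
  expect_equal(window_odds_ratio(9, 4), 2)
  expect_equal(window_odds_ratio(0, 99), 0.01)
})

test_that("indel balance reports counts, lengths and an exact binomial p", {
  v <- data.frame(
    ref_id = "r", pos = seq_len(100) * 10L,
    ref = c(rep("A", 60), vapply(1:40, function(i) {
      paste0("A", strrep("T", 1 + i %% 3))
    }, "")),
    alt = c(vapply(1:60, function(i) {
      paste0("A", strrep("C", 1 + i %% 4))
    }, ""), rep("A", 40)),
    vclass = c(rep("INS", 60), rep("DEL", 40)),
    stringsAsFactors = FALSE)
  ib <- indel_balance(v)
  expect_equal(ib$small$n_ins, 60L)
  expect_equal(ib$small$n_del, 40L)
  d <- dbinom(0:100, 100, 0.5)
  p_oracle <- sum(d[d <= d[61] * (1 + 1e-7)])
  expect_equal(ib$small$count_test$p, p_oracle, tolerance = 1e-9)

  none <- indel_balance(v[0, , drop = FALSE])
  expect_null(none$small$count_test)
  expect_equal(none$small$n_ins, 0L)
})

test_that("shared variants land on the edge matching their carrier set", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  carriers <- list(c("A", "B"), c("A", "B", "C"), c("A", "C"), "A")
  res <- branch_shared_counts(tree, carriers,
                              c("SNV", "SNV", "DEL", "INS"))
  bc <- res$branch_counts
  expect_equal(bc$n_snv[bc$clade == "A|B"], 1L)
  # a variant in every tip sits on the root edge
  expect_equal(bc$n_snv[bc$edge == "root"], 1L)
  expect_equal(bc$n_ins[bc$clade == "A"], 1L)
  expect_equal(sum(bc$n_del), 0L)   # {A,C} matches no clade
  expect_equal(res$n_homoplastic, 1L)
  # conservation: assigned + homoplastic = total
  expect_equal(sum(bc$n_snv, bc$n_del, bc$n_ins) + res$n_homoplastic,
               length(carriers))
  expect_error(branch_shared_counts(tree, list("Z"), "SNV"), "unknown tip")
})
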