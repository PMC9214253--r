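# Shared fixtures: a small simulated panel (built once per test run) and
# SV call/truth matching used by the recovery tests.

.fixture_env <- new.env(parent = emptyenv())

small_panel <- function() {
  if (is.null(.fixture_env$panel)) {
    ch <- data.frame(chrom = c("A", "B"),
                     length = c(400000L, 100000L),
                     gc = c(0.42, 0.50), cpg = c(NA, NA),
                     size_class = c("macro", "micro"),
                     stringsAsFactors = FALSE)
    spec <- ancestor_spec(ch, repeat_density = 0.05, n_tandem_pairs = 6,
                          telomere_units = 10, mito_length = 4000)
    plan <- fusion_plan(junctions = data.frame(a = "A", b = "B",
                                               telomere = TRUE,
                                               stringsAsFactors = FALSE))
    tree <- ape::read.tree(text = "(g1:0.3,g2:0.3);")
    p <- evolution_params(
      indel_rate = 2e-5,
      sv_rates = c(INS = 4e-5, DEL = 4e-5, INV = 4e-5,
                   SEGDUP = 4e-5, SEGDEL = 3e-5),
      numt_rate = 1e-5, het_depth = 0.05)
    panel <- simulate_panel(spec = spec, plan = plan, tree = tree,
                            params = p, outgroup_branch = 0.3,
                            size_classes = size_class_config(2e5, 3e5),
                            seed = 5)
    .fixture_env$panel <- panel
    .fixture_env$blocks <- panel_alignments(panel)
  }
  list(panel = .fixture_env$panel, blocks = .fixture_env$blocks)
}

# panel whose outgroup branch has length 0 (reference = ancestor), so
# every reference/query difference is a planted focal event and call
# sets can be compared to truth exactly
truth_panel <- function() {
  if (is.null(.fixture_env$tpanel)) {
    ch <- data.frame(chrom = c("A", "B"),
                     length = c(300000L, 100000L),
                     gc = c(0.42, 0.50), cpg = c(NA, NA),
                     size_class = c("macro", "micro"),
                     stringsAsFactors = FALSE)
    spec <- ancestor_spec(ch, repeat_density = 0.05, n_tandem_pairs = 4,
                          telomere_units = 10, mito_length = 4000)
    plan <- fusion_plan(junctions = data.frame(a = "A", b = "B",
                                               telomere = TRUE,
                                               stringsAsFactors = FALSE))
    panel <- simulate_panel(
      spec = spec, plan = plan,
      tree = ape::read.tree(text = "(g1:0.3,g2:0.3);"),
      params = evolution_params(
        indel_rate = 2e-5,
        sv_rates = c(INS = 3e-5, DEL = 3e-5, INV = 3e-5,
                     SEGDUP = 3e-5, SEGDEL = 2e-5),
        numt_rate = 1e-5, het_depth = 0.05),
      outgroup_branch = 0,
      size_classes = size_class_config(2e5, 3e5), seed = 17)
    .fixture_env$tpanel <- panel
    .fixture_env$tblocks <- panel_alignments(panel)
  }
  list(panel = .fixture_env$tpanel, blocks = .fixture_env$tblocks)
}

# match SV calls against the planted truth by type and locus overlap
# (with tolerance); sub-detectable segmental events are accepted as the
# plain indel call they necessarily produce
match_svs <- function(calls, truth, tol = 50, min_block = 100) {
  used <- rep(FALSE, nrow(calls))
  hit <- rep(FALSE, nrow(truth))
  pass <- function(truth_type, call_type, sel_truth) {
    for (i in which(sel_truth & !hit)) {
      ts <- truth$ref_start[i] - tol
      te <- max(truth$ref_end[i], truth$ref_start[i]) + tol
      cand <- which(!used & calls$svtype == call_type &
                      calls$ref_id == truth$ref_id[i] &
                      calls$ref_start < te &
                      pmax(calls$ref_end, calls$ref_start) > ts)
      if (length(cand)) {
        used[cand[1L]] <<- TRUE
        hit[i] <<- TRUE
      }
    }
  }
  for (tp in c("INS", "DEL", "INV", "SEGDUP", "SEGDEL")) {
    pass(tp, tp, truth$svtype == tp)
  }
  # a tandem gain/loss below the aligner's minimum block length cannot
  # show the multi-block geometry; it is correctly reported as INS/DEL
  pass("SEGDUP", "INS",
       truth$svtype == "SEGDUP" & truth$length_bp < min_block)
  pass("SEGDEL", "DEL",
       truth$svtype == "SEGDEL" & truth$length_bp < min_block)
  # detectable = long enough for its own anchor geometry to survive the
  # aligner's minimum block length
  detectable <- truth$length_bp >= min_block |
    truth$svtype %in% c("INS", "DEL")
  list(hit = hit, used = used, detectable = detectable)
}

variant_key <- function(v) paste(v$ref_id, v$pos, v$ref, v$alt)
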