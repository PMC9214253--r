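# Chromosomal fusions and translocations applied to the ancestral
# karyotype: the derived (ingroup) lineage concatenates chromosomes with
# tandem TTAGGG arrays at the junctions, leaving a coordinate map back to
# the ancestor that is a bijection everywhere outside the inserted
# telomere arrays.

#' Specify a fusion / translocation plan
#'
#' @param junctions data.frame with columns `a`, `b` (scaffold ids to
#'   join, `a` first) and `telomere` (logical: insert a junction telomere
#'   array). Later junctions may reference the product of earlier ones by
#'   its fused id `<a>+<b>`.
#' @param translocations optional data.frame with columns `src`,
#'   `src_start`, `src_end`, `dest`, `dest_offset` (applied after all
#'   junctions, in the coordinates of the fused karyotype).
#' @return a `fusion_plan` list.
#' @export
fusion_plan <- function(junctions = NULL, translocations = NULL) {
  if (!is.null(junctions)) {
    stopifnot(all(c("a", "b") %in% names(junctions)))
    if (is.null(junctions$telomere)) junctions$telomere <- TRUE
    used <- c(junctions$a, junctions$b)
  }
  structure(list(junctions = junctions, translocations = translocations),
            class = "fusion_plan")
}

fused_id <- function(a, b) paste0(a, "+", b)

#' Apply a fusion plan to a genome
#'
#' Total non-telomere sequence is conserved; junction arrays are tandem
#' TTAGGG units recorded in the returned `junction_telomeres`; the
#' returned homology map (fused -> ancestor) is a bijection outside the
#' inserted arrays.
#'
#' @param seqs named character vector of ancestral scaffolds.
#' @param plan a [fusion_plan()].
#' @param tel_units TTAGGG copies inserted at each flagged junction.
#' @return list with `seqs` (fused karyotype), `map` (a [homology_map()]
#'   from fused to ancestral coordinates), `junction_telomeres`
#'   (data.frame of inserted arrays in fused coordinates).
#' @export
apply_fusion_plan <- function(seqs, plan, tel_units = 50L) {
  stopifnot(inherits(plan, "fusion_plan"))
  cur <- as.list(seqs)
  map <- identity_map(seqs)
  tel_seq <- strrep(TELOMERE_UNIT, tel_units)
  tel_len <- nchar(tel_seq)
  junc <- NULL
  jn <- plan$junctions
  if (!is.null(jn)) {
    for (i in seq_len(nrow(jn))) {
      a <- jn$a[i]; b <- jn$b[i]
      if (!a %in% names(cur)) stop("unknown scaffold in fusion plan: ", a)
      if (!b %in% names(cur)) stop("unknown scaffold in fusion plan: ", b)
      if (a == b) stop("cannot fuse a scaffold to itself")
      with_tel <- isTRUE(jn$telomere[i]) && tel_len > 0L
      len_a <- nchar(cur[[a]])
      ins <- if (with_tel) tel_seq else ""
      newid <- fused_id(a, b)
      newseq <- paste0(cur[[a]], ins, cur[[b]])
      shift_b <- len_a + nchar(ins)
      sel_a <- map$f_chr == a
      sel_b <- map$f_chr == b
      map$f_chr[sel_a | sel_b] <- newid
      map$f_start[sel_b] <- map$f_start[sel_b] + shift_b
      map$f_end[sel_b] <- map$f_end[sel_b] + shift_b
      if (!is.null(junc)) {
        on_b <- junc$chrom == b
        junc$start[on_b] <- junc$start[on_b] + shift_b
        junc$end[on_b] <- junc$end[on_b] + shift_b
        junc$chrom[junc$chrom %in% c(a, b)] <- newid
      }
      if (with_tel) {
        junc <- rbind(junc, data.frame(
          chrom = newid, start = len_a, end = len_a + tel_len,
          units = as.integer(tel_units), stringsAsFactors = FALSE))
      }
      cur[[newid]] <- newseq
      cur[[a]] <- NULL
      cur[[b]] <- NULL
    }
  }
  tr <- plan$translocations
  if (!is.null(tr)) {
    for (i in seq_len(nrow(tr))) {
      src <- tr$src[i]; dst <- tr$dest[i]
      s <- as.integer(tr$src_start[i]); e <- as.integer(tr$src_end[i])
      off <- as.integer(tr$dest_offset[i])
      if (!src %in% names(cur)) stop("unknown scaffold: ", src)
      if (!dst %in% names(cur)) stop("unknown scaffold: ", dst)
      stopifnot(s >= 0, e > s, e <= nchar(cur[[src]]),
                off >= 0, off <= nchar(cur[[dst]]), src != dst)
      seg <- substr(cur[[src]], s + 1L, e)
      cur[[src]] <- paste0(substr(cur[[src]], 1L, s),
                           substring(cur[[src]], e + 1L))
      cur[[dst]] <- paste0(substr(cur[[dst]], 1L, off), seg,
                           substring(cur[[dst]], off + 1L))
      L <- e - s
      # map surgery: split at boundaries, move the segment's pieces
      df <- as.data.frame(map)
      for (ch in c(src, dst)) {
        cuts <- if (ch == src) c(s, e) else off
        sel <- df$f_chr == ch
        part <- .split_pieces(df[sel, , drop = FALSE], cuts)
        df <- rbind(df[!sel, , drop = FALSE], part)
      }
      inside <- df$f_chr == src & df$f_start >= s & df$f_end <= e
      after_src <- df$f_chr == src & df$f_start >= e
      after_dst <- df$f_chr == dst & df$f_start >= off
      df$f_start[after_src] <- df$f_start[after_src] - L
      df$f_end[after_src] <- df$f_end[after_src] - L
      df$f_start[after_dst] <- df$f_start[after_dst] + L
      df$f_end[after_dst] <- df$f_end[after_dst] + L
      df$f_start[inside] <- df$f_start[inside] - s + off
      df$f_end[inside] <- df$f_end[inside] - s + off
      df$f_chr[inside] <- dst
      map <- homology_map(df)
    }
  }
  out <- unlist(cur)
  list(seqs = out, map = homology_map(as.data.frame(map)),
       junction_telomeres = junc)
}
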