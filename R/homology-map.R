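# Homology maps: piecewise interval bijections between two genomes.
#
# A map is a data.frame with columns
#   f_chr, f_start, f_end   focal-side interval (0-based half-open)
#   r_chr, r_start, r_end   partner-side interval
#   strand                  "+" or "-"
# Every piece is gapless (equal lengths on both sides); pieces never
# overlap on either side. On strand "-" ascending focal positions pair
# with descending partner positions:
#   x in [f_start, f_end)  <->  r_end - 1 - (x - f_start).

#' Construct and validate a homology map
#'
#' @param df data.frame with the map columns described above.
#' @return the validated, focal-sorted map.
#' @export
homology_map <- function(df) {
  need <- c("f_chr", "f_start", "f_end", "r_chr", "r_start", "r_end", "strand")
  stopifnot(all(need %in% names(df)))
  df <- df[need]
  if (nrow(df)) {
    stopifnot(all(df$f_end > df$f_start), all(df$r_end > df$r_start),
              all(df$strand %in% c("+", "-")))
    if (any((df$f_end - df$f_start) != (df$r_end - df$r_start))) {
      stop("homology map pieces must be gapless (equal lengths)")
    }
    if (.intervals_overlap(df$f_chr, df$f_start, df$f_end) ||
        .intervals_overlap(df$r_chr, df$r_start, df$r_end)) {
      stop("homology map pieces overlap on one side")
    }
    df <- df[order(df$f_chr, df$f_start), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("homology_map", "data.frame")
  df
}

.intervals_overlap <- function(chr, start, end) {
  o <- order(chr, start)
  chr <- chr[o]; start <- start[o]; end <- end[o]
  n <- length(chr)
  if (n < 2L) return(FALSE)
  same <- chr[-n] == chr[-1L]
  any(same & end[-n] > start[-1L])
}

#' Invert a homology map
#' @param map a [homology_map()].
#' @return the map with focal and partner sides swapped.
#' @export
invert_map <- function(map) {
  homology_map(data.frame(
    f_chr = map$r_chr, f_start = map$r_start, f_end = map$r_end,
    r_chr = map$f_chr, r_start = map$f_start, r_end = map$f_end,
    strand = map$strand, stringsAsFactors = FALSE
  ))
}

#' Lift single positions through a homology map
#'
#' @param map a [homology_map()].
#' @param chr,pos vectors of focal scaffold ids and 0-based positions.
#' @return data.frame `chr, pos, strand` of partner coordinates; `NA`
#'   rows for positions not covered by any piece.
#' @export
lift_positions <- function(map, chr, pos) {
  n <- length(pos)
  chr <- rep_len(chr, n)
  out_chr <- rep(NA_character_, n)
  out_pos <- rep(NA_integer_, n)
  out_str <- rep(NA_character_, n)
  for (ch in unique(chr)) {
    m <- map[map$f_chr == ch, , drop = FALSE]
    sel <- which(chr == ch)
    if (!nrow(m)) next
    idx <- findInterval(pos[sel], m$f_start)
    ok <- idx >= 1L & pos[sel] < m$f_end[pmax(idx, 1L)]
    hit <- sel[ok]; pidx <- idx[ok]
    off <- pos[hit] - m$f_start[pidx]
    fwd <- m$strand[pidx] == "+"
    out_chr[hit] <- m$r_chr[pidx]
    out_pos[hit] <- ifelse(fwd, m$r_start[pidx] + off,
                           m$r_end[pidx] - 1L - off)
    out_str[hit] <- m$strand[pidx]
  }
  data.frame(chr = out_chr, pos = out_pos, strand = out_str,
             stringsAsFactors = FALSE)
}

#' Lift an interval through a homology map
#'
#' The interval is mapped through every covering piece. Full coverage by
#' one piece gives a single unflagged result; coverage of only part of the
#' interval sets `partial`; coverage split over several pieces returns one
#' row per piece with `split = TRUE` (never silently merged). An
#' uncovered interval returns zero rows.
#'
#' @param map a [homology_map()].
#' @param chr,start,end a focal interval (0-based half-open).
#' @return data.frame `chr, start, end, strand, partial, split` in partner
#'   coordinates.
#' @export
lift_interval <- function(map, chr, start, end) {
  stopifnot(length(chr) == 1L, end > start)
  m <- map[map$f_chr == chr & map$f_start < end & map$f_end > start, ,
           drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(chr = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      partial = logical(0), split = logical(0)))
  }
  fs <- pmax(m$f_start, start)
  fe <- pmin(m$f_end, end)
  fwd <- m$strand == "+"
  rs <- ifelse(fwd, m$r_start + (fs - m$f_start),
               m$r_start + (m$f_end - fe))
  re <- rs + (fe - fs)
  covered <- sum(fe - fs)
  data.frame(chr = m$r_chr, start = as.integer(rs), end = as.integer(re),
             strand = m$strand,
             partial = covered < (end - start),
             split = nrow(m) > 1L,
             stringsAsFactors = FALSE)
}

#' Compose two homology maps
#'
#' `a` maps genome X to genome Y and `b` maps Y to Z; the result maps X to
#' Z through the intersection of the shared Y intervals. Material of X
#' without a Y image in `b` (and vice versa) is simply absent from the
#' result.
#'
#' @param a,b [homology_map()]s with `a`'s partner genome equal to `b`'s
#'   focal genome.
#' @return a [homology_map()] from X to Z.
#' @export
compose_maps <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(homology_map(empty_map()))
  chrs <- intersect(unique(a$r_chr), unique(b$f_chr))
  pieces <- vector("list", length(chrs))
  for (k in seq_along(chrs)) {
    ch <- chrs[k]
    ai <- a[a$r_chr == ch, , drop = FALSE]
    bi <- b[b$f_chr == ch, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(ai$r_start + 1L, ai$r_end),
      IRanges::IRanges(bi$f_start + 1L, bi$f_end)
    )
    if (!length(ov)) next
    ia <- S4Vectors::queryHits(ov); ib <- S4Vectors::subjectHits(ov)
    ys <- pmax(ai$r_start[ia], bi$f_start[ib])
    ye <- pmin(ai$r_end[ia], bi$f_end[ib])
    len <- ye - ys
    a_fwd <- ai$strand[ia] == "+"
    xs <- ifelse(a_fwd, ai$f_start[ia] + (ys - ai$r_start[ia]),
                 ai$f_start[ia] + (ai$r_end[ia] - ye))
    b_fwd <- bi$strand[ib] == "+"
    zs <- ifelse(b_fwd, bi$r_start[ib] + (ys - bi$f_start[ib]),
                 bi$r_start[ib] + (bi$f_end[ib] - ye))
    pieces[[k]] <- data.frame(
      f_chr = ai$f_chr[ia], f_start = as.integer(xs),
      f_end = as.integer(xs + len),
      r_chr = bi$r_chr[ib], r_start = as.integer(zs),
      r_end = as.integer(zs + len),
      strand = ifelse(a_fwd == b_fwd, "+", "-"),
      stringsAsFactors = FALSE
    )
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(homology_map(empty_map()))
  homology_map(do.call(rbind, pieces))
}

empty_map <- function() {
  data.frame(f_chr = character(0), f_start = integer(0), f_end = integer(0),
             r_chr = character(0), r_start = integer(0), r_end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Identity homology map for a genome
#' @param seqs named character vector of scaffold sequences, or a named
#'   numeric vector of scaffold lengths.
#' @return a [homology_map()] mapping each scaffold onto itself.
#' @export
identity_map <- function(seqs) {
  lens <- if (is.character(seqs)) nchar(seqs) else seqs
  homology_map(data.frame(
    f_chr = names(lens), f_start = 0L, f_end = as.integer(lens),
    r_chr = names(lens), r_start = 0L, r_end = as.integer(lens),
    strand = "+", stringsAsFactors = FALSE
  ))
}

#' Convert alignment blocks to a homology map (query as focal side)
#'
#' Only gapless blocks (`len1 == len2`, or missing length columns with
#' equal interval widths) can form map pieces; others raise an error.
#'
#' @param blocks alignment block data.frame from [read_coords_table()].
#' @return a [homology_map()] from query to reference coordinates.
#' @export
blocks_to_map <- function(blocks) {
  w_ref <- blocks$ref_end - blocks$ref_start
  w_qry <- blocks$qry_end - blocks$qry_start
  if (any(w_ref != w_qry)) stop("gapped blocks cannot form a homology map")
  homology_map(data.frame(
    f_chr = blocks$qry_id, f_start = blocks$qry_start,
    f_end = blocks$qry_end,
    r_chr = blocks$ref_id, r_start = blocks$ref_start,
    r_end = blocks$ref_end,
    strand = blocks$strand, stringsAsFactors = FALSE
  ))
}

#' Convert a homology map to alignment blocks (focal side as query)
#' @param map a [homology_map()].
#' @param identity identity value to attach to every block.
#' @return alignment block data.frame.
#' @export
map_to_blocks <- function(map, identity = 1) {
  data.frame(
    ref_id = map$r_chr, ref_start = map$r_start, ref_end = map$r_end,
    qry_id = map$f_chr, qry_start = map$f_start, qry_end = map$f_end,
    strand = map$strand, identity = identity,
    len1 = map$r_end - map$r_start, len2 = map$f_end - map$f_start,
    stringsAsFactors = FALSE
  )
}
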