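# Internal edit machinery shared by the simulator: apply a set of
# non-overlapping sequence edits (deletions, insertions, inversions) to
# one scaffold while keeping its homology map (current -> root space)
# a total bijection. Inserted material is mapped to fresh virtual root
# scaffolds so every current base always has root coordinates.

# an edit is a list(pos, del_len, inv_len, ins (int vector), vchr, kind, id)
# pos is 0-based in pre-edit coordinates; del/ins/inv are mutually
# exclusive kinds.

.edit_interval <- function(e) {
  w <- max(e$del_len, e$inv_len)
  c(e$pos, e$pos + w)
}

.edits_overlap <- function(edits, margin = 0L) {
  if (length(edits) < 2L) return(FALSE)
  iv <- t(vapply(edits, .edit_interval, numeric(2)))
  # treat a pure insertion point as width 1 so it cannot sit inside a
  # deletion or inversion interval
  iv[, 2L] <- pmax(iv[, 2L], iv[, 1L] + 1L) + margin
  o <- order(iv[, 1L])
  any(iv[o, 2L][-nrow(iv)] > iv[o, 1L][-1L])
}

# split pieces of one scaffold's map at the given 0-based positions
.split_pieces <- function(p, cuts) {
  cuts <- sort(unique(cuts))
  for (cut in cuts) {
    i <- which(p$f_start < cut & p$f_end > cut)
    if (!length(i)) next
    a <- p[i, , drop = FALSE]; b <- a
    off <- cut - a$f_start
    a$f_end <- cut
    b$f_start <- cut
    if (a$strand == "+") {
      a$r_end <- a$r_start + off
      b$r_start <- a$r_end
    } else {
      a$r_start <- a$r_end - off
      b$r_end <- a$r_start
    }
    p <- rbind(p[-i, , drop = FALSE], a, b)
    p <- p[order(p$f_start), , drop = FALSE]
  }
  p
}

# apply sorted, non-overlapping edits to (seq, pieces); returns
# list(seq, pieces, edits) where each edit gains new_start/new_end
# (post-edit coordinates of the affected/inserted segment)
apply_edits <- function(seq, pieces, edits) {
  if (!length(edits)) {
    return(list(seq = seq, pieces = pieces, edits = edits))
  }
  if (.edits_overlap(edits)) stop("internal: overlapping edits")
  ord <- order(vapply(edits, function(e) e$pos, 0))
  edits <- edits[ord]
  cuts <- unlist(lapply(edits, .edit_interval))
  pieces <- .split_pieces(pieces, cuts)

  seg_seq <- list()
  out_pieces <- list()
  cur <- 0L       # 0-based cursor in old coords
  offset <- 0L    # new minus old
  k <- 0L
  take_pieces <- function(a, b, shift) {
    sel <- pieces$f_start >= a & pieces$f_end <= b
    pp <- pieces[sel, , drop = FALSE]
    if (nrow(pp)) {
      pp$f_start <- pp$f_start + shift
      pp$f_end <- pp$f_end + shift
    }
    pp
  }
  for (e in edits) {
    # untouched segment [cur, e$pos)
    if (e$pos > cur) {
      k <- k + 1L; seg_seq[[k]] <- seq[(cur + 1L):e$pos]
      out_pieces[[length(out_pieces) + 1L]] <- take_pieces(cur, e$pos, offset)
    }
    if (e$del_len > 0L) {
      e$new_start <- e$pos + offset
      e$new_end <- e$new_start           # zero-width in new coords
      cur <- e$pos + e$del_len
      offset <- offset - e$del_len
    } else if (e$inv_len > 0L) {
      a <- e$pos; b <- e$pos + e$inv_len
      k <- k + 1L; seg_seq[[k]] <- revcomp_int(seq[(a + 1L):b])
      pp <- take_pieces(a, b, 0L)
      if (nrow(pp)) {
        new_fs <- (a + offset) + (b - pp$f_end)
        pp$f_end <- new_fs + (pp$f_end - pp$f_start)
        pp$f_start <- new_fs
        pp$strand <- ifelse(pp$strand == "+", "-", "+")
      }
      out_pieces[[length(out_pieces) + 1L]] <- pp
      e$new_start <- a + offset
      e$new_end <- b + offset
      cur <- b
    } else {                              # insertion
      L <- length(e$ins)
      k <- k + 1L; seg_seq[[k]] <- e$ins
      e$new_start <- e$pos + offset
      e$new_end <- e$new_start + L
      out_pieces[[length(out_pieces) + 1L]] <- data.frame(
        f_chr = pieces$f_chr[1L] %||% NA_character_,
        f_start = e$new_start, f_end = e$new_end,
        r_chr = e$vchr, r_start = 0L, r_end = L,
        strand = "+", stringsAsFactors = FALSE)
      cur <- e$pos
      offset <- offset + L
    }
    edits[[match(e$id, vapply(edits, `[[`, 0L, "id"))]] <- e
  }
  n <- length(seq)
  if (cur < n) {
    k <- k + 1L; seg_seq[[k]] <- seq[(cur + 1L):n]
    out_pieces[[length(out_pieces) + 1L]] <- take_pieces(cur, n, offset)
  }
  new_pieces <- do.call(rbind, out_pieces)
  new_pieces <- new_pieces[order(new_pieces$f_start), , drop = FALSE]
  rownames(new_pieces) <- NULL
  list(seq = unlist(seg_seq, use.names = FALSE),
       pieces = new_pieces, edits = edits)
}

new_edit <- function(id, pos, kind, del_len = 0L, inv_len = 0L,
                     ins = integer(0), vchr = NA_character_, meta = NULL) {
  list(id = id, pos = as.integer(pos), kind = kind,
       del_len = as.integer(del_len), inv_len = as.integer(inv_len),
       ins = ins, vchr = vchr, meta = meta,
       new_start = NA_integer_, new_end = NA_integer_)
}
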