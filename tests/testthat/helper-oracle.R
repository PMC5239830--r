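# Independent oracles used to check the implementation: a di-base
# transition table built literally from the pairing rule, and a
# brute-force aligner that scans every reference offset, strand and
# ladder length with no indexing or shortcuts.

.ORACLE_BASES <- c("A", "C", "G", "T")

oracle_color_table <- function() {
  tb <- matrix(NA_integer_, 4, 4, dimnames = list(.ORACLE_BASES, .ORACLE_BASES))
  same_code <- function(x, y, pairs) {
    any(vapply(pairs, function(p) setequal(p, c(x, y)), TRUE))
  }
  for (x in .ORACLE_BASES) for (y in .ORACLE_BASES) {
    tb[x, y] <-
      if (x == y) 0L
      else if (same_code(x, y, list(c("A", "C"), c("G", "T")))) 1L
      else if (same_code(x, y, list(c("A", "G"), c("C", "T")))) 2L
      else 3L  # complementary pair
  }
  tb
}

oracle_encode <- function(s, primer) {
  tb <- oracle_color_table()
  ch <- strsplit(s, "")[[1]]
  prev <- primer
  out <- integer(length(ch))
  for (i in seq_along(ch)) {
    out[i] <- tb[prev, ch[i]]
    prev <- ch[i]
  }
  paste(out, collapse = "")
}

oracle_decode <- function(primer, colors) {
  tb <- oracle_color_table()
  d <- as.integer(strsplit(colors, "")[[1]])
  prev <- primer
  out <- character(length(d))
  for (i in seq_along(d)) {
    out[i] <- .ORACLE_BASES[which(tb[prev, ] == d[i])]
    prev <- out[i]
  }
  paste(out, collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

random_dna <- function(n) paste(sample(.ORACLE_BASES, n, TRUE), collapse = "")

# Brute-force alignment of one read: every reference, both strands,
# every offset, ladder lengths in order, stop at the first length with
# any placement; rank (mismatches, ref id C-locale, position, + strand
# first) and keep k.
oracle_align_read <- function(read, refs, max_mm = 2, k = 1,
                              schedule) {
  colorspace <- is.list(read)
  tb <- oracle_color_table()
  n <- if (colorspace) nchar(read$colors) else nchar(read)
  if (n < schedule$min_length) return(list(records = NULL, status = "too_short"))
  ladder <- if (n == schedule$initial_length) schedule$lengths
            else c(n, schedule$lengths[schedule$lengths < n])
  rc_full <- if (colorspace) as.integer(strsplit(read$colors, "")[[1]])
             else match(strsplit(read, "")[[1]], .ORACLE_BASES)
  # precompute per (ref, strand): base indices, internal colors, primer column
  strands <- list()
  for (rid in names(refs)) {
    for (st in c("+", "-")) {
      s <- if (st == "+") refs[[rid]] else oracle_revcomp(refs[[rid]])
      b <- match(strsplit(s, "")[[1]], .ORACLE_BASES)
      L <- length(b)
      entry <- list(ref_id = rid, strand = st, L = L, b = b)
      if (colorspace) {
        entry$colvec <- if (L > 1) tb[cbind(b[-L], b[-1])] else integer(0)
        entry$pcol <- tb[read$primer, .ORACLE_BASES][b]
      }
      strands[[paste(rid, st)]] <- entry
    }
  }
  for (step in seq_along(ladder) - 1L) {
    m <- ladder[step + 1]
    rc <- rc_full[1:m]
    hits <- list()
    for (e in strands) {
      if (e$L < m) next
      for (q in seq_len(e$L - m + 1)) {
        mm <- if (colorspace) {
          (rc[1] != e$pcol[q]) +
            (if (m > 1) sum(rc[-1] != e$colvec[q:(q + m - 2)]) else 0)
        } else {
          sum(rc != e$b[q:(q + m - 1)])
        }
        if (mm <= max_mm) {
          pos <- if (e$strand == "+") q else e$L - q - m + 2
          hits[[length(hits) + 1]] <- data.frame(
            ref_id = e$ref_id, position = pos, strand = e$strand,
            aligned_length = m, mismatches = mm, trim_step = step,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      idrank <- integer(length(h$ref_id))
      idrank <- match(h$ref_id, sort(unique(h$ref_id), method = "radix"))
      ord <- order(h$mismatches, idrank, h$position, h$strand == "-")
      h <- h[ord, , drop = FALSE][seq_len(min(k, nrow(h))), , drop = FALSE]
      rownames(h) <- NULL
      return(list(records = h, status = "aligned"))
    }
  }
  list(records = NULL, status = "unaligned")
}

# normalize an implementation record data frame for comparison
norm_records <- function(df) {
  df <- df[, c("ref_id", "position", "strand", "aligned_length",
               "mismatches", "trim_step")]
  rownames(df) <- NULL
  df
}
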