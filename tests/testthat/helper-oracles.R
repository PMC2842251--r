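# Independent oracles and fixture builders shared across tests.

# pair code of motif base x against half base y; NA if unpairable
.pair_ok <- function(x, y) {
  key <- paste0(x, y)
  key %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}
.pair_gu <- function(x, y) paste0(x, y) %in% c("GU", "UG")

# Exhaustive-enumeration oracle for the longest complementary stretch.
# Enumerates every contiguous window on every anti-diagonal (a + j constant,
# motif[a] pairing half[j]) and selects the best under the documented
# tie-break (longest, fewest GU, smallest motif start, smallest half start).
# Deliberately structured differently from the implementation (full window
# enumeration instead of a sliding window).
oracle_stretch <- function(motif, half, max_gu) {
  m <- strsplit(motif, "", fixed = TRUE)[[1]]
  h <- strsplit(half, "", fixed = TRUE)[[1]]
  nm <- length(m); nh <- length(h)
  best <- c(len = 0L, gu = 0L, ms = NA_integer_, hs = NA_integer_)
  for (s in 0:(nm + nh - 2)) {
    a <- max(0, s - (nh - 1)):min(nm - 1, s)
    ok <- .pair_ok(m[a + 1], h[s - a + 1])
    gu <- .pair_gu(m[a + 1], h[s - a + 1])
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      cg <- c(0, cumsum(gu[idx]))
      win <- expand.grid(i1 = seq_along(idx), i2 = seq_along(idx))
      win <- win[win$i2 >= win$i1, ]
      win$len <- win$i2 - win$i1 + 1
      win$gu <- cg[win$i2 + 1] - cg[win$i1]
      win <- win[win$gu <= max_gu, ]
      if (!nrow(win)) next
      win$ms <- a[idx[win$i1]]
      win$hs <- s - a[idx[win$i2]]
      o <- order(-win$len, win$gu, win$ms, win$hs)[1]
      cand <- c(len = win$len[o], gu = win$gu[o], ms = win$ms[o],
                hs = win$hs[o])
      if (cand["len"] > best["len"] ||
          (cand["len"] == best["len"] && best["len"] > 0 &&
           (cand["gu"] < best["gu"] ||
            (cand["gu"] == best["gu"] &&
             (cand["ms"] < best["ms"] ||
              (cand["ms"] == best["ms"] && cand["hs"] < best["hs"])))))) {
        best <- cand
      }
    }
  }
  best
}

random_rna_string <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# fully paired duplex energy via the RNAduplex command-line tool (Turner
# 2004 scale, includes the +4.10 initiation term); both strands equal
# length and perfectly complementary so the MFE structure is the full helix
rnaduplex_dg <- function(strand1, strand2) {
  out <- system2("RNAduplex", stdout = TRUE, stderr = FALSE,
                 input = paste0(strand1, "\n", strand2))
  as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", out[1]))
}

write_tmp_fasta <- function(headers, seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

extdata <- function(file) system.file("extdata", file, package = "uaugscan")

# small catalog used by several tests
toy_partition <- function() {
  recs <- mirna_records(
    c("hsa-let-7d", "mmu-let-7d", "hsa-miR-944"),
    c("AGAGGUAGUAGGUUGCAUAGUU", "AGAGGUAGUAGGUUGCAUAGUU",
      "AAAUUAUUGUACAUCGGAUGAG"))
  classify_mirna_conservation(recs[recs$species_prefix == "hsa", ], recs)
}
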