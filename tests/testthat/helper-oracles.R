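# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive exhaustive scanning, not the package's own
# code paths.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random valid CDS: ATG + random codons + TAA
random_cds <- function(n_codons = 10) {
  body <- replicate(n_codons, random_dna(3))
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

random_leader_context <- function(max_leader = 300, min_leader = 0,
                                  max_cds_codons = 30) {
  leader <- random_dna(sample(min_leader:max_leader, 1))
  leader_context("rnd", leader, random_cds(sample(1:max_cds_codons, 1)))
}

# exhaustive uORF scan: test every leader position for ATG and every
# downstream triplet for stop membership
oracle_annotate <- function(ctx, min_length_nt = 6,
                            include_incomplete = FALSE) {
  tx <- strsplit(ctx$transcript_seq, "")[[1]]
  n <- length(tx)
  matg <- ctx$matg_pos
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (p in seq_len(matg - 1)) {
    if (p + 2 > n) next
    if (paste(tx[p:(p + 2)], collapse = "") != "ATG") next
    stop_start <- NA
    q <- p + 3
    while (q + 2 <= n) {
      if (paste(tx[q:(q + 2)], collapse = "") %in% stops) {
        stop_start <- q
        break
      }
      q <- q + 3
    }
    if (is.na(stop_start)) {
      utype <- "INCOMPLETE"; stop_end <- NA; len <- NA
    } else {
      stop_end <- stop_start + 2
      len <- stop_end - p + 1
      utype <- if (stop_end < matg) "TYPE1"
               else if ((p - matg) %% 3 == 0) "TYPE3"
               else "TYPE2"
    }
    keep <- if (utype == "INCOMPLETE") include_incomplete
            else len >= min_length_nt
    if (keep)
      rows[[length(rows) + 1]] <-
        data.frame(uatg_pos = p, stop_start = stop_start,
                   stop_end = stop_end, length_nt = len, utype = utype)
  }
  if (length(rows) == 0)
    return(data.frame(uatg_pos = integer(0), stop_start = integer(0),
                      stop_end = integer(0), length_nt = integer(0),
                      utype = character(0)))
  do.call(rbind, rows)
}

# exhaustive window scan for 20-mer + NGG on both strands
oracle_protospacers <- function(seq) {
  n <- nchar(seq)
  rc1 <- function(b) chartr("ACGT", "TGCA", b)
  out <- list()
  for (s in seq_len(max(n - 19, 0))) {
    e <- s + 19
    if (e + 3 <= n) {
      pam <- substr(seq, e + 1, e + 3)
      if (substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G")
        out[[length(out) + 1]] <-
          data.frame(protospacer = substr(seq, s, e), strand = "+",
                     start = s, end = e)
    }
    if (s >= 4) {
      pam_plus <- substr(seq, s - 3, s - 1)   # minus-strand PAM, rc
      if (substr(pam_plus, 1, 1) == "C" && substr(pam_plus, 2, 2) == "C") {
        win <- substr(seq, s, e)
        rc <- paste(rev(vapply(strsplit(win, "")[[1]], rc1, "")),
                    collapse = "")
        out[[length(out) + 1]] <-
          data.frame(protospacer = rc, strand = "-", start = s, end = e)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(protospacer = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), ]
}

# affine-gap global alignment score by exhaustive state recursion
# (Gotoh-style three-state dynamic program, written independently);
# gap run of length L costs open + L * extend
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               open = 5, extend = 1) {
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  M <- matrix(NEG, na + 1, nb + 1)  # last op aligned a[i] with b[j]
  X <- matrix(NEG, na + 1, nb + 1)  # last op gap in b (consumed a[i])
  Y <- matrix(NEG, na + 1, nb + 1)  # last op gap in a (consumed b[j])
  M[1, 1] <- 0
  for (i in 0:na) for (j in 0:nb) {
    if (i == 0 && j == 0) next
    ii <- i + 1; jj <- j + 1
    if (i > 0 && j > 0) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[ii, jj] <- max(M[ii - 1, jj - 1], X[ii - 1, jj - 1],
                       Y[ii - 1, jj - 1]) + s
    }
    if (i > 0)
      X[ii, jj] <- max(M[ii - 1, jj] - open - extend,
                       X[ii - 1, jj] - extend,
                       Y[ii - 1, jj] - open - extend)
    if (j > 0)
      Y[ii, jj] <- max(M[ii, jj - 1] - open - extend,
                       X[ii, jj - 1] - open - extend,
                       Y[ii, jj - 1] - extend)
  }
  max(M[na + 1, nb + 1], X[na + 1, nb + 1], Y[na + 1, nb + 1])
}

# full enumeration of every alignment path (tiny inputs only); confirms
# the state recursion above
enumerate_align_score <- function(a, b, match = 2, mismatch = -3,
                                  open = 5, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, acc)
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, "M",
          acc + if (av[i] == bv[j]) match else mismatch)
    if (i <= length(av))
      rec(i + 1, j, "X",
          acc - extend - if (last == "X") 0 else open)
    if (j <= length(bv))
      rec(i, j + 1, "Y",
          acc - extend - if (last == "Y") 0 else open)
  }
  rec(1, 1, "M", 0)
  best
}

# random non-overlapping edit set on a reference of length n
random_edit_set <- function(n, n_edits = 3) {
  taken <- logical(n)
  ins_pos <- integer(0)
  rows <- list()
  tries <- 0
  while (length(rows) < n_edits && tries < 50) {
    tries <- tries + 1
    kind <- sample(c("DEL", "INS", "SUB"), 1)
    len <- sample(1:4, 1)
    if (kind == "INS") {
      p <- sample(n, 1)
      if (p %in% ins_pos || (p > 1 && taken[p - 1] && taken[p])) next
      ins_pos <- c(ins_pos, p)
      rows[[length(rows) + 1]] <- edit_ins(p, random_dna(len))
    } else {
      if (len > n) next
      p <- sample(n - len + 1, 1)
      if (any(taken[p:(p + len - 1)])) next
      if (any(ins_pos >= p & ins_pos <= p + len - 1)) next
      taken[p:(p + len - 1)] <- TRUE
      rows[[length(rows) + 1]] <-
        if (kind == "DEL") edit_del(p, len)
        else edit_sub(p, random_dna(len))
    }
  }
  if (length(rows) == 0) return(empty_edit_set())
  es <- do.call(edit_set, rows)
  es[order(es$pos), ]
}
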